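# Per-sample signal quality control.
#
# Four metrics drive the exclusion cascade: probe call rate, derivative
# log ratio spread (DLRS), GC-wave factor, and LRR standard deviation.
# The cascade order is call rate -> DLRS -> wave -> LRR SD, and each
# excluded sample is labeled with the first rule it fails.

#' Derivative log ratio spread (DLRS)
#'
#' The SD of first differences of LRR between adjacent probes —
#' computed within each chromosome and pooled across chromosomes —
#' divided by sqrt(2). For i.i.d. noise of SD sigma the differences
#' have variance 2 sigma^2, so DLRS recovers sigma while being
#' insensitive to the slow-varying CNV signal itself. Sample SD uses
#' the n - 1 denominator; missing probes are dropped before
#' differencing.
#'
#' @param sample_lrr Per-probe LRR values ordered as the map.
#' @param map SNP map aligned with `sample_lrr` (used for chromosome
#'   boundaries); omit for a single-chromosome vector.
#' @return Non-negative scalar.
#' @export
compute_dlrs <- function(sample_lrr, map = NULL) {
  chrom <- if (is.null(map)) rep("1", length(sample_lrr)) else map$chrom
  stopifnot(length(chrom) == length(sample_lrr))
  diffs <- unlist(lapply(split(sample_lrr, chrom), function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2L) diff(x) else numeric()
  }), use.names = FALSE)
  if (length(diffs) < 1L)
    stop("DLRS undefined: no chromosome has >= 2 non-missing probes")
  stats::sd(diffs) / sqrt(2)
}

#' GC-wave factor
#'
#' Pearson correlation between a sample's per-probe LRR and the probe
#' GC fraction, sign preserved. Long-range intensity "waves" track
#' local GC content, so a large |wave factor| flags a wavy sample.
#'
#' @param sample_lrr Per-probe LRR values ordered as the map.
#' @param map SNP map with a non-constant `gc_frac` column.
#' @return Correlation in \[-1, 1\].
#' @export
compute_wave_factor <- function(sample_lrr, map) {
  stopifnot(length(sample_lrr) == nrow(map))
  ok <- !is.na(sample_lrr) & !is.na(map$gc_frac)
  if (sum(ok) < 3L) stop("wave factor undefined: fewer than 3 usable probes")
  if (stats::sd(map$gc_frac[ok]) == 0)
    stop("wave factor undefined: gc_frac is constant")
  if (stats::sd(sample_lrr[ok]) == 0) return(0)
  stats::cor(sample_lrr[ok], map$gc_frac[ok])
}

#' Compute the QC report for every sample of a cohort
#'
#' @param lrr Probes x samples LRR matrix in map order.
#' @param map SNP map aligned with the matrix rows.
#' @return A `data.frame` with one row per sample: `sample_id`,
#'   `call_rate`, `dlrs`, `wave_factor`, `lrr_sd`.
#' @export
sample_qc_metrics <- function(lrr, map) {
  stopifnot(nrow(lrr) == nrow(map))
  data.frame(
    sample_id = colnames(lrr),
    call_rate = colMeans(!is.na(lrr)),
    dlrs = apply(lrr, 2L, compute_dlrs, map = map),
    wave_factor = apply(lrr, 2L, compute_wave_factor, map = map),
    lrr_sd = apply(lrr, 2L, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' QC thresholds
#'
#' Defaults follow conventional array-QC practice: call rate >= 0.98
#' and LRR SD < 0.30 as fixed cutoffs; DLRS flagged when above the
#' cohort mean + 3 SD (or a fixed `dlrs_max` when supplied); wave
#' factor flagged when |r| > 0.10.
#'
#' @param call_rate_min Minimum call rate (inclusive).
#' @param dlrs_max Fixed DLRS cutoff, or `NA` for mean + `dlrs_nsd` SD.
#' @param dlrs_nsd SD multiplier for the cohort-relative DLRS rule.
#' @param wave_max Maximum |wave factor|.
#' @param lrr_sd_max LRR SD strict upper bound.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(call_rate_min = 0.98, dlrs_max = NA,
                          dlrs_nsd = 3, wave_max = 0.10,
                          lrr_sd_max = 0.30) {
  list(call_rate_min = call_rate_min, dlrs_max = dlrs_max,
       dlrs_nsd = dlrs_nsd, wave_max = wave_max, lrr_sd_max = lrr_sd_max)
}

#' Apply the sample-exclusion cascade
#'
#' Rules are applied in order: call rate, DLRS, wave factor, LRR SD.
#' A sample is excluded with the first rule it fails; `excluded` is
#' `TRUE` exactly when `exclusion_reason` is non-empty.
#'
#' @param reports Metric table from [sample_qc_metrics()].
#' @param thresholds A [qc_thresholds()] list.
#' @return `reports` with `excluded` and `exclusion_reason` columns
#'   added, plus attributes `kept` and `excluded` holding the sample id
#'   partition.
#' @export
apply_qc_filters <- function(reports, thresholds = qc_thresholds()) {
  th <- thresholds
  dlrs_cut <- if (is.na(th$dlrs_max)) {
    mean(reports$dlrs) + th$dlrs_nsd * stats::sd(reports$dlrs)
  } else th$dlrs_max
  if (is.na(dlrs_cut)) dlrs_cut <- Inf   # single-sample cohort: no SD
  reason <- rep("", nrow(reports))
  reason[reports$lrr_sd >= th$lrr_sd_max] <- "lrr_sd"
  reason[abs(reports$wave_factor) > th$wave_max] <- "wave_factor"
  reason[reports$dlrs > dlrs_cut] <- "dlrs"
  reason[reports$call_rate < th$call_rate_min] <- "call_rate"
  reports$excluded <- reason != ""
  reports$exclusion_reason <- reason
  structure(reports,
            kept = reports$sample_id[!reports$excluded],
            excluded = reports$sample_id[reports$excluded],
            dlrs_cutoff = dlrs_cut)
}

#' Write the QC report TSV
#'
#' @param report Output of [apply_qc_filters()].
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
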