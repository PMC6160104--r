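# V_ST scan for population-differentiated CNV regions.
#
# V_ST is an F_ST analog on continuous intensity data. At one SNP
# probe, for two populations with n1 and n2 non-missing LRR values,
#
#   V_T = Var(pooled values)                 (total variance)
#   V_S = (n1 V1 + n2 V2) / (n1 + n2)        (size-weighted within)
#   V_ST = (V_T - V_S) / V_T, clamped to [0, 1]
#
# with population (divide-by-n) variances throughout, which makes
# V_ST exactly 0 when both populations hold the same multiset of
# values. Per-SNP values within a region are averaged into the
# region's mean V_ST.

pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

#' Per-SNP V_ST between two populations
#'
#' @param lrr_pop1,lrr_pop2 LRR values at one probe; `NA`s are dropped
#'   and each population must retain >= 2 values.
#' @return The clamped V_ST in \[0, 1\]; the raw (possibly negative)
#'   value is attached as attribute `"raw"`. A zero total variance
#'   returns 0.
#' @export
snp_vst <- function(lrr_pop1, lrr_pop2) {
  x1 <- lrr_pop1[!is.na(lrr_pop1)]
  x2 <- lrr_pop2[!is.na(lrr_pop2)]
  if (length(x1) < 2L || length(x2) < 2L)
    stop("V_ST undefined: each population needs >= 2 non-missing values")
  n1 <- length(x1); n2 <- length(x2)
  v_t <- pop_var(c(x1, x2))
  v_s <- (n1 * pop_var(x1) + n2 * pop_var(x2)) / (n1 + n2)
  if (v_t == 0) return(structure(0, raw = 0))
  raw <- (v_t - v_s) / v_t
  structure(min(max(raw, 0), 1), raw = raw)
}

#' Mean V_ST of one CNV region
#'
#' Evaluates [snp_vst()] at every map probe whose position falls in
#' the closed interval `[start, end]` of the region and averages the
#' per-SNP values. Probes failing the per-population >= 2 values
#' precondition are skipped and counted.
#'
#' @param region One-row region table (or list with `chrom`, `start`,
#'   `end`, `region_id`).
#' @param lrr Probes x samples LRR matrix in map order.
#' @param map SNP map aligned with `lrr`.
#' @param manifest Population manifest.
#' @param pair Character vector of the two population names.
#' @return A list of class `vst_result`: `region_id`, `pair`,
#'   `mean_vst`, `mean_raw`, `snp_vst` (named per-probe vector),
#'   `n_snps` (used), `n_skipped`.
#' @export
region_vst <- function(region, lrr, map, manifest, pair) {
  stopifnot(length(pair) == 2L)
  idx <- which(map$chrom == region$chrom &
                 map$pos >= region$start & map$pos <= region$end)
  if (!length(idx))
    stop("region ", region$region_id, " overlaps no probe in the map")
  s1 <- manifest$sample_id[manifest$population == pair[1L]]
  s2 <- manifest$sample_id[manifest$population == pair[2L]]
  vals <- raws <- stats::setNames(rep(NA_real_, length(idx)),
                                  map$probe_id[idx])
  for (k in seq_along(idx)) {
    v <- tryCatch(snp_vst(lrr[idx[k], s1], lrr[idx[k], s2]),
                  error = function(e) NULL)
    if (!is.null(v)) {
      vals[k] <- as.numeric(v)
      raws[k] <- attr(v, "raw")
    }
  }
  used <- !is.na(vals)
  if (!any(used))
    stop("region ", region$region_id, ": no probe with enough data")
  structure(list(region_id = region$region_id, pair = pair,
                 mean_vst = mean(vals[used]),
                 mean_raw = mean(raws[used]),
                 snp_vst = vals[used], n_snps = sum(used),
                 n_skipped = sum(!used)),
            class = "vst_result")
}

#' Pairwise V_ST scan over CNV regions
#'
#' For each population pair the scan restricts to regions carried by
#' at least `min_carriers` individuals within each of the two
#' populations, computes the mean V_ST per region, and flags
#' differentiated regions under two thresholding rules:
#'
#' * `top5pct` — at or above the 95th percentile of the scanned mean
#'   V_ST values;
#' * `mean2sd` — strictly above mean + 2 SD of the scanned values.
#'
#' Both thresholds are always reported; `rule` selects which one sets
#' the `significant` flag.
#'
#' @param regions Region table.
#' @param lrr Probes x samples LRR matrix in map order.
#' @param map SNP map.
#' @param calls CNV call table (defines carriers for the filter).
#' @param manifest Population manifest.
#' @param pairs List of 2-vectors of population names; default all
#'   pairs in the manifest.
#' @param min_carriers Within-population carrier threshold (>= 1).
#' @param rule `"mean2sd"` (default) or `"top5pct"`.
#' @return A `data.frame` with one row per (region, pair): `region_id`,
#'   `chrom`, `start`, `end`, `pop1`, `pop2`, `n_snps`, `mean_vst`,
#'   `mean_raw`, `threshold_top5pct`, `threshold_mean2sd`,
#'   `sig_top5pct`, `sig_mean2sd`, `significant`, `threshold_used`.
#' @export
vst_scan <- function(regions, lrr, map, calls, manifest, pairs = NULL,
                     min_carriers = 5L, rule = c("mean2sd", "top5pct")) {
  rule <- match.arg(rule)
  if (is.null(pairs)) {
    pops <- unique(manifest$population)
    pairs <- utils::combn(pops, 2L, simplify = FALSE)
  }
  pres <- build_cnv_matrix(regions, calls, manifest, "presence")
  out <- list()
  for (pr in pairs) {
    flt <- filter_min_carriers(pres, k = min_carriers,
                               per_population = TRUE, populations = pr)
    scan_regions <- flt$regions
    if (nrow(scan_regions) == 0L) next
    if (rule == "top5pct" && nrow(scan_regions) < 20L)
      warning("fewer than 20 regions scanned for pair ",
              paste(pr, collapse = " vs "),
              "; the top-5% quantile threshold is unstable")
    res <- lapply(seq_len(nrow(scan_regions)), function(j) {
      region_vst(scan_regions[j, ], lrr, map, manifest, pr)
    })
    mv <- vapply(res, `[[`, numeric(1), "mean_vst")
    thr_q <- stats::quantile(mv, 0.95, names = FALSE)
    thr_m <- mean(mv) + 2 * stats::sd(mv)
    if (is.na(thr_m)) thr_m <- Inf   # single region: SD undefined
    sig_q <- mv >= thr_q
    sig_m <- mv > thr_m
    out[[length(out) + 1L]] <- data.frame(
      region_id = scan_regions$region_id,
      chrom = scan_regions$chrom,
      start = scan_regions$start,
      end = scan_regions$end,
      pop1 = pr[1L], pop2 = pr[2L],
      n_snps = vapply(res, `[[`, numeric(1), "n_snps"),
      mean_vst = mv,
      mean_raw = vapply(res, `[[`, numeric(1), "mean_raw"),
      threshold_top5pct = thr_q,
      threshold_mean2sd = thr_m,
      sig_top5pct = sig_q,
      sig_mean2sd = sig_m,
      significant = if (rule == "mean2sd") sig_m else sig_q,
      threshold_used = if (rule == "mean2sd") thr_m else thr_q,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      pop1 = character(), pop2 = character(),
                      n_snps = integer(), mean_vst = numeric(),
                      mean_raw = numeric(), threshold_top5pct = numeric(),
                      threshold_mean2sd = numeric(),
                      sig_top5pct = logical(), sig_mean2sd = logical(),
                      significant = logical(), threshold_used = numeric(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
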