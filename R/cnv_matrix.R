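# Individual x CNVR matrices.
#
# Two encodings mirror the two cross-population analyses:
#   presence     — 1 iff the sample has >= 1 call overlapping the region
#   copy_number  — the total copy number of the sample's overlapping
#                  call, 2 ("normal state") when it has none
# so presence == (copy_number != 2) cell-wise on the same inputs.

#' Build an individual x CNVR matrix
#'
#' When a sample has several calls overlapping one (complex) region the
#' copy-number code is resolved deterministically: the call covering
#' the most bp of the region wins; ties go to the more extreme state
#' (larger |tcn - 2|); an exact tie prefers the deletion.
#'
#' @param regions Region table from [merge_calls_to_regions()].
#' @param calls CNV call table; every `sample_id` must appear in the
#'   manifest.
#' @param manifest Population manifest; its sample order defines the
#'   matrix row order and samples without calls get all-absent rows.
#' @param encoding `"presence"` (codes 0/1) or `"copy_number"`
#'   (codes 0..4).
#' @return An object of class `cnv_matrix`: a list with `values`
#'   (samples x regions integer matrix), `samples`, `region_ids`,
#'   `regions` (the region table), `encoding`, `manifest`.
#' @export
build_cnv_matrix <- function(regions, calls, manifest,
                             encoding = c("presence", "copy_number")) {
  encoding <- match.arg(encoding)
  validate_cnv_calls(calls)
  orphan <- setdiff(unique(calls$sample_id), manifest$sample_id)
  if (length(orphan))
    stop("sample(s) in calls absent from manifest: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  samples <- manifest$sample_id
  vals <- matrix(if (encoding == "presence") 0L else 2L,
                 nrow = length(samples), ncol = nrow(regions),
                 dimnames = list(samples, regions$region_id))
  for (j in seq_len(nrow(regions))) {
    m <- regions$member_calls[[j]]
    if (!length(m)) next
    if (encoding == "presence") {
      vals[unique(calls$sample_id[m]), j] <- 1L
    } else {
      for (sid in unique(calls$sample_id[m])) {
        mine <- m[calls$sample_id[m] == sid]
        vals[sid, j] <- resolve_tcn(calls[mine, , drop = FALSE],
                                    regions$start[j], regions$end[j])
      }
    }
  }
  structure(list(values = vals, samples = samples,
                 region_ids = regions$region_id, regions = regions,
                 encoding = encoding, manifest = manifest),
            class = "cnv_matrix")
}

# Tie rule for multiple same-sample calls in one region: most covered
# bp, then larger |tcn - 2|, then deletion.
resolve_tcn <- function(calls, region_start, region_end) {
  if (nrow(calls) == 1L) return(calls$tcn)
  cov <- pmin(calls$end, region_end) - pmax(calls$start, region_start) + 1L
  extremity <- abs(calls$tcn - 2L)
  is_del <- calls$tcn < 2L
  pick <- order(-cov, -extremity, -is_del)[1L]
  calls$tcn[pick]
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("cnv_matrix: %d samples x %d regions (encoding: %s)\n",
              nrow(x$values), ncol(x$values), x$encoding))
  invisible(x)
}

#' @export
dim.cnv_matrix <- function(x) dim(x$values)

#' Keep regions with at least k carriers
#'
#' Carrier count is the number of samples with a non-neutral code in
#' the region. With `per_population = TRUE` a region must reach `k`
#' carriers within *every* population (the within-breed filter used
#' before cross-population analyses); otherwise `k` overall. The
#' sample set and the order of surviving regions are unchanged.
#'
#' @param mat A `cnv_matrix`.
#' @param k Minimum carrier count (>= 1), boundary inclusive.
#' @param per_population Apply the threshold within each population.
#' @param populations Optional subset of populations over which the
#'   per-population rule is enforced (default: all in the manifest).
#' @return A filtered `cnv_matrix`.
#' @export
filter_min_carriers <- function(mat, k = 5L, per_population = TRUE,
                                populations = NULL) {
  stopifnot(inherits(mat, "cnv_matrix"), k >= 1L)
  carried <- if (mat$encoding == "presence") mat$values == 1L
             else mat$values != 2L
  if (per_population) {
    pops <- populations %||% unique(mat$manifest$population)
    keep <- rep(TRUE, ncol(carried))
    for (p in pops) {
      rows <- mat$manifest$sample_id[mat$manifest$population == p]
      keep <- keep & colSums(carried[rows, , drop = FALSE]) >= k
    }
  } else {
    keep <- colSums(carried) >= k
  }
  subset_cnv_matrix(mat, keep)
}

subset_cnv_matrix <- function(mat, keep) {
  structure(list(values = mat$values[, keep, drop = FALSE],
                 samples = mat$samples,
                 region_ids = mat$region_ids[keep],
                 regions = mat$regions[keep, , drop = FALSE],
                 encoding = mat$encoding, manifest = mat$manifest),
            class = "cnv_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CNV matrix as TSV (samples in rows, regions in columns)
#'
#' @param mat A `cnv_matrix`.
#' @param path Output path.
#' @export
write_cnv_matrix <- function(mat, path) {
  df <- data.frame(sample_id = mat$samples, mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
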