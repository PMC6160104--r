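# Gene / QTL interval annotation of CNV regions.

#' Annotate CNV regions against a feature track
#'
#' A feature is assigned to a region iff the two intervals share at
#' least 1 bp (1-based inclusive coordinates on the same assembly).
#' No nearest-feature fallback is applied.
#'
#' @param regions Region table (or any data frame with `region_id`,
#'   `chrom`, `start`, `end`).
#' @param track Annotation track from [read_annotation_track()].
#' @return `regions` with list-columns `genes` and `qtls` (feature ids,
#'   ordered by feature start) and counts `n_genes`, `n_qtls` added.
#' @export
annotate_regions <- function(regions, track) {
  genes <- vector("list", nrow(regions))
  qtls <- vector("list", nrow(regions))
  for (i in seq_along(genes)) genes[[i]] <- qtls[[i]] <- character()
  for (ch in unique(regions$chrom)) {
    qi <- which(regions$chrom == ch)
    si <- which(track$chrom == ch)
    if (!length(si)) next
    si <- si[order(track$start[si])]
    q <- IRanges::IRanges(regions$start[qi], regions$end[qi])
    s <- IRanges::IRanges(track$start[si], track$end[si])
    h <- IRanges::findOverlaps(q, s, minoverlap = 1L)
    if (!length(h)) next
    qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
    for (k in seq_along(qh)) {
      ri <- qi[qh[k]]; fi <- si[sh[k]]
      if (track$feature_class[fi] == "gene") {
        genes[[ri]] <- c(genes[[ri]], track$feature_id[fi])
      } else {
        qtls[[ri]] <- c(qtls[[ri]], track$feature_id[fi])
      }
    }
  }
  regions$genes <- genes
  regions$qtls <- qtls
  regions$n_genes <- lengths(genes)
  regions$n_qtls <- lengths(qtls)
  regions
}

#' Gene content summary of annotated regions
#'
#' @param annotated Output of [annotate_regions()].
#' @param digits Rounding for the reported percentages.
#' @return A list: `n_with_genes`, `pct_with_genes`, `n_without`,
#'   `pct_without`, `n_total`; with/without counts sum to the total.
#' @export
gene_content_summary <- function(annotated, digits = 1L) {
  n <- nrow(annotated)
  if (n == 0L) stop("empty region set: no gene content to summarize")
  nw <- sum(annotated$n_genes >= 1L)
  list(n_with_genes = nw,
       pct_with_genes = round(100 * nw / n, digits),
       n_without = n - nw,
       pct_without = round(100 * (n - nw) / n, digits),
       n_total = n)
}

#' Write annotated regions as TSV
#'
#' @param annotated Output of [annotate_regions()].
#' @param path Output path.
#' @export
write_annotated_regions <- function(annotated, path) {
  df <- annotated[setdiff(names(annotated),
                          c("genes", "qtls", "carriers", "member_calls"))]
  df$genes <- vapply(annotated$genes, paste, character(1), collapse = ";")
  df$qtls <- vapply(annotated$qtls, paste, character(1), collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
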