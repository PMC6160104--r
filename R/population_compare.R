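# Cross-population CNVR comparison.
#
# The counting unit is focal-set regions: a region of population A is
# "shared" with B when at least one B region overlaps it by >= 1 bp.
# Counts are therefore not symmetric (|A shared with B| need not equal
# |B shared with A|) and both directions are reported.

overlaps_any <- function(query, subject) {
  # per-chromosome >= 1 bp overlap indicator for each query region
  hit <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    q <- IRanges::IRanges(query$start[qi], query$end[qi])
    s <- IRanges::IRanges(subject$start[si], subject$end[si])
    hit[qi] <- IRanges::overlapsAny(q, s, minoverlap = 1L)
  }
  hit
}

#' Overlap one region set against another
#'
#' @param set_a,set_b Region tables ([merge_calls_to_regions()]).
#' @return A list: `shared` / `unique` (the partition of `set_a`),
#'   `n_shared`, `fraction` (= n_shared / nrow(set_a)),
#'   `shared_length_bp` (total bp of the shared focal regions), and
#'   `pairs` (data frame of overlapping region-id pairs).
#' @export
overlap_regions <- function(set_a, set_b) {
  is_shared <- overlaps_any(set_a, set_b)
  pairs <- do.call(rbind, lapply(unique(set_a$chrom), function(ch) {
    qi <- which(set_a$chrom == ch)
    si <- which(set_b$chrom == ch)
    if (!length(si) || !length(qi)) return(NULL)
    q <- IRanges::IRanges(set_a$start[qi], set_a$end[qi])
    s <- IRanges::IRanges(set_b$start[si], set_b$end[si])
    h <- IRanges::findOverlaps(q, s, minoverlap = 1L)
    if (!length(h)) return(NULL)
    data.frame(a = set_a$region_id[qi][S4Vectors::queryHits(h)],
               b = set_b$region_id[si][S4Vectors::subjectHits(h)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
  list(shared = set_a[is_shared, , drop = FALSE],
       unique = set_a[!is_shared, , drop = FALSE],
       n_shared = sum(is_shared),
       fraction = if (nrow(set_a)) sum(is_shared) / nrow(set_a) else NA_real_,
       shared_length_bp = sum(as.numeric(set_a$length_bp[is_shared])),
       pairs = pairs)
}

#' Venn partition of 2-3 population region sets
#'
#' Each focal region is labeled by the subset of the *other*
#' populations whose region sets overlap it (>= 1 bp); per-population
#' cell counts over those labels always sum to the population's total
#' region count. A region is "all-shared" when it overlaps every other
#' population's set.
#'
#' @param sets Named list (2 or 3 populations) of region tables.
#' @return A list: `cells` (per focal population, a table of counts by
#'   overlap label, `"."` = unique), `unique_counts`, `all_shared`
#'   (per-population count of regions overlapping all others),
#'   `pairwise` (matrix: `pairwise[a, b]` = regions of a shared with
#'   b), `pairwise_fraction`, `shared_length_bp` (same shape).
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L)
    stop("venn_partition supports 2 or 3 populations")
  pops <- names(sets)
  stopifnot(!is.null(pops), !anyDuplicated(pops))
  cells <- list()
  unique_counts <- all_shared <- stats::setNames(integer(length(pops)), pops)
  pw <- pwf <- pwl <- matrix(NA_real_, length(pops), length(pops),
                             dimnames = list(pops, pops))
  for (a in pops) {
    others <- setdiff(pops, a)
    ind <- sapply(others, function(b) overlaps_any(sets[[a]], sets[[b]]))
    ind <- matrix(ind, nrow = nrow(sets[[a]]),
                  dimnames = list(NULL, others))
    label <- apply(ind, 1L, function(r) {
      hit <- others[r]
      if (length(hit)) paste(hit, collapse = "+") else "."
    })
    cells[[a]] <- table(factor(label, levels = c(
      ".", others, if (length(others) == 2L) paste(others, collapse = "+"))))
    unique_counts[a] <- sum(label == ".")
    all_shared[a] <- sum(rowSums(ind) == length(others))
    for (b in others) {
      ov <- overlap_regions(sets[[a]], sets[[b]])
      pw[a, b] <- ov$n_shared
      pwf[a, b] <- ov$fraction
      pwl[a, b] <- ov$shared_length_bp
    }
  }
  list(cells = cells, unique_counts = unique_counts,
       all_shared = all_shared, pairwise = pw,
       pairwise_fraction = pwf, shared_length_bp = pwl)
}
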