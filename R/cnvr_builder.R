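# CNV region construction and descriptive summaries.
#
# A CNVR is the union of per-sample CNV calls that overlap by at least
# 1 bp (transitively), computed per chromosome on 1-based inclusive
# intervals: [a, b] and [c, d] merge iff a <= d and c <= b. Book-ended
# inclusive intervals sharing exactly one bp DO merge; adjacent
# intervals sharing zero bp do not.

#' Merge per-sample CNV calls into CNV regions
#'
#' Regions are the connected components of the >= 1 bp overlap graph
#' within each chromosome; a region's span is the union extent of its
#' member calls (mergeBed semantics). The result is sorted by
#' (chromosome, start).
#'
#' Region length is defined as `end - start` in bp.
#'
#' @param calls A validated CNV call table ([read_cnv_calls()]).
#' @return A `data.frame` with columns `region_id`, `chrom`, `start`,
#'   `end`, `length_bp`, `state` (gain / loss / complex), `n_carriers`,
#'   and list-columns `carriers` (distinct sample ids) and
#'   `member_calls` (row indices into `calls`).
#' @export
merge_calls_to_regions <- function(calls) {
  validate_cnv_calls(calls)
  if (nrow(calls) == 0L) return(empty_regions())
  pieces <- lapply(split(seq_len(nrow(calls)), calls$chrom), function(idx) {
    ir <- IRanges::IRanges(start = calls$start[idx], end = calls$end[idx])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    comp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    data.frame(
      chrom = calls$chrom[idx][1L],
      start = IRanges::start(red),
      end = IRanges::end(red),
      members = I(split(idx, comp)),
      stringsAsFactors = FALSE
    )
  })
  reg <- do.call(rbind, pieces)
  reg <- reg[order(chrom_rank(reg$chrom), reg$start), , drop = FALSE]
  out <- data.frame(
    region_id = sprintf("%s:%d-%d", reg$chrom, reg$start, reg$end),
    chrom = reg$chrom,
    start = reg$start,
    end = reg$end,
    length_bp = reg$end - reg$start,
    stringsAsFactors = FALSE
  )
  out$member_calls <- unname(as.list(reg$members))
  out$carriers <- lapply(out$member_calls,
                         function(m) sort(unique(calls$sample_id[m])))
  out$n_carriers <- lengths(out$carriers)
  out$state <- vapply(out$member_calls,
                      function(m) classify_state(calls$tcn[m]), character(1))
  rownames(out) <- NULL
  out[c("region_id", "chrom", "start", "end", "length_bp", "state",
        "n_carriers", "carriers", "member_calls")]
}

empty_regions <- function() {
  out <- data.frame(region_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    length_bp = integer(), state = character(),
                    n_carriers = integer(), stringsAsFactors = FALSE)
  out$carriers <- list()
  out$member_calls <- list()
  out
}

#' Classify a region state from member total copy numbers
#'
#' Gain if every member call is a duplication (tcn > 2), loss if every
#' member is a deletion (tcn < 2), complex when the region holds both.
#'
#' @param tcn Integer vector of member total copy numbers.
#' @return `"gain"`, `"loss"` or `"complex"`.
#' @export
classify_state <- function(tcn) {
  stopifnot(length(tcn) >= 1L)
  if (all(tcn > 2L)) "gain" else if (all(tcn < 2L)) "loss" else "complex"
}

#' Length class of a region
#'
#' Three half-open classes: \[1, 10) kb, \[10, 100) kb, and >= 100 kb.
#' Lengths below 1 kb are kept in the first class (they are flagged by
#' [summarize_regions()], not dropped).
#'
#' @param length_bp Region length(s) in bp.
#' @return Factor with levels `"1-10kb"`, `"10-100kb"`, `">100kb"`.
#' @export
assign_length_class <- function(length_bp) {
  cut(pmax(length_bp, 1e3), breaks = c(1e3, 1e4, 1e5, Inf),
      labels = c("1-10kb", "10-100kb", ">100kb"),
      right = FALSE, include.lowest = TRUE)
}

#' Frequency class of a region
#'
#' Carrier-count classes partitioning the positive integers:
#' singleton (1 individual), rare (2-4), moderately recurring (5-15),
#' recurring (>= 16). Carriers are distinct individuals; a subject
#' contributing several adjacent calls to one region counts once.
#'
#' @param n_carriers Carrier count(s), >= 1.
#' @return Factor with levels `"singleton"`, `"rare"`, `"moderate"`,
#'   `"recurring"`.
#' @export
assign_frequency_class <- function(n_carriers) {
  stopifnot(all(n_carriers >= 1L))
  cut(n_carriers, breaks = c(1, 2, 5, 16, Inf),
      labels = c("singleton", "rare", "moderate", "recurring"),
      right = FALSE, include.lowest = TRUE)
}

#' Descriptive summaries of calls and regions
#'
#' Produces the per-state region counts with mean/min/max length and
#' genome coverage (total region bp over total autosome bp), the
#' per-chromosome breakdown, and the length- and frequency-class
#' counts. Per-state counts always sum to the total.
#'
#' @param regions Region table from [merge_calls_to_regions()].
#' @param chrom_sizes Chromosome size table; every region chromosome
#'   must be present.
#' @return A list with elements `by_state`, `by_chrom`,
#'   `length_class_counts`, `frequency_class_counts`, `genome_bp`,
#'   `n_sub_kb` (regions shorter than 1 kb, flagged but kept).
#' @export
summarize_regions <- function(regions, chrom_sizes) {
  miss <- setdiff(unique(regions$chrom), chrom_sizes$chrom)
  if (length(miss))
    stop("missing chromosome size for: ", paste(miss, collapse = ", "))
  genome_bp <- sum(as.numeric(chrom_sizes$length_bp))
  state_levels <- c("gain", "loss", "complex")
  st <- factor(regions$state, levels = state_levels)
  one <- function(keep) {
    len <- regions$length_bp[keep]
    data.frame(n = sum(keep),
               mean_length = if (any(keep)) mean(len) else NA_real_,
               min_length = if (any(keep)) min(len) else NA_real_,
               max_length = if (any(keep)) max(len) else NA_real_,
               coverage = sum(as.numeric(len)) / genome_bp)
  }
  by_state <- do.call(rbind, lapply(state_levels, function(s) one(st == s)))
  by_state <- rbind(by_state, one(rep(TRUE, nrow(regions))))
  by_state <- data.frame(state = c(state_levels, "all"), by_state,
                         stringsAsFactors = FALSE)
  by_chrom <- do.call(rbind, lapply(chrom_sizes$chrom, function(ch) {
    keep <- regions$chrom == ch
    data.frame(chrom = ch, n = sum(keep),
               n_gain = sum(keep & st == "gain"),
               n_loss = sum(keep & st == "loss"),
               n_complex = sum(keep & st == "complex"),
               coverage = sum(as.numeric(regions$length_bp[keep])) /
                 chrom_sizes$length_bp[chrom_sizes$chrom == ch],
               stringsAsFactors = FALSE)
  }))
  list(
    by_state = by_state,
    by_chrom = by_chrom,
    length_class_counts = table(assign_length_class(regions$length_bp)),
    frequency_class_counts = table(assign_frequency_class(regions$n_carriers)),
    genome_bp = genome_bp,
    n_sub_kb = sum(regions$length_bp < 1e3)
  )
}
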