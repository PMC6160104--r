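# Readers and writers for the tables the pipeline touches.
#
# Coordinate convention: all in-memory intervals are 1-based inclusive
# (the PennCNV dialect). Only the BED export converts to 0-based
# half-open, and the sidecar TSV keeps the 1-based coordinates so that
# read(write(x)) round-trips exactly.

VALID_TCN <- c(0L, 1L, 3L, 4L)

#' Read a per-sample CNV call table
#'
#' Parses a tab-delimited call table in the PennCNV-style layout:
#' one row per CNV event with columns `sample_id`, `chrom`, `start`,
#' `end` (1-based inclusive), `tcn` (total copy number, one of 0/1/3/4)
#' and `n_snps` (number of supporting array probes).
#'
#' Calls are by definition non-neutral, so a row with `tcn = 2` is a
#' validation error, as is `start > end` or `n_snps < 1`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param chroms Optional character vector of admissible chromosome
#'   labels; when supplied, any other label is a validation error.
#' @return A `data.frame` of validated calls in file order with columns
#'   `sample_id`, `chrom`, `start`, `end`, `tcn`, `n_snps`.
#' @export
read_cnv_calls <- function(path, chroms = NULL) {
  df <- read_tsv_checked(path, c("sample_id", "chrom", "start", "end",
                                 "tcn", "n_snps"))
  if (nrow(df) == 0L) return(empty_calls())
  calls <- data.frame(
    sample_id = as.character(df$sample_id),
    chrom     = as.character(df$chrom),
    start     = parse_int(df$start, "start", path),
    end       = parse_int(df$end, "end", path),
    tcn       = parse_int(df$tcn, "tcn", path),
    n_snps    = parse_int(df$n_snps, "n_snps", path),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(calls, chroms = chroms)
  calls
}

#' Validate a CNV call data frame
#'
#' @param calls A data frame with the `read_cnv_calls()` columns.
#' @param chroms Optional admissible chromosome labels.
#' @return The input, invisibly, after passing all checks.
#' @export
validate_cnv_calls <- function(calls, chroms = NULL) {
  stopifnot(is.data.frame(calls))
  need <- c("sample_id", "chrom", "start", "end", "tcn", "n_snps")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("call table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(calls) == 0L) return(invisible(calls))
  bad <- which(!(calls$tcn %in% VALID_TCN))
  if (length(bad))
    stop("invalid total copy number (must be 0/1/3/4; 2 is the neutral ",
         "state and cannot be a call) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(calls$start > calls$end)
  if (length(bad))
    stop("start > end at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  if (any(calls$start < 1L))
    stop("coordinates are 1-based; start < 1 found")
  if (any(calls$n_snps < 1L))
    stop("n_snps must be >= 1")
  if (!is.null(chroms)) {
    unk <- setdiff(unique(calls$chrom), chroms)
    if (length(unk))
      stop("unknown chromosome label(s): ", paste(unk, collapse = ", "))
  }
  invisible(calls)
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = integer(), end = integer(), tcn = integer(),
             n_snps = integer(), stringsAsFactors = FALSE)
}

#' Read a SNP probe map
#'
#' The map carries one row per array probe: `probe_id`, `chrom`, `pos`
#' (1-based bp) and `gc_frac` (local GC fraction in \[0, 1\]). The map
#' is returned sorted by (chrom, pos); (chrom, pos) must be unique.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A sorted `data.frame` with the four map columns.
#' @export
read_snp_map <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "chrom", "pos", "gc_frac"))
  map <- data.frame(
    probe_id = as.character(df$probe_id),
    chrom    = as.character(df$chrom),
    pos      = parse_int(df$pos, "pos", path),
    gc_frac  = as.numeric(df$gc_frac),
    stringsAsFactors = FALSE
  )
  validate_snp_map(map)
}

#' @rdname read_snp_map
#' @param map A data frame with the map columns.
#' @export
validate_snp_map <- function(map) {
  stopifnot(all(c("probe_id", "chrom", "pos", "gc_frac") %in% names(map)))
  if (any(map$pos < 1L)) stop("probe positions are 1-based; pos < 1 found")
  if (any(map$gc_frac < 0 | map$gc_frac > 1, na.rm = TRUE))
    stop("gc_frac must lie in [0, 1]")
  if (anyDuplicated(map[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in SNP map")
  if (anyDuplicated(map$probe_id)) stop("duplicate probe_id in SNP map")
  map <- map[order(chrom_rank(map$chrom), map$pos), , drop = FALSE]
  rownames(map) <- NULL
  map
}

# Chromosomes sort numerically where the label is numeric ("1".."29"),
# alphabetically otherwise.
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), Inf, num) + as.numeric(factor(chrom)) * 1e-9
}

#' Read an LRR (or BAF) signal matrix keyed on a SNP map
#'
#' The file is tab-delimited with a `probe_id` first column and one
#' column per sample. The returned matrix is aligned to the map order
#' (chromosome, position ascending) regardless of file row order.
#' Literal `NA` / empty cells become `NA` and are excluded pairwise
#' from all downstream variance computations; they are never imputed.
#'
#' @param path Path to the signal file.
#' @param map A SNP map as returned by [read_snp_map()].
#' @return A numeric matrix, probes (rownames = `probe_id`, in map
#'   order) by samples.
#' @export
read_signal_matrix <- function(path, map) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "probe_id")
    stop("signal matrix must have 'probe_id' as its first column")
  ids <- as.character(df$probe_id)
  unknown <- setdiff(ids, map$probe_id)
  if (length(unknown))
    stop("probe(s) in signal file absent from map: ",
         paste(utils::head(unknown, 10L), collapse = ", "))
  mat <- as.matrix(df[-1L])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  # align to map order; probes missing from the file become all-NA rows
  out <- matrix(NA_real_, nrow = nrow(map), ncol = ncol(mat),
                dimnames = list(map$probe_id, colnames(mat)))
  out[ids, ] <- mat
  out
}

#' Write a signal matrix
#'
#' @param mat Probes x samples numeric matrix with probe ids as rownames.
#' @param path Output path.
#' @export
write_signal_matrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population manifest (sample to population assignment)
#'
#' @param path Tab-delimited file with columns `sample_id`, `population`.
#' @return A `data.frame`; `sample_id` is unique and every population
#'   has at least one sample.
#' @export
read_population_manifest <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "population"))
  man <- data.frame(sample_id = as.character(df$sample_id),
                    population = as.character(df$population),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(man$sample_id))
    stop("duplicate sample_id in population manifest")
  man
}

#' Read a chromosome size table
#'
#' @param path Tab-delimited file with columns `chrom`, `length_bp`.
#' @return A `data.frame` with positive lengths, one row per chromosome.
#' @export
read_chrom_sizes <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "length_bp"))
  cs <- data.frame(chrom = as.character(df$chrom),
                   length_bp = parse_int(df$length_bp, "length_bp", path),
                   stringsAsFactors = FALSE)
  if (any(cs$length_bp <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(cs$chrom)) stop("duplicate chromosome in size table")
  cs
}

#' Read a gene or QTL annotation track
#'
#' Tab-delimited, 1-based inclusive intervals: `chrom`, `start`, `end`,
#' `feature_id`, `feature_name`, `feature_class` (gene or qtl).
#'
#' @param path Path to the track file.
#' @return A validated `data.frame`.
#' @export
read_annotation_track <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "feature_id",
                                 "feature_name", "feature_class"))
  tr <- data.frame(chrom = as.character(df$chrom),
                   start = parse_int(df$start, "start", path),
                   end = parse_int(df$end, "end", path),
                   feature_id = as.character(df$feature_id),
                   feature_name = as.character(df$feature_name),
                   feature_class = as.character(df$feature_class),
                   stringsAsFactors = FALSE)
  if (any(tr$start > tr$end)) stop("annotation track has start > end")
  bad <- setdiff(unique(tr$feature_class), c("gene", "qtl"))
  if (length(bad))
    stop("feature_class must be 'gene' or 'qtl'; found: ",
         paste(bad, collapse = ", "))
  tr
}

#' Export CNV regions as BED plus a 1-based sidecar TSV
#'
#' BED uses 0-based half-open coordinates (`start - 1`, `end`); the
#' sidecar TSV (same path with extension `.tsv`) preserves the 1-based
#' inclusive coordinates, state and carrier count so that
#' [read_regions_tsv()] round-trips the region table exactly.
#'
#' @param regions A region table from [merge_calls_to_regions()].
#' @param path Output BED path.
#' @return The sidecar TSV path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart0\tend\tregion_id", con)
  if (nrow(regions)) {
    bed <- sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start - 1L,
                   regions$end, regions$region_id)
    writeLines(bed, con)
  }
  sidecar <- sub("\\.bed$", ".tsv", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".tsv")
  write_regions_tsv(regions, sidecar)
  invisible(sidecar)
}

#' Write / read the 1-based region sidecar TSV
#'
#' @param regions A region table.
#' @param path TSV path.
#' @export
write_regions_tsv <- function(regions, path) {
  df <- data.frame(
    region_id = regions$region_id,
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    length_bp = regions$length_bp,
    state = regions$state,
    n_carriers = regions$n_carriers,
    carriers = vapply(regions$carriers, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_tsv
#' @return For the reader, a region table with the list-column
#'   `carriers` reconstructed.
#' @export
read_regions_tsv <- function(path) {
  df <- read_tsv_checked(path, c("region_id", "chrom", "start", "end",
                                 "length_bp", "state", "n_carriers",
                                 "carriers"))
  df$chrom <- as.character(df$chrom)
  df$region_id <- as.character(df$region_id)
  df$state <- as.character(df$state)
  df$carriers <- strsplit(as.character(df$carriers), ";", fixed = TRUE)
  df
}

#' Convert between 1-based inclusive and BED half-open coordinates
#'
#' `to_bed()` maps `[start, end]` (1-based inclusive) to
#' `[start - 1, end)` (0-based half-open); `from_bed()` inverts it.
#' The two are exact inverses.
#'
#' @param start,end Interval bounds.
#' @return A two-column data frame of converted bounds.
#' @export
to_bed <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' @rdname to_bed
#' @export
from_bed <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

# -- internal helpers ---------------------------------------------------

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  df
}

parse_int <- function(x, col, path) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(path, ": malformed integer in column '", col, "' at data line ",
         bad[1L])
  out
}
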