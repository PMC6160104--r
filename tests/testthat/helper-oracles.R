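# Independent brute-force oracles and fixture builders shared across
# the suite. Oracles deliberately avoid the code paths they check.

# quadratic union-find over all interval pairs: the reference for
# >= 1 bp transitive merging on 1-based inclusive coordinates
oracle_merge <- function(calls) {
  out <- list()
  for (ch in sort(unique(calls$chrom))) {
    idx <- which(calls$chrom == ch)
    n <- length(idx)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j &&
          calls$start[idx[i]] <= calls$end[idx[j]] &&
          calls$start[idx[j]] <= calls$end[idx[i]]) {
        parent[find(i)] <- find(j)
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cc in unique(comp)) {
      m <- idx[comp == cc]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(calls$start[m]), end = max(calls$end[m]),
        n_members = length(m), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# all-pairs >= 1 bp overlap indicator of set A against set B
oracle_shared <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start <= a$end[i] & a$start[i] <= b$end)
  }, logical(1))
}

# direct evaluation of the V_ST formula with population variances
oracle_vst <- function(x1, x2) {
  pv <- function(x) mean((x - mean(x))^2)
  n1 <- length(x1); n2 <- length(x2)
  vt <- pv(c(x1, x2))
  vs <- (n1 * pv(x1) + n2 * pv(x2)) / (n1 + n2)
  if (vt == 0) return(0)
  min(max((vt - vs) / vt, 0), 1)
}

# random call table on a handful of chromosomes
random_calls <- function(n, chroms = c("1", "2", "3"), max_pos = 1e5,
                         samples = sprintf("S%02d", 1:12)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(5000L, n, replace = TRUE)
  data.frame(
    sample_id = sample(samples, n, replace = TRUE),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + len,
    tcn = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
    n_snps = sample(3:50, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# minimal region table from plain intervals (for overlap/annotation
# tests that do not need carriers)
interval_regions <- function(chrom, start, end) {
  data.frame(region_id = sprintf("%s:%d-%d", chrom, start, end),
             chrom = as.character(chrom), start = start, end = end,
             length_bp = end - start, state = "gain",
             n_carriers = 1L, stringsAsFactors = FALSE)
}

# two-population cohort with one CNV template at given frequencies;
# the workhorse of the V_ST recovery tests
two_pop_cohort <- function(p1, p2, n_per_pop = 50L, tcn = 1L,
                           lrr_sd = 0.2, seed = 7L,
                           n_probes = 200L, chrom_length = 1e6) {
  tmpl <- cnv_template("1", 400001L, 440000L, tcn,
                       c(A = p1, B = p2))
  cfg <- simulation_config(
    populations = c(A = n_per_pop, B = n_per_pop),
    n_chrom = 1L, chrom_length_bp = chrom_length,
    n_probes_per_chrom = n_probes, templates = list(tmpl),
    lrr_sd = lrr_sd, seed = seed)
  generate_cohort(cfg)
}
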