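# Synthetic multi-breed cohort generator.
#
# The generator emulates the signal side of an SNP-array CNV study:
# per-probe log R ratios (LRR) with state-dependent means, Gaussian
# noise, optional GC-correlated waviness, optional B-allele
# frequencies, and truth CNV calls at exact template bounds. It is the
# fixture factory for every downstream stage.

#' Default LRR means per total-copy-number state
#'
#' Conventional array-CNV signal levels: the neutral 2-copy state
#' defines the LRR zero point and the means are strictly increasing in
#' copy number.
#'
#' @return A named numeric vector over states "0", "1", "2", "3", "4".
#' @export
default_state_means <- function() {
  c(`0` = -3.5, `1` = -0.66, `2` = 0, `3` = 0.40, `4` = 0.68)
}

#' Describe one CNV template
#'
#' A template is a genomic interval, a total copy number, and a carrier
#' frequency per population. During generation each sample carries the
#' template independently with its population's frequency.
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive bounds.
#' @param tcn Total copy number in 0/1/3/4.
#' @param carrier_freq Named numeric vector, population -> fraction in
#'   \[0, 1\].
#' @return A one-element list of class `cnv_template`.
#' @export
cnv_template <- function(chrom, start, end, tcn, carrier_freq) {
  stopifnot(start <= end, tcn %in% VALID_TCN,
            all(carrier_freq >= 0 & carrier_freq <= 1),
            !is.null(names(carrier_freq)))
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), tcn = as.integer(tcn),
                 carrier_freq = carrier_freq),
            class = "cnv_template")
}

#' Build a simulation configuration
#'
#' @param populations Named integer vector: population -> number of
#'   samples (all >= 1).
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Length of every chromosome, bp.
#' @param n_probes_per_chrom Equally spaced probes per chromosome.
#' @param templates List of [cnv_template()] objects.
#' @param lrr_state_means Named LRR mean per state; any entry overrides
#'   the [default_state_means()] value verbatim.
#' @param lrr_sd Gaussian LRR noise SD (> 0, or 0 for the noise-free
#'   limit used in analytic tests).
#' @param wave_amplitude Coefficient of the GC-correlated wave term
#'   `wave_amplitude * (gc_frac - mean(gc_frac))` added to each probe.
#' @param baf Logical; also emit a B-allele-frequency matrix.
#' @param call_rate_range Two fractions; each sample's call rate is
#'   drawn uniformly from this interval and the complementary probe
#'   fraction is set missing.
#' @param seed Integer master seed; the whole cohort is a deterministic
#'   function of it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(populations,
                              n_chrom = 2L,
                              chrom_length_bp = 1e6,
                              n_probes_per_chrom = 200L,
                              templates = list(),
                              lrr_state_means = default_state_means(),
                              lrr_sd = 0.20,
                              wave_amplitude = 0,
                              baf = FALSE,
                              call_rate_range = c(1, 1),
                              seed = 1L) {
  stopifnot(length(populations) >= 1, all(populations >= 1),
            !is.null(names(populations)),
            n_chrom >= 1, chrom_length_bp >= 1, n_probes_per_chrom >= 2,
            lrr_sd >= 0, length(call_rate_range) == 2,
            all(call_rate_range >= 0 & call_rate_range <= 1),
            call_rate_range[1] <= call_rate_range[2])
  means <- default_state_means()
  means[names(lrr_state_means)] <- lrr_state_means
  if (any(diff(means[order(as.integer(names(means)))]) <= 0))
    stop("lrr_state_means must be strictly increasing in copy number")
  chroms <- as.character(seq_len(n_chrom))
  for (tp in templates) {
    stopifnot(inherits(tp, "cnv_template"))
    if (!(tp$chrom %in% chroms) || tp$end > chrom_length_bp || tp$start < 1)
      stop("template ", tp$chrom, ":", tp$start, "-", tp$end,
           " lies outside chromosome bounds")
    unk <- setdiff(names(tp$carrier_freq), names(populations))
    if (length(unk))
      stop("template frequency given for unknown population: ",
           paste(unk, collapse = ", "))
  }
  structure(list(populations = populations, n_chrom = as.integer(n_chrom),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 n_probes_per_chrom = as.integer(n_probes_per_chrom),
                 templates = templates, lrr_state_means = means,
                 lrr_sd = lrr_sd, wave_amplitude = wave_amplitude,
                 baf = baf, call_rate_range = call_rate_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic multi-breed cohort
#'
#' Probes are equally spaced per chromosome with GC fractions drawn
#' Uniform(0.3, 0.7). Each sample carries each template independently
#' with its population's carrier frequency; probes inside a carried
#' template draw LRR ~ Normal(mean\[tcn\], sd), all others
#' Normal(0, sd), plus the optional GC wave term. Truth calls are
#' recorded at exact template bounds with the template's probe count.
#'
#' Each sample consumes its own RNG substream seeded from
#' `seed + sample index`, so enlarging the cohort never perturbs the
#' samples already generated.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `map` (SNP map), `lrr` (probes x
#'   samples matrix), `baf` (matrix or `NULL`), `truth_calls` (CNV call
#'   table), `manifest` (population manifest) and `chrom_sizes`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- as.character(seq_len(config$n_chrom))
  step <- config$chrom_length_bp / config$n_probes_per_chrom
  pos <- as.integer(round(step * (seq_len(config$n_probes_per_chrom) - 0.5)))
  map <- data.frame(
    probe_id = paste0("P", rep(chroms, each = length(pos)), "_",
                      rep(seq_along(pos), times = length(chroms))),
    chrom = rep(chroms, each = length(pos)),
    pos = rep(pos, times = length(chroms)),
    gc_frac = stats::runif(length(pos) * length(chroms), 0.3, 0.7),
    stringsAsFactors = FALSE
  )
  gc_centered <- map$gc_frac - mean(map$gc_frac)

  # probes covered by each template, in map row indices
  tmpl_probes <- lapply(config$templates, function(tp) {
    which(map$chrom == tp$chrom & map$pos >= tp$start & map$pos <= tp$end)
  })
  empty <- vapply(tmpl_probes, length, integer(1)) == 0L
  if (any(empty))
    stop("template(s) covering no probe: ", paste(which(empty), collapse = ", "))

  pops <- rep(names(config$populations), times = config$populations)
  sample_ids <- unlist(lapply(names(config$populations), function(p) {
    sprintf("%s%03d", p, seq_len(config$populations[[p]]))
  }), use.names = FALSE)
  n_probe <- nrow(map)
  lrr <- matrix(NA_real_, n_probe, length(sample_ids),
                dimnames = list(map$probe_id, sample_ids))
  baf <- if (config$baf) lrr else NULL
  means <- config$lrr_state_means

  truth <- vector("list", length(sample_ids))
  for (s in seq_along(sample_ids)) {
    set.seed(config$seed + s)             # per-sample substream
    state <- rep(2L, n_probe)
    carried <- list()
    for (k in seq_along(config$templates)) {
      tp <- config$templates[[k]]
      freq <- tp$carrier_freq[pops[s]]
      if (is.na(freq)) freq <- 0
      if (stats::runif(1) < freq) {
        state[tmpl_probes[[k]]] <- tp$tcn
        carried[[length(carried) + 1L]] <- data.frame(
          sample_id = sample_ids[s], chrom = tp$chrom, start = tp$start,
          end = tp$end, tcn = tp$tcn, n_snps = length(tmpl_probes[[k]]),
          stringsAsFactors = FALSE)
      }
    }
    x <- means[as.character(state)] +
      if (config$lrr_sd > 0) stats::rnorm(n_probe, 0, config$lrr_sd) else 0
    x <- x + config$wave_amplitude * gc_centered
    cr <- stats::runif(1, config$call_rate_range[1], config$call_rate_range[2])
    n_miss <- round((1 - cr) * n_probe)
    if (n_miss > 0) x[sample.int(n_probe, n_miss)] <- NA_real_
    lrr[, s] <- x
    if (config$baf) baf[, s] <- draw_baf(state, is.na(x))
    truth[[s]] <- if (length(carried)) do.call(rbind, carried) else NULL
  }
  truth <- do.call(rbind, c(truth[!vapply(truth, is.null, logical(1))],
                            list(empty_calls())))
  rownames(truth) <- NULL
  list(
    map = map,
    lrr = lrr,
    baf = baf,
    truth_calls = truth,
    manifest = data.frame(sample_id = sample_ids, population = pops,
                          stringsAsFactors = FALSE),
    chrom_sizes = data.frame(chrom = chroms,
                             length_bp = rep(config$chrom_length_bp,
                                             length(chroms)),
                             stringsAsFactors = FALSE)
  )
}

# BAF as a state-dependent mixture over canonical allele ratios with
# Gaussian jitter (sd 0.03), clipped to [0, 1]. Exercises I/O only.
draw_baf <- function(state, missing) {
  ratios <- list(`0` = 0.5, `1` = c(0, 1), `2` = c(0, 0.5, 1),
                 `3` = c(0, 1/3, 2/3, 1), `4` = c(0, 0.25, 0.5, 0.75, 1))
  centers <- vapply(as.character(state), function(st) {
    r <- ratios[[st]]
    r[sample.int(length(r), 1L)]
  }, numeric(1))
  out <- pmin(pmax(centers + stats::rnorm(length(state), 0, 0.03), 0), 1)
  out[missing] <- NA_real_
  out
}
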