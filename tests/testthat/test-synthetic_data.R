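test_that("default state means anchor the neutral state at zero and increase with copy number", {
  m <- default_state_means()
  expect_identical(unname(m["2"]), 0)
  expect_true(all(diff(m[order(as.integer(names(m)))]) > 0))
  # an override is honored verbatim during generation
  cfg <- simulation_config(c(A = 2L), n_chrom = 1L,
                           n_probes_per_chrom = 10L,
                           lrr_state_means = c(`3` = 0.55),
                           templates = list(
                             cnv_template("1", 1L, 1e6, 3L, c(A = 1))),
                           lrr_sd = 0, seed = 3L)
  co <- generate_cohort(cfg)
  expect_true(all(co$lrr == 0.55))
})

test_that("noise-free generation puts carriers exactly at the state mean", {
  tmpl <- cnv_template("1", 200001L, 400000L, 0L, c(A = 1, B = 0))
  cfg <- simulation_config(c(A = 5L, B = 5L), n_chrom = 1L,
                           chrom_length_bp = 1e6,
                           n_probes_per_chrom = 50L,
                           templates = list(tmpl), lrr_sd = 0, seed = 1L)
  co <- generate_cohort(cfg)
  inside <- co$map$pos >= 200001 & co$map$pos <= 400000
  a <- co$manifest$sample_id[co$manifest$population == "A"]
  b <- co$manifest$sample_id[co$manifest$population == "B"]
  expect_true(all(co$lrr[inside, a] == default_state_means()["0"]))
  expect_true(all(co$lrr[, b] == 0))
  expect_true(all(co$lrr[!inside, a] == 0))
  # truth calls carry exact template bounds and probe counts
  expect_true(all(co$truth_calls$start == 200001L))
  expect_true(all(co$truth_calls$end == 400000L))
  expect_true(all(co$truth_calls$n_snps == sum(inside)))
  expect_setequal(co$truth_calls$sample_id, a)
})

test_that("generation is deterministic in the seed and per-sample substreams are stable", {
  tmpl <- cnv_template("1", 1e5, 2e5, 3L, c(A = 0.5))
  mk <- function(n) simulation_config(c(A = n), n_chrom = 1L,
                                      n_probes_per_chrom = 40L,
                                      templates = list(tmpl), seed = 11L)
  co1 <- generate_cohort(mk(20L))
  co2 <- generate_cohort(mk(20L))
  expect_identical(co1, co2)
  # enlarging the cohort never perturbs earlier samples
  co3 <- generate_cohort(mk(30L))
  expect_identical(co3$lrr[, 1:20], co1$lrr)
})

test_that("carrier counts follow the configured frequency (binomial check)", {
  tmpl <- cnv_template("1", 1e5, 2e5, 1L, c(A = 0.5))
  cfg <- simulation_config(c(A = 200L), n_chrom = 1L,
                           n_probes_per_chrom = 20L,
                           templates = list(tmpl), seed = 5L)
  co <- generate_cohort(cfg)
  carriers <- length(unique(co$truth_calls$sample_id))
  ci <- qbinom(c(0.005, 0.995), 200L, 0.5)  # binomial 99% interval
  expect_gte(carriers, ci[1L])
  expect_lte(carriers, ci[2L])
})

test_that("marginal carrier frequency converges to the template frequency", {
  tmpl <- cnv_template("1", 1e5, 2e5, 3L, c(A = 0.3))
  cfg <- simulation_config(c(A = 1000L), n_chrom = 1L,
                           n_probes_per_chrom = 10L,
                           templates = list(tmpl), lrr_sd = 0, seed = 9L)
  co <- generate_cohort(cfg)
  freq <- length(unique(co$truth_calls$sample_id)) / 1000
  tol <- 3 * sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(freq - 0.3), tol)
})

test_that("mean LRR over a truth call's probes approaches the state mean as noise shrinks", {
  tmpl <- cnv_template("1", 3e5, 5e5, 4L, c(A = 1))
  cfg <- simulation_config(c(A = 3L), n_chrom = 1L,
                           n_probes_per_chrom = 400L,
                           templates = list(tmpl), lrr_sd = 0.01,
                           seed = 2L)
  co <- generate_cohort(cfg)
  inside <- co$map$pos >= 3e5 & co$map$pos <= 5e5
  means <- colMeans(co$lrr[inside, ])
  expect_true(all(abs(means - default_state_means()["4"]) < 0.01))
})

test_that("GC wave term adds the configured LRR-GC correlation", {
  cfg <- simulation_config(c(A = 2L), n_chrom = 1L,
                           n_probes_per_chrom = 2000L,
                           wave_amplitude = 0.5, lrr_sd = 0.05, seed = 4L)
  co <- generate_cohort(cfg)
  r <- cor(co$lrr[, 1L], co$map$gc_frac)
  expect_gt(r, 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(
    simulation_config(c(A = 2L), n_chrom = 1L, chrom_length_bp = 1e5,
                      templates = list(
                        cnv_template("1", 9e4, 2e5, 1L, c(A = 1)))),
    "outside chromosome bounds")
  expect_error(
    simulation_config(c(A = 2L),
                      lrr_state_means = c(`3` = -0.1)),
    "increasing")
  expect_error(cnv_template("1", 10, 5, 1L, c(A = 0.5)))
  expect_error(cnv_template("1", 1, 5, 2L, c(A = 0.5)))
})

test_that("BAF generation emits values in [0,1] matching missingness", {
  tmpl <- cnv_template("1", 1e5, 2e5, 3L, c(A = 1))
  cfg <- simulation_config(c(A = 4L), n_chrom = 1L,
                           n_probes_per_chrom = 100L,
                           templates = list(tmpl), baf = TRUE,
                           call_rate_range = c(0.9, 0.95), seed = 6L)
  co <- generate_cohort(cfg)
  expect_false(is.null(co$baf))
  expect_true(all(co$baf >= 0 & co$baf <= 1, na.rm = TRUE))
  expect_identical(is.na(co$baf), is.na(co$lrr))
})
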