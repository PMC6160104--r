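test_that("per-SNP V_ST hits its analytic limits", {
  x <- c(0.1, 0.4, -0.2, 0.3)
  expect_equal(as.numeric(snp_vst(x, x)), 0)           # identical multisets
  expect_equal(as.numeric(snp_vst(rep(0.5, 4), rep(-0.6, 5))), 1)
  expect_equal(as.numeric(snp_vst(c(0, 0), c(0, 0))), 0)  # zero total variance
  expect_error(snp_vst(0.1, c(0.2, 0.3)), ">= 2")
})

test_that("per-SNP V_ST equals the brute-force variance arithmetic", {
  p1 <- c(0.0, 0.0, 0.2)
  p2 <- c(0.5, 0.7)
  expect_equal(as.numeric(snp_vst(p1, p2)), oracle_vst(p1, p2))
  set.seed(14)
  for (i in 1:25) {
    a <- rnorm(sample(2:30, 1))
    b <- rnorm(sample(2:30, 1), mean = runif(1, -1, 1))
    expect_equal(as.numeric(snp_vst(a, b)), oracle_vst(a, b))
  }
})

test_that("V_ST is shift- and label-invariant and size-weights the within variance", {
  set.seed(2)
  a <- rnorm(10); b <- rnorm(15, 0.5)
  expect_equal(as.numeric(snp_vst(a, b)), as.numeric(snp_vst(a + 3, b + 3)))
  expect_equal(as.numeric(snp_vst(a, b)), as.numeric(snp_vst(b, a)))
  # equal sizes: V_S is the plain average of the two population variances
  a2 <- rnorm(12); b2 <- rnorm(12, 1)
  pv <- function(x) mean((x - mean(x))^2)
  vt <- pv(c(a2, b2))
  expect_equal(as.numeric(snp_vst(a2, b2)),
               (vt - (pv(a2) + pv(b2)) / 2) / vt)
  # with population variances the within component never exceeds the
  # total (exact variance decomposition), so raw values are never
  # negative and the [0, 1] clamp is a no-op on this estimator
  set.seed(40)
  for (i in 1:50) {
    a3 <- rnorm(5); b3 <- rnorm(5)
    v <- snp_vst(a3, b3)
    expect_gte(attr(v, "raw"), 0)
    expect_equal(as.numeric(v), attr(v, "raw"))
  }
})

test_that("region V_ST averages probes in the closed interval and flags limits", {
  co <- two_pop_cohort(1, 0, n_per_pop = 10L, tcn = 0L, lrr_sd = 0,
                       seed = 3L)
  region <- merge_calls_to_regions(co$truth_calls)[1L, ]
  res <- region_vst(region, co$lrr, co$map, co$manifest, c("A", "B"))
  expect_equal(res$mean_vst, 1)   # noise-free two-level signal
  probe_in <- co$map$pos >= region$start & co$map$pos <= region$end
  expect_equal(res$n_snps, sum(probe_in))

  # a single-probe region returns that probe's value
  one <- region
  one$start <- co$map$pos[which(probe_in)[1L]]
  one$end <- one$start
  res1 <- region_vst(one, co$lrr, co$map, co$manifest, c("A", "B"))
  expect_equal(res1$n_snps, 1L)
  expect_equal(res1$mean_vst, unname(res1$snp_vst[1L]))

  none <- region
  none$start <- 1L; none$end <- 2L
  expect_error(region_vst(none, co$lrr, co$map, co$manifest, c("A", "B")),
               "no probe")
})

test_that("a differentiated region clears the null distribution of matched regions", {
  # one template at carrier frequency 0.9 vs 0.0; 100 null templates
  # frequency-matched at 0.45 in both populations
  n_tmpl <- 101L
  starts <- as.integer(seq(1e5, 9.9e6, length.out = n_tmpl))
  tmpls <- lapply(seq_len(n_tmpl), function(i) {
    freq <- if (i == 1L) c(A = 0.9, B = 0.0) else c(A = 0.45, B = 0.45)
    cnv_template("1", starts[i], starts[i] + 10000L, 1L, freq)
  })
  cfg <- simulation_config(c(A = 50L, B = 50L), n_chrom = 1L,
                           chrom_length_bp = 1e7,
                           n_probes_per_chrom = 4000L,
                           templates = tmpls, lrr_sd = 0.2, seed = 77L)
  co <- generate_cohort(cfg)
  vst_of <- function(start, end) {
    region <- list(region_id = "r", chrom = "1", start = start, end = end)
    region_vst(region, co$lrr, co$map, co$manifest, c("A", "B"))$mean_vst
  }
  target <- vst_of(starts[1L], starts[1L] + 10000L)
  null <- vapply(2:n_tmpl,
                 function(i) vst_of(starts[i], starts[i] + 10000L),
                 numeric(1))
  expect_gt(target, quantile(null, 0.99))
})

test_that("mean V_ST rises monotonically with the carrier-frequency gap", {
  gaps <- c(0, 0.3, 0.6, 0.9)
  mv <- vapply(seq_along(gaps), function(i) {
    co <- two_pop_cohort(0.05, 0.05 + gaps[i], n_per_pop = 50L,
                         tcn = 1L, lrr_sd = 0.2, seed = 100L + i)
    region <- list(region_id = "t", chrom = "1",
                   start = 400001L, end = 440000L)
    region_vst(region, co$lrr, co$map, co$manifest,
               c("A", "B"))$mean_vst
  }, numeric(1))
  expect_equal(cor(mv, gaps, method = "spearman"), 1)
})

test_that("scan thresholds follow the percentile and mean+2SD rules", {
  mv <- c(rep(0, 99), 0.9)
  thr_q <- quantile(mv, 0.95, names = FALSE)
  thr_m <- mean(mv) + 2 * sd(mv)
  expect_true(0.9 >= thr_q)
  expect_true(0.9 > thr_m)          # 0.9 > 0.009 + 2 * 0.0895...
  expect_equal(sum(mv > thr_m), 1L)
  # identical values: SD is 0 and the strict inequality flags nothing
  same <- rep(0.4, 30)
  expect_equal(sum(same > mean(same) + 2 * sd(same)), 0L)
})

test_that("the pairwise scan filters by within-population carriers and flags the outlier", {
  # three populations; 10 templates: eight undifferentiated, one
  # strongly differentiated in C, one too rare in A to be scanned there
  starts <- as.integer(seq(50001, 950001, by = 100000))
  tmpls <- lapply(seq_along(starts), function(i) {
    freq <- c(A = 0.5, B = 0.5, C = 0.5)
    if (i == 5L) freq <- c(A = 0.4, B = 0.4, C = 0.95)
    if (i == 9L) freq <- c(A = 0.05, B = 0.5, C = 0.5)
    cnv_template("1", starts[i], starts[i] + 30000L,
                 if (i %% 2) 1L else 3L, freq)
  })
  cfg <- simulation_config(c(A = 30L, B = 30L, C = 30L), n_chrom = 1L,
                           chrom_length_bp = 1e6,
                           n_probes_per_chrom = 400L,
                           templates = tmpls, lrr_sd = 0.15, seed = 19L)
  co <- generate_cohort(cfg)
  regions <- merge_calls_to_regions(co$truth_calls)
  scan <- vst_scan(regions, co$lrr, co$map, co$truth_calls, co$manifest,
                   min_carriers = 5L, rule = "mean2sd")
  # three pairwise scans are present
  expect_setequal(unique(paste(scan$pop1, scan$pop2)),
                  c("A B", "A C", "B C"))
  # the rare-in-A template cannot reach 5 carriers in A (expected 1.5)
  expect_false(any(scan$region_id == "1:850001-880001" &
                     scan$pop1 == "A"))
  # the differentiated region tops both scans involving C and only those
  diff_id <- regions$region_id[regions$start == 450001L]
  ac <- scan[scan$pop1 == "A" & scan$pop2 == "C", ]
  ab <- scan[scan$pop1 == "A" & scan$pop2 == "B", ]
  expect_equal(ac$region_id[which.max(ac$mean_vst)], diff_id)
  expect_true(ac$sig_mean2sd[ac$region_id == diff_id])
  expect_false(any(ab$sig_mean2sd[ab$region_id == diff_id]))
  # both thresholds are reported for every row
  expect_true(all(is.finite(scan$threshold_top5pct)))
  expect_true(all(is.finite(scan$threshold_mean2sd)))
})
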