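test_that("PCA on a rank-1 matrix puts all variance on PC1 and duplicates coincide", {
  m <- matrix(c(0, 1), nrow = 2, dimnames = list(c("a", "b"), "r1"))
  p <- cnv_pca(m)
  expect_equal(p$variance_explained[1L], 1)

  m2 <- matrix(c(0, 1, 1, 0, 1, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("a", "b", "b2"), c("r1", "r2")))
  p2 <- cnv_pca(m2)
  expect_equal(p2$coordinates["b", ], p2$coordinates["b2", ])

  expect_error(cnv_pca(matrix(1, 3, 4)), "constant")
})

test_that("PCA variance fractions match the covariance eigenvalues (direct oracle)", {
  set.seed(99)
  m <- matrix(sample(0:4, 20 * 50, replace = TRUE), nrow = 20)
  p <- cnv_pca(m)
  ev <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(p$variance_explained[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-8)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_lte(sum(p$variance_explained), 1 + 1e-8)
})

test_that("PCA is invariant to adding a constant to a column", {
  set.seed(3)
  m <- matrix(rnorm(60), nrow = 10)
  m2 <- m
  m2[, 2L] <- m2[, 2L] + 7
  expect_equal(cnv_pca(m)$coordinates, cnv_pca(m2)$coordinates,
               tolerance = 1e-10)
})

test_that("Euclidean PCoA agrees with raw-matrix PCA up to axis sign", {
  set.seed(44)
  m <- matrix(sample(0:4, 12 * 20, replace = TRUE), nrow = 12,
              dimnames = list(sprintf("s%02d", 1:12), NULL))
  pca <- cnv_pca(m)
  pcoa <- cnv_pcoa(m, k = 2L)
  for (j in 1:2) {
    expect_equal(abs(unname(pcoa$coordinates[, j])),
                 abs(unname(pca$coordinates[, j])), tolerance = 1e-8)
  }
  expect_equal(pcoa$variance_explained[1:2],
               unname(pca$variance_explained[1:2]), tolerance = 1e-8)
})

test_that("UPGMA reproduces the hand-worked three-taxon example", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- upgma_tree(as.dist(d))
  # first merge is (A, B) at ultrametric height 2 / 2 = 1
  expect_equal(sort(dend$merge[1L, ]), c(-2L, -1L))
  expect_equal(dend$node_heights, c(1, 4))
  # tip depths from the root are all 4 (ultrametric)
  depth <- ape::node.depth.edgelength(dend$phylo)
  expect_equal(unname(depth[1:3]), rep(4, 3))
})

test_that("UPGMA handles ties deterministically and recovers ultrametric inputs", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(letters[1:4], letters[1:4])
  dend <- upgma_tree(as.dist(d))
  expect_equal(dend$height, rep(1, 3))    # all merges at the tie height
  # rerun is identical (deterministic tie-break)
  expect_identical(upgma_tree(as.dist(d))$merge, dend$merge)

  # an ultrametric distance is reproduced exactly by the tree
  du <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 4,
                 6, 6, 4, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  dend2 <- upgma_tree(as.dist(du))
  # tips joining at height d/2 sit at cophenetic distance d
  cd <- as.matrix(ape::cophenetic.phylo(dend2$phylo))
  expect_equal(cd[letters[1:4], letters[1:4]], du)

  expect_error(upgma_tree(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("UPGMA agrees with an independent average-linkage implementation", {
  skip_if_not_installed("phangorn")
  set.seed(8)
  x <- matrix(rnorm(15 * 10), nrow = 15,
              dimnames = list(sprintf("s%02d", 1:15), NULL))
  d <- dist(x)
  mine <- upgma_tree(d)
  ref <- phangorn::upgma(d)
  expect_true(ape::all.equal.phylo(mine$phylo, ref, use.edge.length = FALSE))
  expect_equal(sort(ape::node.depth.edgelength(mine$phylo)),
               sort(ape::node.depth.edgelength(ref)), tolerance = 1e-8)
})

test_that("bootstrap support is 0/1 at one replicate and invariant to column order", {
  set.seed(5)
  m <- matrix(rbinom(8 * 30, 1, 0.5), nrow = 8,
              dimnames = list(sprintf("s%d", 1:8), sprintf("r%02d", 1:30)))
  one <- bootstrap_support(m, n_boot = 1L, seed = 2L)
  expect_true(all(one$support %in% c(0, 1)))

  full <- bootstrap_support(m, n_boot = 25L, seed = 2L)
  perm <- bootstrap_support(m[, sample.int(30L)], n_boot = 25L, seed = 2L)
  expect_identical(full$support, perm$support)
})

test_that("a strong breed split earns high bootstrap support", {
  set.seed(123)
  n_per <- 12L
  n_reg <- 40L
  # between-breed carrier frequencies differ by 0.8
  m <- rbind(
    matrix(rbinom(n_per * n_reg, 1, 0.9), nrow = n_per),
    matrix(rbinom(n_per * n_reg, 1, 0.1), nrow = n_per))
  dimnames(m) <- list(c(sprintf("A%02d", 1:n_per), sprintf("B%02d", 1:n_per)),
                      sprintf("r%02d", 1:n_reg))
  dend <- bootstrap_support(m, n_boot = 200L, seed = 10L)
  keys <- cnvpop:::clade_keys(dend)
  split_a <- paste(sort(sprintf("A%02d", 1:n_per)), collapse = "\r")
  split_b <- paste(sort(sprintf("B%02d", 1:n_per)), collapse = "\r")
  hit <- match(c(split_a, split_b), keys)
  expect_true(any(!is.na(hit)))
  expect_gte(max(dend$support[hit[!is.na(hit)]]), 0.95)
})

test_that("Newick export carries bootstrap labels and reads back", {
  set.seed(6)
  m <- matrix(rbinom(6 * 20, 1, 0.5), nrow = 6,
              dimnames = list(sprintf("s%d", 1:6), sprintf("r%02d", 1:20)))
  dend <- bootstrap_support(m, n_boot = 10L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, rownames(m))
  expect_equal(length(back$node.label), back$Nnode)
})
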