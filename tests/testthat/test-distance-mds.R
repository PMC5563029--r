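test_that("dosage distance reproduces closed-form cases", {
  # identical samples -> 0
  tab <- make_table(matrix(1L, 8, 2), 3L)
  expect_true(all(ibs_distance(tab) == 0))
  # diploid 0/0 vs 1/1 everywhere -> 1
  tab2 <- make_table(cbind(rep(0L, 6), rep(2L, 6)), 2L)
  expect_equal(ibs_distance(tab2)[1, 2], 1)
  # triploid 0/0/0 vs 0/0/1 everywhere -> 1/3
  tab3 <- make_table(cbind(rep(0L, 6), rep(1L, 6)), 3L)
  expect_equal(ibs_distance(tab3)[1, 2], 1 / 3)
})

test_that("dosage distance is a metric on random mixed-ploidy tables", {
  for (seed in c(51, 52, 53)) {
    tab <- random_table(seed, n_sites = 50, n_samples = 6, p_missing = 0)
    d <- ibs_distance(tab)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("pairs without co-called sites error unless masking is allowed", {
  dosage <- cbind(c(1L, NA, NA), c(NA, 1L, NA), c(NA, NA, 1L))
  depth <- ifelse(is.na(dosage), 0L, 10L)
  tab <- make_table(dosage, 3L, depth = depth)
  expect_error(ibs_distance(tab), "co-called")
  d <- ibs_distance(tab, allow_missing_pairs = TRUE)
  expect_true(all(is.na(d[upper.tri(d)])))
})

test_that("classical MDS embeds three equidistant points as an
           equilateral triangle", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  m <- classical_mds(d, 2)
  dd <- as.matrix(stats::dist(m$coordinates))
  expect_true(all(abs(dd[upper.tri(dd)] - 1) < 1e-9))
  expect_true(all(abs(colMeans(m$coordinates)) < 1e-12))
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
})

test_that("classical MDS recovers planted 2-D geometry to 1e-8", {
  for (seed in c(61, 62, 63, 64, 65)) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(30), 15, 2)
      d <- as.matrix(stats::dist(x))
      dimnames(d) <- list(sprintf("p%d", 1:15), sprintf("p%d", 1:15))
      m <- classical_mds(d, 2)
      expect_lt(procrustes_residual(x, m$coordinates), 1e-8)
      # embedded coordinates reproduce the distances
      dd <- as.matrix(stats::dist(m$coordinates))
      expect_lt(max(abs(dd - d)), 1e-8)
    })
  }
})

test_that("MDS output is deterministic, duplicates coincide, k reduces
           with a warning when eigenvalues run out", {
  x <- matrix(c(0, 0, 1, 0, 1, 0.0001, 4, 4), 4, 2, byrow = TRUE)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(sprintf("p%d", 1:4), sprintf("p%d", 1:4))
  m1 <- classical_mds(d, 2)
  m2 <- classical_mds(d, 2)
  expect_identical(m1$coordinates, m2$coordinates)
  # sign convention: largest-magnitude entry of each axis is positive
  for (a in seq_len(ncol(m1$coordinates))) {
    expect_gt(m1$coordinates[which.max(abs(m1$coordinates[, a])), a], 0)
  }
  ddup <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3)
  dimnames(ddup) <- list(c("a", "b", "c"), c("a", "b", "c"))
  mdup <- classical_mds(ddup, 1)
  expect_equal(mdup$coordinates["a", 1], mdup$coordinates["b", 1])
  # 3 collinear-ish points: asking for more dims than positive eigenvalues
  dl <- as.matrix(stats::dist(matrix(c(0, 1, 2), 3, 1)))
  dimnames(dl) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_warning(ml <- classical_mds(dl, 3), "positive eigenvalue")
  expect_lt(ncol(ml$coordinates), 3)
})

test_that("divergence screen flags planted outliers and respects the
           threshold monotonically", {
  # 8 identical references + 2 clear outliers
  dosage <- cbind(matrix(0L, 40, 8), matrix(3L, 40, 2))
  tab <- make_table(dosage, 3L)
  refs <- tab$samples$sample_id[1:8]
  d <- ibs_distance(tab)
  expect_warning(scr <- divergence_screen(d, refs), "degenerate")
  expect_equal(scr$sample_id[scr$flagged],
               tab$samples$sample_id[9:10])
  # raising the threshold never enlarges the flagged set
  suppressWarnings({
    f1 <- divergence_screen(d, refs, threshold = 2)$flagged
    f2 <- divergence_screen(d, refs, threshold = 10)$flagged
  })
  expect_true(all(which(f2) %in% which(f1)))
  expect_error(divergence_screen(d, refs[1:2]), "at least 3")
})
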