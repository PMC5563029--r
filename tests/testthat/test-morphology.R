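test_that("replicate aggregation averages traits and derives LWR from
           aggregated means", {
  rec <- data.frame(
    sample_id = c("a", "a", "b"),
    internode_mm = c(10, 20, 30), stolon_diam_mm = c(1, 1, 2),
    leaf_len_mm = c(10, 20, 12), leaf_wid_mm = c(2, 2, 3)
  )
  agg <- aggregate_replicates(rec)
  expect_equal(agg$sample_id, c("a", "b"))
  expect_equal(agg$leaf_len_mm[1], 15)
  expect_equal(agg$lwr[1], 7.5)  # 15/2, not mean(5, 10)
  # single record: aggregate equals the record
  expect_equal(agg$internode_mm[2], 30)
  # permutation invariance over records
  agg2 <- aggregate_replicates(rec[c(3, 1, 2), ])
  expect_equal(agg2[order(agg2$sample_id), -1],
               agg[order(agg$sample_id), -1], ignore_attr = TRUE)
  expect_error(aggregate_replicates(rec, sample_ids = c("a", "zz")), "zz")
  rec$leaf_wid_mm[1] <- 0
  expect_error(aggregate_replicates(rec), "positive")
})

test_that("k-means R-squared hits its bounds at k = 1 and k = n", {
  withr::with_seed(14, {
    df <- data.frame(sample_id = sprintf("s%d", 1:8),
                     t1 = rnorm(8), t2 = rnorm(8))
  })
  expect_equal(kmeans_cluster(df, k = 1, seed = 1)$r_squared, 0)
  expect_equal(kmeans_cluster(df, k = 8, seed = 1)$r_squared, 1)
  expect_error(kmeans_cluster(df, k = 9, seed = 1), "k <= number")
})

test_that("k-means recovers well-separated planted clusters and agrees
           with the reference implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(3, {
    centers <- matrix(c(0, 0, 20, 0, 0, 20), 3, 2, byrow = TRUE)
    lab <- rep(1:3, each = 15)
    x <- centers[lab, ] + matrix(rnorm(90, 0, 0.5), 45, 2)
  })
  df <- data.frame(sample_id = sprintf("s%02d", 1:45),
                   t1 = x[, 1], t2 = x[, 2])
  res <- kmeans_cluster(df, k = 3, seed = 7)
  expect_equal(mclust::adjustedRandIndex(res$assignments, lab), 1)
  expect_true(res$r_squared > 0.99)
  # independent cross-check: stats::kmeans finds the same partition
  km <- withr::with_seed(7, stats::kmeans(x, 3, nstart = 10))
  expect_equal(mclust::adjustedRandIndex(res$assignments, km$cluster), 1)
  expect_equal(res$ssw, km$tot.withinss, tolerance = 1e-8)
})

test_that("standardized R-squared is invariant to trait-wise affine
           rescaling", {
  withr::with_seed(21, {
    df <- data.frame(sample_id = sprintf("s%d", 1:30),
                     t1 = rnorm(30), t2 = rnorm(30, 0, 5))
  })
  r1 <- kmeans_cluster(df, k = 3, seed = 2, standardize = TRUE)$r_squared
  df2 <- df
  df2$t1 <- df2$t1 * 100 + 7
  df2$t2 <- df2$t2 / 50 - 3
  r2 <- kmeans_cluster(df2, k = 3, seed = 2, standardize = TRUE)$r_squared
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("CCC is negative when R-squared falls below its null
           expectation and errors on degenerate partitions", {
  # an elongated 1-D structure split in two: R2 < E[R2] -> CCC < 0
  withr::with_seed(5, {
    x <- cbind(seq(0, 10, length.out = 60) + rnorm(60, 0, 0.1),
               rnorm(60, 0, 0.1))
  })
  df <- data.frame(sample_id = sprintf("s%02d", 1:60),
                   t1 = x[, 1], t2 = x[, 2])
  res <- kmeans_cluster(df, k = 2, seed = 1)
  expect_lt(res$ccc, 0)
  expect_error(cubic_clustering_criterion(x, rep(1L, 60)),
               "single cluster")
  expect_error(cubic_clustering_criterion(x[1:3, ], c(1L, 2L, 3L)),
               "more samples than clusters")
  expect_warning(ccc1 <- cubic_clustering_criterion(
    matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE), c(1L, 1L, 2L)),
    NA)
})

test_that("kmeans_cluster result at k < 2 reports CCC as NA", {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   t1 = c(1, 2, 3), t2 = c(0, 0.5, 1))
  expect_true(is.na(kmeans_cluster(df, k = 1, seed = 1)$ccc))
})

test_that("cluster summaries flag non-overlapping mean +/- SD intervals", {
  # two tight clusters far apart in t1, identical in t2
  withr::with_seed(33, {
    df <- data.frame(
      sample_id = sprintf("s%02d", 1:20),
      t1 = c(rnorm(10, 34.6, 2), rnorm(10, 21.9, 2)),
      t2 = rnorm(20, 2.1, 0.05)
    )
  })
  res <- kmeans_cluster(df, k = 2, seed = 4)
  summ <- summarize_clusters(res)
  f_t1 <- summ$flags$different[summ$flags$trait == "t1"]
  f_t2 <- summ$flags$different[summ$flags$trait == "t2"]
  expect_true(f_t1)
  expect_false(f_t2)
  # means 10 vs 11 with SD ~1.6: intervals overlap, so no flag
  df2 <- data.frame(sample_id = sprintf("t%02d", 1:8),
                    t1 = c(8, 12, 10, 10, 9, 13, 11, 11))
  fake <- structure(list(
    assignments = stats::setNames(rep(1:2, each = 4), df2$sample_id),
    centers = matrix(c(10, 11), 2, 1, dimnames = list(NULL, "t1")),
    samples = df2), class = "cluster_result")
  s2 <- summarize_clusters(fake)
  expect_false(any(s2$flags$different))
})
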