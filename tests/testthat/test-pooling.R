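test_that("low-read exclusion is strict at the one-million boundary", {
  raw <- c(999999L, 1000000L, 1300000L, 500000L)
  tab <- make_table(matrix(0L, 5, 4), 3L, raw = raw)
  expect_message(kept <- exclude_low_read_samples(tab), "excluded")
  expect_equal(kept$samples$sample_id, c("smp02", "smp03"))
  expect_equal(attr(kept, "excluded_samples"), c("smp01", "smp04"))
})

test_that("exclusion retains the expected count on a 47-sample fixture", {
  raw <- rep(2e6, 47)
  raw[c(3, 9, 20, 31, 44)] <- c(9e5, 1e5, 999999, 5e5, 8e5)
  dosage <- matrix(0L, 4, 47)
  tab <- make_table(dosage, 3L, raw = raw)
  suppressMessages(kept <- exclude_low_read_samples(tab))
  expect_equal(n_samples(kept), 42L)
})

test_that("pooling sums allele depths and conserves total depth", {
  # two members with AD (10,2) and (8,4) -> pooled AD (18,6), depth 24
  dosage <- matrix(c(1L, 1L), 1, 2)
  tab <- make_table(dosage, 3L, depth = matrix(c(12L, 12L), 1, 2),
                    label = c("cv", "cv"))
  tab$ad_ref[] <- c(10L, 8L); tab$ad_alt[] <- c(2L, 4L)
  pool <- pool_cultivar(tab, "cv")
  expect_equal(unname(pool$ad_ref[1, 1]), 18L)
  expect_equal(unname(pool$ad_alt[1, 1]), 6L)
  expect_equal(unname(pool$depth[1, 1]), 24L)

  # conservation on random tables
  for (seed in c(21, 22)) {
    tab <- random_table(seed, n_sites = 40, n_samples = 6,
                        ploidies = 3L)
    tab$samples$group_label <- rep("cv", 6)
    pool <- pool_cultivar(tab, "cv")
    expect_equal(unname(pool$depth[, 1]), unname(rowSums(tab$depth)))
  }

  # single-member cultivar pools to itself
  tab1 <- random_table(23, n_sites = 10, n_samples = 1, ploidies = 3L)
  pool1 <- pool_cultivar(tab1, tab1$samples$group_label[1])
  expect_equal(unname(pool1$depth[, 1]), unname(tab1$depth[, 1]))
  expect_equal(unname(pool1$ad_alt[, 1]), unname(tab1$ad_alt[, 1]))
})

test_that("pooling errors on unknown labels and mixed ploidy", {
  tab <- random_table(30, n_sites = 5, n_samples = 4, ploidies = c(2L, 3L))
  expect_error(pool_cultivar(tab, "nope"), "no samples")
  if (length(unique(tab$samples$ploidy)) > 1) {
    tab$samples$group_label <- rep("cv", 4)
    expect_error(pool_cultivar(tab, "cv"), "mixed ploidy")
  }
})

test_that("dosage re-caller rounds alt fraction with half-away ties", {
  expect_equal(recall_genotype(c(30, 0), 3)$alleles, c(0L, 0L, 0L))
  expect_equal(recall_genotype(c(20, 10), 3)$alleles, c(0L, 0L, 1L))
  expect_true(recall_genotype(c(0, 0), 3)$missing)
  # tie: alt fraction 1/2 at ploidy 3 -> dosage 1.5 -> away from zero -> 2
  expect_equal(recall_genotype(c(10, 10), 3)$alleles, c(0L, 1L, 1L))
  expect_equal(recall_genotype(c(10, 10), 2)$alleles, c(0L, 1L))
  expect_error(recall_genotype(c(-1, 5), 3), "non-negative")
})

test_that("re-called dosage is monotone in alt depth at fixed total", {
  for (p in 2:4) {
    for (tot in c(1, 7, 40)) {
      dos <- vapply(0:tot, function(alt) {
        sum(recall_genotype(c(tot - alt, alt), p)$alleles)
      }, numeric(1))
      expect_true(all(diff(dos) >= 0),
                  label = sprintf("ploidy %d total %d", p, tot))
    }
  }
})

test_that("pooling six clonal members lifts mean depth to ~6x per-sample", {
  means <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_loci = 300,
                      cultivars = cultivar_set("cv", 3, 6, "standard"),
                      within_family_divergence = 0)
    pools <- pool_cultivars(simulate_genotypes(cfg))
    pool_depth_summary(pools)$mean_depth
  }, numeric(1))
  # expected pooled mean ~ 6 x 4.9 = 29.4 (conditional on coverage)
  expect_lt(abs(mean(means) - 6 * 4.9), 3 * stats::sd(means) / sqrt(20) + 1)
})

test_that("noise-free clonal pooling recalls the founder everywhere covered", {
  cfg <- sim_config(seed = 11, n_loci = 400,
                    cultivars = cultivar_set("cv", 3, 6, "standard"),
                    somatic_mutation_rate = 0, sequencing_error = 0,
                    depth_mean = c("2" = 60, "3" = 60, "4" = 60),
                    depth_dispersion = 20)
  g <- simulate_genotypes(cfg)
  pool <- pool_cultivar(g, "cv")
  founder <- attr(g, "truth")$founder_dosage[, "cv"]
  # exactness precondition: pooled depth > 2 x contributing members
  k <- rowSums(g$depth > 0L)
  expect_true(all(pool$depth[, 1] > 2 * k))
  covered <- pool$depth[, 1] > 0L
  expect_equal(unname(pool$dosage[covered, 1]), unname(founder[covered]))
})
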