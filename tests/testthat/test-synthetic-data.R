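test_that("simulation is byte-identical for the same seed and config", {
  cfg <- sim_config(seed = 5, n_loci = 120)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$genotypes$depth, s2$genotypes$depth)
  expect_identical(s1$morphology, s2$morphology)
  expect_identical(s1$flow, s2$flow)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study_data(s1, d1)
  write_study_data(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = paste("bytes of", f))
  }
})

test_that("with no variation injected, clonal samples are identical", {
  cfg <- sim_config(
    seed = 2, n_loci = 150,
    cultivars = cultivar_set("Fam", 3, 8, "standard"),
    within_family_divergence = 0, somatic_mutation_rate = 0,
    sequencing_error = 0,
    depth_mean = c("2" = 100, "3" = 100, "4" = 100),
    depth_dispersion = 10
  )
  g <- simulate_genotypes(cfg)
  expect_false(anyNA(g$dosage))  # depth 100: no zero-read calls here
  for (j in 2:n_samples(g)) {
    expect_identical(g$dosage[, j], g$dosage[, 1],
                     label = paste("sample", j))
  }
})

test_that("invalid generator configs are rejected", {
  expect_error(sim_config(depth_mean = c("2" = 0, "3" = 0, "4" = 0)),
               "depth_mean")
  expect_error(sim_config(somatic_mutation_rate = 1.5), "rates")
  expect_error(sim_config(raw_read_count_range = c(5, 1)),
               "raw_read_count_range")
})

test_that("divergent founder loci arise at the configured binomial rate", {
  # two families, divergence 0.01 each vs the consensus: founder genotype
  # CLASS differences between them occur at >= the per-family rate; count
  # across seeds should track the planted probability
  n_loci <- 1000
  rate <- 0.01
  counts <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_loci = n_loci,
                      cultivars = rbind(
                        cultivar_set("A", 3, 1, "standard"),
                        cultivar_set("B", 3, 1, "standard")),
                      within_family_divergence = rate,
                      somatic_mutation_rate = 0, sequencing_error = 0)
    f <- attr(simulate_genotypes(cfg), "truth")$founder_dosage
    sum(f[, "A"] != f[, "B"])
  }, numeric(1))
  # each locus differs when either founder diverges and lands on a
  # different dosage: probability <= 2 * rate
  p_max <- 2 * rate
  expect_lt(mean(counts), n_loci * p_max + 3 * sqrt(n_loci * p_max / 20))
  expect_gt(mean(counts), 0.5 * n_loci * rate)
})

test_that("zero-SD morphology reproduces cluster means exactly; noisy
           sample means recover them within CLT error", {
  cfg0 <- sim_config(seed = 1, n_loci = 10)
  mc <- cfg0$morph_cluster_params
  mc[grep("_sd$", names(mc))] <- 0
  cfg_sd0 <- sim_config(seed = 1, n_loci = 10, morph_cluster_params = mc)
  ids <- c(a = 1L, b = 2L, c = 3L)
  rec <- simulate_morphology(cfg_sd0, ids)
  expect_equal(nrow(rec), 3 * 24)  # 4 pots x 3 stolons x 2 dates
  agg <- aggregate_replicates(rec)
  expect_equal(agg$internode_mm, c(34.6, 21.9, 24.7))
  expect_equal(agg$leaf_len_mm, c(14.9, 9.9, 29.8))

  # with default SDs, sample-level means recover the cluster mean within
  # CLT error across seeds (sample effect + averaged replicate noise)
  errs <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, n_loci = 10)
    rec <- simulate_morphology(cfg, c(x = 1L))
    mean(rec$internode_mm) - 34.6
  }, numeric(1))
  sd_one <- cfg0$morph_cluster_params$internode_sd[1] * sqrt(1 + 1 / 24)
  expect_lt(abs(mean(errs)), 3 * sd_one / sqrt(50))
})

test_that("flow readings scale with genome size and recover it", {
  md <- make_samples(c("a", "b"), c(3L, 3L))
  cfg0 <- sim_config(seed = 9, n_loci = 10, flow_cv = 0,
                     genome_sizes = c("2" = 1.0, "3" = 1.67, "4" = 2.0))
  fl <- simulate_flow(cfg0, md)
  expect_equal(fl$fl2a_sample, fl$fl2a_standard)  # ratio exactly 1
  cfg2 <- sim_config(seed = 9, n_loci = 10, flow_cv = 0,
                     genome_sizes = c("2" = 1.0, "3" = 3.34, "4" = 2.0))
  fl2 <- simulate_flow(cfg2, md)
  expect_equal(fl2$fl2a_sample / fl2$fl2a_standard, c(2, 2))

  # Monte-Carlo recovery of the configured pg at cv = 0.02
  ests <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, n_loci = 10, flow_cv = 0.02)
    fl <- simulate_flow(cfg, md[1, , drop = FALSE])
    estimate_genome_size(fl$fl2a_sample, fl$fl2a_standard)
  }, numeric(1))
  expect_true(all(abs(ests - 1.61) / 1.61 < 3 * 0.02))
  cfg_missing <- sim_config(seed = 1, n_loci = 10,
                            genome_sizes = c("3" = 1.61))
  expect_error(simulate_flow(cfg_missing, make_samples("z", 2L)),
               "genome size")
})

test_that("noise-free contaminant-free configs flag no divergent samples", {
  cfg <- sim_config(
    seed = 4, n_loci = 200,
    cultivars = rbind(cultivar_set("Fam", 3, 8, "standard"),
                      cultivar_set("Fam", 3, 6, "off_type")),
    within_family_divergence = 0, somatic_mutation_rate = 0,
    sequencing_error = 0,
    depth_mean = c("2" = 80, "3" = 80, "4" = 80)
  )
  g <- simulate_genotypes(cfg)
  d <- ibs_distance(g)
  refs <- g$samples$sample_id[g$samples$role == "standard"]
  scr <- divergence_screen(d, refs)
  expect_false(any(scr$flagged))
  expect_true(all(scr$z == 0))
})
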