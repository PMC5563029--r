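# Fixture builders and independent brute-force oracles shared by the suite.

make_sites <- function(n) {
  data.frame(site_id = sprintf("s%04d", seq_len(n)),
             position = (seq_len(n) - 1L) %% 64L,
             ref = rep("A", n), alt = rep("C", n),
             stringsAsFactors = FALSE)
}

make_samples <- function(ids, ploidy, label = ids, raw = 2e6,
                         role = "standard") {
  data.frame(sample_id = ids, group_label = label,
             ploidy = as.integer(ploidy),
             raw_read_count = as.integer(raw), role = role,
             stringsAsFactors = FALSE)
}

# Build a genotype_table from a dosage matrix; allele depths are derived
# proportionally so the table invariants hold.
make_table <- function(dosage, ploidy, depth = NULL, label = NULL,
                       raw = 2e6, role = "standard") {
  dosage <- as.matrix(dosage)
  ns <- nrow(dosage); np <- ncol(dosage)
  ids <- sprintf("smp%02d", seq_len(np))
  if (is.null(label)) label <- ids
  if (is.null(depth)) depth <- matrix(50L, ns, np)
  depth <- as.matrix(depth)
  pl <- rep_len(ploidy, np)
  ad_alt <- matrix(0L, ns, np)
  for (j in seq_len(np)) {
    d <- dosage[, j]
    ad_alt[, j] <- ifelse(is.na(d), 0L,
                          as.integer(round(depth[, j] * d / pl[j])))
  }
  genotype_table(make_sites(ns), make_samples(ids, pl, label, raw, role),
                 dosage, depth, depth - ad_alt, ad_alt)
}

# Random table with missing calls, for property tests (independent of the
# package's simulator).
random_table <- function(seed, n_sites = 30, n_samples = 6,
                         ploidies = c(2L, 3L, 4L), p_missing = 0.1) {
  withr::with_seed(seed, {
    pl <- ploidies[sample.int(length(ploidies), n_samples, replace = TRUE)]
    dosage <- matrix(NA_integer_, n_sites, n_samples)
    depth <- matrix(0L, n_sites, n_samples)
    for (j in seq_len(n_samples)) {
      dosage[, j] <- sample(0:pl[j], n_sites, replace = TRUE)
      miss <- runif(n_sites) < p_missing
      dosage[miss, j] <- NA_integer_
      depth[, j] <- ifelse(miss, 0L, sample(1:120, n_sites, replace = TRUE))
    }
    make_table(dosage, pl, depth)
  })
}

# Independent oracle for the differentiating-locus rule: collapse dosage
# to a genotype class by explicit case analysis and flag on inequality.
oracle_class <- function(dosage, ploidy) {
  if (is.na(dosage)) return("MISSING")
  if (dosage == 0) return("HOM_REF")
  if (dosage == ploidy) return("HOM_ALT")
  "HET"
}

oracle_pair_flag <- function(dosage_a, dosage_b, ploidy) {
  ca <- oracle_class(dosage_a, ploidy)
  cb <- oracle_class(dosage_b, ploidy)
  ca != cb
}

# Per-element brute-force Venn classifier.
oracle_venn_counts <- function(a, b, c) {
  u <- unique(c(a, b, c))
  key <- vapply(u, function(e) {
    paste0(as.integer(e %in% a), as.integer(e %in% b),
           as.integer(e %in% c))
  }, "")
  counts <- integer(7)
  names(counts) <- c("100", "010", "001", "110", "101", "011", "111")
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}

# Fixture for pairwise-matrix exactness: six triploid pools with planted
# per-pair counts of differentiating loci inside and outside the depth
# window. Loci planted for a pair are missing (depth 0) in every other
# pool, so each locus contributes to exactly one pair.
planted_pair_fixture <- function(n_pools = 6, in_window_depth = 50L,
                                 out_window_depth = 20L) {
  planted_in <- function(i, j) i + j       # planted in-window count
  planted_out <- function(i, j) 3L         # planted out-of-window count
  rows <- list()
  for (i in seq_len(n_pools - 1L)) {
    for (j in seq(i + 1L, n_pools)) {
      n_in <- planted_in(i, j); n_out <- planted_out(i, j)
      for (k in seq_len(n_in + n_out)) {
        d <- rep(NA_integer_, n_pools)
        dp <- rep(0L, n_pools)
        d[i] <- 0L; d[j] <- 3L
        dp[c(i, j)] <- if (k <= n_in) in_window_depth else out_window_depth
        rows[[length(rows) + 1L]] <- list(dosage = d, depth = dp)
      }
    }
  }
  dosage <- do.call(rbind, lapply(rows, `[[`, "dosage"))
  depth <- do.call(rbind, lapply(rows, `[[`, "depth"))
  expected_in <- matrix(0L, n_pools, n_pools)
  expected_all <- matrix(0L, n_pools, n_pools)
  for (i in seq_len(n_pools - 1L)) {
    for (j in seq(i + 1L, n_pools)) {
      expected_in[i, j] <- expected_in[j, i] <- planted_in(i, j)
      expected_all[i, j] <- expected_all[j, i] <-
        planted_in(i, j) + planted_out(i, j)
    }
  }
  list(pools = make_table(dosage, 3L, depth), expected_in = expected_in,
       expected_all = expected_all)
}

# Study-design layout used by divergence-screen recovery tests: 36
# standard references across six cultivar families plus 47 unknowns
# (42 clonal family members, 5 independent contaminants).
screen_study_layout <- function() {
  rbind(
    cultivar_set("Champion", 3, 6, "standard"),
    cultivar_set("MiniVerde", 3, 6, "standard"),
    cultivar_set("Tifdwarf", 3, 6, "standard"),
    cultivar_set("TifEagle", 3, 6, "standard"),
    cultivar_set("Tifgreen", 3, 6, "standard"),
    cultivar_set("Tifway", 3, 6, "standard", divergence = 0.05),
    cultivar_set("Champion", 3, 10, "desirable"),
    cultivar_set("Champion", 3, 15, "off_type"),
    cultivar_set("MiniVerde", 3, 4, "desirable"),
    cultivar_set("MiniVerde", 3, 7, "off_type"),
    cultivar_set("TifEagle", 3, 3, "desirable"),
    cultivar_set("TifEagle", 3, 3, "off_type"),
    cultivar_set(paste0("Contaminant", 1:5), 3, 1, "off_type",
                 contaminant = TRUE)
  )
}

# Orthogonal Procrustes residual (rotation/reflection + translation, no
# scaling): closed-form via SVD, independent of any MDS code.
procrustes_residual <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sqrt(sum((xc - yc %*% rot)^2))
}
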