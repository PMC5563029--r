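#' Define a set of simulated clonal cultivar families
#'
#' Convenience constructor for the `cultivars` table of [sim_config()].
#' Each row defines one batch of clonal replicate samples. Rows sharing a
#' `label` share one founder genotype (same clone sampled in different
#' roles); `contaminant = TRUE` rows are drawn as independent founders at
#' the contaminant divergence rate.
#'
#' @param label Cultivar / family name.
#' @param ploidy Ploidy (2, 3 or 4).
#' @param n_reps Number of replicate samples for this row.
#' @param role Sample role (`standard`, `desirable`, `off_type`,
#'   `progenitor`).
#' @param contaminant Logical; independent high-divergence founder.
#' @param divergence Optional per-family founder divergence probability,
#'   overriding the config-level default for this label.
#' @return A `data.frame` usable as (part of) a `cultivars` table.
#' @export
cultivar_set <- function(label, ploidy, n_reps, role,
                         contaminant = FALSE, divergence = NA_real_) {
  data.frame(label = label, ploidy = as.integer(ploidy),
             n_reps = as.integer(n_reps), role = role,
             contaminant = contaminant, divergence = divergence,
             stringsAsFactors = FALSE)
}

#' Study-design cultivar layout
#'
#' The default sampling design emulated by the generator: six triploid
#' standard cultivar families with six clonal replicates each (five of
#' common 'Tifgreen'-family origin plus the genetically distinct 'Tifway'),
#' 47 putting-green samples of unknown identity (42 clonal members of the
#' standard families in desirable/off-type roles plus 5 unrelated
#' contaminants), and diploid / tetraploid progenitor selections.
#'
#' @return A `cultivars` table for [sim_config()].
#' @export
study_cultivars <- function() {
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
                 contaminant = TRUE),
    cultivar_set(c("Cdactylon_A", "Cdactylon_B"), 4, 3, "progenitor",
                 divergence = 0.30),
    cultivar_set(c("Ctransvaalensis_A", "Ctransvaalensis_B"), 2, 3,
                 "progenitor", divergence = 0.30)
  )
}

#' Default morphology cluster parameters
#'
#' Three phenotypic clusters for the four measured traits (mm). Cluster
#' means for internode length and leaf length follow the published
#' cluster profile (internode 34.6 / 21.9 / 24.7 mm; leaf length
#' 14.9 / 9.9 / 29.8 mm); stolon diameter and leaf width sit in the
#' reported 0.7--0.8 mm and 2.0--2.2 mm ranges with no separation.
#' `weight` gives the expected cluster-size proportions (14/26/12 of 52).
#'
#' @return A `data.frame` with one row per cluster: trait means and SDs
#'   plus a sampling weight.
#' @export
default_morph_clusters <- function() {
  data.frame(
    cluster = 1:3,
    internode_mean = c(34.6, 21.9, 24.7), internode_sd = c(5, 4, 4),
    stolon_diam_mean = c(0.8, 0.7, 0.8), stolon_diam_sd = c(0.08, 0.08, 0.08),
    leaf_len_mean = c(14.9, 9.9, 29.8), leaf_len_sd = c(3, 2.5, 4),
    leaf_wid_mean = c(2.2, 2.0, 2.1), leaf_wid_sd = c(0.25, 0.25, 0.25),
    weight = c(14, 26, 12) / 52
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults
#' reproduce the emulated study design: per-sample negative-binomial GBS
#' depths with means 9.5 / 4.9 / 7.4 reads for diploid / triploid /
#' tetraploid samples, per-sample raw read totals log-uniform over
#' 1.3--13.9 million, rare contaminant founders, three-cluster morphology
#' and 2C genome sizes proportional to ploidy anchored at 1.61 pg for the
#' triploid family.
#'
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param n_loci Number of biallelic variant loci to simulate.
#' @param cultivars Cultivar layout table (see [cultivar_set()]).
#' @param within_family_divergence Per-locus probability that a family
#'   founder's genotype differs from the cross-family consensus.
#' @param contaminant_divergence Same, for contaminant founders.
#' @param somatic_mutation_rate Per-locus, per-sample probability of a
#'   single-allele dosage step away from the founder genotype.
#' @param depth_mean Named numeric vector of expected reads per call,
#'   indexed by ploidy (`"2"`, `"3"`, `"4"`).
#' @param depth_dispersion Negative-binomial size (dispersion) parameter.
#' @param sequencing_error Per-read probability of reporting the wrong
#'   allele.
#' @param raw_read_count_range Two-vector `(low, high)` of per-sample raw
#'   read totals; totals are drawn log-uniformly.
#' @param morph_cluster_params Morphology cluster table
#'   (see [default_morph_clusters()]).
#' @param flow_cv Coefficient of variation of simulated FL2-A readings.
#' @param genome_sizes Named numeric vector of 2C genome sizes (pg),
#'   indexed by ploidy.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 2000L,
                       cultivars = study_cultivars(),
                       within_family_divergence = 0.005,
                       contaminant_divergence = 0.30,
                       somatic_mutation_rate = 1e-3,
                       depth_mean = c("2" = 9.5, "3" = 4.9, "4" = 7.4),
                       depth_dispersion = 2,
                       sequencing_error = 0.01,
                       raw_read_count_range = c(1.3e6, 13.9e6),
                       morph_cluster_params = default_morph_clusters(),
                       flow_cv = 0.02,
                       genome_sizes = c("2" = 1.61 * 2 / 3, "3" = 1.61,
                                        "4" = 1.61 * 4 / 3)) {
  cfg <- structure(
    list(seed = as.integer(seed), n_loci = as.integer(n_loci),
         cultivars = cultivars,
         within_family_divergence = within_family_divergence,
         contaminant_divergence = contaminant_divergence,
         somatic_mutation_rate = somatic_mutation_rate,
         depth_mean = depth_mean, depth_dispersion = depth_dispersion,
         sequencing_error = sequencing_error,
         raw_read_count_range = raw_read_count_range,
         morph_cluster_params = morph_cluster_params,
         flow_cv = flow_cv, genome_sizes = genome_sizes),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg A [sim_config()].
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(cfg$within_family_divergence, cfg$contaminant_divergence,
             cfg$somatic_mutation_rate, cfg$sequencing_error)
  if (any(probs < 0) || any(probs > 1)) {
    stop("divergence, mutation and error rates must lie in [0, 1]")
  }
  if (any(cfg$depth_mean <= 0)) stop("depth_mean must be > 0")
  if (cfg$depth_dispersion <= 0) stop("depth_dispersion must be > 0")
  if (cfg$n_loci < 1L) stop("n_loci must be >= 1")
  if (cfg$flow_cv < 0) stop("flow_cv must be >= 0")
  if (any(cfg$genome_sizes <= 0)) stop("genome_sizes must be > 0")
  rr <- cfg$raw_read_count_range
  if (length(rr) != 2L || any(rr <= 0) || rr[2] < rr[1]) {
    stop("raw_read_count_range must be a positive (low, high) pair")
  }
  cv <- cfg$cultivars
  req <- c("label", "ploidy", "n_reps", "role")
  if (!all(req %in% names(cv))) {
    stop("cultivars table is missing columns: ",
         paste(setdiff(req, names(cv)), collapse = ", "))
  }
  if (!all(cv$ploidy %in% c(2L, 3L, 4L))) stop("cultivar ploidy must be 2-4")
  if (!all(as.character(cv$ploidy) %in% names(cfg$depth_mean))) {
    stop("depth_mean is missing an entry for some ploidy in cultivars")
  }
  mc <- cfg$morph_cluster_params
  sd_cols <- grep("_sd$", names(mc), value = TRUE)
  if (any(as.matrix(mc[sd_cols]) < 0)) stop("morphology SDs must be >= 0")
  invisible(cfg)
}

## round half away from zero (here arguments are >= 0, so half up)
round_half_away <- function(x) floor(x + 0.5)

#' Simulate a GBS genotype table
#'
#' Draws, per locus, a shared consensus alternate-allele fraction; each
#' cultivar family founder follows the per-ploidy consensus dosage except
#' at loci selected with its divergence probability, where dosage is
#' uniform over the `ploidy + 1` genotypes. Each replicate sample is its
#' founder plus rare somatic single-allele dosage steps. Per-call total
#' depth is negative-binomial; allele depths are binomial around the true
#' dosage fraction perturbed by the sequencing error rate (with error
#' rate exactly 0, reads reflect the true allele mix deterministically,
#' up to integer rounding). A call with zero reads is missing. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [genotype_table()] with a `truth` attribute: a list with the
#'   per-locus consensus fraction, the founder dosage matrix
#'   (loci x family), and a per-sample table of family, role and
#'   contaminant flag.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    nl <- config$n_loci
    cv <- config$cultivars
    if (is.null(cv$contaminant)) cv$contaminant <- FALSE
    if (is.null(cv$divergence)) cv$divergence <- NA_real_

    cons_frac <- stats::runif(nl)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nl, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    sites <- data.frame(
      site_id = sprintf("tag%06d", seq_len(nl)),
      position = sample(0:63, nl, replace = TRUE),
      ref = ref, alt = unname(alt), stringsAsFactors = FALSE
    )

    ## one founder per unique label
    labels <- unique(cv$label)
    founder <- matrix(NA_integer_, nl, length(labels),
                      dimnames = list(sites$site_id, labels))
    label_ploidy <- integer(length(labels)); names(label_ploidy) <- labels
    for (l in labels) {
      rows <- cv[cv$label == l, , drop = FALSE]
      if (length(unique(rows$ploidy)) != 1L) {
        stop("label '", l, "' declared with mixed ploidy")
      }
      p <- rows$ploidy[1]
      label_ploidy[l] <- p
      div <- rows$divergence[1]
      if (is.na(div)) {
        div <- if (isTRUE(rows$contaminant[1])) {
          config$contaminant_divergence
        } else {
          config$within_family_divergence
        }
      }
      fd <- as.integer(round_half_away(p * cons_frac))
      divergent <- stats::runif(nl) < div
      fd[divergent] <- sample(0:p, sum(divergent), replace = TRUE)
      founder[, l] <- fd
    }

    ## per-sample true genotypes
    role_tag <- c(standard = "ST", desirable = "DS", off_type = "OT",
                  progenitor = "PG")
    sample_rows <- list(); true_dosage <- list()
    for (i in seq_len(nrow(cv))) {
      l <- cv$label[i]; p <- cv$ploidy[i]
      for (r in seq_len(cv$n_reps[i])) {
        sid <- sprintf("%s_%s%02d", l, role_tag[[cv$role[i]]], r)
        d <- founder[, l]
        mut <- stats::runif(nl) < config$somatic_mutation_rate
        if (any(mut)) {
          step <- sample(c(-1L, 1L), sum(mut), replace = TRUE)
          dm <- d[mut] + step
          dm[dm < 0L] <- 1L        # step inward when at a bound
          dm[dm > p] <- p - 1L
          d[mut] <- dm
        }
        sample_rows[[length(sample_rows) + 1L]] <- data.frame(
          sample_id = sid, group_label = l, ploidy = p,
          raw_read_count = NA_integer_, role = cv$role[i],
          contaminant = isTRUE(cv$contaminant[i]),
          stringsAsFactors = FALSE
        )
        true_dosage[[length(true_dosage) + 1L]] <- d
      }
    }
    samples <- do.call(rbind, sample_rows)
    if (anyDuplicated(samples$sample_id)) {
      stop("cultivars layout produces duplicate sample ids; ",
           "split roles into separate rows per label")
    }
    np <- nrow(samples)
    dosage_true <- matrix(unlist(true_dosage), nl, np)

    ## raw read totals, log-uniform
    rr <- config$raw_read_count_range
    samples$raw_read_count <-
      as.integer(round(exp(stats::runif(np, log(rr[1]), log(rr[2])))))

    ## depths and allele depths
    mu <- config$depth_mean[as.character(samples$ploidy)]
    depth <- matrix(0L, nl, np); ad_alt <- matrix(0L, nl, np)
    for (j in seq_len(np)) {
      depth[, j] <- stats::rnbinom(nl, size = config$depth_dispersion,
                                   mu = mu[j])
      f_true <- dosage_true[, j] / samples$ploidy[j]
      e <- config$sequencing_error
      if (e == 0) {
        ## error-free reads reflect the true allele mix exactly, up to
        ## integer rounding
        ad_alt[, j] <- as.integer(round_half_away(depth[, j] * f_true))
      } else {
        p_alt <- f_true * (1 - e) + (1 - f_true) * e
        ad_alt[, j] <- stats::rbinom(nl, depth[, j], p_alt)
      }
    }
    ad_ref <- depth - ad_alt
    dosage <- dosage_true
    dosage[depth == 0L] <- NA_integer_   # no reads, no call

    truth <- list(
      consensus_fraction = cons_frac,
      founder_dosage = founder,
      samples = samples[, c("sample_id", "group_label", "role",
                            "contaminant")]
    )
    tab <- genotype_table(sites,
                          samples[, c("sample_id", "group_label", "ploidy",
                                      "raw_read_count", "role")],
                          dosage, depth, ad_ref, ad_alt)
    attr(tab, "truth") <- truth
    tab
  })
}

## positive truncated normal draw: redraw non-positive values
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    k <- x <= 0
    x[k] <- stats::rnorm(sum(k), mean, sd)
  }
  x
}

#' Simulate replicate morphology measurements
#'
#' Emulates the glasshouse measurement design: four replicate pots per
#' sample, three stolons per pot, measured on two dates, for 24 records
#' per sample. Variation is hierarchical, as in real morphometric data:
#' each sample draws its own true trait value from
#' `Normal(cluster mean, cluster SD)` (between-sample variation within a
#' phenotypic cluster), and each replicate record adds measurement noise
#' of the same SD around the sample's value. All draws are truncated at
#' zero. With SD 0 every record equals its cluster mean exactly.
#'
#' @param config A [sim_config()].
#' @param assignments Named integer vector mapping sample id to a cluster
#'   id present in `config$morph_cluster_params`.
#' @return A `data.frame` with columns `sample_id, date, pot, stolon,
#'   internode_mm, stolon_diam_mm, leaf_len_mm, leaf_wid_mm`.
#' @export
simulate_morphology <- function(config, assignments) {
  validate_sim_config(config)
  mc <- config$morph_cluster_params
  bad <- setdiff(unique(assignments), mc$cluster)
  if (length(bad)) stop("unknown cluster id(s): ", paste(bad, collapse = ", "))
  withr::with_seed(config$seed + 1L, {
    dates <- c("2014-06-03", "2014-06-25")
    grid <- expand.grid(stolon = 1:3, pot = 1:4, date = dates,
                        stringsAsFactors = FALSE)
    out <- vector("list", length(assignments))
    for (i in seq_along(assignments)) {
      row <- mc[mc$cluster == assignments[i], , drop = FALSE]
      n <- nrow(grid)
      ## sample-level true trait values, then replicate measurement noise
      s_int <- rnorm_pos(1, row$internode_mean, row$internode_sd)
      s_sto <- rnorm_pos(1, row$stolon_diam_mean, row$stolon_diam_sd)
      s_len <- rnorm_pos(1, row$leaf_len_mean, row$leaf_len_sd)
      s_wid <- rnorm_pos(1, row$leaf_wid_mean, row$leaf_wid_sd)
      out[[i]] <- data.frame(
        sample_id = names(assignments)[i],
        date = grid$date, pot = grid$pot, stolon = grid$stolon,
        internode_mm = rnorm_pos(n, s_int, row$internode_sd),
        stolon_diam_mm = rnorm_pos(n, s_sto, row$stolon_diam_sd),
        leaf_len_mm = rnorm_pos(n, s_len, row$leaf_len_sd),
        leaf_wid_mm = rnorm_pos(n, s_wid, row$leaf_wid_sd),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate flow-cytometry FL2-A readings
#'
#' The internal standard's mean FL2-A is a fixed positive constant; each
#' sample's reading is the standard scaled by the ratio of its configured
#' 2C genome size to the standard's 1.67 pg/2C, with multiplicative
#' normal noise of coefficient of variation `flow_cv` (truncated at 0).
#'
#' @param config A [sim_config()].
#' @param samples Sample metadata `data.frame` (needs `sample_id`,
#'   `ploidy`); every ploidy present must have an entry in
#'   `config$genome_sizes`.
#' @return A `data.frame` with columns `sample_id, fl2a_sample,
#'   fl2a_standard`.
#' @export
simulate_flow <- function(config, samples) {
  validate_sim_config(config)
  gs <- config$genome_sizes[as.character(samples$ploidy)]
  if (anyNA(gs)) {
    stop("no genome size configured for ploidy ",
         paste(unique(samples$ploidy[is.na(gs)]), collapse = ", "))
  }
  withr::with_seed(config$seed + 2L, {
    standard <- 1e5
    noise <- 1 + stats::rnorm(nrow(samples), 0, config$flow_cv)
    while (any(noise <= 0)) {
      k <- noise <= 0
      noise[k] <- 1 + stats::rnorm(sum(k), 0, config$flow_cv)
    }
    data.frame(sample_id = samples$sample_id,
               fl2a_sample = standard * (gs / 1.67) * noise,
               fl2a_standard = standard,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a complete study data set
#'
#' Runs [simulate_genotypes()], assigns the desirable/off-type samples to
#' morphology clusters deterministically in the configured cluster-size
#' proportions, and runs [simulate_morphology()] and [simulate_flow()].
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` ([genotype_table()]),
#'   `morphology`, `flow` (data frames) and `truth` (consensus fractions,
#'   founder dosages, per-sample contaminant flags and true morphology
#'   cluster labels).
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  truth <- attr(geno, "truth")
  unknown <- geno$samples$sample_id[
    geno$samples$role %in% c("desirable", "off_type")]
  mc <- config$morph_cluster_params
  w <- mc$weight / sum(mc$weight)
  n <- length(unknown)
  bounds <- round(cumsum(w) * n)
  sizes <- diff(c(0L, bounds))
  assignments <- stats::setNames(rep(mc$cluster, times = sizes), unknown)
  morph <- simulate_morphology(config, assignments)
  flow <- simulate_flow(config, geno$samples)
  truth$morph_cluster <- assignments
  list(genotypes = geno, morphology = morph, flow = flow, truth = truth)
}

#' Write simulated study data to disk
#'
#' Writes `genotypes.vcf`, `metadata.csv`, `morphology.csv`, `flow.csv`
#' and a `truth.json` sidecar (founder dosages, contaminant flags, true
#' cluster labels) for recovery tests.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_study_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    metadata = file.path(dir, "metadata.csv"),
    morphology = file.path(dir, "morphology.csv"),
    flow = file.path(dir, "flow.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$genotypes, paths[["vcf"]])
  utils::write.csv(sim$genotypes$samples, paths[["metadata"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$morphology, paths[["morphology"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$flow, paths[["flow"]], row.names = FALSE,
                   quote = FALSE)
  truth <- sim$truth
  truth$founder_dosage <- as.data.frame(truth$founder_dosage)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
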