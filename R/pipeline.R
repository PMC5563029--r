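#' Pipeline run configuration
#'
#' Collects the input paths and every stage parameter of the end-to-end
#' workflow with the module defaults, in the stage order: low-read
#' exclusion, per-cultivar pooling, informative-variant identification,
#' cross-ploidy Venn partition, IBS distance / MDS / divergence screen,
#' flow-cytometry genome sizes, and morphology clustering.
#'
#' @param vcf Path to the multi-sample VCF.
#' @param metadata Path to the sample-metadata CSV.
#' @param morphology Path to the morphology CSV.
#' @param flow Path to the flow-cytometry CSV.
#' @param out_dir Output directory for stage artifacts.
#' @param min_reads Raw-read exclusion threshold.
#' @param window A [depth_window()] (or `NULL`) for informative variants.
#' @param z_threshold Robust z threshold of the divergence screen.
#' @param mds_k MDS dimensions.
#' @param k Morphology cluster count.
#' @param seed Seed for k-means initialization.
#' @param standardize Standardize traits before clustering?
#' @param restarts K-means restarts.
#' @param reference_roles Roles whose samples act as references (pooling
#'   members and divergence-screen baseline).
#' @param ploidy_reference Genome-size reference table.
#' @param min_variant_depth Depth for [group_variant_set()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(vcf, metadata, morphology, flow, out_dir,
                       min_reads = 1e6, window = depth_window(),
                       z_threshold = 3.5, mds_k = 2L, k = 3L, seed = 1L,
                       standardize = FALSE, restarts = 10L,
                       reference_roles = "standard",
                       ploidy_reference = default_ploidy_reference(),
                       min_variant_depth = 1L) {
  paths <- list(vcf = vcf, metadata = metadata, morphology = morphology,
                flow = flow, out_dir = out_dir)
  for (f in names(paths)) {
    if (is.null(paths[[f]]) || !is.character(paths[[f]]) ||
        !nzchar(paths[[f]])) {
      stop("run_config: field '", f, "' must be a non-empty path")
    }
  }
  structure(
    c(paths,
      list(min_reads = min_reads, window = window,
           z_threshold = z_threshold, mds_k = as.integer(mds_k),
           k = as.integer(k), seed = as.integer(seed),
           standardize = isTRUE(standardize),
           restarts = as.integer(restarts),
           reference_roles = reference_roles,
           ploidy_reference = ploidy_reference,
           min_variant_depth = as.integer(min_variant_depth))),
    class = "run_config"
  )
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the end-to-end off-type characterization pipeline
#'
#' Executes every stage on the configured inputs and writes one artifact
#' file per stage under `out_dir`, plus a machine-readable
#' `manifest.json` (parameter values, seed, input checksums, stage
#' summaries). Outputs are plain TSV/JSON with no timestamps, so two runs
#' with the same configuration produce bit-identical files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   paths of all artifacts written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("vcf", "metadata", "morphology", "flow")) {
    if (!file.exists(config[[f]])) {
      stop("run_pipeline: input '", f, "' not found at ", config[[f]])
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  artifacts <- character(0)

  metadata <- read_sample_metadata(config$metadata)
  table <- read_vcf(config$vcf, metadata)

  ## stage: low-read exclusion
  retained <- exclude_low_read_samples(table, config$min_reads)
  excluded <- attr(retained, "excluded_samples")

  ## stage: pooling (triploid reference cultivars)
  pools <- pool_cultivars(retained, roles = config$reference_roles,
                          ploidy = 3L)
  depth_summary <- pool_depth_summary(pools)
  artifacts["pooled_vcf"] <- write_vcf(pools, out("pooled.vcf"))
  artifacts["pool_depth"] <- write_tsv(depth_summary,
                                       out("pool_depth_summary.tsv"))

  ## stage: informative variants
  pm <- pairwise_matrix(pools, config$window)
  dl <- differing_loci(pools, config$window)
  dl_all <- differing_loci(pools, window = NULL)
  pm_df <- data.frame(cultivar = rownames(pm), as.data.frame(unclass(pm)),
                      check.names = FALSE, stringsAsFactors = FALSE)
  artifacts["pairwise_matrix"] <- write_tsv(pm_df,
                                            out("pairwise_matrix.tsv"))
  artifacts["differing_loci"] <- write_tsv(dl, out("differing_loci.tsv"))

  ## stage: cross-ploidy Venn partition
  ploidies <- sort(unique(retained$samples$ploidy))
  if (length(ploidies) == 3L) {
    sets <- lapply(ploidies, function(p) {
      group_variant_set(retained,
                        retained$samples$sample_id[
                          retained$samples$ploidy == p],
                        config$min_variant_depth)
    })
    names(sets) <- paste0(ploidies, "x")
    vp <- venn(sets)
    venn_df <- data.frame(region = names(vp$regions),
                          n = unname(vp$regions),
                          stringsAsFactors = FALSE)
    venn_df <- rbind(venn_df,
                     data.frame(region = paste0("total_", names(vp$totals)),
                                n = unname(vp$totals)))
    artifacts["venn"] <- write_tsv(venn_df, out("venn_partition.tsv"))
  } else {
    vp <- NULL
  }

  ## stage: distance, MDS, divergence screen
  d <- ibs_distance(retained)
  mds <- classical_mds(d, config$mds_k)
  ref_ids <- retained$samples$sample_id[
    retained$samples$role %in% config$reference_roles &
      retained$samples$ploidy == 3L]
  tri_ids <- retained$samples$sample_id[retained$samples$ploidy == 3L]
  screen <- divergence_screen(d[tri_ids, tri_ids, drop = FALSE], ref_ids,
                              config$z_threshold)
  d_df <- data.frame(sample_id = rownames(d), as.data.frame(d),
                     check.names = FALSE, stringsAsFactors = FALSE)
  coords <- data.frame(sample_id = rownames(mds$coordinates),
                       mds$coordinates, check.names = FALSE,
                       stringsAsFactors = FALSE)
  artifacts["distance"] <- write_tsv(d_df, out("distance_matrix.tsv"))
  artifacts["mds"] <- write_tsv(coords, out("mds_coordinates.tsv"))
  artifacts["divergence"] <- write_tsv(screen, out("divergence_screen.tsv"))

  ## stage: genome size
  flow <- utils::read.csv(config$flow, stringsAsFactors = FALSE)
  gsr <- genome_size_report(flow, config$ploidy_reference)
  artifacts["genome_size"] <- write_tsv(gsr, out("genome_size.tsv"))

  ## stage: morphology clustering
  records <- utils::read.csv(config$morphology, stringsAsFactors = FALSE)
  morph <- aggregate_replicates(records)
  clust <- kmeans_cluster(morph, k = config$k, seed = config$seed,
                          standardize = config$standardize,
                          restarts = config$restarts)
  summ <- summarize_clusters(clust)
  assign_df <- data.frame(sample_id = names(clust$assignments),
                          cluster = unname(clust$assignments),
                          stringsAsFactors = FALSE)
  artifacts["assignments"] <- write_tsv(assign_df,
                                        out("morphology_clusters.tsv"))
  artifacts["cluster_summary"] <- write_tsv(summ$summary,
                                            out("cluster_summary.tsv"))
  artifacts["cluster_flags"] <- write_tsv(summ$flags,
                                          out("cluster_flags.tsv"))
  diagnostics <- list(k = config$k, sizes = clust$sizes,
                      r_squared = clust$r_squared, ccc = clust$ccc,
                      ssw_per_cluster = clust$ssw_per_cluster)
  jsonlite::write_json(diagnostics, out("cluster_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts["diagnostics"] <- out("cluster_diagnostics.json")

  ## manifest
  manifest <- list(
    package = "offtypeR",
    version = as.character(utils::packageVersion("offtypeR")),
    seed = config$seed,
    parameters = list(
      min_reads = config$min_reads,
      window = if (is.null(config$window)) NULL else unclass(config$window),
      z_threshold = config$z_threshold, mds_k = config$mds_k,
      k = config$k, standardize = config$standardize,
      restarts = config$restarts,
      reference_roles = config$reference_roles,
      min_variant_depth = config$min_variant_depth
    ),
    inputs = stats::setNames(
      as.list(unname(tools::md5sum(unlist(config[c("vcf", "metadata",
                                                   "morphology",
                                                   "flow")])))),
      c("vcf", "metadata", "morphology", "flow")),
    excluded_samples = excluded,
    n_samples_retained = n_samples(retained),
    n_divergent_flagged = sum(screen$flagged),
    artifacts = as.list(basename(artifacts))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  artifacts["manifest"] <- out("manifest.json")

  invisible(list(
    table = table, retained = retained, pools = pools,
    pairwise_matrix = pm, differing_loci = dl,
    differing_loci_unwindowed = dl_all, venn = vp, distance = d,
    mds = mds, screen = screen, genome_size = gsr, morphology = morph,
    clusters = clust, cluster_summary = summ, artifacts = artifacts
  ))
}
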