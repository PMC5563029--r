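#' Exclude samples with too few raw reads
#'
#' Drops samples whose total raw read count falls below `min_reads`
#' (strictly: a sample with exactly `min_reads` reads is retained).
#' Excluded sample ids are reported in a message and attached as
#' attribute `excluded_samples`.
#'
#' @param table A [genotype_table()].
#' @param min_reads Minimum raw read count; default one million.
#' @return The restricted [genotype_table()].
#' @export
exclude_low_read_samples <- function(table, min_reads = 1e6) {
  stopifnot(inherits(table, "genotype_table"))
  if (anyNA(table$samples$raw_read_count)) {
    stop("raw_read_count missing for some sample")
  }
  keep <- table$samples$raw_read_count >= min_reads
  excluded <- table$samples$sample_id[!keep]
  if (length(excluded)) {
    message("excluded ", length(excluded), " sample(s) below ", min_reads,
            " raw reads: ", paste(excluded, collapse = ", "))
  }
  out <- subset_samples(table, table$samples$sample_id[keep])
  attr(out, "excluded_samples") <- excluded
  out
}

## Vectorized dosage re-caller: alternate dosage = round(ploidy * alt/total)
## with ties rounded half away from zero; NA where total depth is 0.
recall_dosage <- function(ad_ref, ad_alt, ploidy) {
  if (any(ad_ref < 0) || any(ad_alt < 0)) {
    stop("allele depths must be non-negative")
  }
  tot <- ad_ref + ad_alt
  d <- ifelse(tot == 0L, NA_integer_,
              as.integer(floor(ploidy * ad_alt / tot + 0.5)))
  d
}

#' Re-call a genotype from pooled allele depths
#'
#' Deterministic dosage caller used on pooled per-cultivar allele depths:
#' the alternate dosage is `round(ploidy * alt_depth / total_depth)` with
#' ties rounded half away from zero; zero total depth yields a missing
#' call. This replaces a probabilistic variant caller with a transparent
#' rule whose downstream consumers (genotype classes and depths) are
#' unaffected by the substitution.
#'
#' @param allele_depths Length-2 non-negative integer vector `(ref, alt)`.
#' @param ploidy Ploidy of the pooled cultivar (2, 3 or 4).
#' @return A [genotype_call()].
#' @export
#' @examples
#' recall_genotype(c(20, 10), 3) # alt fraction 1/3 -> 0/0/1
recall_genotype <- function(allele_depths, ploidy) {
  stopifnot(length(allele_depths) == 2L, ploidy %in% c(2L, 3L, 4L))
  if (any(allele_depths < 0)) stop("allele depths must be non-negative")
  allele_depths <- as.integer(allele_depths)
  d <- recall_dosage(allele_depths[1], allele_depths[2], ploidy)
  tot <- sum(allele_depths)
  if (is.na(d)) {
    genotype_call(missing = TRUE, ploidy = ploidy, depth_total = 0L,
                  allele_depths = c(0L, 0L))
  } else {
    genotype_call(c(rep(0L, ploidy - d), rep(1L, d)), depth_total = tot,
                  allele_depths = allele_depths)
  }
}

#' Pool clonal replicates of one cultivar
#'
#' Sums per-allele read depths across all member samples carrying the
#' given group label and re-calls the pooled genotype per site with
#' [recall_genotype()], increasing effective depth the way merging
#' alignment files before re-calling does. Pooled total depth at every
#' site equals the sum of member depths.
#'
#' @param table A [genotype_table()] (typically after
#'   [exclude_low_read_samples()]).
#' @param label Cultivar group label to pool.
#' @param roles Optional character vector restricting members to given
#'   roles (e.g. `"standard"`).
#' @return A single-sample [genotype_table()] whose one "sample" is the
#'   pooled cultivar (sample id = label, raw reads summed).
#' @export
pool_cultivar <- function(table, label, roles = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  member <- table$samples$group_label == label
  if (!is.null(roles)) member <- member & table$samples$role %in% roles
  if (!any(member)) stop("no samples with label '", label, "'")
  pl <- unique(table$samples$ploidy[member])
  if (length(pl) != 1L) {
    stop("samples under label '", label, "' have mixed ploidy")
  }
  ad_ref <- rowSums(table$ad_ref[, member, drop = FALSE])
  ad_alt <- rowSums(table$ad_alt[, member, drop = FALSE])
  depth <- ad_ref + ad_alt
  dosage <- recall_dosage(ad_ref, ad_alt, pl)
  role <- if (all(table$samples$role[member] == table$samples$role[member][1]))
    table$samples$role[member][1] else "standard"
  samples <- data.frame(
    sample_id = label, group_label = label, ploidy = pl,
    raw_read_count = sum(table$samples$raw_read_count[member]),
    role = role, stringsAsFactors = FALSE
  )
  genotype_table(table$sites, samples,
                 matrix(dosage, ncol = 1), matrix(as.integer(depth), ncol = 1),
                 matrix(as.integer(ad_ref), ncol = 1),
                 matrix(as.integer(ad_alt), ncol = 1))
}

#' Pool every cultivar of a genotype table
#'
#' Applies [pool_cultivar()] to each distinct group label (optionally
#' restricted by role and ploidy) and binds the pools into one table with
#' one column per cultivar.
#'
#' @param table A [genotype_table()].
#' @param roles Optional role filter for member samples.
#' @param ploidy Optional ploidy filter for pooled cultivars.
#' @return A [genotype_table()] of pooled cultivars.
#' @export
pool_cultivars <- function(table, roles = NULL, ploidy = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  sel <- rep(TRUE, n_samples(table))
  if (!is.null(roles)) sel <- sel & table$samples$role %in% roles
  if (!is.null(ploidy)) sel <- sel & table$samples$ploidy %in% ploidy
  labels <- unique(table$samples$group_label[sel])
  if (!length(labels)) stop("no samples match the requested roles/ploidy")
  pools <- lapply(labels, function(l) pool_cultivar(table, l, roles = roles))
  out <- pools[[1]]
  if (length(pools) > 1L) {
    samples <- do.call(rbind, lapply(pools, `[[`, "samples"))
    bind <- function(f) do.call(cbind, lapply(pools, `[[`, f))
    out <- genotype_table(table$sites, samples, bind("dosage"),
                          bind("depth"), bind("ad_ref"), bind("ad_alt"))
  }
  out
}

#' Depth summary of pooled cultivars
#'
#' @param pools A pooled [genotype_table()] from [pool_cultivars()].
#' @return A `data.frame` with columns `cultivar`, `mean_depth` (mean
#'   pooled depth over covered sites), `n_sites_covered`.
#' @export
pool_depth_summary <- function(pools) {
  stopifnot(inherits(pools, "genotype_table"))
  data.frame(
    cultivar = pools$samples$sample_id,
    mean_depth = vapply(seq_len(n_samples(pools)), function(j) {
      d <- pools$depth[, j]
      if (any(d > 0L)) mean(d[d > 0L]) else 0
    }, numeric(1)),
    n_sites_covered = colSums(pools$depth > 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
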