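#' Construct a genotype table
#'
#' The central container: a rectangular sites-by-samples grid of
#' ploidy-aware biallelic genotype calls plus per-sample metadata.
#' Internally the grid is held as four aligned matrices (alternate-allele
#' dosage, total depth, reference-allele depth, alternate-allele depth);
#' a missing call is an `NA` dosage. Row order follows `sites`, column
#' order follows `samples`.
#'
#' @param sites `data.frame` with columns `site_id` (unique tag
#'   identifiers), `position` (0-based integer within the tag),
#'   `ref` and `alt` (allele strings, `ref != alt`).
#' @param samples `data.frame` with columns `sample_id` (unique),
#'   `group_label`, `ploidy` (2, 3 or 4), `raw_read_count` (>= 0) and
#'   `role` (one of `standard`, `desirable`, `off_type`, `progenitor`).
#' @param dosage Integer matrix (sites x samples) of alternate-allele
#'   counts, `NA` for missing calls; entry must lie in `0..ploidy` of its
#'   sample.
#' @param depth Integer matrix of total read depths (>= 0).
#' @param ad_ref,ad_alt Integer matrices of per-allele read depths;
#'   `ad_ref + ad_alt == depth` everywhere.
#'
#' @return An object of class `genotype_table`.
#' @seealso [read_vcf()], [write_vcf()], [call_at()]
#' @export
genotype_table <- function(sites, samples, dosage, depth, ad_ref, ad_alt) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  dosage <- as.matrix(dosage); storage.mode(dosage) <- "integer"
  depth <- as.matrix(depth); storage.mode(depth) <- "integer"
  ad_ref <- as.matrix(ad_ref); storage.mode(ad_ref) <- "integer"
  ad_alt <- as.matrix(ad_alt); storage.mode(ad_alt) <- "integer"
  dimnames(dosage) <- dimnames(depth) <- dimnames(ad_ref) <-
    dimnames(ad_alt) <- list(sites$site_id, samples$sample_id)
  x <- structure(
    list(sites = sites, samples = samples, dosage = dosage, depth = depth,
         ad_ref = ad_ref, ad_alt = ad_alt),
    class = "genotype_table"
  )
  validate_genotype_table(x)
  x
}

#' Validate genotype-table invariants
#'
#' Checks rectangularity, unique site and sample identifiers, allele-depth
#' additivity (`ad_ref + ad_alt == depth`) and that every non-missing
#' dosage lies in `0..ploidy` of its sample.
#'
#' @param x A [genotype_table()].
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_genotype_table <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  req_site <- c("site_id", "position", "ref", "alt")
  req_samp <- c("sample_id", "group_label", "ploidy", "raw_read_count", "role")
  if (!all(req_site %in% names(x$sites))) {
    stop("sites is missing columns: ",
         paste(setdiff(req_site, names(x$sites)), collapse = ", "))
  }
  if (!all(req_samp %in% names(x$samples))) {
    stop("samples is missing columns: ",
         paste(setdiff(req_samp, names(x$samples)), collapse = ", "))
  }
  if (anyDuplicated(x$sites$site_id)) stop("site_id values must be unique")
  if (anyDuplicated(x$samples$sample_id)) {
    stop("sample_id values must be unique")
  }
  if (any(x$sites$ref == x$sites$alt)) {
    stop("ref and alt alleles must differ at every site")
  }
  if (!all(x$samples$ploidy %in% c(2L, 3L, 4L))) {
    stop("ploidy must be 2, 3 or 4")
  }
  if (any(x$samples$raw_read_count < 0)) {
    stop("raw_read_count must be non-negative")
  }
  ns <- nrow(x$sites); np <- nrow(x$samples)
  for (m in c("dosage", "depth", "ad_ref", "ad_alt")) {
    if (!identical(dim(x[[m]]), c(ns, np))) {
      stop("matrix '", m, "' is not sites x samples")
    }
  }
  if (any(x$depth < 0L) || any(x$ad_ref < 0L) || any(x$ad_alt < 0L)) {
    stop("read depths must be non-negative")
  }
  if (!all(x$ad_ref + x$ad_alt == x$depth)) {
    stop("allele depths must sum to total depth at every call")
  }
  if (ns > 0L && np > 0L) {
    pl <- matrix(x$samples$ploidy, nrow = ns, ncol = np, byrow = TRUE)
    bad <- !is.na(x$dosage) & (x$dosage < 0L | x$dosage > pl)
    if (any(bad)) stop("dosage outside 0..ploidy for some call")
  }
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table: %d sites x %d samples; %.1f%% missing>\n",
              nrow(x$sites), nrow(x$samples),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Number of sites / samples in a genotype table
#' @param x A [genotype_table()].
#' @return Integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) nrow(x$samples)

#' Extract one genotype call from a table
#'
#' @param x A [genotype_table()].
#' @param site Site identifier or row index.
#' @param sample Sample identifier or column index.
#' @return A [genotype_call()].
#' @export
call_at <- function(x, site, sample) {
  stopifnot(inherits(x, "genotype_table"))
  i <- if (is.character(site)) match(site, x$sites$site_id) else as.integer(site)
  j <- if (is.character(sample)) match(sample, x$samples$sample_id) else as.integer(sample)
  if (is.na(i) || i < 1L || i > n_sites(x)) stop("unknown site: ", site)
  if (is.na(j) || j < 1L || j > n_samples(x)) stop("unknown sample: ", sample)
  p <- x$samples$ploidy[j]
  d <- x$dosage[i, j]
  if (is.na(d)) {
    genotype_call(missing = TRUE, ploidy = p, depth_total = x$depth[i, j],
                  allele_depths = c(x$ad_ref[i, j], x$ad_alt[i, j]))
  } else {
    genotype_call(c(rep(0L, p - d), rep(1L, d)), depth_total = x$depth[i, j],
                  allele_depths = c(x$ad_ref[i, j], x$ad_alt[i, j]))
  }
}

#' Restrict a genotype table to a subset of samples
#'
#' @param x A [genotype_table()].
#' @param sample_ids Character vector of sample identifiers to keep, in
#'   the order given.
#' @return A [genotype_table()] with the selected columns.
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "genotype_table"))
  j <- match(sample_ids, x$samples$sample_id)
  if (anyNA(j)) {
    stop("unknown sample(s): ",
         paste(sample_ids[is.na(j)], collapse = ", "))
  }
  genotype_table(x$sites, x$samples[j, , drop = FALSE],
                 x$dosage[, j, drop = FALSE], x$depth[, j, drop = FALSE],
                 x$ad_ref[, j, drop = FALSE], x$ad_alt[, j, drop = FALSE])
}

## Dosage-fraction matrix (sites x samples): dosage / ploidy, NA kept.
dosage_fraction_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  sweep(x$dosage, 2L, x$samples$ploidy, "/")
}
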