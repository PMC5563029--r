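#' Read-depth window for informative-variant filtering
#'
#' Loci are compared between cultivar pairs only where both pooled
#' cultivars' read depths fall inside the window. The default window is
#' `[40, 100)`: depth at least 40 and strictly less than 100. Setting
#' `high_inclusive = TRUE` selects the alternative "no more than 100"
#' dialect, under which depth 100 is retained.
#'
#' @param low Inclusive lower depth bound (>= 0).
#' @param high Upper depth bound (>= `low`).
#' @param high_inclusive Logical; whether `high` itself passes.
#' @return An object of class `depth_window`.
#' @export
depth_window <- function(low = 40L, high = 100L, high_inclusive = FALSE) {
  low <- as.numeric(low); high <- as.numeric(high)
  if (low < 0 || high < low) stop("need 0 <= low <= high")
  structure(list(low = low, high = high,
                 high_inclusive = isTRUE(high_inclusive)),
            class = "depth_window")
}

#' Does a call's depth pass a window?
#'
#' @param call A non-missing [genotype_call()], or a numeric vector of
#'   total depths.
#' @param window A [depth_window()], or `NULL` for no filtering (always
#'   `TRUE`).
#' @return Logical (vector).
#' @export
passes_window <- function(call, window) {
  depth <- if (inherits(call, "genotype_call")) {
    if (call$missing) stop("passes_window is undefined for a missing call")
    call$depth_total
  } else {
    as.numeric(call)
  }
  if (is.null(window)) return(rep(TRUE, length(depth)))
  stopifnot(inherits(window, "depth_window"))
  upper <- if (window$high_inclusive) depth <= window$high
           else depth < window$high
  depth >= window$low & upper
}

#' Differentiating-locus flag for one cultivar pair
#'
#' A locus differentiates two cultivars when their genotype classes
#' (homozygous reference / heterozygous / homozygous alternate) differ.
#' Heterozygotes of differing allele dosage -- e.g. `0/0/1` versus
#' `0/1/1` in triploids -- are the same class and are deliberately NOT
#' flagged, since dosage differences within heterozygotes cannot be
#' attributed to a subgenome without phasing.
#'
#' @param call_a,call_b Non-missing [genotype_call()]s of equal ploidy.
#' @return Logical.
#' @export
#' @examples
#' a <- recall_genotype(c(30, 0), 3)   # 0/0/0
#' b <- recall_genotype(c(0, 30), 3)   # 1/1/1
#' pair_flag(a, b)                      # TRUE
pair_flag <- function(call_a, call_b) {
  stopifnot(inherits(call_a, "genotype_call"),
            inherits(call_b, "genotype_call"))
  if (call_a$missing || call_b$missing) {
    stop("pair_flag requires two non-missing calls")
  }
  if (call_a$ploidy != call_b$ploidy) {
    stop("ploidy mismatch: ", call_a$ploidy, " vs ", call_b$ploidy)
  }
  genotype_class(call_a) != genotype_class(call_b)
}

## Per-pair site mask and flag count on pooled class/depth matrices.
pair_site_flags <- function(pools, i, j, window) {
  ok <- !is.na(pools$dosage[, i]) & !is.na(pools$dosage[, j])
  if (!is.null(window)) {
    ok <- ok & passes_window(pools$depth[, i], window) &
      passes_window(pools$depth[, j], window)
  }
  p <- pools$samples$ploidy
  ci <- class_from_dosage(pools$dosage[, i], p[i])
  cj <- class_from_dosage(pools$dosage[, j], p[j])
  ok & ci != cj
}

#' Pairwise differentiating-variant count matrix
#'
#' Counts, for every pair of pooled cultivars, the loci where both pools
#' are called, both pass the depth window (if one is given), and the
#' genotype classes differ ([pair_flag()]). Sites failing the window or
#' missing in either pool are skipped for that pair only.
#'
#' @param pools A pooled [genotype_table()] (>= 2 cultivars, equal
#'   ploidy).
#' @param window A [depth_window()] or `NULL` for no depth filtering.
#' @return An object of class `pairwise_diff_matrix`: a symmetric,
#'   zero-diagonal integer matrix with cultivar labels as dimnames.
#' @export
pairwise_matrix <- function(pools, window = depth_window()) {
  stopifnot(inherits(pools, "genotype_table"))
  n <- n_samples(pools)
  if (n < 2L) stop("need at least two pooled cultivars")
  if (length(unique(pools$samples$ploidy)) != 1L) {
    stop("pairwise comparison requires equal ploidy across cultivars")
  }
  labels <- pools$samples$sample_id
  counts <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      k <- sum(pair_site_flags(pools, i, j, window))
      counts[i, j] <- counts[j, i] <- as.integer(k)
    }
  }
  structure(counts, class = c("pairwise_diff_matrix", class(counts)))
}

#' Loci differentiating at least one cultivar pair
#'
#' @param pools A pooled [genotype_table()] (>= 2 cultivars, equal
#'   ploidy).
#' @param window A [depth_window()] or `NULL`.
#' @return A `data.frame` with columns `site_id` and `n_flagging_pairs`
#'   (> 0), one row per differentiating locus, in site order.
#' @export
differing_loci <- function(pools, window = depth_window()) {
  stopifnot(inherits(pools, "genotype_table"))
  n <- n_samples(pools)
  if (n < 2L) stop("need at least two pooled cultivars")
  if (length(unique(pools$samples$ploidy)) != 1L) {
    stop("pairwise comparison requires equal ploidy across cultivars")
  }
  n_flag <- integer(n_sites(pools))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      n_flag <- n_flag + pair_site_flags(pools, i, j, window)
    }
  }
  data.frame(site_id = pools$sites$site_id[n_flag > 0L],
             n_flagging_pairs = n_flag[n_flag > 0L],
             stringsAsFactors = FALSE, row.names = NULL)
}
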