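#' Identity-by-state dosage distance matrix
#'
#' A ploidy-aware pairwise genotype distance: for samples `a` and `b`,
#' the mean over co-called sites of the absolute difference of their
#' alternate-allele dosage fractions. For diploids this reduces to the
#' usual allele-sharing (IBS) distance scaled to `[0, 1]`; across
#' ploidies it compares genotypes on the common dosage-fraction scale.
#'
#' @param table A [genotype_table()] with at least two samples.
#' @param min_shared_sites Minimum number of co-called sites a pair must
#'   share.
#' @param allow_missing_pairs If `TRUE`, a pair below the threshold gets
#'   an `NA` entry instead of an error.
#' @return A symmetric numeric matrix with zero diagonal and entries in
#'   `[0, 1]`, sample ids as dimnames.
#' @export
ibs_distance <- function(table, min_shared_sites = 1L,
                         allow_missing_pairs = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  n <- n_samples(table)
  if (n < 2L) stop("need at least two samples")
  f <- dosage_fraction_matrix(table)
  ids <- table$samples$sample_id
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- !is.na(f[, i]) & !is.na(f[, j])
      m <- sum(shared)
      if (m < min_shared_sites) {
        if (allow_missing_pairs) {
          d[i, j] <- d[j, i] <- NA_real_
          next
        }
        stop("samples '", ids[i], "' and '", ids[j], "' share only ", m,
             " co-called site(s)")
      }
      d[i, j] <- d[j, i] <- mean(abs(f[shared, i] - f[shared, j]))
    }
  }
  d
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a distance matrix: double-center the squared
#' distances, eigendecompose, and scale the top eigenvectors by the
#' square roots of their (positive) eigenvalues. If fewer than `k`
#' eigenvalues are positive the returned dimensionality is reduced with
#' a warning. For determinism each axis's sign is fixed so that its
#' largest-magnitude coordinate is positive.
#'
#' @param d Symmetric distance matrix (e.g. from [ibs_distance()]).
#' @param k Number of requested dimensions (>= 1).
#' @return An object of class `mds_result`: list with `coordinates`
#'   (samples x k, column means zero) and `eigenvalues` (non-increasing,
#'   positive).
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(d)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = min(k, n - 1L), eig = TRUE)
  )
  pts <- fit$points
  n_pos <- ncol(pts)
  if (n_pos < k) {
    warning("only ", n_pos, " positive eigenvalue(s); returning ", n_pos,
            " dimension(s) instead of ", k)
  }
  kk <- min(k, n_pos)
  pts <- pts[, seq_len(kk), drop = FALSE]
  for (a in seq_len(kk)) {
    i <- which.max(abs(pts[, a]))
    if (pts[i, a] < 0) pts[, a] <- -pts[, a]
  }
  colnames(pts) <- paste0("dim", seq_len(kk))
  structure(list(coordinates = pts, eigenvalues = fit$eig[seq_len(kk)]),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result: %d samples x %d dims; eigenvalues %s>\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' Screen for samples genetically divergent from reference standards
#'
#' Scores every sample by its mean distance to the reference (standard
#' cultivar) samples, self excluded, and converts the score to a robust
#' z-value against the reference samples' own score distribution:
#' `z = (score - median(ref scores)) / (1.4826 * MAD(ref scores))`.
#' Samples with `z > threshold` are flagged divergent. Reference samples
#' are scored and can be flagged too. If the reference MAD is zero, any
#' sample scoring above the median is flagged (with a warning); if all
#' scores are equal, no sample is flagged.
#'
#' @param d Distance matrix (e.g. from [ibs_distance()]).
#' @param reference_ids Ids of at least three reference samples.
#' @param threshold Robust z threshold (default 3.5).
#' @return A `data.frame` with columns `sample_id`, `score`, `z`,
#'   `flagged`.
#' @export
divergence_screen <- function(d, reference_ids, threshold = 3.5) {
  d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix needs sample ids as dimnames")
  miss <- setdiff(reference_ids, ids)
  if (length(miss)) {
    stop("reference sample(s) absent from distance matrix: ",
         paste(miss, collapse = ", "))
  }
  if (length(reference_ids) < 3L) stop("need at least 3 reference samples")
  score <- vapply(ids, function(s) {
    refs <- setdiff(reference_ids, s)
    mean(d[s, refs])
  }, numeric(1))
  baseline <- score[reference_ids]
  med <- stats::median(baseline)
  madv <- stats::mad(baseline)  # constant 1.4826
  if (madv == 0) {
    z <- ifelse(score > med, Inf, 0)
    if (any(z > threshold)) {
      warning("degenerate baseline (MAD = 0): flagging every sample ",
              "scoring above the reference median")
    }
  } else {
    z <- (score - med) / madv
  }
  data.frame(sample_id = ids, score = unname(score), z = unname(z),
             flagged = unname(z > threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}
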