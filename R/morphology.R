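#' Aggregate replicate morphology records per sample
#'
#' Averages each measured trait over all pots, stolons and dates of a
#' sample, then derives the leaf length:width ratio (LWR) from the
#' aggregated leaf means (rather than averaging per-record ratios, which
#' is unstable under measurement noise).
#'
#' @param records `data.frame` with columns `sample_id`, `internode_mm`,
#'   `stolon_diam_mm`, `leaf_len_mm`, `leaf_wid_mm` (all positive);
#'   replicate-structure columns (`date`, `pot`, `stolon`) are ignored.
#' @param sample_ids Optional ids that must all be present; a listed
#'   sample with zero records is an error.
#' @return A `data.frame` with one row per sample: the four trait means
#'   plus `lwr`.
#' @export
aggregate_replicates <- function(records, sample_ids = NULL) {
  traits <- c("internode_mm", "stolon_diam_mm", "leaf_len_mm",
              "leaf_wid_mm")
  if (!all(c("sample_id", traits) %in% names(records))) {
    stop("records are missing columns: ",
         paste(setdiff(c("sample_id", traits), names(records)),
               collapse = ", "))
  }
  if (nrow(records) == 0L) stop("no morphology records")
  if (any(as.matrix(records[traits]) <= 0)) {
    stop("all trait measurements must be positive")
  }
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, records$sample_id)
    if (length(absent)) {
      stop("no records for sample(s): ", paste(absent, collapse = ", "))
    }
  }
  agg <- stats::aggregate(records[traits],
                          by = list(sample_id = records$sample_id),
                          FUN = mean)
  agg <- agg[match(unique(records$sample_id), agg$sample_id), , drop = FALSE]
  agg$lwr <- agg$leaf_len_mm / agg$leaf_wid_mm
  rownames(agg) <- NULL
  agg
}

## k-means++ initial centers (Arthur & Vassilvitskii seeding)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (c in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1L, prob = prob)
      centers[c, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[c, ])^2))
    }
  }
  centers
}

## Squared distances of points to each center: n x k matrix
dist2_to_centers <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(sweep(-2 * cross, 2L, rowSums(centers^2), "+"), 1L,
        rowSums(x^2), "+")
}

## One Lloyd run from given centers; empty clusters are reseeded from the
## point farthest from its center. SSW is asserted non-increasing.
lloyd_run <- function(x, centers, iter_max = 300L) {
  k <- nrow(centers)
  assign_prev <- rep(0L, nrow(x))
  ssw_prev <- Inf
  for (it in seq_len(iter_max)) {
    d2 <- dist2_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    ## reseed empty clusters from the farthest point
    for (c in which(tabulate(assign, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
      centers[c, ] <- x[far, ]
      message("kmeans: reseeded empty cluster ", c, " from farthest point")
      d2 <- dist2_to_centers(x, centers)
      assign <- max.col(-d2, ties.method = "first")
    }
    ssw <- sum(d2[cbind(seq_len(nrow(x)), assign)])
    if (ssw > ssw_prev + 1e-8 * max(1, ssw_prev)) {
      stop("internal error: SSW increased during Lloyd iteration")
    }
    converged <- identical(assign, assign_prev)
    assign_prev <- assign
    ssw_prev <- ssw
    for (c in seq_len(k)) {
      centers[c, ] <- colMeans(x[assign == c, , drop = FALSE])
    }
    if (converged) break
  }
  d2 <- dist2_to_centers(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  ssw <- sum(d2[cbind(seq_len(nrow(x)), assign)])
  list(assignments = assign, centers = centers, ssw = ssw)
}

#' K-means clustering of morphology samples
#'
#' Clusters the five-trait vectors (four measured traits plus LWR) with
#' Lloyd's algorithm under k-means++ initialization, keeping the best of
#' `restarts` runs by within-cluster sum of squares. Reports
#' `r_squared = 1 - SSW/SST` and the cubic clustering criterion
#' ([cubic_clustering_criterion()]; `NA` when `k < 2`).
#'
#' @param samples Aggregated trait table from [aggregate_replicates()],
#'   or any data frame with a `sample_id` column and numeric trait
#'   columns.
#' @param k Number of clusters (`1 <= k <= n`).
#' @param seed Integer seed for initialization.
#' @param standardize If `TRUE`, traits are scaled to unit variance
#'   before clustering (traits have heterogeneous units).
#' @param restarts Number of k-means++ restarts.
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return An object of class `cluster_result`: list with `assignments`
#'   (named integer vector), `centers`, `sizes`, `ssw`, `ssw_per_cluster`,
#'   `sst`, `r_squared`, `ccc`, `traits` (the matrix clustered, after any
#'   standardization) and `samples` (the input trait table).
#' @export
kmeans_cluster <- function(samples, k = 3L, seed = 1L, standardize = FALSE,
                           restarts = 10L, iter_max = 300L) {
  trait_cols <- setdiff(names(samples), "sample_id")
  x <- as.matrix(samples[trait_cols])
  if (!is.numeric(x)) stop("trait columns must be numeric")
  n <- nrow(x)
  if (k < 1L || k > n) stop("need 1 <= k <= number of samples (", n, ")")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
    x <- x[, , drop = FALSE]
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  best <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- lloyd_run(x, kmeanspp_init(x, k), iter_max)
      if (is.null(best) || fit$ssw < best$ssw) best <- fit
    }
    best
  })
  sst <- sum(scale(x, center = TRUE, scale = FALSE)^2)
  r2 <- if (sst > 0) 1 - best$ssw / sst else 0
  ssw_per <- vapply(seq_len(k), function(c) {
    xi <- x[best$assignments == c, , drop = FALSE]
    sum(scale(xi, center = TRUE, scale = FALSE)^2)
  }, numeric(1))
  ccc <- if (k >= 2L && n > k) {
    cubic_clustering_criterion(x, best$assignments)
  } else {
    NA_real_
  }
  centers <- best$centers
  dimnames(centers) <- list(paste0("cluster", seq_len(k)), trait_cols)
  structure(
    list(assignments = stats::setNames(best$assignments,
                                       samples$sample_id),
         centers = centers, sizes = tabulate(best$assignments, k),
         ssw = best$ssw, ssw_per_cluster = ssw_per, sst = sst,
         r_squared = r2, ccc = ccc, traits = x, samples = samples),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k=%d sizes=%s R2=%.3f CCC=%s>\n",
              nrow(x$centers), paste(x$sizes, collapse = "/"),
              x$r_squared,
              if (is.na(x$ccc)) "NA" else sprintf("%.2f", x$ccc)))
  invisible(x)
}

#' Cubic clustering criterion (Sarle's approximation)
#'
#' Compares the observed clustering R-squared to its expectation under a
#' null of uniform sampling from a hyperbox whose edges are proportional
#' to the square roots of the data's covariance eigenvalues. The box is
#' notionally tiled by `q` hypercube cells of edge `c`; the effective
#' dimensionality `p*` is the number of axes longer than the cell edge,
#' determined by a fixed-point iteration (the cell edge depends on which
#' axes count). With scaled axis lengths `u_j = s_j / c`,
#' \deqn{E[R^2] = 1 - \frac{\sum_{j \le p^*} (n+u_j)^{-1} +
#'   \sum_{j > p^*} u_j^2 (n+u_j)^{-1}}{\sum_j u_j^2}
#'   \cdot \frac{(n-q)^2}{n} \cdot \left(1 + \frac{4}{n}\right)}
#' and the criterion is
#' \deqn{CCC = \ln\!\frac{1 - E[R^2]}{1 - R^2} \cdot
#'   \frac{\sqrt{n p^*/2}}{(0.001 + E[R^2])^{1.2}}.}
#' Large positive values support the clustering; negative values (the
#' observed R-squared below its null expectation) indicate a poor fit or
#' a unimodal/elongated structure.
#'
#' @param x Numeric data matrix (n samples x p traits) -- the same
#'   matrix the clustering was run on.
#' @param assignments Integer cluster assignment per row (a partition
#'   with at least 2 clusters; `n > q` required).
#' @return The CCC value; `+Inf` with a warning when R-squared is 1.
#' @references Sarle, W.S. (1983) Cubic Clustering Criterion, SAS
#'   Technical Report A-108.
#' @export
cubic_clustering_criterion <- function(x, assignments) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples")
  cl <- unique(assignments)
  q <- length(cl)
  if (q < 2L) stop("CCC is undefined for a single cluster (R-squared ",
                   "degenerates); use k >= 2")
  if (n <= q) stop("need more samples than clusters")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sst <- sum(xc^2)
  ssw <- sum(vapply(cl, function(c) {
    xi <- xc[assignments == c, , drop = FALSE]
    sum(scale(xi, center = TRUE, scale = FALSE)^2)
  }, numeric(1)))
  if (sst == 0) stop("degenerate data: zero total variance")
  r2 <- 1 - ssw / sst
  if (r2 >= 1) {
    warning("R-squared is 1; CCC diverges")
    return(Inf)
  }

  ev <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE,
              only.values = TRUE)$values
  tol <- max(ev) * 1e-12
  s <- sqrt(ev[ev > tol])
  v <- length(s)

  ## fixed-point determination of the effective dimensionality p*
  pstar <- max(1L, min(v, q - 1L))
  c_edge <- NA_real_
  for (it in seq_len(100L)) {
    vbar <- prod(s[seq_len(pstar)])
    c_new <- (vbar / q)^(1 / pstar)
    u <- s / c_new
    p_new <- max(1L, min(sum(u >= 1), q - 1L, v))
    if (!is.na(c_edge) && p_new == pstar &&
        abs(c_new - c_edge) <= 1e-10 * max(1, c_edge)) {
      c_edge <- c_new
      break
    }
    pstar <- p_new
    c_edge <- c_new
  }
  u <- s / c_edge

  term1 <- sum(1 / (n + u[seq_len(pstar)]))
  term2 <- if (pstar < v) {
    sum(u[(pstar + 1):v]^2 / (n + u[(pstar + 1):v]))
  } else {
    0
  }
  e_r2 <- 1 - ((term1 + term2) / sum(u^2)) * ((n - q)^2 / n) * (1 + 4 / n)
  log((1 - e_r2) / (1 - r2)) * sqrt(n * pstar / 2) /
    ((0.001 + e_r2)^1.2)
}

#' Per-cluster trait summary with SD-overlap difference flags
#'
#' For each cluster and trait, the mean and standard deviation of the
#' member samples (on the original trait scale); for each trait and
#' cluster pair, a flag marking the means as different when the
#' mean +/- SD intervals do not overlap.
#'
#' @param result A `cluster_result` from [kmeans_cluster()].
#' @return A list with `summary` (`cluster`, `trait`, `n`, `mean`, `sd`)
#'   and `flags` (`trait`, `cluster_a`, `cluster_b`, `different`).
#' @export
summarize_clusters <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  samples <- result$samples
  trait_cols <- setdiff(names(samples), "sample_id")
  k <- nrow(result$centers)
  rows <- list(); flags <- list()
  stats_by <- array(NA_real_, c(k, length(trait_cols), 2L))
  for (c in seq_len(k)) {
    member <- result$assignments == c
    for (t in seq_along(trait_cols)) {
      vals <- samples[[trait_cols[t]]][member]
      sdv <- if (length(vals) > 1L) stats::sd(vals) else {
        warning("cluster ", c, " is a singleton; SD reported as 0")
        0
      }
      stats_by[c, t, ] <- c(mean(vals), sdv)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = c, trait = trait_cols[t], n = sum(member),
        mean = mean(vals), sd = sdv, stringsAsFactors = FALSE
      )
    }
  }
  for (t in seq_along(trait_cols)) {
    for (a in seq_len(k - 1L)) {
      for (b in seq(a + 1L, k)) {
        ma <- stats_by[a, t, 1]; sa <- stats_by[a, t, 2]
        mb <- stats_by[b, t, 1]; sb <- stats_by[b, t, 2]
        different <- (ma + sa < mb - sb) || (mb + sb < ma - sa)
        flags[[length(flags) + 1L]] <- data.frame(
          trait = trait_cols[t], cluster_a = a, cluster_b = b,
          different = different, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(summary = do.call(rbind, rows), flags = do.call(rbind, flags))
}
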