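#' Variant set observed in a sample group
#'
#' A site is counted as a variant for a group when at least one member
#' sample carries a non-missing call with at least one alternate allele
#' and total depth of at least `min_depth` -- mirroring how a per-group
#' variant caller only emits records where non-reference evidence exists.
#'
#' @param table A [genotype_table()].
#' @param sample_ids Non-empty character vector of member sample ids.
#' @param min_depth Minimum per-call depth for a call to count
#'   (default 1, i.e. no extra filter beyond being called).
#' @return Character vector of site ids.
#' @export
group_variant_set <- function(table, sample_ids, min_depth = 1L) {
  stopifnot(inherits(table, "genotype_table"))
  if (length(sample_ids) == 0L) stop("sample group must be non-empty")
  j <- match(sample_ids, table$samples$sample_id)
  if (anyNA(j)) {
    stop("unknown sample(s): ", paste(sample_ids[is.na(j)], collapse = ", "))
  }
  d <- table$dosage[, j, drop = FALSE]
  dp <- table$depth[, j, drop = FALSE]
  hit <- !is.na(d) & d >= 1L & dp >= min_depth
  table$sites$site_id[rowSums(hit) > 0L]
}

#' Three-way Venn partition of variant sets
#'
#' Partitions the union of three site-id sets into the seven disjoint
#' membership regions and reports per-group totals. Region names encode
#' membership by concatenating group labels (e.g. `"A&B"` holds elements
#' in A and B but not C).
#'
#' @param sets List of exactly three character vectors of site ids.
#' @param labels Character vector of three group labels; defaults to the
#'   list names or `A`, `B`, `C`.
#' @return An object of class `venn_partition`: a list with `labels`,
#'   `regions` (named integer vector of the 7 disjoint counts) and
#'   `totals` (per-group set sizes).
#' @export
venn <- function(sets, labels = NULL) {
  if (length(sets) != 3L) stop("venn requires exactly 3 sets")
  sets <- lapply(sets, unique)
  if (is.null(labels)) {
    labels <- names(sets)
    if (is.null(labels) || any(!nzchar(labels))) labels <- c("A", "B", "C")
  }
  a <- sets[[1]]; b <- sets[[2]]; c <- sets[[3]]
  abc <- intersect(intersect(a, b), c)
  ab <- setdiff(intersect(a, b), abc)
  ac <- setdiff(intersect(a, c), abc)
  bc <- setdiff(intersect(b, c), abc)
  only_a <- setdiff(a, union(b, c))
  only_b <- setdiff(b, union(a, c))
  only_c <- setdiff(c, union(a, b))
  regions <- c(length(only_a), length(only_b), length(only_c),
               length(ab), length(ac), length(bc), length(abc))
  names(regions) <- c(labels,
                      paste(labels[1], labels[2], sep = "&"),
                      paste(labels[1], labels[3], sep = "&"),
                      paste(labels[2], labels[3], sep = "&"),
                      paste(labels, collapse = "&"))
  totals <- stats::setNames(lengths(list(a, b, c)), labels)
  structure(list(labels = labels, regions = regions, totals = totals),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  for (i in seq_along(x$regions)) {
    cat(sprintf("  %-12s %d\n", names(x$regions)[i], x$regions[i]))
  }
  cat("  totals:", paste(sprintf("%s=%d", names(x$totals), x$totals),
                         collapse = ", "), "\n")
  invisible(x)
}
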