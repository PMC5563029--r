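#' Construct a ploidy-aware genotype call
#'
#' A genotype call records one sample's unphased genotype at one biallelic
#' locus as a sorted tuple of allele indices (0 = reference, 1 = alternate)
#' of length equal to the sample's ploidy, together with the total read
#' depth and per-allele read depths. Genotypes are unphased: `0/1/0` and
#' `0/0/1` denote the same call, so allele tuples are normalized by sorting.
#'
#' @param alleles Integer vector of allele indices in `{0, 1}`, one entry
#'   per chromosome copy. Ignored (may be `NULL`) when `missing = TRUE`
#'   and `ploidy` is given instead.
#' @param depth_total Total read depth at the locus (non-negative integer).
#' @param allele_depths Length-2 integer vector of reads supporting the
#'   reference and alternate allele; must sum to `depth_total`.
#' @param missing Logical; `TRUE` for a no-call (`./.`-style genotype).
#' @param ploidy Declared ploidy, required for a missing call; for a
#'   non-missing call it defaults to `length(alleles)` and must agree.
#'
#' @return An object of class `genotype_call` with fields `alleles`,
#'   `depth_total`, `allele_depths`, `missing` and `ploidy`.
#' @seealso [genotype_class()], [dosage_fraction()]
#' @export
#' @examples
#' genotype_call(c(0, 0, 1), depth_total = 42, allele_depths = c(28, 14))
genotype_call <- function(alleles = NULL, depth_total = 0L,
                          allele_depths = c(0L, 0L), missing = FALSE,
                          ploidy = NULL) {
  depth_total <- as.integer(depth_total)
  allele_depths <- as.integer(allele_depths)
  if (length(allele_depths) != 2L || any(allele_depths < 0L)) {
    stop("allele_depths must be two non-negative counts (ref, alt)")
  }
  if (is.na(depth_total) || depth_total < 0L) {
    stop("depth_total must be a non-negative count")
  }
  if (sum(allele_depths) != depth_total) {
    stop("sum(allele_depths) must equal depth_total")
  }
  if (missing) {
    if (is.null(ploidy)) ploidy <- length(alleles)
    ploidy <- as.integer(ploidy)
    if (length(ploidy) != 1L || is.na(ploidy) || ploidy < 1L) {
      stop("a missing call needs a declared ploidy")
    }
    alleles <- rep(NA_integer_, ploidy)
  } else {
    alleles <- sort(as.integer(alleles))
    if (length(alleles) < 1L || anyNA(alleles) || !all(alleles %in% c(0L, 1L))) {
      stop("alleles must be indices in {0, 1} (biallelic model)")
    }
    if (is.null(ploidy)) ploidy <- length(alleles)
    ploidy <- as.integer(ploidy)
    if (length(alleles) != ploidy) {
      stop("number of alleles (", length(alleles),
           ") does not match declared ploidy (", ploidy, ")")
    }
  }
  structure(
    list(alleles = alleles, depth_total = depth_total,
         allele_depths = allele_depths, missing = isTRUE(missing),
         ploidy = ploidy),
    class = "genotype_call"
  )
}

#' @export
print.genotype_call <- function(x, ...) {
  gt <- if (x$missing) {
    paste(rep(".", x$ploidy), collapse = "/")
  } else {
    paste(x$alleles, collapse = "/")
  }
  cat(sprintf("<genotype_call %s DP=%d AD=%d,%d>\n", gt, x$depth_total,
              x$allele_depths[1], x$allele_depths[2]))
  invisible(x)
}

#' Genotype class of a biallelic call
#'
#' Collapses a ploidy-aware genotype to one of the three biallelic genotype
#' classes -- homozygous reference, heterozygous, homozygous alternate --
#' or `MISSING` for a no-call. Allele dosage is deliberately discarded
#' within heterozygotes: for a triploid, `0/0/1` and `0/1/1` are both
#' `HET`. This collapse is what the differentiating-locus rule in
#' [pair_flag()] operates on.
#'
#' @param call A [genotype_call()].
#' @return One of `"HOM_REF"`, `"HET"`, `"HOM_ALT"`, `"MISSING"`.
#' @export
#' @examples
#' genotype_class(genotype_call(c(0, 0, 1), 3, c(2, 1))) # "HET"
genotype_class <- function(call) {
  stopifnot(inherits(call, "genotype_call"))
  if (call$missing) return("MISSING")
  class_from_dosage(sum(call$alleles), call$ploidy)
}

## Vectorized genotype class from alternate-allele dosage; NA dosage is
## MISSING. Used on whole dosage matrices downstream.
class_from_dosage <- function(dosage, ploidy) {
  out <- rep("HET", length(dosage))
  out[!is.na(dosage) & dosage == 0L] <- "HOM_REF"
  out[!is.na(dosage) & dosage == ploidy] <- "HOM_ALT"
  out[is.na(dosage)] <- "MISSING"
  out
}

#' Alternate-allele dosage fraction
#'
#' The number of alternate alleles divided by ploidy: a ploidy-independent
#' genotype coordinate in `[0, 1]` that lets genotypes of diploid,
#' triploid and tetraploid samples be compared on one scale (the basis of
#' [ibs_distance()]).
#'
#' @param call A non-missing [genotype_call()].
#' @return A real number in `[0, 1]`.
#' @export
#' @examples
#' dosage_fraction(genotype_call(c(0, 0, 1), 3, c(2, 1))) # 1/3
dosage_fraction <- function(call) {
  stopifnot(inherits(call, "genotype_call"))
  if (call$missing) {
    stop("dosage_fraction is undefined for a missing call")
  }
  sum(call$alleles) / call$ploidy
}
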