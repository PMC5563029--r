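#' Estimate 2C genome size from flow-cytometry fluorescence
#'
#' The sample's 2C DNA content is the ratio of its mean FL2-A
#' fluorescence to the internal standard's, scaled by the standard's
#' known genome size (default: *Sorghum bicolor* BTx623, 1.67 pg/2C).
#'
#' @param fl2a_sample Mean FL2-A of the sample (> 0); vectorized.
#' @param fl2a_standard Mean FL2-A of the internal standard (> 0).
#' @param standard_pg Genome size of the standard in pg/2C.
#' @return Estimated genome size(s) in pg/2C.
#' @export
#' @examples
#' estimate_genome_size(2e5, 1e5) # 3.34 pg/2C
estimate_genome_size <- function(fl2a_sample, fl2a_standard,
                                 standard_pg = 1.67) {
  if (any(fl2a_sample <= 0) || any(fl2a_standard <= 0) || standard_pg <= 0) {
    stop("fluorescence values and standard genome size must be positive")
  }
  (fl2a_sample / fl2a_standard) * standard_pg
}

#' Reference table of known 2C genome sizes
#'
#' @param label Reference entry names (unique).
#' @param ploidy Ploidy of each entry.
#' @param pg_2c 2C genome size in pg (> 0).
#' @return A `data.frame` of class `ploidy_reference`.
#' @export
ploidy_reference <- function(label, ploidy, pg_2c) {
  if (anyDuplicated(label)) stop("reference labels must be unique")
  if (any(pg_2c <= 0)) stop("pg_2c must be positive")
  structure(
    data.frame(label = label, ploidy = as.integer(ploidy), pg_2c = pg_2c,
               stringsAsFactors = FALSE),
    class = c("ploidy_reference", "data.frame")
  )
}

#' Default genome-size reference table
#'
#' Ships only the two published triploid hybrid values -- the
#' 'Tifgreen'-family hybrids (1.61 pg/2C) and 'Tifway' (1.37 pg/2C).
#' Diploid and tetraploid reference sizes are deliberately not invented;
#' supply them via [ploidy_reference()] when classifying those ploidies.
#'
#' @return A [ploidy_reference()] table.
#' @export
default_ploidy_reference <- function() {
  ploidy_reference(label = c("Tifgreen-family", "Tifway"),
                   ploidy = c(3L, 3L), pg_2c = c(1.61, 1.37))
}

#' Classify a genome size against reference entries
#'
#' Picks the reference entry with the smallest relative deviation
#' `|pg - pg_2c| / pg_2c`; returns unclassified when even the nearest
#' entry deviates by more than `max_rel_dev`. Ties are broken toward the
#' lower ploidy (reported in a message).
#'
#' @param pg Estimated genome size(s) in pg/2C; vectorized.
#' @param reference A [ploidy_reference()] table (non-empty).
#' @param max_rel_dev Maximum relative deviation for classification.
#' @return A `data.frame` with columns `pg_2c`, `label`, `ploidy`,
#'   `deviation`; unclassified rows have `NA` label and ploidy.
#' @export
classify_ploidy <- function(pg, reference = default_ploidy_reference(),
                            max_rel_dev = 0.15) {
  if (nrow(reference) == 0L) stop("reference table is empty")
  out <- data.frame(pg_2c = pg, label = NA_character_,
                    ploidy = NA_integer_, deviation = NA_real_,
                    stringsAsFactors = FALSE)
  ord <- order(reference$ploidy)  # tie-break toward lower ploidy
  ref <- reference[ord, , drop = FALSE]
  for (i in seq_along(pg)) {
    dev <- abs(pg[i] - ref$pg_2c) / ref$pg_2c
    best <- which.min(dev)  # first minimum = lowest ploidy on ties
    if (sum(dev == dev[best]) > 1L) {
      message("classify_ploidy: tie at pg = ", pg[i],
              "; choosing lower ploidy (", ref$ploidy[best], ")")
    }
    out$deviation[i] <- dev[best]
    if (dev[best] <= max_rel_dev) {
      out$label[i] <- ref$label[best]
      out$ploidy[i] <- ref$ploidy[best]
    }
  }
  out
}

#' Genome-size report for a flow-cytometry table
#'
#' @param flow `data.frame` with columns `sample_id`, `fl2a_sample`,
#'   `fl2a_standard`.
#' @param reference A [ploidy_reference()] table.
#' @param standard_pg Genome size of the internal standard (pg/2C).
#' @param max_rel_dev Classification tolerance (see [classify_ploidy()]).
#' @return A `data.frame` with columns `sample_id`, `pg_2c`, `label`,
#'   `ploidy`, `deviation`.
#' @export
genome_size_report <- function(flow, reference = default_ploidy_reference(),
                               standard_pg = 1.67, max_rel_dev = 0.15) {
  req <- c("sample_id", "fl2a_sample", "fl2a_standard")
  if (!all(req %in% names(flow))) {
    stop("flow table is missing columns: ",
         paste(setdiff(req, names(flow)), collapse = ", "))
  }
  pg <- estimate_genome_size(flow$fl2a_sample, flow$fl2a_standard,
                             standard_pg)
  cls <- classify_ploidy(pg, reference, max_rel_dev)
  cbind(data.frame(sample_id = flow$sample_id, stringsAsFactors = FALSE),
        cls)
}
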