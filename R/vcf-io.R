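#' Read a sample-metadata table
#'
#' Expects a CSV with header
#' `sample_id,group_label,ploidy,raw_read_count,role`.
#'
#' @param path Path to the CSV file.
#' @return A validated `data.frame` of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group_label", "ploidy", "raw_read_count", "role")
  if (!all(req %in% names(md))) {
    stop("metadata is missing columns: ",
         paste(setdiff(req, names(md)), collapse = ", "))
  }
  md$ploidy <- as.integer(md$ploidy)
  md$raw_read_count <- as.integer(md$raw_read_count)
  bad_role <- setdiff(unique(md$role),
                      c("standard", "desirable", "off_type", "progenitor"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  md
}

#' Read a multi-sample VCF into a genotype table
#'
#' Parses a VCF 4.2 file with `GT`, `DP` and `AD` FORMAT fields into a
#' [genotype_table()]. Only biallelic records are modelled: multi-allelic
#' records are skipped, and the number skipped is reported in a message
#' and attached as attribute `n_multiallelic_skipped`. A `./.`-style GT
#' becomes a missing call. Genotypes are unphased; allele tuples are
#' normalized by sorting.
#'
#' @param path Path to the VCF file (plain text or gzipped).
#' @param metadata Sample metadata `data.frame` as returned by
#'   [read_sample_metadata()]; every VCF sample must have an entry, and
#'   each sample's GT ploidy must match its declared ploidy.
#' @return A [genotype_table()] whose samples follow the VCF column order.
#' @export
read_vcf <- function(path, metadata) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  alt <- fix[, "ALT"]
  multi <- is.na(alt) | grepl(",", alt, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0L) {
    message("read_vcf: skipped ", n_multi, " multi-allelic record(s)")
    v <- v[!multi, ]
    fix <- v@fix
  }
  vcf_samples <- colnames(v@gt)[-1L]
  missing_md <- setdiff(vcf_samples, metadata$sample_id)
  if (length(missing_md)) {
    stop("no metadata for VCF sample(s): ",
         paste(missing_md, collapse = ", "))
  }
  samples <- metadata[match(vcf_samples, metadata$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  sites <- data.frame(
    site_id = ids,
    position = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  ns <- nrow(sites); np <- nrow(samples)

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")

  dosage <- matrix(NA_integer_, ns, np)
  depth <- matrix(0L, ns, np)
  ad_ref <- matrix(0L, ns, np)
  ad_alt <- matrix(0L, ns, np)
  for (j in seq_len(np)) {
    gt_j <- gt[, j]
    alleles <- strsplit(gt_j, "[/|]")
    n_alleles <- lengths(alleles)
    is_miss <- is.na(gt_j) |
      vapply(alleles, function(a) length(a) == 0L || all(a == "."),
             logical(1))
    bad <- !is_miss & n_alleles != samples$ploidy[j]
    if (any(bad)) {
      stop("GT ploidy inconsistent with metadata for sample '",
           samples$sample_id[j], "' at site '", sites$site_id[which(bad)[1]],
           "'")
    }
    dos <- integer(ns)
    dos[is_miss] <- NA_integer_
    dos[!is_miss] <- vapply(alleles[!is_miss], function(a) sum(a == "1"),
                            integer(1))
    bad_allele <- !is_miss &
      !vapply(alleles, function(a) all(a %in% c("0", "1")), logical(1))
    if (any(bad_allele)) {
      stop("non-biallelic allele index in GT for sample '",
           samples$sample_id[j], "'")
    }
    dosage[, j] <- dos
  }
  depth[] <- as.integer(ifelse(is.na(dp), 0, dp))
  for (j in seq_len(np)) {
    parts <- strsplit(ifelse(is.na(ad[, j]), "0,0", ad[, j]), ",", fixed = TRUE)
    ad_ref[, j] <- as.integer(vapply(parts, `[`, "", 1L))
    ad_alt[, j] <- as.integer(vapply(parts, function(p) {
      if (length(p) >= 2L) p[2L] else "0"
    }, ""))
  }
  ## Harmonize DP with AD where DP was absent but AD present
  no_dp <- depth == 0L & (ad_ref + ad_alt) > 0L
  depth[no_dp] <- ad_ref[no_dp] + ad_alt[no_dp]

  out <- genotype_table(sites, samples, dosage, depth, ad_ref, ad_alt)
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Write a genotype table as VCF 4.2
#'
#' Serializes a [genotype_table()] with `GT:DP:AD` genotype fields.
#' `CHROM` and `ID` both carry the tag identifier; `POS` is the 1-based
#' position within the tag. Missing calls are written as `.`-filled GT
#' with as many copies as the sample's ploidy. The output contains no
#' timestamps, so two writes of the same table are byte-identical, and
#' `read_vcf(write_vcf(x))` reproduces `x`.
#'
#' @param table A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  validate_genotype_table(table)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=offtypeR",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic Depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples$sample_id), collapse = "\t")
  )
  ns <- n_sites(table); np <- n_samples(table)
  body <- character(ns)
  ploidy <- table$samples$ploidy
  gt_field <- matrix("", ns, np)
  for (j in seq_len(np)) {
    p <- ploidy[j]
    d <- table$dosage[, j]
    miss_gt <- paste(rep(".", p), collapse = "/")
    gt <- vapply(d, function(k) {
      if (is.na(k)) miss_gt
      else paste(c(rep("0", p - k), rep("1", k)), collapse = "/")
    }, "")
    gt_field[, j] <- paste0(gt, ":", table$depth[, j], ":",
                            table$ad_ref[, j], ",", table$ad_alt[, j])
  }
  fixed <- paste(table$sites$site_id, table$sites$position + 1L,
                 table$sites$site_id, table$sites$ref, table$sites$alt,
                 ".", ".", ".", "GT:DP:AD", sep = "\t")
  body <- if (ns == 0L) {
    character(0)
  } else if (np > 0L) {
    paste(fixed, apply(gt_field, 1L, paste, collapse = "\t"), sep = "\t")
  } else {
    fixed
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n")
  invisible(path)
}
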