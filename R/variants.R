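# Variant input and the SNP-retention filters applied before index
# computation.

#' Filter settings for SNP retention
#'
#' Defaults mirror the retention rule the scan assumes: mean base quality of
#' at least 20, site (SNP) quality of at least 20, and read depth of at least
#' 5. The depth rule is applied to both bulks by default because an index is
#' computed for each; `depth_mode = "either"` relaxes it to one bulk.
#'
#' @param min_base_quality,min_site_quality,min_depth Inclusive thresholds.
#' @param depth_mode `"both"` (default) or `"either"`.
#' @return A list with class `"filter_config"`.
#' @export
filter_config <- function(min_base_quality = 20, min_site_quality = 20,
                          min_depth = 5, depth_mode = c("both", "either")) {
  check_number(min_base_quality, "min_base_quality", min = 0)
  check_number(min_site_quality, "min_site_quality", min = 0)
  check_number(min_depth, "min_depth", min = 0)
  structure(
    list(min_base_quality = min_base_quality,
         min_site_quality = min_site_quality,
         min_depth = min_depth,
         depth_mode = match.arg(depth_mode)),
    class = "filter_config"
  )
}

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(sprintf("(^|;)%s=[^;]+", key), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, gregexpr(sprintf("(^|;)%s=", key), info))) > 0
  out[hit] <- sub(sprintf("^;?%s=", key), "", m)
  out
}

#' Read bulk allele depths from a VCF
#'
#' Keeps biallelic SNP rows carrying an `AD` FORMAT field and returns one
#' record per site with per-bulk counts of reads matching each parental
#' allele. Allele orientation is taken from the `PA` INFO key (A parent
#' first) when present; otherwise `REF` is treated as the A-parent allele and
#' a note is emitted. Multiallelic rows and indels are skipped with a logged
#' count.
#'
#' @param path VCF file (plain or bgzipped).
#' @param high_sample,low_sample Sample column names for the compound
#'   (high-branching) and simple (low-branching) bulks.
#' @return A tibble of SNP records (see [simulate_bulk_reads()] for columns).
#' @export
read_variants <- function(path, high_sample = "HIGH_BULK",
                          low_sample = "LOW_BULK") {
  if (!file.exists(path)) {
    abort(sprintf("I/O error: file not found: %s", path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  for (s in c(high_sample, low_sample)) {
    if (!s %in% samples) {
      abort(sprintf("I/O error: sample '%s' not present in %s", s, path))
    }
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  biallelic <- fix$REF %in% bases & fix$ALT %in% bases
  n_skip <- sum(!biallelic)
  if (n_skip > 0L) {
    inform(sprintf("read_variants: skipped %d multiallelic/indel row(s)", n_skip))
  }
  if (!any(biallelic)) {
    return(tibble(chrom = character(), pos = integer(),
                  allele_a = character(), allele_b = character(),
                  site_quality = numeric(), base_quality = numeric(),
                  high_a = integer(), high_total = integer(),
                  low_a = integer(), low_total = integer()))
  }

  fmt <- vcf@gt[biallelic, "FORMAT"]
  if (any(!vapply(strsplit(fmt, ":"), function(x) "AD" %in% x, logical(1L)))) {
    abort("format error: every SNP row must carry an AD FORMAT field")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")[biallelic, , drop = FALSE]
  parse_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad)) abort("format error: malformed AD field")
    m <- matrix(as.integer(unlist(lapply(parts, `[`, 1:2))), ncol = 2L, byrow = TRUE)
    m
  }
  ad_high <- parse_ad(ad[, high_sample])
  ad_low <- parse_ad(ad[, low_sample])

  info <- fix$INFO[biallelic]
  ref <- fix$REF[biallelic]
  alt <- fix$ALT[biallelic]
  pa <- parse_info_field(info, "PA")
  if (all(is.na(pa))) {
    inform("read_variants: no PA annotation found; treating REF as the A-parent allele")
  }
  pa_split <- strsplit(ifelse(is.na(pa), paste(ref, alt, sep = ","), pa), ",")
  allele_a <- vapply(pa_split, `[`, "", 1L)
  allele_b <- vapply(pa_split, `[`, "", 2L)
  a_is_ref <- allele_a == ref
  if (any(!a_is_ref & allele_a != alt)) {
    abort("format error: PA alleles do not match REF/ALT")
  }

  pick <- function(adm, ref_first) ifelse(ref_first, adm[, 1L], adm[, 2L])
  bq <- suppressWarnings(as.numeric(parse_info_field(info, "BQ")))

  tibble(
    chrom = fix$CHROM[biallelic],
    pos = as.integer(fix$POS[biallelic]),
    allele_a = allele_a, allele_b = allele_b,
    site_quality = suppressWarnings(as.numeric(fix$QUAL[biallelic])),
    base_quality = bq,
    high_a = as.integer(pick(ad_high, a_is_ref)),
    high_total = as.integer(ad_high[, 1L] + ad_high[, 2L]),
    low_a = as.integer(pick(ad_low, a_is_ref)),
    low_total = as.integer(ad_low[, 1L] + ad_low[, 2L])
  )
}

#' Keep only sites where the two parents are homozygous for different alleles
#'
#' Sites with missing parental calls, a heterozygous parent, or identical
#' parental genotypes are dropped (with a logged count): only fixed
#' between-parent differences are informative for a bulk segregant scan.
#'
#' @param records SNP-record tibble.
#' @param parent_a_genotypes,parent_b_genotypes Character vectors aligned with
#'   `records` giving each parent's genotype at the site in allele space
#'   (`"AA"`, `"AB"`, `"BB"`, or `NA`).
#' @return The filtered tibble.
#' @export
restrict_to_parental_polymorphic <- function(records, parent_a_genotypes,
                                             parent_b_genotypes) {
  if (length(parent_a_genotypes) != nrow(records) ||
      length(parent_b_genotypes) != nrow(records)) {
    abort("parental genotype vectors must align with the record table")
  }
  hom <- c("AA", "BB")
  keep <- !is.na(parent_a_genotypes) & !is.na(parent_b_genotypes) &
    parent_a_genotypes %in% hom & parent_b_genotypes %in% hom &
    parent_a_genotypes != parent_b_genotypes
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    inform(sprintf(
      "restrict_to_parental_polymorphic: dropped %d site(s) without a fixed parental difference",
      n_drop))
  }
  records[keep, , drop = FALSE]
}

#' Apply the SNP-retention quality filters
#'
#' Retains records with `base_quality >= min_base_quality`,
#' `site_quality >= min_site_quality`, and read depth of at least `min_depth`
#' in both bulks (or either, per `cfg$depth_mode`). Thresholds are inclusive;
#' input order is preserved; per-filter drop counts are logged.
#'
#' @param records SNP-record tibble.
#' @param cfg A [filter_config()].
#' @return The filtered tibble.
#' @export
apply_quality_filters <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  check_columns(records, c("base_quality", "site_quality",
                           "high_total", "low_total"), "records")
  ok_bq <- records$base_quality >= cfg$min_base_quality
  ok_sq <- records$site_quality >= cfg$min_site_quality
  ok_depth <- if (cfg$depth_mode == "both") {
    records$high_total >= cfg$min_depth & records$low_total >= cfg$min_depth
  } else {
    records$high_total >= cfg$min_depth | records$low_total >= cfg$min_depth
  }
  keep <- ok_bq & ok_sq & ok_depth
  keep[is.na(keep)] <- FALSE
  inform(sprintf(
    "apply_quality_filters: kept %d/%d (dropped %d base-quality, %d site-quality, %d depth)",
    sum(keep), nrow(records), sum(!ok_bq, na.rm = TRUE),
    sum(!ok_sq, na.rm = TRUE), sum(!ok_depth, na.rm = TRUE)))
  records[keep, , drop = FALSE]
}
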