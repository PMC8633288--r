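# Pooled-DNA sequencing emulation: per-site bulk allele depths with seeded
# quality defects so downstream retention filters have something to remove.

sample_site_qualities <- function(n, fail_frac) {
  # pass sites sit comfortably above the default >=20 cutoffs; failing sites
  # land just below one of them (site quality, base quality) or get starved
  # of depth — mode chosen uniformly
  site_q <- round(runif(n, 30, 60), 2)
  base_q <- round(runif(n, 25, 40), 2)
  fail <- runif(n) < fail_frac
  mode <- sample(c("site", "base", "depth"), n, replace = TRUE)
  site_q[fail & mode == "site"] <- round(runif(sum(fail & mode == "site"), 5, 19.99), 2)
  base_q[fail & mode == "base"] <- round(runif(sum(fail & mode == "base"), 5, 19.99), 2)
  list(site_q = site_q, base_q = base_q, depth_starved = fail & mode == "depth")
}

#' Simulate pooled short-read allele depths for two bulks
#'
#' For each parental SNP the true B-allele frequency in a bulk is the allele
#' count among bulk members over twice the bulk size. Sequencing depth per
#' bulk is Poisson(`depth_mean`); reads matching the A (low-branching parent)
#' allele are binomial with the allele-misassignment rate `seq_error` folded
#' in. A configurable fraction of sites receives a quality or depth defect so
#' that the default retention filters drop a known subset.
#'
#' @param population Tibble from [simulate_f2_population()].
#' @param high_bulk,low_bulk Integer plant ids (see [select_bulks()]).
#' @param config The [sim_config()] used to build the population.
#' @param seed Seed for the read-sampling stage; defaults to `config$seed + 1`
#'   so population and reads stay jointly reproducible yet independently
#'   re-runnable.
#' @return A tibble of SNP records: `chrom`, `pos`, `allele_a`, `allele_b`,
#'   `site_quality`, `base_quality`, `high_a`, `high_total`, `low_a`,
#'   `low_total`.
#' @export
simulate_bulk_reads <- function(population, high_bulk, low_bulk, config,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(high_bulk) == 0L || length(low_bulk) == 0L) {
    abort("empty bulk: both bulks must contain at least one plant")
  }
  check_columns(population, c("id", "genotypes"), "population")

  dose_mat <- function(ids) {
    rows <- match(ids, population$id)
    if (anyNA(rows)) abort("bulk ids not found in the population")
    do.call(rbind, population$genotypes[rows])
  }
  f_high <- colSums(dose_mat(high_bulk)) / (2 * length(high_bulk))
  f_low <- colSums(dose_mat(low_bulk)) / (2 * length(low_bulk))

  n_snp <- length(config$snp_positions)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    allele_a <- sample(bases, n_snp, replace = TRUE)
    allele_b <- vapply(allele_a, function(a) sample(setdiff(bases, a), 1L), "")

    qual <- sample_site_qualities(n_snp, config$qual_fail_frac)
    depth_mean <- ifelse(qual$depth_starved, min(2, config$depth_mean), config$depth_mean)
    high_total <- rpois(n_snp, depth_mean)
    low_total <- rpois(n_snp, depth_mean)

    e <- config$seq_error
    p_a_high <- (1 - f_high) * (1 - e) + f_high * e
    p_a_low <- (1 - f_low) * (1 - e) + f_low * e
    high_a <- rbinom(n_snp, high_total, p_a_high)
    low_a <- rbinom(n_snp, low_total, p_a_low)

    tibble(
      chrom = config$chrom,
      pos = as.integer(config$snp_positions),
      allele_a = unname(allele_a), allele_b = unname(allele_b),
      site_quality = qual$site_q, base_quality = qual$base_q,
      high_a = high_a, high_total = high_total,
      low_a = low_a, low_total = low_total
    )
  })
}

#' Write simulated bulk allele depths as a minimal VCF 4.2
#'
#' One sample column per bulk with an `AD` FORMAT field (allele depths ordered
#' REF,ALT), `QUAL` carrying the simulated site quality, and two INFO keys:
#' `BQ` (mean supporting base quality) and `PA` (parental alleles, A-parent
#' first) so allele orientation survives the round trip.
#'
#' @param records Tibble from [simulate_bulk_reads()].
#' @param path Output file.
#' @param high_name,low_name Sample column names for the two bulks.
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(records, path,
                           high_name = "HIGH_BULK", low_name = "LOW_BULK") {
  check_columns(records, c("chrom", "pos", "allele_a", "allele_b",
                           "site_quality", "base_quality",
                           "high_a", "high_total", "low_a", "low_total"),
                "records")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=branchmapr",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean supporting base quality\">",
    "##INFO=<ID=PA,Number=2,Type=String,Description=\"Parental alleles, A parent first\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (REF,ALT)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", high_name, low_name), collapse = "\t")
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tBQ=%.2f;PA=%s,%s\tAD\t%d,%d\t%d,%d",
    records$chrom, records$pos, records$allele_a, records$allele_b,
    records$site_quality, records$base_quality,
    records$allele_a, records$allele_b,
    records$high_a, records$high_total - records$high_a,
    records$low_a, records$low_total - records$low_a
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the simulation ground truth as TSV
#'
#' Records the true QTL position plus each plant's QTL genotype and phenotype,
#' for downstream assertions against scan and fine-mapping output.
#'
#' @param population Tibble from [simulate_f2_population()].
#' @param config The matching [sim_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(population, config, path) {
  truth <- dplyr::mutate(
    dplyr::select(population, "id", "qtl_genotype", "phenotype"),
    chrom = config$chrom, qtl_pos_bp = config$qtl_pos_bp, .before = 1L
  )
  readr::write_tsv(truth, path)
  invisible(path)
}
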