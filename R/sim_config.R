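#' Configuration for the F2 bulk-segregant simulator
#'
#' Bundles every parameter of the synthetic genetic design: one chromosome of
#' a biparental F2 cross segregating a single partially dominant branching
#' QTL, with phenotypic extremes pooled into two sequencing bulks.
#'
#' The phenotype is a negative-binomial branch count whose mean depends on the
#' QTL genotype. `AA` carries two copies of the low-branching parental allele
#' (the "A", ST147-like allele), `BB` two copies of the high-branching allele
#' (the "B", ST024-like allele), and the heterozygote mean sits strictly
#' between the two — partial dominance, so `mu_low < mu_mid < mu_high` is
#' enforced. The default means (4.5, 60, 130 branches) and dispersion (0.2)
#' are calibrated so that the branch-count thresholds used to pick bulks
#' (more than 200, fewer than 1.5 branches) select roughly 25-35 plants each
#' out of a 960-plant population, matching the mapping design the package
#' emulates.
#'
#' @param chrom Chromosome name used in all outputs.
#' @param chrom_length_bp Chromosome length in base pairs (default 98 Mb,
#'   a tomato chromosome-1-like length).
#' @param snp_positions Ordered 1-based positions of parental SNPs. Default
#'   `NULL` places one SNP every `snp_spacing_bp`.
#' @param snp_spacing_bp Grid spacing used when `snp_positions` is `NULL`.
#' @param cm_per_mb Genetic-to-physical scale, centimorgan per megabase.
#' @param qtl_pos_bp Position of the simulated QTL.
#' @param mu_low,mu_mid,mu_high Mean branch counts for QTL genotypes
#'   `AA`, `AB`, `BB`.
#' @param dispersion Negative-binomial dispersion of the branch count
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param n_f2 Number of F2 individuals.
#' @param bulk_high_n,bulk_low_n Nominal bulk sizes, used by rank-based bulk
#'   selection and by the null-threshold simulation (defaults 24 and 31).
#' @param depth_mean Mean sequencing depth per site per bulk (Poisson).
#' @param seq_error Per-read probability that a read is assigned to the wrong
#'   parental allele.
#' @param qual_fail_frac Fraction of simulated sites given a quality or depth
#'   defect that the default retention filters should remove.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#'
#' @return A list with class `"sim_config"`.
#' @seealso [simulate_f2_population()], [simulate_bulk_reads()]
#' @export
#' @examples
#' cfg <- sim_config(n_f2 = 200, seed = 42)
#' cfg$qtl_pos_bp
sim_config <- function(chrom = "chr1",
                       chrom_length_bp = 98e6,
                       snp_positions = NULL,
                       snp_spacing_bp = 50e3,
                       cm_per_mb = 1.5,
                       qtl_pos_bp = 45e6,
                       mu_low = 4.5,
                       mu_mid = 60,
                       mu_high = 130,
                       dispersion = 0.2,
                       n_f2 = 960,
                       bulk_high_n = 24,
                       bulk_low_n = 31,
                       depth_mean = 30,
                       seq_error = 0.005,
                       qual_fail_frac = 0.1,
                       seed = 1) {
  check_number(chrom_length_bp, "chrom_length_bp", min = 1, integerish = TRUE)
  check_number(cm_per_mb, "cm_per_mb", min = 0)
  check_number(qtl_pos_bp, "qtl_pos_bp", min = 1, max = chrom_length_bp, integerish = TRUE)
  check_number(mu_low, "mu_low", min = 0)
  check_number(mu_mid, "mu_mid", min = 0)
  check_number(mu_high, "mu_high", min = 0)
  # strictly increasing means = partial dominance; equal means are allowed
  # as the explicit QTL-free null (phenotype carries no genotype signal)
  if (mu_low > mu_mid || mu_mid > mu_high) {
    abort("configuration error: genotype means must satisfy mu_low <= mu_mid <= mu_high")
  }
  check_number(dispersion, "dispersion", min = 0)
  check_number(n_f2, "n_f2", min = 1, integerish = TRUE)
  check_number(bulk_high_n, "bulk_high_n", min = 1, integerish = TRUE)
  check_number(bulk_low_n, "bulk_low_n", min = 1, integerish = TRUE)
  check_number(depth_mean, "depth_mean", min = 0)
  check_number(seq_error, "seq_error", min = 0, max = 1)
  check_number(qual_fail_frac, "qual_fail_frac", min = 0, max = 1)
  check_number(seed, "seed", integerish = TRUE)

  if (is.null(snp_positions)) {
    check_number(snp_spacing_bp, "snp_spacing_bp", min = 1, integerish = TRUE)
    snp_positions <- seq(snp_spacing_bp, chrom_length_bp, by = snp_spacing_bp)
  }
  snp_positions <- as.numeric(snp_positions)
  if (any(!is.finite(snp_positions)) || any(snp_positions < 1) ||
      any(snp_positions > chrom_length_bp)) {
    abort("configuration error: snp_positions must lie in [1, chrom_length_bp]")
  }
  if (is.unsorted(snp_positions, strictly = TRUE)) {
    abort("configuration error: snp_positions must be strictly increasing")
  }

  structure(
    list(
      chrom = chrom, chrom_length_bp = chrom_length_bp,
      snp_positions = snp_positions, cm_per_mb = cm_per_mb,
      qtl_pos_bp = qtl_pos_bp,
      mu_low = mu_low, mu_mid = mu_mid, mu_high = mu_high,
      dispersion = dispersion, n_f2 = as.integer(n_f2),
      bulk_high_n = as.integer(bulk_high_n), bulk_low_n = as.integer(bulk_low_n),
      depth_mean = depth_mean, seq_error = seq_error,
      qual_fail_frac = qual_fail_frac, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  chromosome     : %s (%.1f Mb, %d SNPs, %.2f cM/Mb)\n",
              x$chrom, x$chrom_length_bp / 1e6, length(x$snp_positions), x$cm_per_mb))
  cat(sprintf("  QTL            : %.2f Mb, branch-count means %.1f / %.1f / %.1f (AA/AB/BB)\n",
              x$qtl_pos_bp / 1e6, x$mu_low, x$mu_mid, x$mu_high))
  cat(sprintf("  population     : %d F2, bulks %d/%d, depth %.0fx, seed %d\n",
              x$n_f2, x$bulk_high_n, x$bulk_low_n, x$depth_mean, x$seed))
  invisible(x)
}
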