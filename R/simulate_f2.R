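# F2 population simulation: two independent gametes per plant, crossovers as
# a Poisson process on a uniform genetic map (Haldane, no interference).

# one gamete evaluated at genetic positions `gpos` (cM): 0 = A allele, 1 = B
sample_gamete <- function(gpos, map_length_cm) {
  n_x <- if (map_length_cm > 0) rpois(1L, map_length_cm / 100) else 0L
  start <- rbinom(1L, 1L, 0.5)
  if (n_x == 0L) {
    return(rep.int(start, length(gpos)))
  }
  breaks <- sort(runif(n_x, 0, map_length_cm))
  (start + findInterval(gpos, breaks)) %% 2L
}

#' Simulate an F2 population segregating one branching QTL
#'
#' Each individual is built from two independent gametes; every gamete gets a
#' Poisson number of crossovers placed uniformly on the genetic map (Haldane
#' model, no interference, uniform cM/Mb scale). The branch-count phenotype is
#' drawn from a negative binomial whose mean depends on the QTL genotype
#' (partial dominance: heterozygotes intermediate).
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per plant: `id`, `qtl_genotype`
#'   (`"AA"`/`"AB"`/`"BB"`), `phenotype` (branch count), and `genotypes`, a
#'   list-column of integer B-allele dosages (0/1/2) along
#'   `config$snp_positions`.
#' @export
#' @examples
#' pop <- simulate_f2_population(sim_config(n_f2 = 50, seed = 1))
#' table(pop$qtl_genotype)
simulate_f2_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    map_length_cm <- config$chrom_length_bp / 1e6 * config$cm_per_mb
    gpos_snp <- config$snp_positions / 1e6 * config$cm_per_mb
    gpos <- c(gpos_snp, config$qtl_pos_bp / 1e6 * config$cm_per_mb)
    n_snp <- length(config$snp_positions)
    qtl_idx <- n_snp + 1L

    geno_list <- vector("list", config$n_f2)
    qtl_dose <- integer(config$n_f2)
    for (i in seq_len(config$n_f2)) {
      dose <- sample_gamete(gpos, map_length_cm) + sample_gamete(gpos, map_length_cm)
      geno_list[[i]] <- as.integer(dose[seq_len(n_snp)])
      qtl_dose[i] <- dose[qtl_idx]
    }

    qtl_genotype <- c("AA", "AB", "BB")[qtl_dose + 1L]
    mu <- c(config$mu_low, config$mu_mid, config$mu_high)[qtl_dose + 1L]
    phenotype <- if (config$dispersion > 0) {
      rnbinom(config$n_f2, size = 1 / config$dispersion, mu = mu)
    } else {
      rpois(config$n_f2, mu)
    }

    tibble(
      id = seq_len(config$n_f2),
      qtl_genotype = qtl_genotype,
      phenotype = as.integer(phenotype),
      genotypes = geno_list
    )
  })
}

#' Select extreme phenotypic bulks by branch-count thresholds
#'
#' Reproduces the bulk definition used in the mapping design: every plant with
#' more branches than `high_min` joins the compound-inflorescence bulk and
#' every plant with fewer than `low_max` joins the simple-inflorescence bulk
#' (defaults 200 and 1.5 branches).
#'
#' @param population Tibble from [simulate_f2_population()].
#' @param high_min Lower branch-count bound (exclusive) for the compound bulk.
#' @param low_max Upper bound (exclusive) for the simple bulk.
#' @return A list with integer id vectors `high` and `low`.
#' @export
select_bulks <- function(population, high_min = 200, low_max = 1.5) {
  check_columns(population, c("id", "phenotype"), "population")
  if (!(high_min > low_max)) {
    abort("configuration error: high_min must exceed low_max")
  }
  high <- population$id[population$phenotype > high_min]
  low <- population$id[population$phenotype < low_max]
  if (length(high) == 0L) {
    abort(sprintf("empty bulk: no plant has phenotype > %s (high_min)", high_min))
  }
  if (length(low) == 0L) {
    abort(sprintf("empty bulk: no plant has phenotype < %s (low_max)", low_max))
  }
  list(high = high, low = low)
}

#' Select bulks of fixed size by phenotype rank
#'
#' Takes the `n_high` highest-branching and `n_low` lowest-branching plants
#' (ties broken by plant id). Used for null-calibration runs, where the
#' phenotype carries no QTL signal and absolute thresholds would select empty
#' bulks.
#'
#' @inheritParams select_bulks
#' @param n_high,n_low Bulk sizes.
#' @return A list with integer id vectors `high` and `low`.
#' @export
select_bulks_by_rank <- function(population, n_high = 24, n_low = 31) {
  check_columns(population, c("id", "phenotype"), "population")
  if (n_high + n_low > nrow(population)) {
    abort("configuration error: bulk sizes exceed the population size")
  }
  ord <- order(population$phenotype, population$id)
  list(
    high = sort(population$id[tail(ord, n_high)]),
    low = sort(population$id[head(ord, n_low)])
  )
}
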