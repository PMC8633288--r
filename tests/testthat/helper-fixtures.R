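# shared fixture builders; everything is generated in code at test time

small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    chrom_length_bp = 10e6, snp_spacing_bp = 100e3, qtl_pos_bp = 5e6,
    n_f2 = 200, depth_mean = 30, seed = 11
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

# a deterministic SNP-record table with hand-set counts
toy_records <- function(n = 5) {
  tibble::tibble(
    chrom = "chr1",
    pos = as.integer(seq(1e5, by = 1e5, length.out = n)),
    allele_a = rep("A", n), allele_b = rep("G", n),
    site_quality = 50, base_quality = 35,
    high_a = rep(5L, n), high_total = rep(10L, n),
    low_a = rep(8L, n), low_total = rep(10L, n)
  )
}

# random index points for window-scan properties
random_points <- function(n, chrom_length, seed) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(chrom_length, n))
    ih <- runif(n)
    il <- runif(n)
    tibble::tibble(chrom = "chr1", pos = pos, index_high = ih,
                   index_low = il, delta = ih - il)
  })
}

# O(n * w) brute-force window recomputation, the oracle for the scan
brute_force_windows <- function(points, window_bp, step_bp, chrom_length) {
  starts <- seq(1, chrom_length, by = step_bp)
  rows <- lapply(starts, function(s) {
    e <- min(s + window_bp, chrom_length + 1)
    inside <- points$pos >= s & points$pos < e
    n <- sum(inside)
    tibble::tibble(
      chrom = "chr1", start = as.integer(s), end = as.integer(e),
      midpoint = (s + e) / 2,
      mean_index_high = if (n) mean(points$index_high[inside]) else NA_real_,
      mean_index_low = if (n) mean(points$index_low[inside]) else NA_real_,
      mean_delta = if (n) mean(points$delta[inside]) else NA_real_,
      n_snps = as.integer(n)
    )
  })
  dplyr::bind_rows(rows)
}

# definitional BH step-up: sort ascending, q_(i) = min_{j>=i} p_(j) m / j
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[ord] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# markers every 200 kb across a 4 Mb fine-mapping region
fine_markers <- function() {
  pos <- seq(43e6, 47e6, by = 200e3)
  tibble::tibble(marker = sprintf("M%02d", seq_along(pos)),
                 chrom = "chr1", pos = pos)
}

carg_pwm <- function() {
  load_pwm(system.file("extdata", "carg_box_synthetic.jaspar",
                       package = "branchmapr"))
}
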