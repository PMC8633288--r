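test_that("the SNP index is the A-parent read fraction and errors on zero depth", {
  rec <- toy_records(1)
  rec$high_a <- 10L; rec$high_total <- 10L
  expect_identical(snp_index(rec, "high"), 1)
  rec$high_a <- 0L; rec$high_total <- 12L
  expect_identical(snp_index(rec, "high"), 0)
  rec$high_a <- 7L; rec$high_total <- 10L
  expect_identical(snp_index(rec, "high"), 0.7)

  rec$low_total <- 0L
  expect_error(snp_index(rec, "low"), "zero.*depth")
})

test_that("the delta is compound minus simple and reaches -1 under perfect selection", {
  rec <- toy_records(1)
  rec$high_a <- 2L; rec$high_total <- 10L   # index_high 0.2
  rec$low_a <- 9L; rec$low_total <- 10L     # index_low 0.9
  expect_equal(delta_snp_index(rec), -0.7)

  rec$low_a <- 2L
  expect_equal(delta_snp_index(rec), 0)

  # bulks fixed for opposite alleles, no sequencing error: compound bulk
  # carries no A-parent reads at the QTL
  cfg <- small_config(seq_error = 0, qual_fail_frac = 0, n_f2 = 20, seed = 31)
  pop <- simulate_f2_population(cfg)
  pop$genotypes <- lapply(seq_len(20), function(i) {
    rep(if (i <= 10) 2L else 0L, length(cfg$snp_positions))
  })
  reads <- simulate_bulk_reads(pop, 1:10, 11:20, cfg)
  reads <- reads[reads$high_total > 0 & reads$low_total > 0, ]
  expect_true(all(delta_snp_index(reads) == -1))
})

test_that("window means equal a brute-force recomputation and respect the geometry", {
  pts <- random_points(300, 5e6, seed = 41)
  got <- sliding_window_scan(pts, window_bp = 1e6, step_bp = 1e4,
                             chrom_length = 5e6)
  oracle <- brute_force_windows(pts, 1e6, 1e4, 5e6)
  expect_identical(got$mean_delta, oracle$mean_delta)
  expect_identical(got$mean_index_high, oracle$mean_index_high)
  expect_identical(got$n_snps, oracle$n_snps)
  expect_identical(got$start, oracle$start)
  expect_identical(got$end, oracle$end)
  # windows anchored at 1 with the step as phase, truncated at the end
  expect_identical(got$start[1:3], c(1L, 10001L, 20001L))
  expect_true(all(got$end - got$start <= 1e6))
  # empty windows are missing, never zero
  expect_true(all(is.na(got$mean_delta[got$n_snps == 0L])))
  # window means stay inside the range of their member values
  nonempty <- !is.na(got$mean_delta)
  expect_true(all(got$mean_delta[nonempty] >= -1 & got$mean_delta[nonempty] <= 1))
})

test_that("constant deltas give constant window means", {
  pts <- random_points(100, 2e6, seed = 43)
  pts$delta <- 0.5
  got <- sliding_window_scan(pts, 1e6, 1e4, 2e6)
  expect_true(all(got$mean_delta[!is.na(got$mean_delta)] == 0.5))

  one <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
                        index_high = 1, index_low = 1 - c(0.2, 0.4, 0.6),
                        delta = c(0.2, 0.4, 0.6))
  w <- sliding_window_scan(one, 1000, 1000, 1000)
  expect_equal(w$mean_delta, 0.4)
})

test_that("unsorted input is rejected rather than silently sorted", {
  pts <- random_points(50, 1e6, seed = 47)
  expect_error(sliding_window_scan(pts[rev(seq_len(50)), ], 1e5, 1e4, 1e6),
               "sorted")
})

test_that("the null threshold is deterministic, positive, and zero at alpha 1", {
  expect_identical(null_delta_threshold(30, 24, 31, alpha = 1), 0)
  t1 <- null_delta_threshold(rep(30, 100), 24, 31, alpha = 0.01,
                             n_sims = 1000, seed = 3)
  t2 <- null_delta_threshold(rep(30, 100), 24, 31, alpha = 0.01,
                             n_sims = 1000, seed = 3)
  expect_identical(t1, t2)
  expect_gt(t1, 0)
  expect_lt(t1, 1)
  # bigger bulks concentrate the null delta toward zero
  t_big <- null_delta_threshold(rep(1000, 100), 500, 500, alpha = 0.01,
                                n_sims = 1000, seed = 3)
  expect_lt(t_big, t1 / 3)
  expect_error(null_delta_threshold(numeric(0), 24, 31), "degenerate")
})

test_that("candidate regions are maximal runs above the threshold", {
  w <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(seq(1, by = 10, length.out = 8)),
    end = as.integer(seq(21, by = 10, length.out = 8)),
    mean_delta = c(0.1, 0.5, 0.6, 0.1, NA, 0.7, 0.7, 0.2)
  )
  expect_identical(nrow(call_candidate_regions(w, 0.9)), 0L)

  one <- call_candidate_regions(w, 0.55)
  expect_identical(nrow(one), 2L)
  expect_identical(one$start[1L], 21L)
  expect_identical(one$end[1L], 41L)

  regions <- call_candidate_regions(w, 0.45)
  expect_identical(nrow(regions), 2L)   # the NA window breaks the run
  expect_equal(regions$peak_abs_delta, c(0.6, 0.7))
  expect_true(all(regions$peak_abs_delta >= regions$threshold_used))
})

test_that("a seeded QTL is recovered near its true position with a negative peak", {
  cfg <- sim_config(seed = 1)
  pop <- simulate_f2_population(cfg)
  b <- select_bulks(pop)
  rec <- simulate_bulk_reads(pop, b$high, b$low, cfg)
  filt <- suppressMessages(apply_quality_filters(rec))
  scan <- bsa_scan(filt, chrom_length = cfg$chrom_length_bp,
                   n_high = length(b$high), n_low = length(b$low),
                   n_sims = 500, seed = 2)
  pk <- peak_window(scan)
  expect_lt(abs(pk$midpoint - cfg$qtl_pos_bp), 1e6)
  # high-branching allele comes from the B parent: A-parent reads are
  # depleted in the compound bulk, so the peak delta is negative
  expect_lt(pk$mean_delta, 0)
  # the top candidate region contains the truth
  top <- scan$regions[which.max(scan$regions$peak_abs_delta), ]
  expect_true(top$start <= cfg$qtl_pos_bp && cfg$qtl_pos_bp < top$end)
})
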