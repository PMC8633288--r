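test_that("FPKM follows its closed form", {
  expect_equal(fpkm(100, 1000, 1e7), 10)
  expect_equal(fpkm(0, 1000, 1e7), 0)
  expect_error(fpkm(10, 0, 1e7), "length")

  withr::with_seed(81, {
    counts <- matrix(rpois(300, 50), 50, 6)
    lens <- sample(200:3000, 50)
    libs <- round(runif(6, 1e6, 5e6))
  })
  got <- fpkm(counts, lens, libs)
  oracle <- 1e9 * counts / outer(lens, libs)
  expect_equal(got, oracle)
})

test_that("the pooled two-library z-test matches prop.test without correction", {
  expect_equal(two_library_test(10, 100, 20, 200), {
    stats::prop.test(c(10, 20), c(100, 200), correct = FALSE)$p.value
  })
  expect_equal(two_library_test(5, 50, 5, 50), 1)   # equal proportions
  expect_equal(two_library_test(0, 10, 0, 20), 1)   # degenerate pooled p
  expect_equal(two_library_test(10, 10, 5, 5), 1)   # pooled p = 1

  # high-precision oracle at sequencing scale
  p <- two_library_test(30, 1e6, 60, 1e6)
  phat <- 90 / 2e6
  z <- (30e-6 - 60e-6) / sqrt(phat * (1 - phat) * 2e-6)
  expect_equal(p, 2 * stats::pnorm(-abs(z)), tolerance = 1e-12)
  expect_lt(p, 0.01)

  expect_error(two_library_test(5, 0, 1, 10), "positive")
  expect_error(two_library_test(-1, 10, 1, 10), "0 <= k <= n")
})

test_that("BH adjustment equals the definitional step-up and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)

  p <- withr::with_seed(83, runif(1e4))
  q <- bh_adjust(p)
  expect_equal(q, brute_force_bh(p))
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG thresholds are strict and low-abundance genes are never called", {
  counts <- tibble::tibble(
    gene = c("g_low", "g_edge", "g_down"),
    length = 1000L,
    c1 = c(5L, 200L, 1000L), c2 = c(5L, 200L, 1000L),
    m1 = c(9L, 300L, 200L), m2 = c(9L, 300L, 200L)
  )
  samples <- tibble::tibble(
    sample = c("c1", "c2", "m1", "m2"),
    group = c("ctrl", "ctrl", "mut", "mut"),
    library_size = rep(1e7, 4)
  )
  res <- call_degs(counts, samples, case = "mut", control = "ctrl")
  # both means below 1 FPKM: never a DEG no matter the p value
  expect_identical(res$direction[res$gene == "g_low"], "ns")
  # fold change exactly 1.5 fails the strict bound
  expect_equal(res$fold_change[res$gene == "g_edge"], 1.5)
  expect_identical(res$direction[res$gene == "g_edge"], "ns")
  expect_identical(res$direction[res$gene == "g_down"], "down")
})

test_that("seeded repressed genes are recovered and match a predicate oracle", {
  sim <- simulate_expression(n_genes = 1000, n_down = 50, fold = 5, seed = 85)
  res <- call_degs(sim$counts, sim$samples, case = "mutant", control = "control")
  called_down <- res$gene[res$direction == "down"]
  expect_true(all(sim$down_genes %in% called_down))

  # independent predicate evaluation of the DEG definition
  oracle_down <- with(res, gene[
    !is.na(p_adj) & pmax(mean_fpkm_case, mean_fpkm_control) > 1 &
      fold_change < 0.6666 & p_adj < 0.05
  ])
  expect_setequal(called_down, oracle_down)
  # the contamination from null genes is small
  expect_lt(length(setdiff(called_down, sim$down_genes)), 10L)
})

test_that("swapping comparison labels inverts the fold change and keeps p", {
  sim <- simulate_expression(n_genes = 200, n_down = 20, seed = 87)
  fwd <- call_degs(sim$counts, sim$samples, case = "mutant", control = "control")
  rev <- call_degs(sim$counts, sim$samples, case = "control", control = "mutant")
  tested <- !is.na(fwd$p_raw)
  expect_equal(fwd$p_raw[tested], rev$p_raw[tested])
  expect_equal(fwd$fold_change[tested], 1 / rev$fold_change[tested])
  flips <- c(up = "down", down = "up", ns = "ns")
  expect_identical(unname(flips[fwd$direction]), rev$direction)
})

test_that("relaxing any threshold never removes a called DEG", {
  sim <- simulate_expression(n_genes = 500, n_down = 30, fold = 3, seed = 89)
  base <- call_degs(sim$counts, sim$samples, "mutant", "control")
  base_set <- base$gene[base$direction != "ns"]
  relaxed_args <- list(
    list(fpkm_min = 0.5), list(fc_up = 1.2), list(fc_down = 0.8),
    list(q_max = 0.2)
  )
  for (args in relaxed_args) {
    res <- do.call(call_degs, c(list(sim$counts, sim$samples, "mutant",
                                     "control"), args))
    expect_true(all(base_set %in% res$gene[res$direction != "ns"]))
  }
})

test_that("realized FDR stays controlled under a 90%-null simulation", {
  fdp <- vapply(1:200, function(s) {
    sim <- simulate_expression(n_genes = 300, n_down = 30, fold = 4,
                               lib_size = 5e5, seed = 9000 + s)
    res <- call_degs(sim$counts, sim$samples, "mutant", "control",
                     fpkm_min = 0, fc_up = Inf, fc_down = Inf, q_max = 0.05)
    called <- res$gene[!is.na(res$p_adj) & res$p_adj < 0.05]
    if (length(called) == 0L) return(0)
    mean(!called %in% sim$down_genes)
  }, numeric(1L))
  se <- stats::sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 3 * se)
})

test_that("shared_down implements k-of-n set logic", {
  sets <- list(a = c("g1", "g2"), b = c("g2", "g3"), c = "g3")
  expect_identical(shared_down(sets, min_k = 2), c("g2", "g3"))
  expect_identical(shared_down(sets, min_k = 1), c("g1", "g2", "g3"))
  expect_identical(shared_down(sets, min_k = 3), character(0))
  expect_error(shared_down(list(a = "g1")), "at least two")

  # from a fitted multi-mutant analysis
  sim <- simulate_expression(n_genes = 300, n_down = 25, fold = 5, seed = 91)
  counts3 <- sim$counts
  m2 <- simulate_expression(n_genes = 300, n_down = 40, fold = 5, seed = 92)
  counts3$m2_1 <- m2$counts$mutant_1
  counts3$m2_2 <- m2$counts$mutant_2
  counts3$m2_3 <- m2$counts$mutant_3
  samples3 <- dplyr::bind_rows(
    sim$samples,
    tibble::tibble(sample = c("m2_1", "m2_2", "m2_3"), group = "mutant2",
                   library_size = colSums(as.matrix(counts3[, c("m2_1", "m2_2", "m2_3")])))
  )
  res <- deg_analysis(counts3, samples3, control = "control")
  down_sets <- lapply(split(res$table, res$table$comparison),
                      function(d) d$gene[d$direction == "down"])
  expect_identical(shared_down(res, min_k = 2),
                   sort(intersect(down_sets[[1L]], down_sets[[2L]])))
})
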