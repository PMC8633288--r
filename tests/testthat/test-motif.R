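test_that("JASPAR matrices normalize to probability columns", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 flat",
               "A [ 1 1 1 1 1 1 1 1 1 1 ]",
               "C [ 1 1 1 1 1 1 1 1 1 1 ]",
               "G [ 1 1 1 1 1 1 1 1 1 1 ]",
               "T [ 1 1 1 1 1 1 1 1 1 1 ]"), path)
  pwm <- load_pwm(path)
  expect_true(all(abs(pwm$probs - 0.25) < 1e-12))

  writeLines(c(">M2 fixed", "A [ 100 100 100 100 ]", "C [ 0 0 0 0 ]",
               "G [ 0 0 0 0 ]", "T [ 0 0 0 0 ]"), path)
  pwm0 <- load_pwm(path, pseudocount = 0)
  expect_equal(unname(pwm0$probs["A", ]), rep(1, 4))
  expect_equal(unname(pwm0$probs["C", ]), rep(0, 4))

  writeLines(c(">M3 ragged", "A [ 1 1 1 1 ]", "C [ 1 1 1 ]",
               "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]"), path)
  expect_error(load_pwm(path), "ragged")

  carg <- carg_pwm()
  expect_identical(carg$width, 10L)
  expect_true(all(abs(colSums(carg$probs) - 1) < 1e-9))
  expect_identical(consensus_string(carg), "CCWWWWWWGG")
})

test_that("a planted consensus is the unique top-scoring forward hit", {
  pwm <- carg_pwm()
  withr::with_seed(101, {
    bg <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  })
  bg[16:25] <- c("C", "C", "A", "T", "A", "T", "T", "A", "G", "G")
  seqc <- paste(bg, collapse = "")
  hits <- scan_pwm(seqc, pwm, min_rel_score = 0.99)
  fwd <- hits[hits$strand == "+", ]
  expect_identical(fwd$start, 15L)
  expect_equal(fwd$rel_score, 1)
})

test_that("the PWM consensus attains relative score exactly 1", {
  pwm <- carg_pwm()
  hits <- scan_pwm("CCAAATTTGG", pwm, min_rel_score = 1)
  expect_true(any(hits$rel_score == 1))
  # every window score sits inside the achievable range
  all_hits <- scan_pwm(simulate_promoter(500, 0, seed = 103)$sequence, pwm,
                       min_rel_score = 0)
  expect_true(all(all_hits$rel_score >= 0 & all_hits$rel_score <= 1))
})

test_that("scanning the reverse complement mirrors the hit set", {
  pwm <- carg_pwm()
  prom <- simulate_promoter(800, 2, seed = 105)
  hits <- scan_pwm(prom$sequence, pwm, min_rel_score = 0.8)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(prom$sequence)))
  hits_rc <- scan_pwm(rc, pwm, min_rel_score = 0.8)
  L <- nchar(prom$sequence)
  mirrored <- tibble::tibble(
    start = L - pwm$width - hits$start,
    strand = ifelse(hits$strand == "+", "-", "+"),
    score = hits$score
  )
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  got <- hits_rc[order(hits_rc$start, hits_rc$strand),
                 c("start", "strand", "score")]
  expect_equal(as.data.frame(got), as.data.frame(mirrored),
               ignore_attr = TRUE)
})

test_that("raising the threshold never adds hits, and N windows are skipped", {
  pwm <- carg_pwm()
  prom <- simulate_promoter(1000, 2, seed = 107)
  loose <- scan_pwm(prom$sequence, pwm, min_rel_score = 0.7)
  strict <- scan_pwm(prom$sequence, pwm, min_rel_score = 0.9)
  expect_true(all(paste(strict$start, strict$strand) %in%
                    paste(loose$start, loose$strand)))

  intact <- "AAAAAAAAAAAAAAAAAAAACCATATATGGAAAA"
  expect_true(20L %in% scan_pwm(intact, pwm, 0.8)$start)
  with_n <- sub("^(.{20})CC", "\\1NC", intact)
  got_n <- scan_pwm(with_n, pwm, 0.8)
  expect_identical(nrow(got_n[got_n$strand == "+", ]), 0L)
  expect_identical(nrow(scan_pwm("CCAT", pwm)), 0L)  # shorter than the motif
})

test_that("three planted boxes in a 2.3 kb promoter are all recovered", {
  pwm <- carg_pwm()
  prom <- simulate_promoter(2300, 3, seed = 109)
  hits <- scan_pwm(prom$sequence, pwm, min_rel_score = 0.8)
  expect_true(all(prom$sites %in% hits$start))
})

test_that("degenerate consensus matching equals a regex oracle on both strands", {
  seqc <- simulate_promoter(10000, 4, seed = 111)$sequence
  hits <- consensus_scan(seqc, "CCWWWWWWGG")
  fwd_oracle <- gregexpr("CC[AT]{6}GG", seqc)[[1L]]
  fwd_starts <- if (fwd_oracle[1L] == -1L) integer(0) else as.integer(fwd_oracle) - 1L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqc)))
  rev_oracle <- gregexpr("CC[AT]{6}GG", rc)[[1L]]
  rev_starts <- if (rev_oracle[1L] == -1L) integer(0) else {
    nchar(seqc) - 10L - (as.integer(rev_oracle) - 1L)
  }
  expect_setequal(hits$start[hits$strand == "+"], fwd_starts)
  expect_setequal(hits$start[hits$strand == "-"], sort(rev_starts))
  expect_identical(nrow(consensus_scan("CCAAATTTGG"))
                   >= 1L, TRUE)
  expect_identical(consensus_scan("CCAAATTTGG")$start[1L], 0L)
  expect_identical(nrow(consensus_scan("CCGAATTTGG")[
    consensus_scan("CCGAATTTGG")$strand == "+", ]), 0L)
})

test_that("deleting a 40 bp window removes exactly the hit inside it", {
  pwm <- carg_pwm()
  prom <- simulate_promoter(2300, 3, seed = 113)
  s1 <- prom$sites[1L]
  del_start <- max(0L, s1 - 15L)
  del_end <- del_start + 40L

  eff <- deletion_effect(prom$sequence, del_start, del_end, pwm,
                         min_rel_score = 0.8)
  expect_true(s1 %in% eff$before$start)
  expect_false(s1 %in% eff$after$start_orig)
  # the other planted boxes survive with coordinates mapped back
  for (s in prom$sites[-1L]) {
    expect_true(s %in% eff$before$start)
    expect_true(s %in% eff$after$start_orig)
  }

  # deleting a hit-free interval only shifts coordinates
  quiet <- deletion_effect(prom$sequence, 2200, 2240, pwm, 0.8)
  expect_setequal(quiet$after$start_orig, quiet$before$start)
})

test_that("an EMSA-scale 49 bp probe scores a hit only with an intact CArG core", {
  pwm <- carg_pwm()
  withr::with_seed(115, {
    flank <- sample(c("A", "C", "G", "T"), 39, replace = TRUE)
  })
  probe <- paste(c(flank[1:20], "C", "C", "T", "T", "A", "A", "T", "T", "G", "G",
                   flank[21:39]), collapse = "")
  expect_gte(nrow(scan_pwm(probe, pwm, min_rel_score = 0.8)), 1L)
  mutated <- paste(c(flank[1:20], "G", "A", "T", "T", "C", "C", "T", "G", "C", "A",
                     flank[21:39]), collapse = "")
  expect_identical(nrow(scan_pwm(mutated, pwm, min_rel_score = 0.8)), 0L)
})
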