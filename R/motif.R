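# CArG-box promoter scanning: JASPAR position-frequency matrices, log2-odds
# PWM scoring on both strands, a degenerate-consensus mode, and the effect of
# deleting a promoter interval on the hit set.

DNA_BASES <- c("A", "C", "G", "T")

#' Load a position weight matrix from a JASPAR-format file
#'
#' Parses the JASPAR text layout (`>ID name` header, one `A/C/G/T [ ... ]`
#' count row per base) and converts counts to probabilities with a
#' pseudocount: `p[b, i] = (c[b, i] + pseudocount) / (colsum + 4 pseudocount)`.
#'
#' @param path JASPAR-format file.
#' @param pseudocount Added to every count before normalization
#'   (default 0.8).
#' @param background Background base frequencies, A/C/G/T order (default
#'   uniform).
#' @return An object of class `"pwm"`: id, name, counts, probabilities,
#'   log2-odds score matrix, and the achievable score range.
#' @export
load_pwm <- function(path, pseudocount = 0.8, background = rep(0.25, 4)) {
  if (!file.exists(path)) {
    abort(sprintf("I/O error: file not found: %s", path))
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  header <- grepl("^>", lines)
  id <- "PWM"
  name <- ""
  if (any(header)) {
    h <- strsplit(sub("^>", "", lines[which(header)[1L]]), "\\s+")[[1L]]
    id <- h[1L]
    if (length(h) > 1L) name <- paste(h[-1L], collapse = " ")
    lines <- lines[!header]
  }
  rows <- lapply(lines, function(l) {
    base <- toupper(sub("^([ACGTacgt]).*$", "\\1", l))
    nums <- regmatches(l, gregexpr("[0-9]*\\.?[0-9]+", l))[[1L]]
    list(base = base, counts = as.numeric(nums))
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!setequal(bases, DNA_BASES) || length(bases) != 4L) {
    abort("format error: expected exactly one count row per base A, C, G, T")
  }
  widths <- lengths(lapply(rows, `[[`, "counts"))
  if (length(unique(widths)) != 1L) {
    abort("format error: ragged matrix (count rows differ in length)")
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- bases
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (ncol(counts) < 4L) {
    abort("format error: motif width must be at least 4")
  }
  new_pwm(counts, pseudocount, background, id = id, name = name)
}

#' Build a PWM from a count matrix
#'
#' @param counts 4-by-width numeric matrix, rows in A/C/G/T order.
#' @inheritParams load_pwm
#' @param id,name Motif identifiers.
#' @return A `"pwm"` object.
#' @export
new_pwm <- function(counts, pseudocount = 0.8, background = rep(0.25, 4),
                    id = "PWM", name = "") {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  check_number(pseudocount, "pseudocount", min = 0)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    abort("background must be four positive frequencies summing to 1")
  }
  probs <- sweep(counts + pseudocount, 2L, colSums(counts) + 4 * pseudocount, "/")
  score <- log2(sweep(probs, 1L, background, "/"))
  rownames(probs) <- rownames(score) <- DNA_BASES
  structure(
    list(id = id, name = name, counts = counts, probs = probs,
         score = score, pseudocount = pseudocount, background = background,
         width = ncol(counts),
         min_score = sum(apply(score, 2L, min)),
         max_score = sum(apply(score, 2L, max))),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s %s: width %d, score range [%.2f, %.2f] bits\n",
              x$id, x$name, x$width, x$min_score, x$max_score))
  cat("  consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' Consensus string of a PWM (highest-probability base per column, IUPAC W
#' for an A/T tie)
#' @param pwm A `"pwm"` object.
#' @return A character string.
#' @export
consensus_string <- function(pwm) {
  paste(apply(pwm$probs, 2L, function(col) {
    top <- which(col > max(col) - 1e-12)
    if (setequal(DNA_BASES[top], c("A", "T"))) "W" else DNA_BASES[top[1L]]
  }), collapse = "")
}

as_dna_string <- function(sequence) {
  if (inherits(sequence, "DNAString")) return(sequence)
  Biostrings::DNAString(toupper(as.character(sequence)))
}

# forward-strand window scores for one sequence; NA where the window holds N
pwm_window_scores <- function(seq_chr, pwm) {
  codes <- match(strsplit(seq_chr, "", fixed = TRUE)[[1L]], DNA_BASES)
  L <- length(codes)
  w <- pwm$width
  if (L < w) return(numeric(0))
  n_win <- L - w + 1L
  scores <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  for (i in seq_len(w)) {
    ci <- codes[i:(i + n_win - 1L)]
    bad <- is.na(ci)
    valid <- valid & !bad
    ci[bad] <- 1L
    scores <- scores + pwm$score[cbind(ci, i)]
  }
  scores[!valid] <- NA_real_
  scores
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window as the sum of per-position log2 odds
#' `log2(p / background)` and reports windows whose relative score
#' `(score - min) / (max - min)` reaches `min_rel_score`. Reverse-strand
#' matches are reported with forward-strand coordinates; overlapping
#' forward/reverse hits at a palindromic locus are both kept. Windows
#' containing `N` are skipped.
#'
#' @param sequence DNA string (character or `Biostrings::DNAString`) over
#'   `A/C/G/T/N`.
#' @param pwm A `"pwm"` object.
#' @param min_rel_score Relative-score threshold in \[0, 1\] (default 0.8).
#' @param seq_id Sequence id for the output.
#' @return A tibble of hits: `seq_id`, `start` (0-based forward offset),
#'   `strand`, `score`, `rel_score`, `match`; empty when the sequence is
#'   shorter than the motif.
#' @export
scan_pwm <- function(sequence, pwm, min_rel_score = 0.8, seq_id = "seq") {
  stopifnot(inherits(pwm, "pwm"))
  check_number(min_rel_score, "min_rel_score", min = 0, max = 1)
  dna <- as_dna_string(sequence)
  fwd <- as.character(dna)
  rev <- as.character(Biostrings::reverseComplement(dna))
  L <- nchar(fwd)
  w <- pwm$width
  empty <- tibble(seq_id = character(), start = integer(),
                  strand = character(), score = numeric(),
                  rel_score = numeric(), match = character())
  if (L < w) return(empty)

  rng <- pwm$max_score - pwm$min_score
  one_strand <- function(seq_chr, strand) {
    s <- pwm_window_scores(seq_chr, pwm)
    rel <- (s - pwm$min_score) / rng
    keep <- which(!is.na(rel) & rel >= min_rel_score)
    if (length(keep) == 0L) return(empty)
    start0 <- keep - 1L
    if (strand == "-") start0 <- L - w - start0
    tibble(
      seq_id = seq_id, start = as.integer(start0), strand = strand,
      score = s[keep], rel_score = rel[keep],
      match = substring(fwd, start0 + 1L, start0 + w)
    )
  }
  hits <- dplyr::bind_rows(one_strand(fwd, "+"), one_strand(rev, "-"))
  dplyr::arrange(hits, .data$start, .data$strand)
}

#' Scan for a degenerate consensus motif
#'
#' Exact IUPAC-pattern matching on both strands (default the CArG box
#' `CCWWWWWWGG`, i.e. `CC(A/T)6GG`), via `Biostrings::matchPattern` with
#' `fixed = FALSE`. All hits score 1.
#'
#' @param sequence DNA string.
#' @param pattern IUPAC degenerate pattern.
#' @param seq_id Sequence id for the output.
#' @return A tibble of hits shaped like [scan_pwm()] output.
#' @export
consensus_scan <- function(sequence, pattern = "CCWWWWWWGG", seq_id = "seq") {
  dna <- as_dna_string(sequence)
  L <- length(dna)
  w <- nchar(pattern)
  pat <- Biostrings::DNAString(pattern)
  empty <- tibble(seq_id = character(), start = integer(),
                  strand = character(), score = numeric(),
                  rel_score = numeric(), match = character())
  if (L < w) return(empty)
  fwd_m <- Biostrings::matchPattern(pat, dna, fixed = FALSE)
  rev_m <- Biostrings::matchPattern(pat, Biostrings::reverseComplement(dna),
                                    fixed = FALSE)
  fwd_str <- as.character(dna)
  mk <- function(starts1, strand) {
    if (length(starts1) == 0L) return(empty)
    start0 <- if (strand == "+") starts1 - 1L else L - w - (starts1 - 1L)
    tibble(seq_id = seq_id, start = as.integer(start0), strand = strand,
           score = 1, rel_score = 1,
           match = substring(fwd_str, start0 + 1L, start0 + w))
  }
  hits <- dplyr::bind_rows(mk(Biostrings::start(fwd_m), "+"),
                           mk(Biostrings::start(rev_m), "-"))
  dplyr::arrange(hits, .data$start, .data$strand)
}

#' Effect of deleting a promoter interval on the motif hit set
#'
#' Splices `[del_start, del_end)` (0-based, half-open) out of the sequence,
#' rescans, and maps post-deletion hit coordinates back to the original
#' frame: hits left of the deletion keep their offset, hits right of it are
#' shifted by the deletion length, and hits spanning the new junction get
#' `start_orig = NA` (they did not exist in the original sequence). Any hit
#' inside the deleted interval is necessarily absent afterwards.
#'
#' @param sequence DNA string.
#' @param del_start,del_end Deletion interval, 0-based half-open.
#' @param pwm A `"pwm"` object.
#' @param min_rel_score Threshold passed to [scan_pwm()].
#' @param seq_id Sequence id.
#' @return A list with tibbles `before` and `after`; `after` carries the
#'   extra column `start_orig`.
#' @export
deletion_effect <- function(sequence, del_start, del_end, pwm,
                            min_rel_score = 0.8, seq_id = "seq") {
  dna <- as_dna_string(sequence)
  L <- length(dna)
  check_number(del_start, "del_start", min = 0, max = L, integerish = TRUE)
  check_number(del_end, "del_end", min = 0, max = L, integerish = TRUE)
  if (del_end <= del_start) {
    abort("deletion interval is out of range or empty")
  }
  del_len <- del_end - del_start
  seq_chr <- as.character(dna)
  spliced <- paste0(substring(seq_chr, 1L, del_start),
                    substring(seq_chr, del_end + 1L, L))

  before <- scan_pwm(seq_chr, pwm, min_rel_score, seq_id)
  after <- scan_pwm(spliced, pwm, min_rel_score, seq_id)
  w <- pwm$width
  spans_junction <- after$start < del_start & after$start + w > del_start
  after$start_orig <- ifelse(
    spans_junction, NA_integer_,
    ifelse(after$start < del_start, after$start, after$start + del_len)
  )
  list(before = before, after = after)
}

#' Simulate a promoter with planted CArG boxes
#'
#' Random background sequence with `n_sites` consensus CArG boxes
#' (`CC` + six random `A/T` + `GG`) planted at well-separated offsets —
#' a synthetic stand-in for a ~2.3 kb promoter carrying three
#' MADS-box binding sites.
#'
#' @param length Promoter length in bp (default 2300).
#' @param n_sites Number of planted boxes.
#' @param seed Seed.
#' @return A list: `sequence` (character), `sites` (0-based planted starts).
#' @export
simulate_promoter <- function(length = 2300, n_sites = 3, seed = 1) {
  check_number(length, "length", min = 50, integerish = TRUE)
  check_number(n_sites, "n_sites", min = 0, integerish = TRUE)
  with_seed(seed, {
    bases <- sample(DNA_BASES, length, replace = TRUE)
    w <- 10L
    gap <- floor(length / (n_sites + 1L))
    sites <- integer(0)
    if (n_sites > 0L) {
      sites <- vapply(seq_len(n_sites), function(k) {
        lo <- (k - 1L) * gap + 25L
        hi <- k * gap - 25L - w
        as.integer(sample(lo:hi, 1L))
      }, integer(1L))
      for (s in sites) {
        box <- c("C", "C", sample(c("A", "T"), 6L, replace = TRUE), "G", "G")
        bases[(s + 1L):(s + w)] <- box
      }
    }
    list(sequence = paste(bases, collapse = ""), sites = sites)
  })
}
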