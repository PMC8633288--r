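# SNP index / delta SNP index computation, sliding-window smoothing, and
# simulation-based candidate-region calling.

#' Per-bulk SNP index
#'
#' The SNP index of a bulk at a site is the fraction of its reads carrying
#' the A-parent (low-branching, ST147-like) allele.
#'
#' @param records SNP-record tibble.
#' @param bulk `"high"` (compound-inflorescence bulk) or `"low"`.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' r <- tibble::tibble(high_a = 7L, high_total = 10L, low_a = 9L, low_total = 10L)
#' snp_index(r, "high")
snp_index <- function(records, bulk = c("high", "low")) {
  bulk <- match.arg(bulk)
  a <- records[[paste0(bulk, "_a")]]
  total <- records[[paste0(bulk, "_total")]]
  if (is.null(a) || is.null(total)) {
    abort(sprintf("records lack %s-bulk count columns", bulk))
  }
  if (any(total <= 0)) {
    abort(sprintf(
      "undefined SNP index: zero %s-bulk depth at %d site(s); filter zero-depth records upstream",
      bulk, sum(total <= 0)))
  }
  a / total
}

#' Delta SNP index: compound bulk minus simple bulk
#'
#' Subtracts the simple-inflorescence bulk's SNP index from the
#' compound-inflorescence bulk's. Near a branching QTL whose high allele
#' comes from the B parent, the compound bulk is depleted of A-parent reads
#' and the delta goes negative.
#'
#' @param records SNP-record tibble.
#' @return Numeric vector in \[-1, 1\].
#' @export
delta_snp_index <- function(records) {
  snp_index(records, "high") - snp_index(records, "low")
}

#' Attach per-site indices to a record table
#'
#' @param records SNP-record tibble (both bulk depths must be positive).
#' @return A tibble of index points: `chrom`, `pos`, `index_high`,
#'   `index_low`, `delta`.
#' @export
add_snp_indices <- function(records) {
  tibble(
    chrom = records$chrom,
    pos = records$pos,
    index_high = snp_index(records, "high"),
    index_low = snp_index(records, "low"),
    delta = snp_index(records, "high") - snp_index(records, "low")
  )
}

window_starts <- function(chrom_length, step_bp) {
  seq.int(1L, chrom_length, by = step_bp)
}

#' Sliding-window averaging of SNP indices
#'
#' Windows of `window_bp` base pairs advance in `step_bp` steps, anchored at
#' position 1; each covers the half-open interval
#' `[start, min(start + window_bp, chrom_length + 1))` so trailing windows
#' are truncated at the chromosome end rather than dropped. Per-window values
#' are unweighted arithmetic means over the SNPs whose position falls inside
#' the window; windows without SNPs are emitted with `NA` means.
#'
#' @param points Index-point tibble from [add_snp_indices()], sorted by
#'   (`chrom`, `pos`); unsorted input is an error, never silently sorted.
#' @param window_bp,step_bp Window and step size in bp (defaults 1,000 kb and
#'   10 kb).
#' @param chrom_length Chromosome length in bp; a single value, or a named
#'   vector when `points` spans several chromosomes.
#' @return A tibble of window statistics: `chrom`, `start`, `end` (1-based
#'   start, exclusive end), `midpoint`, `mean_index_high`, `mean_index_low`,
#'   `mean_delta`, `n_snps`.
#' @export
sliding_window_scan <- function(points, window_bp = 1e6, step_bp = 1e4,
                                chrom_length) {
  check_columns(points, c("chrom", "pos", "index_high", "index_low", "delta"),
                "points")
  check_number(window_bp, "window_bp", min = 1, integerish = TRUE)
  check_number(step_bp, "step_bp", min = 1, integerish = TRUE)
  if (window_bp < step_bp) {
    abort("configuration error: window_bp must be >= step_bp")
  }
  grp <- match(points$chrom, unique(points$chrom))
  interleaved <- is.unsorted(grp)
  unsorted_pos <- any(vapply(split(points$pos, grp), is.unsorted, logical(1L)))
  if (interleaved || unsorted_pos) {
    abort("points must be sorted by (chrom, pos); refusing to sort silently")
  }

  chroms <- unique(points$chrom)
  if (length(chrom_length) == 1L && is.null(names(chrom_length))) {
    chrom_length <- setNames(rep(chrom_length, length(chroms)), chroms)
  }
  if (!all(chroms %in% names(chrom_length))) {
    abort("chrom_length must be named for every chromosome in points")
  }

  scan_one <- function(chrom) {
    p <- points[points$chrom == chrom, ]
    len <- chrom_length[[chrom]]
    if (any(p$pos > len)) {
      abort(sprintf("points on %s exceed the stated chromosome length", chrom))
    }
    starts <- window_starts(len, step_bp)
    ends <- pmin(starts + window_bp, len + 1)
    # first/last point index in each half-open window; means are then taken
    # over the same contiguous slices a brute-force filter would select
    i1 <- findInterval(starts - 0.5, p$pos) + 1L
    i2 <- findInterval(ends - 0.5, p$pos)
    n <- pmax(i2 - i1 + 1L, 0L)
    mean_slice <- function(x) {
      vapply(seq_along(starts), function(k) {
        if (n[k] == 0L) NA_real_ else mean(x[i1[k]:i2[k]])
      }, numeric(1L))
    }
    tibble(
      chrom = chrom, start = as.integer(starts), end = as.integer(ends),
      midpoint = (starts + ends) / 2,
      mean_index_high = mean_slice(p$index_high),
      mean_index_low = mean_slice(p$index_low),
      mean_delta = mean_slice(p$delta),
      n_snps = as.integer(n)
    )
  }
  dplyr::bind_rows(lapply(chroms, scan_one))
}

#' Monte-Carlo null threshold for the windowed delta SNP index
#'
#' Simulates QTL-free windows: each replicate draws one B-allele frequency per
#' bulk as the mean of `2 * n` Bernoulli(0.5) chromosome draws (an F2 locus
#' unlinked to the phenotype), shared across the SNPs of the window — sites
#' 10 kb apart in an F2 are almost perfectly linked, so within a 1 Mb window
#' the bulk composition, not read sampling, dominates the window mean. Read
#' counts are binomial at depths resampled from the observed depth
#' distribution. The threshold is the two-sided `(1 - alpha)` quantile of the
#' absolute simulated window means.
#'
#' @param depths Empirical per-site depth sample (positive integers), e.g.
#'   `c(filtered$high_total, filtered$low_total)`.
#' @param n_high,n_low Bulk sizes in plants.
#' @param alpha Tail probability; `alpha >= 1` returns 0.
#' @param n_sims Number of simulated windows (at least 100).
#' @param n_snps_per_window Typical SNP count per window (default 20,
#'   matching a 1 Mb window over a 50 kb marker grid).
#' @param seed Seed; the threshold is deterministic given it.
#' @return A single non-negative number.
#' @export
null_delta_threshold <- function(depths, n_high, n_low, alpha = 0.01,
                                 n_sims = 1000, n_snps_per_window = 20,
                                 seed = 1) {
  depths <- depths[is.finite(depths) & depths > 0]
  if (length(depths) == 0L) {
    abort("degenerate depth sample: no positive depths supplied")
  }
  check_number(alpha, "alpha", min = 0)
  if (alpha >= 1) return(0)
  check_number(n_sims, "n_sims", min = 100, integerish = TRUE)
  check_number(n_high, "n_high", min = 1, integerish = TRUE)
  check_number(n_low, "n_low", min = 1, integerish = TRUE)

  with_seed(seed, {
    f_h <- rbinom(n_sims, 2L * n_high, 0.5) / (2 * n_high)
    f_l <- rbinom(n_sims, 2L * n_low, 0.5) / (2 * n_low)
    m <- n_snps_per_window
    d_h <- matrix(sample(depths, n_sims * m, replace = TRUE), n_sims, m)
    d_l <- matrix(sample(depths, n_sims * m, replace = TRUE), n_sims, m)
    idx_h <- matrix(rbinom(n_sims * m, d_h, rep(1 - f_h, m)), n_sims, m) / d_h
    idx_l <- matrix(rbinom(n_sims * m, d_l, rep(1 - f_l, m)), n_sims, m) / d_l
    abs_means <- abs(rowMeans(idx_h - idx_l))
    unname(quantile(abs_means, 1 - alpha, type = 7))
  })
}

#' Call candidate QTL regions from windowed deltas
#'
#' Maximal runs of consecutive windows whose absolute mean delta reaches the
#' threshold are merged into genomic intervals; runs break at empty (missing)
#' windows. Each region reports its peak absolute delta.
#'
#' @param windows Tibble from [sliding_window_scan()].
#' @param threshold Non-negative threshold on `|mean_delta|`, typically from
#'   [null_delta_threshold()].
#' @return A tibble of regions: `chrom`, `start`, `end`, `peak_abs_delta`,
#'   `threshold_used`, `n_windows`; empty when nothing qualifies.
#' @export
call_candidate_regions <- function(windows, threshold) {
  check_columns(windows, c("chrom", "start", "end", "mean_delta"), "windows")
  check_number(threshold, "threshold", min = 0)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  peak_abs_delta = numeric(), threshold_used = numeric(),
                  n_windows = integer())
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    w <- w[order(w$start), ]
    qual <- !is.na(w$mean_delta) & abs(w$mean_delta) >= threshold
    if (!any(qual)) next
    r <- rle(qual)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]:stops[k]
      out[[length(out) + 1L]] <- tibble(
        chrom = ch,
        start = min(w$start[i]), end = max(w$end[i]),
        peak_abs_delta = max(abs(w$mean_delta[i])),
        threshold_used = threshold,
        n_windows = length(i)
      )
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

#' One-call bulked segregant scan
#'
#' Convenience wrapper running the whole scan on a filtered record table:
#' per-site indices, sliding-window smoothing, a simulated null threshold,
#' and candidate-region calling. Returns a fitted-scan object with
#' [tidy()], [glance()] and [autoplot()] methods.
#'
#' @param records Filtered SNP-record tibble (positive depth in both bulks).
#' @param chrom_length Chromosome length(s) in bp.
#' @param window_bp,step_bp Window geometry (defaults 1,000 kb / 10 kb).
#' @param n_high,n_low Bulk sizes for the null simulation.
#' @param alpha Null tail probability for the threshold.
#' @param n_sims Null simulation size.
#' @param seed Seed for the null simulation.
#' @return An object of class `"bsa_scan"`.
#' @export
bsa_scan <- function(records, chrom_length, window_bp = 1e6, step_bp = 1e4,
                     n_high = 24, n_low = 31, alpha = 0.01, n_sims = 1000,
                     seed = 1) {
  points <- add_snp_indices(records)
  windows <- sliding_window_scan(points, window_bp, step_bp, chrom_length)
  med_spacing <- if (nrow(points) > 1L) {
    stats::median(diff(sort(points$pos)))
  } else {
    window_bp
  }
  threshold <- null_delta_threshold(
    depths = c(records$high_total, records$low_total),
    n_high = n_high, n_low = n_low, alpha = alpha, n_sims = n_sims,
    n_snps_per_window = max(1L, round(window_bp / med_spacing)),
    seed = seed
  )
  regions <- call_candidate_regions(windows, threshold)
  structure(
    list(points = points, windows = windows, threshold = threshold,
         regions = regions,
         params = list(window_bp = window_bp, step_bp = step_bp,
                       n_high = n_high, n_low = n_low, alpha = alpha,
                       n_sims = n_sims, seed = seed)),
    class = "bsa_scan"
  )
}

#' Peak window of a scan
#'
#' @param x A `"bsa_scan"` object or a window tibble.
#' @return The single window row with the largest `|mean_delta|` (first one
#'   on ties, in start order).
#' @export
peak_window <- function(x) {
  w <- if (inherits(x, "bsa_scan")) x$windows else x
  w <- w[!is.na(w$mean_delta), ]
  if (nrow(w) == 0L) abort("no non-empty windows to take a peak from")
  w[which.max(abs(w$mean_delta)), ]
}

#' @export
print.bsa_scan <- function(x, ...) {
  pk <- peak_window(x)
  cat("<bsa_scan>\n")
  cat(sprintf("  %d SNPs, %d windows (%.0f kb / %.0f kb), |delta| threshold %.3f (alpha = %g)\n",
              nrow(x$points), nrow(x$windows), x$params$window_bp / 1e3,
              x$params$step_bp / 1e3, x$threshold, x$params$alpha))
  cat(sprintf("  peak: %s:%.2f Mb, mean delta %+.3f over %d SNPs; %d candidate region(s)\n",
              pk$chrom, pk$midpoint / 1e6, pk$mean_delta, pk$n_snps,
              nrow(x$regions)))
  invisible(x)
}
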