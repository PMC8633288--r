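# broom-style accessors for the fitted-object classes

#' Tidy a bulked segregant scan
#'
#' @param x A `"bsa_scan"` object.
#' @param ... Unused.
#' @return The window tibble (one row per sliding window).
#' @method tidy bsa_scan
#' @export
tidy.bsa_scan <- function(x, ...) {
  x$windows
}

#' One-row summary of a bulked segregant scan
#'
#' @param x A `"bsa_scan"` object.
#' @param ... Unused.
#' @return A tibble with the SNP and window counts, the null threshold, the
#'   peak window's midpoint and mean delta, and the number of candidate
#'   regions.
#' @method glance bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  pk <- peak_window(x)
  tibble(
    n_snps = nrow(x$points),
    n_windows = nrow(x$windows),
    threshold = x$threshold,
    alpha = x$params$alpha,
    peak_chrom = pk$chrom,
    peak_midpoint = pk$midpoint,
    peak_mean_delta = pk$mean_delta,
    n_regions = nrow(x$regions)
  )
}

#' Per-line interval constraints of a fine-mapping fit
#'
#' @param x A `"fine_map"` object.
#' @param ... Unused.
#' @return A tibble with one row per compatible segment per line: `line`,
#'   `lo`, `hi` (open interval bounds in bp).
#' @method tidy fine_map
#' @export
tidy.fine_map <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$constraints), function(id) {
    m <- x$constraints[[id]]
    tibble(line = id, lo = m[, 1L], hi = m[, 2L])
  }))
}

#' One-row summary of a fine-mapping fit
#'
#' @param x A `"fine_map"` object.
#' @param ... Unused.
#' @return A tibble with the interval bounds, flanking markers, width, and
#'   number of informative lines.
#' @method glance fine_map
#' @export
glance.fine_map <- function(x, ...) {
  tibble(
    chrom = x$chrom,
    lo = unname(x$interval["lo"]),
    hi = unname(x$interval["hi"]),
    left_marker = x$left_marker,
    right_marker = x$right_marker,
    width_bp = unname(x$interval["hi"] - x$interval["lo"]),
    n_lines = x$n_lines
  )
}

#' Per-gene table of a differential-expression analysis
#'
#' @param x A `"deg_result"` object.
#' @param ... Unused.
#' @return The stacked per-comparison gene tibble.
#' @method tidy deg_result
#' @export
tidy.deg_result <- function(x, ...) {
  x$table
}

#' Per-comparison summary of a differential-expression analysis
#'
#' @param x A `"deg_result"` object.
#' @param ... Unused.
#' @return A tibble with one row per comparison: genes tested and up/down
#'   calls.
#' @method glance deg_result
#' @export
glance.deg_result <- function(x, ...) {
  x$table %>%
    dplyr::group_by(.data$comparison) %>%
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_tested = sum(!is.na(.data$p_raw)),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop"
    )
}
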