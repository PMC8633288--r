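# ggplot2 displays for each result type

#' Plot a bulked segregant scan
#'
#' Windowed delta SNP index along the chromosome, with the simulated null
#' threshold (dashed) and candidate regions shaded.
#'
#' @param object A `"bsa_scan"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bsa_scan
#' @export
autoplot.bsa_scan <- function(object, ...) {
  w <- object$windows[!is.na(object$windows$mean_delta), ]
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$midpoint / 1e6,
                                       y = .data$mean_delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1L) +
    ggplot2::labs(x = "Position (Mb)", y = "Windowed delta SNP index",
                  title = "Bulked segregant scan") +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot per-site SNP indices of both bulks
#'
#' @param points Index-point tibble from [add_snp_indices()].
#' @return A ggplot.
#' @export
plot_snp_index <- function(points) {
  long <- tidyr::pivot_longer(points, c("index_high", "index_low"),
                              names_to = "bulk", values_to = "index")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos / 1e6, y = .data$index,
                                     colour = .data$bulk)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.4) +
    ggplot2::facet_wrap(~chrom, ncol = 1L) +
    ggplot2::labs(x = "Position (Mb)", y = "SNP index (A-parent read fraction)") +
    ggplot2::theme_minimal()
}

#' MA-style plot of a differential-expression analysis
#'
#' Mean FPKM (log10) against log2 fold change, coloured by call.
#'
#' @param object A `"deg_result"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deg_result
#' @export
autoplot.deg_result <- function(object, ...) {
  d <- object$table[!is.na(object$table$fold_change), ]
  d$mean_fpkm <- (d$mean_fpkm_case + d$mean_fpkm_control) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$mean_fpkm + 0.01),
                                  y = log2(pmax(.data$fold_change, 1e-6)),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "log10 mean FPKM", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Plot a fine-mapping fit
#'
#' Per-line compatible segments with the final interval shaded.
#'
#' @param object A `"fine_map"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fine_map
#' @export
autoplot.fine_map <- function(object, ...) {
  d <- tidy(object)
  span <- range(object$markers$pos)
  d$lo <- pmax(d$lo, span[1L] - 0.05 * diff(span))
  d$hi <- pmin(d$hi, span[2L] + 0.05 * diff(span))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo / 1e6, xend = .data$hi / 1e6,
                                       y = .data$line, yend = .data$line),
                          linewidth = 2, colour = "grey40") +
    ggplot2::annotate("rect",
                      xmin = object$interval["lo"] / 1e6,
                      xmax = object$interval["hi"] / 1e6,
                      ymin = -Inf, ymax = Inf,
                      alpha = 0.2, fill = "firebrick") +
    ggplot2::geom_vline(xintercept = object$markers$pos / 1e6,
                        linetype = "dotted", colour = "grey70") +
    ggplot2::labs(x = "Position (Mb)", y = "Recombinant line",
                  title = "Interval constraints and narrowed QTL region") +
    ggplot2::theme_minimal()
}

#' Plot motif hits along a promoter
#'
#' @param hits Hit tibble from [scan_pwm()] or [consensus_scan()].
#' @param seq_length Promoter length in bp (x-axis extent).
#' @return A ggplot.
#' @export
plot_motif_hits <- function(hits, seq_length = NULL) {
  p <- ggplot2::ggplot(hits, ggplot2::aes(x = .data$start,
                                          y = .data$rel_score,
                                          shape = .data$strand)) +
    ggplot2::geom_point(size = 3, colour = "firebrick") +
    ggplot2::labs(x = "Offset in promoter (bp, 0-based)",
                  y = "Relative PWM score") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(seq_length)) p <- p + ggplot2::xlim(0, seq_length)
  p
}
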