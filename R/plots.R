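#' Plot a G' QTL scan
#'
#' Significance track (`-log10(P)` against genomic position, faceted by
#' chromosome) with the QTL-discovery threshold line and called intervals
#' shaded.
#'
#' @param object A `gprime_scan`.
#' @param chroms Optional chromosome subset.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gprime_scan
#' @export
autoplot.gprime_scan <- function(object, chroms = NULL, ...) {
  track <- object$track
  iv <- object$intervals
  if (!is.null(chroms)) {
    track <- dplyr::filter(track, .data$CHROM %in% chroms)
    iv <- dplyr::filter(iv, .data$CHROM %in% chroms)
  }
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$POS / 1000,
                                           y = .data$neglog10p)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::geom_hline(yintercept = object$params$neglog_threshold,
                        linetype = "dotted") +
    ggplot2::facet_wrap(~CHROM, scales = "free_x") +
    ggplot2::labs(x = "position (kbp)", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
  if (nrow(iv)) {
    p <- p + ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$start / 1000, xmax = .data$end / 1000),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.15)
  }
  p
}

#' Plot pool allele-frequency profiles
#'
#' 1-kbp window medians of the CEN.PK allele frequency in the reference and
#' selected pools, with the neutral 0.50 line.
#'
#' @param scan A `gprime_scan` (or the output of
#'   [window_median_frequency()]).
#' @param chroms Optional chromosome subset.
#' @return A ggplot object.
#' @export
plot_pool_frequencies <- function(scan, chroms = NULL) {
  med <- if (inherits(scan, "gprime_scan")) scan$medians else scan
  if (!is.null(chroms)) med <- dplyr::filter(med, .data$CHROM %in% chroms)
  long <- med |>
    tidyr::pivot_longer(c("median_freq_LOW", "median_freq_HIGH"),
                        names_to = "pool", values_to = "freq") |>
    dplyr::mutate(pool = dplyr::if_else(.data$pool == "median_freq_HIGH",
                                        "selected (high NaCl)", "reference"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_start / 1000,
                                     y = .data$freq, colour = .data$pool)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c("reference" = "grey40",
                                            "selected (high NaCl)" = "firebrick")) +
    ggplot2::facet_wrap(~CHROM, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (kbp)", y = "CEN.PK allele frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a modality call
#'
#' Histogram of the values with the fitted one- and two-component mixture
#' densities overlaid; the selected model is drawn solid.
#'
#' @param object A `modality_call`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot modality_call
#' @export
autoplot.modality_call <- function(object, bins = 40, ...) {
  # reconstruct the observation range from the fits
  f2 <- object$fit2
  xs <- seq(min(f2$means) - 4 * max(f2$sds),
            max(f2$means) + 4 * max(f2$sds), length.out = 400)
  dens <- dplyr::bind_rows(
    tibble(x = xs, model = "k = 1",
           density = dnorm(xs, object$fit1$means, object$fit1$sds)),
    tibble(x = xs, model = "k = 2",
           density = f2$weights[1] * dnorm(xs, f2$means[1], f2$sds[1]) +
             f2$weights[2] * dnorm(xs, f2$means[2], f2$sds[2])))
  chosen <- if (object$decision == "bimodal") "k = 2" else "k = 1"
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                     colour = .data$model,
                                     linetype = .data$model == chosen)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(title = sprintf("%s (Delta BIC = %.1f)", object$decision,
                                  object$delta_bic),
                  x = "relative NaCl tolerance", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot tolerance class histograms by generation
#'
#' @param tolerance_classes Tibble with columns `generation` and `class` (or
#'   `tolerance`, binned on the fly).
#' @return A ggplot object.
#' @export
plot_class_histogram <- function(tolerance_classes) {
  df <- tolerance_classes
  if (!"class" %in% names(df)) df$class <- assign_class(df$tolerance)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class)) +
    ggplot2::geom_bar(fill = "grey60") +
    ggplot2::geom_vline(xintercept = 20, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "tolerance class (width 0.05; reference strain = 20)",
                  y = "segregants") +
    ggplot2::theme_minimal()
  if ("generation" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~generation)
  }
  p
}
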