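#' Stacked clonal-composition bars
#'
#' One bar per sample, segments sized by clonal abundance — the standard
#' clonal-tracking composition display.
#'
#' @param abundance Tibble `sample_id`, `barcode`, `abundance`.
#' @return A ggplot object.
#' @export
plot_clonal_composition <- function(abundance) {
  ggplot2::ggplot(filter(abundance, .data$abundance > 0),
                  ggplot2::aes(x = .data$sample_id, y = .data$abundance,
                               fill = .data$barcode)) +
    ggplot2::geom_col(color = "grey20", linewidth = 0.1,
                      show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "clonal abundance (% of MNC)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Tissue-bias scatter with the 99% band
#'
#' Blood abundance against target-tissue abundance per clone on log10 axes,
#' with the blood-spleen-derived band drawn as dashed lines and calls
#' colored.
#'
#' @param bias_calls Output of [tissue_bias()].
#' @param floor Pseudo-abundance used for the ratios (display only).
#' @return A ggplot object.
#' @export
plot_tissue_bias <- function(bias_calls, floor = 0.001) {
  ggplot2::ggplot(bias_calls,
                  ggplot2::aes(x = seq_len(nrow(bias_calls)),
                               y = .data$log2_ratio, color = .data$call)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$band_low[1]),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$band_high[1]),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "clone", y = "log2 target / blood abundance",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Clone trajectories across serial transplants
#'
#' @param classified Output of [classify_trajectories()] (long features are
#'   re-derived from the `log10_p*` columns).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(classified) {
  long <- classified |>
    tidyr::pivot_longer(dplyr::starts_with("log10_p"),
                        names_to = "passage", values_to = "log10_abundance",
                        names_prefix = "log10_p") |>
    mutate(passage = as.integer(.data$passage))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$passage,
                                     y = .data$log10_abundance,
                                     group = .data$clone,
                                     color = .data$class)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "transplant generation",
                  y = "log10 mean abundance (%)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_clonotrx
#' @export
autoplot.dge_fps <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(pmax(.data$p, 1e-300)),
                                    y = .data$fps,
                                    color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$params$alpha_fps,
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_vline(xintercept = -log10(object$params$alpha_p),
                        linetype = "dashed", color = "grey50") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "-log10 one-sided Mann-Whitney p",
                  y = "false-positive score",
                  title = object$grouping$label) +
    ggplot2::theme_minimal()
}

#' Autoplot methods for clonotrx results
#'
#' @param object A clonotrx result object.
#' @param ... Unused.
#' @name autoplot_clonotrx
NULL
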