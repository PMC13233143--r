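#' Plot a positional profile
#'
#' Per-bin mean attention as columns with the 3-bin rolling average as a
#' line, TSS marked at 0.
#'
#' @param object A `positional_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot positional_profile
#' @export
autoplot.positional_profile <- function(object, ...) {
  b <- object$bins
  ggplot2::ggplot(b, ggplot2::aes(x = .data$bin_start + object$bin_width / 2)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$mean_attention),
                      fill = "grey70", width = object$bin_width) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "firebrick",
                       linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance to TSS (bp)", y = "mean attention",
                  title = "Motif positional profile") +
    ggplot2::theme_minimal()
}

#' Plot motif enrichment
#'
#' Carrier count against -log10 q-value, significant motifs highlighted.
#'
#' @param object A `motif_discovery`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motif_discovery
#' @export
autoplot.motif_discovery <- function(object, ...) {
  m <- object$motifs
  ggplot2::ggplot(m, ggplot2::aes(x = .data$n, y = -log10(.data$q),
                                  color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "sequences containing motif", y = "-log10(q)",
                  color = "significant",
                  title = "Hypergeometric motif enrichment") +
    ggplot2::theme_minimal()
}

#' Plot a SHAP token summary
#'
#' Top tokens by mean absolute SHAP value, with 95% CI error bars on the
#' mean; occurrence counts in the labels.
#'
#' @param object A `shap_token_summary`.
#' @param top_k Tokens to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shap_token_summary
#' @export
autoplot.shap_token_summary <- function(object, top_k = 15, ...) {
  top <- rank_tokens(object, by = "abs_mean", top_k = top_k)
  top$token_text <- factor(top$token_text,
                           levels = rev(top$token_text))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$mean_shap,
                                    y = .data$token_text,
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_shap - .data$ci_half_width,
                   xmax = .data$mean_shap + .data$ci_half_width),
      height = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       hjust = -0.2, size = 2.8) +
    ggplot2::labs(x = "mean SHAP value (95% CI)", y = NULL,
                  title = "Top tokens by mean |SHAP|") +
    ggplot2::theme_minimal()
}
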