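#' Plot a mark distribution
#'
#' Raw normalized profile (points) with the DFT-smoothed profile overlaid
#' (line), against bp relative to the occurrence centre.
#'
#' @param md A `"mark_distribution"` with `normalized`/`smoothed` filled.
#' @return A ggplot object.
#' @export
plot_mark_distribution <- function(md) {
  if (is.null(md$smoothed)) md <- normalize_and_smooth(md)
  B <- length(md$bins)
  df <- tibble(
    bp = (seq_len(B) - 0.5) * md$bin_width - md$halfwidth,
    normalized = md$normalized,
    smoothed = md$smoothed
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$normalized),
                        colour = "grey50", size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "bp from occurrence centre", y = "mass per bin",
      title = paste0(md$word %||% "", "  (", md$track_name, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_mark_distribution
#' @param object A `"mark_distribution"`.
#' @param ... Unused.
#' @export
autoplot.mark_distribution <- function(object, ...) {
  plot_mark_distribution(object)
}

#' ROC curve of a site evaluation
#'
#' @param object A `"site_eval"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_eval <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(fpr = 0, sensitivity = 0),
    object$roc[order(object$roc$fpr, object$roc$sensitivity),
               c("fpr", "sensitivity")],
    tibble(fpr = 1, sensitivity = 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUROC = %.3f", object$auroc)
    ) +
    ggplot2::theme_minimal()
}

#' Probability logo-style bar plot of a motif
#'
#' Stacked per-position base probabilities (a lightweight stand-in for a
#' sequence logo).
#'
#' @param object A `"pfm_motif"`.
#' @param pseudocount Pseudocount for normalization.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfm_motif <- function(object, pseudocount = 0.25, ...) {
  df <- tidy.pfm_motif(object, pseudocount)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$probability,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(
      A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839"
    )) +
    ggplot2::labs(title = paste0(object$id, "  ", object$consensus),
                  x = "position", y = "probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
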