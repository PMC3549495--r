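#' Plot pathway selection frequencies
#'
#' Horizontal bar chart of the top pathways by selection frequency across
#' subsamples, with the uniform null level 1/L marked.
#'
#' @param object a [rank_pathways()] result.
#' @param top number of pathways to show (default 20).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psrrr_ranking <- function(object, top = 20, ...) {
  df <- head(object$pathway_freq, top)
  null_level <- 1 / nrow(object$pathway_freq)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$freq,
    y = stats::reorder(.data$pathway, .data$freq)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = null_level, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("selection frequency (B = %d)", object$B),
      y = NULL,
      title = "Pathway selection frequencies",
      subtitle = sprintf("dashed line: uniform null 1/L = %.3f", null_level)
    )
}

#' Plot a weight-tuning trajectory
#'
#' Convergence of the tuning loop: the total deviation from the uniform null
#' selection distribution per iteration, against the stopping bound.
#'
#' @param object a [tune_weights()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.weight_schedule <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$sum_abs_d),
    sum_abs_d = object$sum_abs_d
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$sum_abs_d)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$epsilon, linetype = "dashed") +
    ggplot2::labs(
      x = "tuning iteration", y = "sum |d_l|",
      title = "Pathway weight tuning",
      subtitle = sprintf("dashed line: convergence bound epsilon = %g",
                         object$epsilon)
    )
}

#' Plot the voxel screening p-value distribution
#'
#' Histogram of -log10 ANCOVA p-values with the Bonferroni selection
#' threshold marked.
#'
#' @param object an [ancova_screen()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_selection <- function(object, ...) {
  df <- tibble::tibble(neglog10_p = -log10(pmax(object$p_values, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$neglog10_p)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey40") +
    ggplot2::geom_vline(xintercept = -log10(object$threshold),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = "-log10 p (diagnosis ANCOVA)", y = "voxels",
      title = sprintf("Voxel screening: %d / %d selected",
                      object$n_selected, object$q_star)
    )
}

#' Plot fitted pathway coefficient norms
#'
#' Group norms `||b_l||` of a fit, highlighting selected pathways.
#'
#' @param object a [fit_psrrr()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psrrr_fit <- function(object, ...) {
  lay <- as_group_layout(object$mapping)
  norms <- vapply(seq_along(lay$size), function(l) {
    sqrt(sum(object$b[lay$start[l] + seq_len(lay$size[l])]^2))
  }, numeric(1))
  df <- tibble::tibble(
    pathway = object$mapping$pathways, norm = norms,
    selected = norms > 0
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$norm, y = stats::reorder(.data$pathway, .data$norm),
    fill = .data$selected
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "||b_l||", y = NULL,
                  title = sprintf("Pathway coefficient norms (lambda = %.3g)",
                                  object$lambda))
}
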