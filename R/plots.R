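# Plotting and generic re-exports.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-split prediction metrics
#'
#' Boxplots of accuracy, sensitivity, and specificity across the repeated
#' train/test subsamplings, with the chance level at 50% marked.
#'
#' @param object A `repeated_cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot repeated_cv_result
#' @export
autoplot.repeated_cv_result <- function(object, ...) {
  per <- object$per_split
  long <- do.call(rbind, lapply(
    c("accuracy", "sensitivity", "specificity"),
    function(m) data.frame(metric = m, value = per[[m]])))
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "percent",
      title = sprintf("Test performance over %d subsamplings%s",
                      nrow(per),
                      if (isTRUE(object$null)) " (permutation null)" else ""))
}

#' Scree plot of normalized component variances
#'
#' Normalized variance (each component's variance relative to the leading
#' component's) against component index, with the 0.25 display cutoff the
#' study uses to rank network components.
#'
#' @param object A `connectivity_basis`.
#' @param n_components Number of leading components to show (default: the
#'   basis rank).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot connectivity_basis
#' @export
autoplot.connectivity_basis <- function(object, n_components = NULL, ...) {
  n_show <- n_components %||% object$rank
  df <- utils::head(tidy(object), n_show)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$normalized_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dashed") +
    ggplot2::labs(x = "component", y = "normalized variance")
}

#' Heatmap of the averaged SVM weight matrix
#'
#' Diagonal cells weight single-component features; off-diagonal cells
#' weight component interactions.
#'
#' @param summary A `weight_matrix_summary` (or a `repeated_cv_result`,
#'   whose weight matrix is used).
#' @param n_components Show only the leading block of this size (the study
#'   displays the first 8 of 17).
#' @return A ggplot object.
#' @export
plot_weight_matrix <- function(summary, n_components = NULL) {
  if (inherits(summary, "repeated_cv_result")) summary <- summary$weight_matrix
  stopifnot(inherits(summary, "weight_matrix_summary"))
  M <- summary$matrix
  if (!is.null(n_components)) {
    n_components <- min(n_components, nrow(M))
    M <- M[seq_len(n_components), seq_len(n_components), drop = FALSE]
  }
  df <- expand.grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
  df$weight <- M[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "component", y = "component", fill = "mean weight")
}

#' @importFrom ggplot2 .data
NULL
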