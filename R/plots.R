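#' ROC curve for an evaluation report
#'
#' @param object A `dsim_eval`.
#' @param ... Unused.
#' @return A ggplot: the empirical ROC curve with the AUC in the subtitle.
#' @export
autoplot.dsim_eval <- function(object, ...) {
  s <- c(object$scores_pos, object$scores_neg)
  y <- rep(c(1L, 0L), c(object$n_pos, object$n_neg))
  th <- c(Inf, sort(unique(s), decreasing = TRUE))
  roc <- tibble::tibble(
    fpr = vapply(th, function(t) mean(object$scores_neg >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(object$scores_pos >= t), numeric(1))
  )
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Benchmark vs random pairs",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}

#' Scatter of the first two embedding dimensions
#'
#' @param object A `dsim_embedding`.
#' @param labels Optional named character vector id -> category used to
#'   colour the points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsim_embedding <- function(object, labels = NULL, ...) {
  df <- tibble::tibble(disease_id = object$node_ids,
                       dim_1 = object$X[, 1],
                       dim_2 = if (object$d >= 2) object$X[, 2] else 0)
  if (!is.null(labels)) {
    df$category <- unname(labels[df$disease_id])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim_1, y = .data$dim_2,
                                          colour = .data$category))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim_1, y = .data$dim_2))
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = sprintf("Disease embedding (d = %d, %s)",
                                  object$d, object$method))
}

#' Dimension-sweep AUC plot
#'
#' @param sweep Tibble from [dimension_sweep()].
#' @return A ggplot of AUC against embedding dimension.
#' @export
plot_dimension_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$dim, y = .data$auc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "embedding dimension d", y = "AUC",
                  title = "Stability of AUC across embedding dimensions")
}

#' Top-k recovery curve plot
#'
#' @param curve Tibble from [topk_recovery_curve()].
#' @return A ggplot of recovered positives against ranking depth k.
#' @export
plot_topk_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$n_recovered)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "top-k ranked pairs", y = "benchmark pairs recovered",
                  title = "Recovery of benchmark pairs by rank")
}
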