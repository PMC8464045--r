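#' Tidy an affinity model into a long tibble
#'
#' @param x an `affinity_model`.
#' @param ... unused.
#' @return Tibble (tf, protein, weight).
#' @method tidy affinity_model
#' @export
tidy.affinity_model <- function(x, ...) {
  tibble::tibble(tf = rep(x$tf_ids, times = ncol(x$W)),
                 protein = rep(x$protein_ids, each = nrow(x$W)),
                 weight = as.vector(x$W))
}

#' One-row model summary
#'
#' @param x an `affinity_model`.
#' @param ... unused.
#' @return Tibble with hyperparameters and solver state.
#' @method glance affinity_model
#' @export
glance.affinity_model <- function(x, ...) {
  tibble::tibble(n_tfs = nrow(x$W), n_proteins = ncol(x$W),
                 lambda1 = x$lambda1, lambda2 = x$lambda2,
                 svd_rank = x$svd_rank, sparsity = x$sparsity,
                 converged = x$converged, iterations = x$iterations,
                 objective = x$objective)
}

#' Tidy a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return The per-grid-point score tibble.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$grid

#' Heatmap of the learned TF x protein interaction matrix
#'
#' @param object an `affinity_model`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot affinity_model
#' @export
autoplot.affinity_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
      x = .data$protein, y = .data$tf, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(x = "surface protein", y = "transcription factor",
                  fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Boxplot of per-cell scores for a method comparison
#'
#' @param object a `method_comparison` from [evaluate_methods_cv()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(
      x = .data$method, y = .data$rho, fill = .data$method)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "per-cell Spearman rho") +
    ggplot2::theme_minimal()
}

#' Dot plot of significant-TF frequencies
#'
#' @param report a `significance_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_tf_frequency <- function(report, ...) {
  freq <- report$frequency
  y <- if ("cell_type" %in% names(freq)) "cell_type" else NULL
  p <- ggplot2::ggplot(freq, ggplot2::aes(
      x = .data$tf,
      y = if (is.null(y)) "all cells" else .data$cell_type,
      size = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "transcription factor", y = NULL,
                  size = "fraction of cells\nsignificant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  p
}

#' @importFrom ggplot2 .data
NULL
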