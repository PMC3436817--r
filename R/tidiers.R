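#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained hierarchy model
#'
#' @param x A `hierloc_model`.
#' @param ... Unused.
#' @return One row per decision node: `node`, `n_support`, `bias`,
#'   `platt_a`, `platt_b`, `regularization_c`.
#' @exportS3Method generics::tidy
tidy.hierloc_model <- function(x, ...) {
  dplyr::bind_rows(lapply(x$node_models, function(nm) {
    tibble::tibble(node = nm$node_id,
                   n_support = length(nm$support_ids),
                   bias = nm$bias, platt_a = nm$platt_a,
                   platt_b = nm$platt_b,
                   regularization_c = nm$regularization_c)
  }))
}

#' @rdname tidy.hierloc_model
#' @exportS3Method generics::glance
glance.hierloc_model <- function(x, ...) {
  tibble::tibble(domain = x$topology$domain,
                 n_classes = length(x$topology$leaves),
                 n_nodes = length(x$node_models),
                 n_train = nrow(x$train),
                 k = x$params$k, sigma = x$params$sigma,
                 normalize = x$params$normalize)
}

#' Tidy cross-validation results
#'
#' @param x A `hierloc_cv`.
#' @param ... Unused.
#' @return `tidy()`: the per-class metric tibble (reported classes only).
#'   `glance()`: one row with `qn`, `n_classes`, `n_proteins`, `n_folds`.
#' @exportS3Method generics::tidy
tidy.hierloc_cv <- function(x, ...) x$metrics

#' @rdname tidy.hierloc_cv
#' @exportS3Method generics::glance
glance.hierloc_cv <- function(x, ...) {
  tibble::tibble(qn = x$qn,
                 n_classes = length(x$reported_classes),
                 n_proteins = nrow(x$predictions),
                 n_folds = x$config$n_folds)
}

#' Tidy a confusion matrix into long form
#'
#' @param x A `hierloc_confusion`.
#' @param ... Unused.
#' @return Tibble with `observed`, `predicted`, `n`.
#' @exportS3Method generics::tidy
tidy.hierloc_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    observed = rep(rownames(m), times = ncol(m)),
    predicted = rep(colnames(m), each = nrow(m)),
    n = as.integer(as.vector(m)))
}

#' Tidy a fragment benchmark
#'
#' @param x A `hierloc_fragments`.
#' @param ... Unused.
#' @return The per-variant summary tibble (`variant`, `n`, `qn`).
#' @exportS3Method generics::tidy
tidy.hierloc_fragments <- function(x, ...) x$summary

#' Plot reliability-threshold curves
#'
#' Accuracy and coverage of the predictions kept at each reliability-index
#' threshold.
#'
#' @param object A [ri_curves()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hierloc_ri_curves <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("threshold", "accuracy", "coverage")],
    c("accuracy", "coverage"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   color = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "reliability-index threshold", y = NULL,
                  color = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a tile heatmap
#'
#' @param object A `hierloc_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hierloc_confusion <- function(object, ...) {
  df <- tidy.hierloc_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-class cross-validation metrics
#'
#' @param object A `hierloc_cv`.
#' @param ... Unused.
#' @return A ggplot of per-class accuracy, coverage and gAv.
#' @exportS3Method ggplot2::autoplot
autoplot.hierloc_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics,
                            c("accuracy", "coverage", "gav"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = sprintf("Q%d = %.2f",
                                  length(object$reported_classes),
                                  object$qn)) +
    ggplot2::theme_minimal()
}
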