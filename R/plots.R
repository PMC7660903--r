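# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-class F1 bars of an evaluation
#'
#' @param object A `virann_metrics`.
#' @param metric One of `"f1"`, `"precision"`, `"recall"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot virann_metrics
#' @export
autoplot.virann_metrics <- function(object, metric = c("f1", "precision",
                                                       "recall"), ...) {
  metric <- match.arg(metric)
  dat <- object$per_class
  dat$class <- factor(dat$class, levels = object$classes)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class,
                                    y = .data[[metric]],
                                    fill = factor(.data$cutoff))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_viridis_d(name = "score cutoff") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Row-normalized confusion-matrix heat map
#'
#' @param metrics A `virann_metrics`.
#' @param cutoff Which cutoff's matrix to draw (default the first).
#' @return A ggplot; a perfect classifier is 1 on the diagonal.
#' @export
plot_confusion <- function(metrics, cutoff = names(metrics$confusion)[1]) {
  m <- metrics$confusion[[as.character(cutoff)]]
  rs <- rowSums(m)
  m <- m / ifelse(rs == 0, 1, rs)
  dat <- tibble::as_tibble(as.table(m))
  names(dat) <- c("truth", "predicted", "fraction")
  dat$truth <- factor(dat$truth, levels = rev(rownames(m)))
  dat$predicted <- factor(dat$predicted, levels = colnames(m))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                    fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$fraction > 0, sprintf("%.2f", .data$fraction),
                     "")), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "true class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Score-to-confidence curves
#'
#' @param object A `confidence_table`.
#' @param ... Unused.
#' @return A ggplot of confidence against score threshold, one line per
#'   class (sparse carried-forward segments dashed).
#' @method autoplot confidence_table
#' @export
autoplot.confidence_table <- function(object, ...) {
  dat <- object[!is.na(object$confidence), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$threshold,
                                    y = .data$confidence,
                                    color = .data$class,
                                    linetype = .data$sparse)) +
    ggplot2::geom_step() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "ensemble score threshold", y = "confidence") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Metric progression over score cutoffs
#'
#' Weighted precision/recall/F1 and the retained fraction as low-scoring
#' queries are excluded.
#'
#' @param metrics A `virann_metrics` evaluated at several cutoffs.
#' @return A ggplot.
#' @export
plot_cutoff_sweep <- function(metrics) {
  dat <- tidyr::pivot_longer(
    metrics$summary[, c("cutoff", "weighted_precision", "weighted_recall",
                        "weighted_f1", "retained_fraction")],
    -"cutoff", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                    color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "minimum ensemble score", y = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves
#'
#' @param metrics A `virann_metrics` with ROC data.
#' @return A ggplot, one curve per class with AUC in the legend.
#' @export
plot_roc <- function(metrics) {
  if (is.null(metrics$roc)) stop("metrics object carries no ROC data")
  keep <- !vapply(metrics$roc$curve, is.null, logical(1))
  dat <- tidyr::unnest(metrics$roc[keep, ], "curve")
  dat$label <- sprintf("%s (AUC %.2f)", dat$class, dat$auc)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    color = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = NULL) +
    ggplot2::theme_minimal()
}
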