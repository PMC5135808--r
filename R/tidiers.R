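#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x a `recur_cv` object.
#' @param ... unused.
#' @return a tibble with one row per repeat: `repeat_id`, `auc`.
#' @export
tidy.recur_cv <- function(x, ...) {
  tibble(repeat_id = seq_along(x$auc), auc = x$auc)
}

#' One-row summary of a cross-validation result
#'
#' @param x a `recur_cv` object.
#' @param ... unused.
#' @return a tibble: `folds`, `repeats`, `n_trees`, `mean_auc`, `sd_auc`,
#'   `min_auc`, `max_auc`.
#' @export
glance.recur_cv <- function(x, ...) {
  tibble(
    folds = x$folds, repeats = x$repeats, n_trees = x$n_trees,
    mean_auc = x$mean_auc, sd_auc = stats::sd(x$auc),
    min_auc = min(x$auc), max_auc = max(x$auc)
  )
}

#' Tidy a trained forest
#'
#' @param x a `recur_forest` object.
#' @param ... unused.
#' @return a tibble of per-feature Mean Decrease Accuracy: `feature`,
#'   `mda` (percentage points).
#' @export
tidy.recur_forest <- function(x, ...) {
  imp <- x$fit$importance
  if (!"MeanDecreaseAccuracy" %in% colnames(imp)) {
    rlang::abort("retrain with train_forest(..., importance = TRUE) to tidy importances")
  }
  tibble(
    feature = rownames(imp),
    mda = as.numeric(imp[, "MeanDecreaseAccuracy"]) * 100
  )
}

#' One-row summary of a trained forest
#'
#' @param x a `recur_forest` object.
#' @param ... unused.
#' @return a tibble: `n_trees`, `mtry`, `oob_error`.
#' @export
glance.recur_forest <- function(x, ...) {
  tibble(
    n_trees = x$n_trees, mtry = x$fit$mtry,
    oob_error = unname(tail(x$fit$err.rate[, "OOB"], 1))
  )
}

#' ROC curve of a cross-validation result
#'
#' @param object a `recur_cv` object.
#' @param ... unused.
#' @return a ggplot: pooled held-out ROC curve with the chance diagonal.
#' @export
autoplot.recur_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_step(color = "#c0392b", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Pooled ROC, mean AUC = %.3f", object$mean_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Variable-importance plot of a trained forest
#'
#' @param object a `recur_forest` object.
#' @param ... unused.
#' @return a ggplot: features ordered by Mean Decrease Accuracy.
#' @export
autoplot.recur_forest <- function(object, ...) {
  df <- tidy.recur_forest(object)
  df$feature <- factor(df$feature, levels = df$feature[order(df$mda)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mda, y = .data$feature)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::labs(x = "Mean decrease accuracy (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a sample-addition validation report
#'
#' @param report output of [validation_report()].
#' @return a ggplot: revealed-recurrence counts per selection method,
#'   faceted by check window.
#' @export
plot_validation <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$method, y = .data$revealed)) +
    ggplot2::geom_col(fill = "#2980b9") +
    ggplot2::facet_wrap(~window, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = NULL, y = "Mutations with recurrence revealed",
      title = "Recurrence revealed by sample addition"
    ) +
    ggplot2::theme_minimal()
}
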