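# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a training fit into its per-epoch history
#' @param x A `seiz_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.seiz_fit <- function(x, ...) x$history

#' One-row summary of a training fit
#' @param x A `seiz_fit`.
#' @param ... Unused.
#' @return A one-row tibble: method, epochs, stop reason, best losses.
#' @export
glance.seiz_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    adapt_method = x$adapt_method, epochs_run = x$epochs_run,
    stop_reason = x$stop_reason, best_val_loss = x$best_val_loss,
    final_train_loss = h$train_loss[nrow(h)],
    final_train_acc = h$train_acc[nrow(h)],
    final_val_acc = h$val_acc[nrow(h)])
}

#' Tidy an evaluation report into one row per metric
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with `metric`, `value`, `undefined`.
#' @export
tidy.eval_report <- function(x, ...) {
  metrics <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
  if (!is.null(x$auc)) metrics <- c(metrics, "auc")
  tibble::tibble(metric = metrics,
                 value = unlist(x[metrics], use.names = FALSE),
                 undefined = metrics %in% x$undefined)
}

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble with counts and metrics.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
                 accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, precision = x$precision,
                 f1 = x$f1, auc = x$auc %||% NA_real_)
}

#' Tidy a LOPO result into its per-subject table
#' @param x A `lopo_result`.
#' @param ... Unused.
#' @return The per-subject tibble.
#' @export
tidy.lopo_result <- function(x, ...) x$per_subject

#' Summary (mean +/- sd across subjects) of a LOPO result
#' @param x A `lopo_result`.
#' @param ... Unused.
#' @return The summary tibble.
#' @export
glance.lopo_result <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Plot training/validation curves of a fit
#' @param object A `seiz_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seiz_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           cols = dplyr::any_of(c("train_loss", "val_loss",
                                                  "train_acc", "val_acc")),
                           names_to = "series", values_to = "value")
  h <- tidyr::separate(h, "series", into = c("split", "measure"), sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' Plot the ROC curve of an evaluation report
#' @param object An `eval_report` that carries a `roc` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  assert_that(!is.null(object$roc), "report carries no ROC table")
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc %||% NA))
}

#' Plot per-subject accuracy of a method comparison
#' @param object A `da_comparison`.
#' @param metric One of `"accuracy"`, `"f1"`, `"auc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.da_comparison <- function(object, metric = "accuracy", ...) {
  tab <- object$table[object$table$subject_id != "average", ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$subject_id,
                                    y = .data[[metric]],
                                    fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "held-out subject", y = metric, fill = NULL)
}
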