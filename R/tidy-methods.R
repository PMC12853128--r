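# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics report
#'
#' @param x A `metrics_report` from [evaluate_predictions()].
#' @param ... Unused.
#' @return One row per metric: `metric`, `value`.
#' @export
tidy.metrics_report <- function(x, ...) {
  nm <- c("SN", "SP", "BACC", "ACC", "PREC", "F1", "MCC", "AUC", "AUPR")
  tibble(metric = nm, value = unlist(x[nm], use.names = FALSE))
}

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  as_tibble(x[c("TP", "FP", "TN", "FN", "BACC", "F1", "MCC", "AUC", "AUPR",
                "threshold", "n")])
}

#' Tidy a trained network
#'
#' @param x A `glycobind_net`.
#' @param ... Unused.
#' @return One row per parameter block with its dimensions.
#' @export
tidy.glycobind_net <- function(x, ...) {
  tibble(parameter = names(x$params),
         n = vapply(x$params, length, integer(1)),
         dims = vapply(x$params, function(p) {
           paste(if (is.matrix(p)) dim(p) else length(p), collapse = "x")
         }, character(1)))
}

#' @rdname tidy.glycobind_net
#' @export
glance.glycobind_net <- function(x, ...) {
  tibble(strategy = x$strategy_tag, n_params = net_n_params(x),
         epochs = length(x$loss_trajectory),
         final_loss = if (length(x$loss_trajectory)) tail(x$loss_trajectory, 1) else NA_real_)
}

#' Tidy a feature-group selection result
#'
#' @param x A `selection_result` from [ifs_greedy()].
#' @param ... Unused.
#' @return The full greedy trace: `step`, `candidate`, `score`, `chosen`.
#' @export
tidy.selection_result <- function(x, ...) x$trace

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(chosen = paste(x$chosen_groups, collapse = "+"),
         n_groups = length(x$chosen_groups), score = x$best_score)
}

#' Plot ROC and precision-recall curves
#'
#' @param object A tibble from [prediction_curves()].
#' @param ... Unused.
#' @return A ggplot object (ROC and PR panels).
#' @export
autoplot.prediction_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~.data$curve, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Threshold-free prediction curves
#'
#' @param probabilities,labels As in [evaluate_predictions()].
#' @return Tibble (class `prediction_curves`) with `curve` (`ROC`/`PR`),
#'   `x` (FPR / recall) and `y` (TPR / precision), ready for [autoplot].
#' @export
prediction_curves <- function(probabilities, labels) {
  r <- roc_points(probabilities, as.numeric(labels))
  rec <- r$tp / r$P
  prec <- ifelse(r$tp + r$fp > 0, r$tp / (r$tp + r$fp), 1)
  out <- bind_rows(
    tibble(curve = "ROC", x = r$fpr, y = r$tpr),
    tibble(curve = "PR", x = rec, y = prec))
  class(out) <- c("prediction_curves", class(out))
  out
}

#' Training-loss trajectory plot
#'
#' @param object A `glycobind_net`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glycobind_net <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_trajectory),
               loss = object$loss_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = paste("strategy", object$strategy_tag)) +
    ggplot2::theme_minimal()
}
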