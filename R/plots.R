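# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the distribution of training uncertainties against a threshold
#'
#' Histogram of the uncertainty values in one or more profile tibbles with
#' the reliability threshold overlaid — the usual way to judge how a
#' calibrated Tukey fence sits in the training distribution.
#'
#' @param profiles A profile tibble from [model_uncertainty()] /
#'   [representation_uncertainty()], or a row-bound combination of several
#'   (faceted by `source`).
#' @param threshold Optional [calibrate_threshold()] result drawn as a
#'   vertical line.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_uncertainty_distribution <- function(profiles, threshold = NULL,
                                          bins = 40L) {
  p <- ggplot2::ggplot(profiles, ggplot2::aes(x = .data$sd)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~source, scales = "free") +
    ggplot2::labs(x = "prediction uncertainty (s.d. of member predictions)",
                  y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold$value,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot range-stratified RMSE
#'
#' Bar chart of per-bin RMSE from [stratified_rmse()].
#'
#' @param strata The tibble returned by [stratified_rmse()].
#' @return A ggplot object.
#' @export
plot_stratified_rmse <- function(strata) {
  strata$bin <- factor(strata$bin, levels = strata$bin)
  ggplot2::ggplot(strata, ggplot2::aes(x = .data$bin, y = .data$rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "observed-value range", y = "RMSE") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ilscreen
#' @method autoplot il_discrimination
#' @export
autoplot.il_discrimination <- function(object, ...) {
  ggplot2::ggplot(object$by_group,
                  ggplot2::aes(x = .data$method, y = .data$n_flagged)) +
    ggplot2::geom_col(data = object$means,
                      ggplot2::aes(y = .data$mean_flagged),
                      fill = "grey80") +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 1.8,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "uncertainty method",
      y = "candidates flagged unreliable",
      title = "Unreliable out-of-domain candidates by uncertainty method",
      subtitle = "bars: mean over groups; points: individual groups"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot methods for screening and benchmark results
#'
#' `autoplot.il_discrimination()` draws the per-method flagged-candidate
#' counts (bars: group means, points: groups). `autoplot.il_screen_report()`
#' draws the sequential-screening funnel with per-stage attrition.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-ilscreen
#' @method autoplot il_screen_report
#' @export
autoplot.il_screen_report <- function(object, ...) {
  st <- object$stages
  st$stage <- factor(seq_len(nrow(st)), labels = st$property)
  long <- tidyr::pivot_longer(
    st[, c("stage", "n_unreliable", "n_failed", "n_survivors")],
    cols = -"stage", names_to = "outcome", values_to = "n"
  )
  long$outcome <- factor(long$outcome,
                         levels = c("n_unreliable", "n_failed", "n_survivors"),
                         labels = c("unreliable", "failed cutoff", "survived"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$n,
                                     fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c("firebrick", "goldenrod", "seagreen")) +
    ggplot2::labs(x = "screening stage", y = "candidates", fill = NULL,
                  title = "Sequential screening funnel") +
    ggplot2::theme_minimal()
}

#' Plot permutation importance
#'
#' @param importance The tibble returned by [global_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  imp <- importance
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$feature,
                                    fill = factor(.data$direction))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`-1` = "firebrick", `0` = "grey60",
                                          `1` = "seagreen"),
                               labels = c(`-1` = "decreases prediction",
                                          `0` = "neutral",
                                          `1` = "increases prediction")) +
    ggplot2::labs(x = "mean RMSE increase when permuted", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
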