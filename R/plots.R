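#' @importFrom ggplot2 ggplot aes geom_line geom_abline geom_point geom_ribbon
#'   labs theme_minimal autoplot scale_color_brewer
NULL

#' Plot a reliability (calibration) curve
#'
#' Observed versus expected error for the Mondrian cross-conformal predictor
#' and the naive logistic model; perfect calibration is the dashed diagonal.
#'
#' @param object A [reliability_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reliability_curve
#' @export
autoplot.reliability_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("alpha", "error_mccp", "error_lr")],
    -"alpha", names_to = "method", values_to = "observed"
  )
  long$method <- dplyr::recode(long$method,
                               error_mccp = "MCCP", error_lr = "Logistic")
  ggplot(long, aes(x = .data$alpha, y = .data$observed,
                   color = .data$method)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    geom_line() +
    scale_color_brewer(palette = "Set1") +
    labs(x = "expected error rate", y = "observed error rate",
         color = NULL, title = "Calibration of MCCP vs naive logistic") +
    theme_minimal()
}

#' Plot coverage and predicted-subset AUC against the error rate
#'
#' @param object An [evaluation_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mccp_evaluation
#' @export
autoplot.mccp_evaluation <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df[, c("alpha", "coverage", "auc")],
                              -"alpha", names_to = "metric")
  ggplot(long, aes(x = .data$alpha, y = .data$value)) +
    geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    labs(x = "error rate", y = NULL,
         title = "Coverage and predicted-subset AUC") +
    theme_minimal()
}

#' Head-to-head plot: MCCP vs the empirical extreme-percentile method
#'
#' AUC at matched coverage: for the conformal method coverage varies with the
#' error rate, for the empirical method it is twice the extreme percentile.
#'
#' @param evaluation An [evaluation_report()] (supplies the MCCP curve).
#' @param empirical Tibble with columns `coverage` and `auc` for the
#'   empirical method (one row per x%).
#' @return A ggplot.
#' @export
plot_head_to_head <- function(evaluation, empirical) {
  mccp <- tibble(coverage = evaluation$coverage, auc = evaluation$auc,
                 method = "MCCP")
  emp <- tibble(coverage = empirical$coverage, auc = empirical$auc,
                method = "Empirical")
  ggplot(dplyr::bind_rows(mccp, emp),
         aes(x = .data$coverage, y = .data$auc, color = .data$method)) +
    geom_line() + geom_point(size = 0.8) +
    scale_color_brewer(palette = "Dark2") +
    labs(x = "coverage", y = "AUC (predicted subset)", color = NULL) +
    theme_minimal()
}
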