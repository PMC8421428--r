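#' Observed error of a naive probability classifier
#'
#' At expected error rate `alpha`, an individual counts as an error when its
#' predicted case probability exceeds `1 - alpha` although it is a true
#' control, or falls below `alpha` although it is a true case (both
#' inequalities strict). The observed error is the fraction of such
#' individuals.
#'
#' @param probabilities Predicted case probabilities in \[0, 1\].
#' @param labels True labels (1 case / 0 control).
#' @param alpha Expected error rate.
#' @param class Restrict to `"case"`, `"control"`, or use `"all"` (default).
#' @return A fraction in \[0, 1\].
#' @export
observed_error_lr <- function(probabilities, labels, alpha,
                              class = c("all", "case", "control")) {
  class <- match.arg(class)
  if (any(probabilities < 0 | probabilities > 1))
    abort("probabilities must be in [0, 1]")
  err <- (labels == 0 & probabilities > (1 - alpha)) |
    (labels == 1 & probabilities < alpha)
  keep <- switch(class, all = TRUE, case = labels == 1, control = labels == 0)
  mean(err[keep])
}

#' Observed error of Mondrian conformal predictions
#'
#' The fraction of individuals whose true-class p-value is at or below
#' `alpha` — equivalently, whose true label falls outside the prediction
#' region at that error rate. Per-class validity means this stays at or below
#' `alpha` (up to Monte-Carlo noise) for each class separately.
#'
#' @param pvals Data frame with columns `p0`, `p1`.
#' @param labels True labels (1 case / 0 control).
#' @param alpha Expected error rate.
#' @param class Restrict to `"case"`, `"control"`, or use `"all"` (default).
#' @return A fraction in \[0, 1\].
#' @export
observed_error_mccp <- function(pvals, labels, alpha,
                                class = c("all", "case", "control")) {
  class <- match.arg(class)
  p_true <- ifelse(labels == 1, pvals$p1, pvals$p0)
  keep <- switch(class, all = TRUE, case = labels == 1, control = labels == 0)
  mean((p_true <= alpha)[keep])
}

#' Coverage (efficiency) of prediction regions
#'
#' The fraction of individuals receiving a singleton prediction (case or
#' control) at the region's error rate; uncertain and empty regions do not
#' count.
#'
#' @param regions Output of [prediction_region()].
#' @return A fraction in \[0, 1\].
#' @export
coverage_rate <- function(regions) {
  mean(regions$outcome %in% c("case", "control"))
}

#' AUC, PPV and NPV restricted to the predicted subset
#'
#' Within the individuals receiving a singleton prediction: AUC of the
#' (covariate-adjusted, when several feature columns are supplied) logistic
#' score against true labels, with a DeLong 95% CI (via pROC); PPV = fraction
#' of true cases among predicted cases and NPV = fraction of true controls
#' among predicted controls, each with an exact binomial 95% CI. Degenerate
#' subsets (fewer than 2 cases and 2 controls for AUC; no predicted cases for
#' PPV; no predicted controls for NPV) yield `NA` with a reason code rather
#' than a silent 0.
#'
#' @param data Data frame with an `outcome` column (from
#'   [prediction_region()]), the true label column and the feature column(s).
#' @param label_col Binary status column.
#' @param feature_cols Score column(s); with more than one, a logistic
#'   regression on the predicted subset supplies the composite score.
#' @return One-row tibble: `auc`, `auc_low`, `auc_high`, `ppv`, `ppv_low`,
#'   `ppv_high`, `npv`, `npv_low`, `npv_high`, `n_predicted_cases`,
#'   `n_predicted_controls`, `coverage`, `reason` (NA when all metrics are
#'   defined).
#' @export
stratified_metrics <- function(data, label_col = "status",
                               feature_cols = "score") {
  predicted <- data$outcome %in% c("case", "control")
  sub <- data[predicted, , drop = FALSE]
  y <- sub[[label_col]]
  n_pc <- sum(sub$outcome == "case")
  n_pn <- sum(sub$outcome == "control")
  reasons <- character(0)

  # AUC on the predicted subset
  if (sum(y == 1) >= 2 && sum(y == 0) >= 2) {
    score <- if (length(feature_cols) > 1) {
      sc <- fit_scorer(sub, label_col, feature_cols)
      decision_value(sc, sub)
    } else {
      sub[[feature_cols]]
    }
    roc <- pROC::roc(y, score, quiet = TRUE, direction = "<", levels = c(0, 1))
    ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
    auc3 <- c(ci[2], ci[1], ci[3])
  } else {
    auc3 <- rep(NA_real_, 3)
    reasons <- c(reasons, "auc: fewer than 2 cases or 2 controls predicted")
  }

  ppv3 <- if (n_pc > 0) {
    k <- sum(sub$outcome == "case" & y == 1)
    bt <- binom.test(k, n_pc)
    c(k / n_pc, bt$conf.int[1], bt$conf.int[2])
  } else {
    reasons <- c(reasons, "ppv: no predicted cases")
    rep(NA_real_, 3)
  }
  npv3 <- if (n_pn > 0) {
    k <- sum(sub$outcome == "control" & y == 0)
    bt <- binom.test(k, n_pn)
    c(k / n_pn, bt$conf.int[1], bt$conf.int[2])
  } else {
    reasons <- c(reasons, "npv: no predicted controls")
    rep(NA_real_, 3)
  }

  tibble(
    auc = auc3[1], auc_low = auc3[2], auc_high = auc3[3],
    ppv = ppv3[1], ppv_low = ppv3[2], ppv_high = ppv3[3],
    npv = npv3[1], npv_low = npv3[2], npv_high = npv3[3],
    n_predicted_cases = n_pc, n_predicted_controls = n_pn,
    coverage = mean(predicted),
    reason = if (length(reasons)) paste(reasons, collapse = "; ") else NA_character_
  )
}

#' Empirical top-x% / bottom-x% comparator
#'
#' The standard PRS decision rule the conformal method is compared against:
#' label the top x% of PRS predicted cases and the bottom x% predicted
#' controls, everyone else unpredicted, so coverage is 2x% by construction
#' (up to integer rounding). Quantile ties are resolved by a stable sort on
#' (score, then row order). The same predicted-subset metrics as
#' [stratified_metrics()] are returned for head-to-head comparison at
#' matched coverage.
#'
#' @param data Data frame with the score and label columns.
#' @param x_percent Extreme percentage in (0, 50\].
#' @param label_col Binary status column.
#' @param feature_cols Score column(s); the first is the ranking PRS.
#' @return A list: `assignments` (the input plus an `outcome` column) and
#'   `metrics` (one-row tibble from [stratified_metrics()]).
#' @export
empirical_method <- function(data, x_percent, label_col = "status",
                             feature_cols = "score") {
  if (x_percent <= 0 || x_percent > 50)
    abort("x_percent must be in (0, 50]")
  n <- nrow(data)
  k <- round(x_percent / 100 * n)
  score <- data[[feature_cols[1]]]
  ord <- order(score, seq_len(n)) # stable: ascending score, then row order
  outcome <- rep("uncertain", n)
  if (k > 0) {
    outcome[ord[seq_len(k)]] <- "control"
    outcome[ord[seq(n - k + 1, n)]] <- "case"
  }
  out <- as_tibble(data)
  out$outcome <- factor(outcome, levels = c("case", "control", "uncertain", "empty"))
  list(
    assignments = out,
    metrics = stratified_metrics(out, label_col, feature_cols)
  )
}

#' Reliability (calibration) curves for MCCP and naive logistic regression
#'
#' Outer stratified k-fold cross-validation: on each outer training split a
#' Mondrian cross-conformal predictor and a plain logistic regression (fitted
#' on the combined proper-training + calibration data) are built, and both
#' predict the held-out fold; every individual is predicted exactly once.
#' Observed errors are then computed over `alpha_grid` — for the conformal
#' predictor the fraction of true-class p-values at or below alpha, for the
#' logistic model the strict-threshold rule of [observed_error_lr()].
#'
#' @param data Data frame with label and feature columns.
#' @param label_col Binary status column.
#' @param feature_cols Predictor columns.
#' @param n_outer_folds Outer cross-validation folds (default 5).
#' @param n_folds Inner cross-conformal folds (default 5).
#' @param alpha_grid Expected error rates (default 0.01 to 0.5 by 0.01).
#' @param seed Integer seed for both fold layers.
#' @param bare_count Passed to the conformal layer.
#' @return A tibble of class `reliability_curve`: `alpha`, `error_mccp`,
#'   `error_mccp_case`, `error_mccp_control`, `error_lr`. The pooled
#'   per-individual predictions (`p0`, `p1`, `lr_prob`, label, features) are
#'   attached as attribute `"predictions"`.
#' @export
reliability_curve <- function(data, label_col = "status",
                              feature_cols = "score",
                              n_outer_folds = 5, n_folds = 5,
                              alpha_grid = seq(0.01, 0.5, by = 0.01),
                              seed = 1, bare_count = FALSE) {
  y <- data[[label_col]]
  set.seed(seed + 2000L)
  fold <- integer(nrow(data))
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    if (length(idx) < n_outer_folds)
      abort(sprintf("class %s too small for %d outer folds", cls, n_outer_folds))
    fold[idx] <- sample(rep_len(seq_len(n_outer_folds), length(idx)))
  }

  preds <- purrr::map(seq_len(n_outer_folds), function(k) {
    train <- data[fold != k, , drop = FALSE]
    test <- data[fold == k, , drop = FALSE]
    fit <- cross_conformal(train, label_col, feature_cols,
                           n_folds = n_folds, seed = seed + k,
                           bare_count = bare_count)
    pv <- predict(fit, test)
    lr <- fit_scorer(train, label_col, feature_cols)
    pv$lr_prob <- plogis(decision_value(lr, test))
    dplyr::bind_cols(as_tibble(test), pv)
  })
  preds <- dplyr::bind_rows(preds)

  curve <- purrr::map_dfr(alpha_grid, function(a) {
    tibble(
      alpha = a,
      error_mccp = observed_error_mccp(preds, preds[[label_col]], a),
      error_mccp_case = observed_error_mccp(preds, preds[[label_col]], a, "case"),
      error_mccp_control = observed_error_mccp(preds, preds[[label_col]], a, "control"),
      error_lr = observed_error_lr(preds$lr_prob, preds[[label_col]], a)
    )
  })
  attr(curve, "predictions") <- preds
  class(curve) <- c("reliability_curve", class(curve))
  curve
}

#' Per-alpha evaluation report
#'
#' For each error rate in `alpha_grid`, applies [prediction_region()] to
#' pooled conformal predictions and tabulates observed errors, coverage, the
#' uncertain and empty fractions, and the predicted-subset AUC/PPV/NPV with
#' 95% CIs.
#'
#' @param predictions Per-individual tibble with `p0`, `p1`, the label column
#'   and feature column(s) (e.g. attribute `"predictions"` of
#'   [reliability_curve()]).
#' @param label_col Binary status column.
#' @param feature_cols Score column(s) for the stratified AUC.
#' @param alpha_grid Error rates to evaluate.
#' @return A tibble with one row per alpha, of class `mccp_evaluation`.
#' @export
evaluation_report <- function(predictions, label_col = "status",
                              feature_cols = "score",
                              alpha_grid = seq(0.01, 0.5, by = 0.01)) {
  out <- purrr::map_dfr(alpha_grid, function(a) {
    reg <- prediction_region(predictions, a)
    m <- stratified_metrics(reg, label_col, feature_cols)
    dplyr::bind_cols(
      tibble(
        alpha = a,
        observed_error = observed_error_mccp(predictions, predictions[[label_col]], a),
        observed_error_case = observed_error_mccp(predictions, predictions[[label_col]], a, "case"),
        observed_error_control = observed_error_mccp(predictions, predictions[[label_col]], a, "control"),
        frac_uncertain = mean(reg$outcome == "uncertain"),
        frac_empty = mean(reg$outcome == "empty")
      ),
      m
    )
  })
  class(out) <- c("mccp_evaluation", class(out))
  out
}
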