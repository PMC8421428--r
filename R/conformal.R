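#' Build a per-class calibration table
#'
#' Sorts the nonconformity scores of the calibration individuals within each
#' true class. Mondrian p-values are computed against these class-conditional
#' score distributions.
#'
#' @param d_cal Decision values of the calibration individuals.
#' @param y_cal Their true labels (1 case / 0 control).
#' @return An object of class `calibration_table`: sorted NCM vectors `case`
#'   and `control` and the class sizes.
#' @export
calibration_table <- function(d_cal, y_cal) {
  n_case <- sum(y_cal == 1); n_control <- sum(y_cal == 0)
  if (n_case < 1 || n_control < 1)
    abort(sprintf(
      "calibration set needs both classes (got %d cases, %d controls)",
      n_case, n_control))
  structure(
    list(
      case = sort(nonconformity(d_cal[y_cal == 1], "case")),
      control = sort(nonconformity(d_cal[y_cal == 0], "control")),
      n_case = n_case, n_control = n_control
    ),
    class = "calibration_table"
  )
}

# count of sorted values >= v, vectorized over v; ties counted inclusively
.count_ge <- function(sorted, v) {
  length(sorted) - findInterval(v, sorted, left.open = TRUE)
}

#' Mondrian (class-conditional) conformal p-values
#'
#' For each test individual and each hypothesized class y, the p-value is
#' `(#\{j in calibration class y : NCM_j >= NCM_i\} + c) / (N_cal_y + 1)`,
#' with ties counted inclusively. `c = 1` (the default) is the standard
#' Mondrian inductive-conformal convention that counts the test point itself
#' and guarantees p-values in (0, 1\] with conservative per-class validity;
#' `bare_count = TRUE` sets `c = 0`, the bare count against the
#' calibration set alone.
#'
#' @param table A [calibration_table()].
#' @param d_test Decision values of the test individuals.
#' @param bare_count Use the bare-count convention (`c = 0`)?
#' @return A tibble with columns `p0` (control) and `p1` (case).
#' @examples
#' tab <- calibration_table(d_cal = c(-2, -1, 0, 1, 2), y_cal = c(0, 0, 0, 1, 1))
#' mondrian_pvalues(tab, d_test = c(-1.5, 1.5))
#' @export
mondrian_pvalues <- function(table, d_test, bare_count = FALSE) {
  cc <- if (bare_count) 0 else 1
  p1 <- (.count_ge(table$case, nonconformity(d_test, "case")) + cc) /
    (table$n_case + 1)
  p0 <- (.count_ge(table$control, nonconformity(d_test, "control")) + cc) /
    (table$n_control + 1)
  tibble(p0 = p0, p1 = p1)
}

#' Pooled (non-Mondrian) inductive-conformal p-values
#'
#' Same counting as [mondrian_pvalues()] but against the whole calibration
#' set at once: for hypothesized class y, every calibration individual j
#' contributes the score `-y * d_j` regardless of its own label, and the
#' denominator is `N_cal + 1`. Provided as the comparator whose per-class
#' validity breaks down under case-control imbalance, which the Mondrian
#' (class-conditional) variant repairs.
#'
#' @inheritParams mondrian_pvalues
#' @param d_cal Decision values of all calibration individuals.
#' @return A tibble with columns `p0` and `p1`.
#' @export
icp_pvalues <- function(d_cal, d_test, bare_count = FALSE) {
  cc <- if (bare_count) 0 else 1
  n <- length(d_cal)
  sc_case <- sort(nonconformity(d_cal, "case"))
  sc_control <- sort(nonconformity(d_cal, "control"))
  p1 <- (.count_ge(sc_case, nonconformity(d_test, "case")) + cc) / (n + 1)
  p0 <- (.count_ge(sc_control, nonconformity(d_test, "control")) + cc) / (n + 1)
  tibble(p0 = p0, p1 = p1)
}

#' Fit a Mondrian cross-conformal predictor
#'
#' Splits the training data into `n_folds` stratified folds. For each fold, a
#' logistic scorer is fitted on the other `n_folds - 1` folds and the held-out
#' fold becomes the calibration set, giving one [calibration_table()] per
#' fold. Predictions on new individuals compute one (p0, p1) pair per fold
#' and return their arithmetic means. Stratification by class guarantees
#' every calibration fold contains both classes even at prevalence 0.01;
#' fold assignment is deterministic given `seed`.
#'
#' @param data Training data frame with label and feature columns.
#' @param label_col Binary status column (1 case / 0 control).
#' @param feature_cols Predictor columns (PRS first, then covariates).
#' @param n_folds Number of cross-conformal folds (default 5, minimum 2).
#' @param seed Integer seed for the fold assignment.
#' @param bare_count Passed to [mondrian_pvalues()].
#' @return An object of class `mccp` with one scorer + calibration table per
#'   fold.
#' @examples
#' d <- tibble::tibble(status = rbinom(300, 1, 0.3), score = rnorm(300))
#' d$score <- d$score + d$status
#' fit <- cross_conformal(d, n_folds = 5, seed = 1)
#' predict(fit, d[1:5, ])
#' @export
cross_conformal <- function(data, label_col = "status", feature_cols = "score",
                            n_folds = 5, seed = 1, bare_count = FALSE) {
  if (n_folds < 2) abort("n_folds must be at least 2")
  y <- data[[label_col]]
  n_case <- sum(y == 1); n_control <- sum(y == 0)
  if (min(n_case, n_control) < n_folds)
    abort(sprintf(
      "smallest class has %d members, too few for %d folds; use fewer folds",
      min(n_case, n_control), n_folds))

  set.seed(seed)
  fold <- integer(nrow(data))
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }

  folds <- purrr::map(seq_len(n_folds), function(k) {
    train <- data[fold != k, , drop = FALSE]
    cal <- data[fold == k, , drop = FALSE]
    scorer <- fit_scorer(train, label_col, feature_cols)
    list(
      scorer = scorer,
      table = calibration_table(decision_value(scorer, cal), cal[[label_col]])
    )
  })

  structure(
    list(
      folds = folds,
      fold_assignment = fold,
      label_col = label_col,
      feature_cols = feature_cols,
      n_folds = n_folds,
      bare_count = bare_count,
      seed = seed
    ),
    class = "mccp"
  )
}

#' Predict Mondrian cross-conformal p-values
#'
#' @param object An `mccp` fit from [cross_conformal()].
#' @param newdata Data frame with the scorer's feature columns.
#' @param ... Unused.
#' @return A tibble with `p0`, `p1` (fold-averaged Mondrian p-values) and
#'   `decision` (fold-averaged decision value, for reference).
#' @export
predict.mccp <- function(object, newdata, ...) {
  per_fold <- purrr::map(object$folds, function(f) {
    d <- decision_value(f$scorer, newdata)
    pv <- mondrian_pvalues(f$table, d, object$bare_count)
    pv$decision <- d
    pv
  })
  tibble(
    p0 = rowMeans(vapply(per_fold, function(p) p$p0, numeric(nrow(newdata)))),
    p1 = rowMeans(vapply(per_fold, function(p) p$p1, numeric(nrow(newdata)))),
    decision = rowMeans(vapply(per_fold, function(p) p$decision,
                               numeric(nrow(newdata))))
  )
}

#' @export
print.mccp <- function(x, ...) {
  tab <- x$folds[[1]]$table
  cat(sprintf("<mccp> %d-fold Mondrian cross-conformal predictor\n", x$n_folds))
  cat(sprintf("  features: %s\n", paste(x$feature_cols, collapse = ", ")))
  cat(sprintf("  fold-1 calibration: %d cases, %d controls\n",
              tab$n_case, tab$n_control))
  cat(sprintf("  counting convention: %s\n",
              if (x$bare_count) "bare count (c = 0)" else "test point included (c = 1)"))
  invisible(x)
}

#' Prediction regions, confidence and credibility
#'
#' Applies the four-outcome decision rule at error rate `alpha` to a table of
#' per-individual (p0, p1): the region is `{y : p_y > alpha}`, so an
#' individual is predicted **case** (p1 > alpha, p0 <= alpha), **control**
#' (p0 > alpha, p1 <= alpha), **uncertain** (both above) or **empty** /
#' unpredictable (both at or below). Confidence is `1 - min(p0, p1)` (the
#' greatest 1 - alpha at which the region is a single class) and credibility
#' is `max(p0, p1)` (the smallest alpha at which the region is empty). The
#' point prediction is the class with the larger p-value; ties go to control
#' (configurable), a deliberately conservative rule.
#'
#' @param pvals Data frame with columns `p0` and `p1` (e.g. from
#'   [predict.mccp()]); other columns are carried through.
#' @param alpha Error rate in \[0, 1\].
#' @param tie Point-prediction tie rule when p0 == p1: `"control"` (default)
#'   or `"case"`.
#' @return The input tibble plus `alpha`, `outcome` (factor case / control /
#'   uncertain / empty), `confidence`, `credibility`, `point_prediction`.
#' @examples
#' prediction_region(tibble::tibble(p0 = 0.01, p1 = 0.8), alpha = 0.05)
#' @export
prediction_region <- function(pvals, alpha, tie = c("control", "case")) {
  tie <- match.arg(tie)
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  p0 <- pvals$p0; p1 <- pvals$p1
  in1 <- p1 > alpha; in0 <- p0 > alpha
  outcome <- dplyr::case_when(
    in1 & !in0 ~ "case",
    in0 & !in1 ~ "control",
    in0 & in1 ~ "uncertain",
    TRUE ~ "empty"
  )
  point <- ifelse(p1 > p0, "case",
                  ifelse(p0 > p1, "control", tie))
  out <- as_tibble(pvals)
  out$alpha <- alpha
  out$outcome <- factor(outcome, levels = c("case", "control", "uncertain", "empty"))
  out$confidence <- 1 - pmin(p0, p1)
  out$credibility <- pmax(p0, p1)
  out$point_prediction <- point
  out
}
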