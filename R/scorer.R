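#' Fit the underlying logistic scorer
#'
#' Maximum-likelihood logistic regression of case-control status on PRS (and
#' optional covariates). The decision value d(x) used by the conformal layer
#' is the fitted linear predictor (log-odds); it is monotone in the predicted
#' case probability, so p-values, regions and ranks are identical to those a
#' probability-scale scorer would give, while being numerically robust in the
#' tails. Under perfect separation the fit falls back to a ridge-stabilized
#' logistic regression (L2 penalty on the slopes, never the intercept) with a
#' warning.
#'
#' @param data Data frame containing the label and feature columns.
#' @param label_col Name of the binary status column (1 case / 0 control).
#' @param feature_cols Character vector of predictor columns (PRS first, then
#'   any covariates).
#' @return An object of class `prs_scorer` with elements `coefficients`
#'   (named vector, intercept first) and `feature_cols`.
#' @examples
#' d <- tibble::tibble(status = rbinom(100, 1, 0.5), prs = rnorm(100))
#' sc <- fit_scorer(d, "status", "prs")
#' head(decision_value(sc, d))
#' @export
fit_scorer <- function(data, label_col = "status", feature_cols = "score") {
  y <- data[[label_col]]
  if (length(unique(y)) < 2)
    abort("training data contain a single class; cannot fit a scorer")
  x <- as.matrix(data[, feature_cols, drop = FALSE])
  if (!all(is.finite(x))) abort("features must be finite")

  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(`(Intercept)` = 1, x), y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    warn("separation detected; using a ridge-stabilized logistic fit")
    cf <- ridge_logistic(x, y, lambda = 1)
  } else {
    cf <- fit$coefficients
  }
  names(cf) <- c("(Intercept)", feature_cols)
  structure(list(coefficients = cf, feature_cols = feature_cols),
            class = "prs_scorer")
}

# penalized IRLS: logistic regression with an L2 penalty on the slopes
# (never the intercept); keeps coefficients finite under separation
ridge_logistic <- function(x, y, lambda = 1, max_iter = 100L) {
  xd <- cbind(1, x)
  p <- ncol(xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  b <- c(qlogis(mean(y)), rep(0, p - 1))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(xd %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    grad <- crossprod(xd, y - mu) - pen %*% b
    hess <- crossprod(xd * w, xd) + pen
    step <- solve(hess, grad)
    b <- b + as.vector(step)
    if (max(abs(step)) < 1e-10) break
  }
  as.vector(b)
}

#' Decision value of a fitted scorer
#'
#' The linear predictor (log-odds of case status) for each row of `data`.
#'
#' @param scorer A `prs_scorer` from [fit_scorer()].
#' @param data Data frame containing the scorer's feature columns.
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(scorer, data) {
  x <- as.matrix(data[, scorer$feature_cols, drop = FALSE])
  as.vector(cbind(1, x) %*% scorer$coefficients)
}

#' Nonconformity measure
#'
#' `NCM_y = -y * d(x)` with class encoding case = +1, control = -1: large
#' values mean the individual looks unusual for the hypothesized class.
#'
#' @param d Decision values (from [decision_value()]).
#' @param class `"case"` or `"control"` (or +1 / -1).
#' @return Numeric vector of nonconformity scores.
#' @export
nonconformity <- function(d, class) {
  y <- if (is.character(class)) {
    switch(class, case = 1, control = -1,
           abort("class must be 'case' or 'control'"))
  } else {
    as.numeric(class)
  }
  -y * d
}

#' @export
print.prs_scorer <- function(x, ...) {
  cat("<prs_scorer> logistic scorer\n")
  print(x$coefficients)
  invisible(x)
}
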