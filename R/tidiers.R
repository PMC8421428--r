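#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Mondrian cross-conformal fit
#'
#' One row per fold and coefficient of the underlying logistic scorers.
#'
#' @param x An `mccp` object from [cross_conformal()].
#' @param ... Unused.
#' @return A tibble: `fold`, `term`, `estimate`.
#' @method tidy mccp
#' @export
tidy.mccp <- function(x, ...) {
  purrr::imap_dfr(x$folds, function(f, k) {
    tibble(fold = k, term = names(f$scorer$coefficients),
           estimate = unname(f$scorer$coefficients))
  })
}

#' One-row summary of a Mondrian cross-conformal fit
#'
#' @param x An `mccp` object.
#' @param ... Unused.
#' @return A tibble: `n_folds`, calibration class sizes (summed over folds),
#'   the counting convention and seed.
#' @method glance mccp
#' @export
glance.mccp <- function(x, ...) {
  tibble(
    n_folds = x$n_folds,
    n_cal_cases = sum(vapply(x$folds, function(f) f$table$n_case, 1L)),
    n_cal_controls = sum(vapply(x$folds, function(f) f$table$n_control, 1L)),
    bare_count = x$bare_count,
    seed = x$seed
  )
}

#' Tidy a fitted logistic scorer
#' @param x A `prs_scorer`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`.
#' @method tidy prs_scorer
#' @export
tidy.prs_scorer <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}
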