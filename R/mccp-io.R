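#' Save or load a calibrated cross-conformal predictor
#'
#' Serializes an `mccp` fit as a versioned JSON archive: per-fold scorer
#' coefficients and sorted per-class calibration nonconformity scores, plus
#' the feature names, counting convention and seed. The archive is plain text
#' and round-trips exactly.
#'
#' @param fit An `mccp` object from [cross_conformal()].
#' @param path Output (or input) JSON path.
#' @return `write_mccp()`: `path`, invisibly. `read_mccp()`: the `mccp`
#'   object.
#' @export
write_mccp <- function(fit, path) {
  payload <- list(
    format = "mondrianprs/mccp",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("mondrianprs")),
    label_col = fit$label_col,
    feature_cols = fit$feature_cols,
    n_folds = fit$n_folds,
    bare_count = fit$bare_count,
    seed = fit$seed,
    folds = purrr::map(fit$folds, function(f) {
      list(
        coefficients = as.list(f$scorer$coefficients),
        cal_case = f$table$case,
        cal_control = f$table$control
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mccp
#' @export
read_mccp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "mondrianprs/mccp"))
    abort("not a mondrianprs calibrated-predictor archive")
  folds <- purrr::map(seq_len(p$n_folds), function(k) {
    f <- if (is.data.frame(p$folds)) {
      list(coefficients = as.list(p$folds$coefficients[k, ]),
           cal_case = p$folds$cal_case[[k]],
           cal_control = p$folds$cal_control[[k]])
    } else {
      p$folds[[k]]
    }
    cf <- unlist(f$coefficients)
    scorer <- structure(
      list(coefficients = cf, feature_cols = p$feature_cols),
      class = "prs_scorer"
    )
    table <- structure(
      list(case = as.numeric(f$cal_case), control = as.numeric(f$cal_control),
           n_case = length(f$cal_case), n_control = length(f$cal_control)),
      class = "calibration_table"
    )
    list(scorer = scorer, table = table)
  })
  structure(
    list(folds = folds, fold_assignment = NULL, label_col = p$label_col,
         feature_cols = p$feature_cols, n_folds = p$n_folds,
         bare_count = p$bare_count, seed = p$seed),
    class = "mccp"
  )
}
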