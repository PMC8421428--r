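# calibration table whose class-y NCM lists are exactly the given vectors
table_from_ncms <- function(case_ncms, control_ncms) {
  calibration_table(d_cal = c(-case_ncms, control_ncms),
                    y_cal = c(rep(1, length(case_ncms)),
                              rep(0, length(control_ncms))))
}

test_that("Mondrian p-values reproduce hand counts under both conventions", {
  tab <- table_from_ncms(case_ncms = c(1, 2, 3), control_ncms = c(5, 6, 7))
  # test NCM_case = 2.5: one calibration case at or above
  pv <- mondrian_pvalues(tab, d_test = -2.5)
  expect_equal(pv$p1, (1 + 1) / 4)
  pv0 <- mondrian_pvalues(tab, d_test = -2.5, bare_count = TRUE)
  expect_equal(pv0$p1, 1 / 4)
  # below every calibration score: maximal conformity
  pv_min <- mondrian_pvalues(tab, d_test = -0.5)
  expect_equal(pv_min$p1, 1)
})

test_that("p-values match the O(N^2) brute-force counter, ties included", {
  set.seed(71)
  n_cal <- 200
  d_cal <- round(rnorm(n_cal), 1) # coarse grid forces ties
  y_cal <- rbinom(n_cal, 1, 0.3)
  d_test <- round(rnorm(50), 1)
  tab <- calibration_table(d_cal, y_cal)
  for (pl in c(FALSE, TRUE)) {
    cc <- if (pl) 0 else 1
    pv <- mondrian_pvalues(tab, d_test, bare_count = pl)
    for (i in seq_along(d_test)) {
      expect_equal(pv$p1[i],
                   bf_conformal_p(-d_cal[y_cal == 1], -d_test[i], cc))
      expect_equal(pv$p0[i],
                   bf_conformal_p(d_cal[y_cal == 0], d_test[i], cc))
    }
    ip <- icp_pvalues(d_cal, d_test, bare_count = pl)
    for (i in seq_along(d_test)) {
      expect_equal(ip$p1[i], bf_conformal_p(-d_cal, -d_test[i], cc))
      expect_equal(ip$p0[i], bf_conformal_p(d_cal, d_test[i], cc))
    }
  }
})

test_that("pooled counts partition into per-class counts", {
  set.seed(72)
  d_cal <- rnorm(40); y_cal <- rbinom(40, 1, 0.5)
  d_test <- rnorm(10)
  for (i in seq_along(d_test)) {
    pooled <- sum(-d_cal >= -d_test[i])
    by_class <- sum(-d_cal[y_cal == 1] >= -d_test[i]) +
      sum(-d_cal[y_cal == 0] >= -d_test[i])
    expect_identical(pooled, by_class)
  }
})

test_that("calibration order does not affect p-values", {
  set.seed(73)
  d_cal <- rnorm(100); y_cal <- rbinom(100, 1, 0.4)
  d_test <- rnorm(20)
  perm <- sample(100)
  p1 <- mondrian_pvalues(calibration_table(d_cal, y_cal), d_test)
  p2 <- mondrian_pvalues(calibration_table(d_cal[perm], y_cal[perm]), d_test)
  expect_equal(p1, p2)
})

test_that("pooled p-values inflate the minority class under imbalance", {
  set.seed(74)
  n0 <- 990; n1 <- 10
  d_cal <- c(rnorm(n0, 0), rnorm(n1, 2))
  y_cal <- c(rep(0, n0), rep(1, n1))
  d_test <- rnorm(200, 2) # test individuals drawn like the minority class
  tab <- calibration_table(d_cal, y_cal)
  mond <- mondrian_pvalues(tab, d_test)
  icp <- icp_pvalues(d_cal, d_test)
  expect_gt(mean(icp$p1), mean(mond$p1))
})

test_that("empty calibration classes are rejected", {
  expect_error(calibration_table(rnorm(10), rep(1, 10)), "both classes")
})

test_that("cross-conformal averaging behaves like a mean over folds", {
  set.seed(75)
  d <- tibble::tibble(score = rnorm(200))
  d$status <- rbinom(200, 1, plogis(d$score))
  fit <- cross_conformal(d, n_folds = 4, seed = 7)
  newdata <- tibble::tibble(score = rnorm(30))
  pv <- predict(fit, newdata)
  per_fold <- lapply(fit$folds, function(f) {
    mondrian_pvalues(f$table, decision_value(f$scorer, newdata))
  })
  p1_mat <- sapply(per_fold, `[[`, "p1")
  expect_equal(pv$p1, rowMeans(p1_mat))
  expect_true(all(pv$p1 >= apply(p1_mat, 1, min) - 1e-12))
  expect_true(all(pv$p1 <= apply(p1_mat, 1, max) + 1e-12))
  # identical folds average to the single-fold value
  fit2 <- fit
  fit2$folds <- list(fit$folds[[1]], fit$folds[[1]])
  pv2 <- predict(fit2, newdata)
  expect_equal(pv2$p1, per_fold[[1]]$p1)
  expect_equal(pv2$p0, per_fold[[1]]$p0)
})

test_that("cross-conformal folding is stratified, seeded and size-checked", {
  set.seed(76)
  d <- tibble::tibble(score = rnorm(100),
                      status = rep(c(0L, 1L), times = c(90, 10)))
  fit <- cross_conformal(d, n_folds = 5, seed = 3)
  expect_identical(fit$fold_assignment,
                   cross_conformal(d, n_folds = 5, seed = 3)$fold_assignment)
  for (f in fit$folds) {
    expect_gte(f$table$n_case, 1)
    expect_gte(f$table$n_control, 1)
  }
  expect_error(cross_conformal(d, n_folds = 20, seed = 1), "fewer folds")
})

test_that("cross-conformal predictions are valid per class", {
  set.seed(77)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x - 2))
  train <- tibble::tibble(score = x[1:1000], status = y[1:1000])
  test <- tibble::tibble(score = x[1001:2000], status = y[1001:2000])
  fit <- cross_conformal(train, n_folds = 5, seed = 5)
  pv <- predict(fit, test)
  for (cls in c("case", "control")) {
    n_cls <- sum(test$status == (cls == "case"))
    err <- observed_error_mccp(pv, test$status, 0.1, cls)
    expect_lte(err, 0.1 + 3 * sqrt(0.1 * 0.9 / n_cls))
  }
})

test_that("the worked prediction-region example and the four-outcome rule hold", {
  reg <- prediction_region(tibble::tibble(p0 = 0.01, p1 = 0.8), alpha = 0.05)
  expect_identical(as.character(reg$outcome), "case")
  expect_equal(reg$credibility, 0.8)
  expect_equal(reg$confidence, 0.99)
  expect_identical(reg$point_prediction, "case")

  tie <- prediction_region(tibble::tibble(p0 = 0.5, p1 = 0.5), alpha = 0.05)
  expect_identical(as.character(tie$outcome), "uncertain")
  expect_identical(tie$point_prediction, "control") # documented tie rule
  expect_identical(
    prediction_region(tibble::tibble(p0 = 0.5, p1 = 0.5), 0.05,
                      tie = "case")$point_prediction, "case")

  unpred <- prediction_region(tibble::tibble(p0 = 0.01, p1 = 0.03), alpha = 0.05)
  expect_identical(as.character(unpred$outcome), "empty")
})

test_that("regions are nested in alpha and the identities hold exactly", {
  set.seed(78)
  pv <- tibble::tibble(p0 = runif(100), p1 = runif(100))
  grid <- seq(0, 1, by = 0.05)
  region_set <- function(reg) {
    cbind(case = reg$p1 > reg$alpha, control = reg$p0 > reg$alpha)
  }
  prev <- NULL
  for (a in grid) {
    reg <- prediction_region(pv, a)
    expect_equal(reg$confidence, 1 - pmin(pv$p0, pv$p1))
    expect_equal(reg$credibility, pmax(pv$p0, pv$p1))
    cur <- region_set(reg)
    if (!is.null(prev)) expect_true(all(cur <= prev)) # shrinks as alpha grows
    prev <- cur
  }
})
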