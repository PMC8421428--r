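test_that("naive-classifier observed error follows the strict-threshold rule", {
  y <- c(rep(0, 50), rep(1, 50))
  perfect <- c(rep(0, 50), rep(1, 50))
  expect_equal(observed_error_lr(perfect, y, 0.3), 0)
  # probabilities all 0.5: no individual crosses either strict cut
  expect_equal(observed_error_lr(rep(0.5, 100), y, 0.3), 0)
  set.seed(81)
  prob <- runif(100)
  for (a in c(0, 0.1, 0.37, 0.5, 1)) {
    expect_equal(observed_error_lr(prob, y, a), bf_observed_error_lr(prob, y, a))
  }
})

test_that("conformal observed error equals the outside-region fraction", {
  set.seed(82)
  pv <- tibble::tibble(p0 = runif(200), p1 = runif(200))
  y <- rbinom(200, 1, 0.3)
  expect_equal(observed_error_mccp(tibble::tibble(p0 = rep(1, 5), p1 = rep(1, 5)),
                                   rbinom(5, 1, 0.5), 0.9), 0)
  expect_equal(observed_error_mccp(pv, y, 0), 0) # default convention: p > 0
  for (a in seq(0.05, 0.95, by = 0.1)) {
    reg <- prediction_region(pv, a)
    outside <- ifelse(y == 1, reg$p1 <= a, reg$p0 <= a)
    expect_equal(observed_error_mccp(pv, y, a), mean(outside))
    # coverage two ways: from outcomes and from the p-value inequalities
    expect_equal(coverage_rate(reg), mean(xor(pv$p0 > a, pv$p1 > a)))
    # coverage + uncertain + empty = 1
    expect_equal(coverage_rate(reg) + mean(reg$outcome == "uncertain") +
                   mean(reg$outcome == "empty"), 1)
  }
})

test_that("coverage counts singleton predictions only", {
  mk <- function(oc) tibble::tibble(
    outcome = factor(oc, levels = c("case", "control", "uncertain", "empty")))
  expect_equal(coverage_rate(mk(rep("uncertain", 10))), 0)
  expect_equal(coverage_rate(mk(c("case", "control", "uncertain", "empty"))), 0.5)
})

test_that("stratified metrics reproduce arithmetic and concordance oracles", {
  # 2x2 with TP=8 FP=2 TN=85 FN=5 among the predicted
  set.seed(83)
  d <- tibble::tibble(
    status = c(rep(1, 8), rep(0, 2), rep(0, 85), rep(1, 5)),
    outcome = factor(c(rep("case", 10), rep("control", 90)),
                     levels = c("case", "control", "uncertain", "empty")),
    score = rnorm(100) + c(rep(1, 8), rep(0, 2), rep(0, 85), rep(1, 5))
  )
  m <- stratified_metrics(d)
  expect_equal(m$ppv, 0.8)
  expect_equal(m$npv, 85 / 90)
  expect_equal(m$auc, bf_auc(d$status, d$score))
  bt <- binom.test(8, 10)
  expect_equal(c(m$ppv_low, m$ppv_high), bt$conf.int[1:2])

  # perfect predictions
  d2 <- tibble::tibble(
    status = c(rep(1, 10), rep(0, 40)),
    outcome = factor(c(rep("case", 10), rep("control", 40)),
                     levels = c("case", "control", "uncertain", "empty")),
    score = c(rnorm(10, 3), rnorm(40, 0))
  )
  m2 <- stratified_metrics(d2)
  expect_equal(m2$ppv, 1)
  expect_equal(m2$npv, 1)

  # AUC against the all-pairs oracle on a noisier 50-individual instance
  d3 <- tibble::tibble(
    status = rbinom(50, 1, 0.4),
    outcome = factor(rep(c("case", "control"), 25),
                     levels = c("case", "control", "uncertain", "empty")),
    score = rnorm(50)
  )
  expect_equal(stratified_metrics(d3)$auc, bf_auc(d3$status, d3$score))
})

test_that("degenerate predicted subsets report reasons, not zeros", {
  d <- tibble::tibble(
    status = rep(1, 10),
    outcome = factor(rep("case", 10),
                     levels = c("case", "control", "uncertain", "empty")),
    score = rnorm(10)
  )
  m <- stratified_metrics(d)
  expect_true(is.na(m$auc))
  expect_true(is.na(m$npv))
  expect_match(m$reason, "no predicted controls")
  expect_equal(m$ppv, 1)
})

test_that("the empirical method assigns exactly the extreme tails", {
  set.seed(84)
  d <- tibble::tibble(score = rnorm(100), status = rbinom(100, 1, 0.3))
  res <- empirical_method(d, 5)
  expect_equal(sum(res$assignments$outcome == "case"), 5)
  expect_equal(sum(res$assignments$outcome == "control"), 5)
  expect_equal(res$metrics$coverage, 0.10)
  # the predicted cases are exactly the top-5 scores
  top5 <- order(d$score, decreasing = TRUE)[1:5]
  expect_setequal(which(res$assignments$outcome == "case"), top5)
  all_in <- empirical_method(d, 50)
  expect_equal(all_in$metrics$coverage, 1)
  expect_error(empirical_method(d, 60), "x_percent")
})

test_that("reliability curve partitions the data and is monotone for MCCP", {
  set.seed(85)
  n <- 1500
  d <- tibble::tibble(id = seq_len(n), score = rnorm(n))
  d$status <- rbinom(n, 1, plogis(1.2 * d$score - 1.5))
  curve <- reliability_curve(d, alpha_grid = seq(0.05, 0.5, by = 0.05), seed = 2)
  preds <- attr(curve, "predictions")
  expect_identical(sort(preds$id), d$id) # each individual tested exactly once
  expect_true(all(diff(curve$error_mccp) >= 0)) # nestedness implies monotone
  # validity of the pooled curve at a moderate tolerance
  for (i in seq_len(nrow(curve))) {
    expect_lte(curve$error_mccp[i],
               curve$alpha[i] + 3 * sqrt(curve$alpha[i] *
                                           (1 - curve$alpha[i]) / n))
  }
})

test_that("evaluation report keeps the coverage identity on a grid", {
  set.seed(86)
  preds <- tibble::tibble(p0 = runif(300), p1 = runif(300),
                          status = rbinom(300, 1, 0.4), score = rnorm(300))
  rep_ <- evaluation_report(preds, alpha_grid = c(0.05, 0.2, 0.5))
  expect_equal(rep_$coverage + rep_$frac_uncertain + rep_$frac_empty,
               rep(1, 3))
  expect_true(all(rep_$observed_error >= 0 & rep_$observed_error <= 1))
})
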