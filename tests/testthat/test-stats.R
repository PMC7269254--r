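test_that("ROC/Youden calibration separates a separable cohort at the midpoint", {
  cal <- roc_youden(c(2, 3, 1, 1.5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cal$best_cutoff, 1.75)
  expect_equal(cal$youden_j, 1)
  expect_equal(cal$sensitivity, 1)
  expect_equal(cal$specificity, 1)
  expect_equal(cal$accuracy, 1)
  expect_false(is.unsorted(cal$roc_points$cutoff))

  same <- roc_youden(rep(2, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(same$youden_j, 0) # no discrimination

  expect_error(roc_youden(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("label inversion gives the same optimal J magnitude", {
  withr::local_seed(40)
  for (i in 1:10) {
    sc <- round(runif(20, 0, 5), 2)
    lab <- runif(20) > 0.5
    if (all(lab) || !any(lab)) next
    j1 <- roc_youden(sc, lab)$youden_j
    j2 <- roc_youden(-sc, !lab)$youden_j
    expect_equal(j1, j2, tolerance = 1e-12)
  }
})

test_that("best J matches the enumeration oracle and pROC on random score sets", {
  withr::local_seed(41)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    sc <- round(rnorm(n, 2, 1.5), 2)
    lab <- runif(n) > 0.5
    if (all(lab) || !any(lab)) next
    cal <- roc_youden(sc, lab)
    expect_equal(cal$youden_j, oracle_best_j(sc, lab), tolerance = 1e-12)
    expect_equal(cal$youden_j,
                 cal$sensitivity + cal$specificity - 1, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  for (i in 1:5) {
    sc <- round(rnorm(30, 2, 1.5), 2)
    lab <- runif(30) > 0.4
    if (all(lab) || !any(lab)) next
    cal <- roc_youden(sc, lab)
    r <- pROC::roc(response = lab, predictor = sc, quiet = TRUE,
                   direction = "<")
    co <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("sensitivity", "specificity"), transpose = FALSE)
    expect_equal(cal$youden_j, max(co$sensitivity + co$specificity - 1),
                 tolerance = 1e-9)
  }
})

test_that("accuracy identities hold for rate and count variants", {
  expect_equal(confusion_metrics(0.95, 0.90, 20 / 50), 0.92)
  expect_equal(confusion_metrics(1, 1, 0.3), 1)
  cm <- confusion_from_counts(tp = 19, fp = 3, tn = 27, fn = 1)
  expect_equal(cm$sensitivity, 0.95)
  expect_equal(cm$specificity, 0.90)
  expect_equal(cm$accuracy, 0.92)
  # the two variants agree on any confusion table
  withr::local_seed(42)
  for (i in 1:20) {
    tp <- sample(0:30, 1); fn <- sample(1:30, 1)
    tn <- sample(0:30, 1); fp <- sample(1:30, 1)
    cm <- confusion_from_counts(tp, fp, tn, fn)
    prev <- (tp + fn) / (tp + fn + tn + fp)
    expect_equal(confusion_metrics(cm$sensitivity, cm$specificity, prev),
                 cm$accuracy, tolerance = 1e-12)
  }
  expect_error(confusion_metrics(1.2, 0.5, 0.5), "0, 1")
})

test_that("summary t-test reproduces cohort and hand-computed values", {
  tt <- ttest_from_summary(15.90, 5.38, 20, 11.93, 5.31, 30)
  expect_equal(round(tt$p, 3), 0.013) # printed precision
  expect_equal(tt$df, 48)

  eq <- ttest_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)

  hand <- ttest_from_summary(1, 1, 10, 0, 1, 10)
  expect_equal(hand$t, 1 / sqrt(2 / 10), tolerance = 1e-10) # 2.2360
  expect_equal(hand$df, 18)

  # agrees with a raw-data t-test fed the same summaries
  withr::local_seed(43)
  x <- rnorm(15, 3, 2); y <- rnorm(20, 1, 1.5)
  raw <- t.test(x, y, var.equal = TRUE)
  sm <- ttest_from_summary(mean(x), sd(x), 15, mean(y), sd(y), 20)
  expect_equal(sm$t, unname(raw$statistic), tolerance = 1e-10)
  expect_equal(sm$p, raw$p.value, tolerance = 1e-10)
  raw_w <- t.test(x, y)
  sm_w <- ttest_from_summary(mean(x), sd(x), 15, mean(y), sd(y), 20,
                             welch = TRUE)
  expect_equal(sm_w$p, raw_w$p.value, tolerance = 1e-10)
  expect_error(ttest_from_summary(1, 0, 10, 0, 1, 10), "> 0")
})

test_that("chi-squared matches the textbook double loop and chisq.test", {
  tab <- matrix(c(5, 1, 2, 4, 4, 0, 15, 0, 5, 3, 0, 2), nrow = 4, byrow = TRUE)
  cs <- suppressWarnings(chi_square(tab))
  expect_equal(cs$statistic, oracle_chisq(tab), tolerance = 1e-12)
  expect_equal(cs$df, 6)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(cs$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cs$p, ref$p.value, tolerance = 1e-12)

  prop <- matrix(c(2, 4, 3, 6), 2) # proportional rows -> independence
  expect_equal(suppressWarnings(chi_square(prop))$statistic, 0,
               tolerance = 1e-12)

  diag2 <- matrix(c(10, 0, 0, 10), 2)
  ds <- suppressWarnings(chi_square(diag2))
  expect_equal(ds$statistic, 20)
  expect_equal(ds$df, 1)

  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_warning(chi_square(matrix(c(1, 2, 3, 4), 2)), "expected")
})

test_that("Pearson correlation handles exact and hand-computed cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  h <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(h$r, 0.6)
  expect_error(pearson_r(x, rep(1, 10)), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("pooled mean weights group means by size", {
  expect_equal(pooled_mean(c(36.90, 38.70), c(30, 20)), 37.62)
  expect_equal(pooled_mean(5.5, 7), 5.5)
  expect_equal(pooled_mean(c(0, 10), c(1, 1)), 5)
})

test_that("VVA classification is strict at the cutoff", {
  expect_equal(classify_vva(4.56, 1.95), "VVA")
  expect_equal(classify_vva(1.95, 1.95), "no VVA") # tie rule
  expect_equal(classify_vva(1.18, 1.95), "no VVA")
  expect_equal(classify_vva(c(0, 2, 5), 1.95), c("no VVA", "VVA", "VVA"))
  expect_error(classify_vva(-1, 1.95), ">= 0")
})
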