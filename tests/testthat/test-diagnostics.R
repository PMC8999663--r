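test_that("empirical AUC equals exhaustive pair counting, ties included", {
  # constructed instance with cross-class ties
  scores <- c(1, 2, 2, 3, 4, 4, 5, 6)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  roc <- empirical_auc(scores, labels)
  expect_equal(roc$auc, auc_brute(scores, labels))
  # random instances up to n = 50, with heavy ties
  withr::with_seed(99, {
    for (i in 1:20) {
      n <- sample(6:50, 1)
      sc <- sample(seq(0, 2, by = 0.1), n, replace = TRUE)
      lb <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      expect_equal(empirical_auc(sc, lb)$auc, auc_brute(sc, lb))
    }
  })
})

test_that("AUC boundary behaviour: separation, null, monotone invariance", {
  expect_equal(empirical_auc(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  withr::with_seed(5, {
    sc <- rnorm(2000)
    lb <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
    expect_equal(empirical_auc(sc, lb)$auc, 0.5, tolerance = 0.05)
    # strictly monotone transforms leave the AUC unchanged
    base <- empirical_auc(sc, lb)$auc
    expect_equal(empirical_auc(exp(sc), lb)$auc, base)
    expect_equal(empirical_auc(atan(3 * sc) - 2, lb)$auc, base)
  })
  expect_error(empirical_auc(1:5, rep(TRUE, 5)), class = "ctperf_input_error")
})

test_that("AUC and DeLong CI agree with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    sc <- c(rnorm(30, 0.8, 0.2), rnorm(70, 1.0, 0.2))
    lb <- rep(c(TRUE, FALSE), c(30, 70))
  })
  ours <- empirical_auc(sc, lb)
  ref <- pROC::roc(lb, sc, direction = ">", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$auc_ci[1], ci[1], tolerance = 1e-6)
  expect_equal(ours$auc_ci[2], ci[3], tolerance = 1e-6)
})

test_that("DeLong paired test: identity, rank invariance, pROC agreement", {
  withr::with_seed(23, {
    lb <- rep(c(TRUE, FALSE), c(25, 75))
    a <- rnorm(100) - lb
    b <- 0.6 * (a - mean(a)) + rnorm(100, sd = 0.8)
  })
  same <- delong_paired_test(a, a, lb)
  expect_equal(same$difference, 0)
  expect_equal(same$p.value, 1)
  mono <- delong_paired_test(exp(a / 2), a, lb)
  expect_equal(mono$difference, 0)
  res <- delong_paired_test(a, b, lb)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(lb, a, direction = ">", quiet = TRUE)
  rb <- pROC::roc(lb, b, direction = ">", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("Youden cutoff maximises J over the exhaustive threshold scan", {
  yd <- youden_cutoff(c(0.5, 0.6, 0.7, 0.9, 1.0, 1.1),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(yd$cutoff, 0.8)
  expect_equal(yd$j, 1)
  withr::with_seed(31, {
    for (i in 1:10) {
      sc <- round(rnorm(50), 1)
      lb <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 48, replace = TRUE))
      expect_equal(youden_cutoff(sc, lb)$j, youden_brute(sc, lb))
    }
  })
  expect_equal(youden_cutoff(rep(1, 10),
                             rep(c(TRUE, FALSE), 5))$j, 0)
})

test_that("Wilson intervals reproduce published diagnostic-table cells", {
  ci <- wilson_ci(49, 63)
  expect_equal(floor(100 * ci$lower + 0.5), 66)
  expect_equal(floor(100 * ci$upper + 0.5), 86)
  expect_equal(floor(100 * wilson_ci(283, 337)$lower + 0.5), 80)
  full <- wilson_ci(63, 63)
  expect_equal(floor(100 * full$upper + 0.5), 100)
  expect_lt(full$lower, 1)
  # closed form agrees with the score interval of prop.test
  for (x in c(5, 32, 49)) {
    ref <- stats::prop.test(x, 63, correct = FALSE)$conf.int
    ours <- wilson_ci(x, 63)
    expect_equal(ours$lower, ref[1], tolerance = 1e-10)
    expect_equal(ours$upper, ref[2], tolerance = 1e-10)
  }
  expect_error(wilson_ci(5, 0), class = "ctperf_input_error")
})

test_that("confusion metrics reproduce printed PPV/NPV cells", {
  m <- confusion_metrics(tp = 49, fp = 54, fn = 14, tn = 283)
  pct <- function(metric) floor(100 * m$estimate[m$metric == metric] + 0.5)
  expect_equal(pct("sensitivity"), 78)
  expect_equal(pct("specificity"), 84)
  expect_equal(pct("ppv"), 48)
  expect_equal(pct("npv"), 95)
  v <- confusion_metrics(tp = 42, fn = 21, fp = 34, tn = 303)
  expect_equal(floor(100 * v$estimate[v$metric == "ppv"] + 0.5), 55)
  perfect <- confusion_metrics(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_true(all(perfect$estimate == 1))
  degen <- confusion_metrics(tp = 0, fp = 0, fn = 5, tn = 5)
  expect_false(degen$defined[degen$metric == "ppv"])
  expect_true(all(degen$defined[degen$metric != "ppv"]))
})

test_that("confusion reconstruction from printed percentages round-trips", {
  cm <- reconstruct_confusion(78, 84, 63, 337)
  expect_equal(cm$tp, 49)
  expect_equal(cm$tn, 283)
  cm2 <- reconstruct_confusion(51, 86, 63, 337)
  expect_equal(cm2$tp, 32)
  expect_equal(cm2$tn, 290)
  cm3 <- reconstruct_confusion(100, 100, 10, 10)
  expect_equal(unlist(cm3), c(tp = 10, fp = 0, fn = 0, tn = 10))
  # re-deriving the percentages recovers the printed values
  m <- confusion_metrics(cm)
  expect_equal(floor(100 * m$estimate[1] + 0.5), 78)
  expect_equal(floor(100 * m$estimate[2] + 0.5), 84)
})

test_that("Mann-Whitney U matches enumeration and wilcox.test", {
  sep <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3, 4))
  expect_equal(sep$u, 12)
  a <- c(1.2, 3.4, 3.4, 5.0, 2.2)
  b <- c(0.5, 3.4, 4.1, 2.2)
  ours <- mann_whitney_u(a, b)
  expect_equal(ours$u, u_brute(a, b))
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(ours$u, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-8)
  ident <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$u, 9 / 2)
})

test_that("Cohen's kappa matches hand arithmetic on a 2x2 table", {
  # table a=30 (both+), b=10 (A+ B-), c=5 (A- B+), d=55 (both-)
  a_calls <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 5, 55))
  b_calls <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 5, 55))
  k <- cohen_kappa(a_calls, b_calls)
  po <- 0.85
  pe <- 0.4 * 0.35 + 0.6 * 0.65
  expect_equal(k$value, (po - pe) / (1 - pe))
  both <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  expect_equal(cohen_kappa(both, both)$value, 1)
  withr::with_seed(8, {
    x <- sample(c(TRUE, FALSE), 5000, replace = TRUE)
    y <- sample(c(TRUE, FALSE), 5000, replace = TRUE)
  })
  expect_equal(cohen_kappa(x, y)$value, 0, tolerance = 0.05)
  flat <- cohen_kappa(rep(TRUE, 10), rep(TRUE, 10))
  expect_false(flat$defined)
})

test_that("ICC(2,1) matches an independent ANOVA mean-squares oracle", {
  withr::with_seed(14, {
    truth <- rnorm(10, 100, 15)
    ratings <- cbind(truth + rnorm(10, 0, 4), truth + 2 + rnorm(10, 0, 4))
  })
  res <- icc_absolute_agreement(ratings)
  # oracle: two-way ANOVA decomposition via aov(), then the agreement formula
  df <- data.frame(y = as.vector(ratings),
                   target = factor(rep(1:10, 2)),
                   rater = factor(rep(1:2, each = 10)))
  ms <- summary(stats::aov(y ~ target + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 10; k <- 2
  icc_ref <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$value, icc_ref, tolerance = 1e-12)
  expect_true(res$lower < res$value && res$value < res$upper)
  # rater B identical to A
  expect_equal(icc_absolute_agreement(cbind(truth, truth))$value, 1)
  # huge independent noise destroys agreement
  withr::with_seed(15, noisy <- cbind(truth, rnorm(10, 100, 200)))
  expect_lt(abs(icc_absolute_agreement(noisy)$value), 0.45)
  expect_error(icc_absolute_agreement(ratings[1:3, ]),
               class = "ctperf_input_error")
  expect_false(icc_absolute_agreement(matrix(5, 6, 2))$defined)
})

test_that("paired t-test matches t.test and flags degenerate input", {
  withr::with_seed(26, {
    a <- rnorm(10, 70, 9)
    b <- a + rnorm(10, 5, 3)
  })
  ours <- paired_t_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value)
  expect_equal(ours$estimate, unname(ref$estimate))
  same <- paired_t_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(paired_t_test(a, a + 5), class = "ctperf_degenerate_error")
})

test_that("effective dose is the DLP conversion", {
  expect_equal(effective_dose(754.4), 10.5616)
  expect_equal(effective_dose(0), 0)
  expect_equal(effective_dose(100), 1.4)
  expect_error(effective_dose(-1), class = "ctperf_input_error")
})

test_that("DeLong variance components are nonnegative and PSD", {
  withr::with_seed(44, {
    for (i in 1:10) {
      lb <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 30, replace = TRUE))
      a <- rnorm(32)
      b <- rnorm(32)
      expect_gte(empirical_auc(a, lb)$auc_var, 0)
      res <- delong_paired_test(a, b, lb)
      # var(diff) >= 0 is implied by a finite z statistic
      expect_true(is.finite(res$statistic))
    }
  })
})
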