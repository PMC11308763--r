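test_that("confusion metrics reproduce the worked clinical example", {
  r <- confusion_metrics(108, 138, 10, 13)
  val <- function(m) r$estimate[r$metric == m]
  expect_equal(round(val("sensitivity"), 1), 89.3)
  expect_equal(round(val("specificity"), 1), 93.2)
  expect_equal(round(val("accuracy"), 1), 91.4)
  expect_equal(round(val("ppv"), 1), 91.5)
  expect_equal(round(val("npv"), 1), 91.4)
  expect_equal(round(val("plr"), 1), 13.2)
  expect_equal(round(val("nlr"), 1), 0.1)
  # exact binomial CIs at the rendered precision
  ci <- function(m) round(unlist(r[r$metric == m, c("lo", "hi")]),
                          1)
  expect_equal(unname(ci("sensitivity")), c(82.3, 94.2))
  expect_equal(unname(ci("specificity")), c(87.9, 96.7))
  expect_equal(unname(ci("ppv")), c(85.0, 95.9))
  expect_equal(unname(ci("npv")), c(85.7, 95.3))
})

test_that("degenerate confusion tables behave sensibly", {
  perf <- confusion_metrics(20, 20, 0, 0)
  v <- function(r, m) r$estimate[r$metric == m]
  expect_equal(v(perf, "sensitivity"), 100)
  expect_equal(v(perf, "specificity"), 100)
  expect_equal(v(perf, "nlr"), 0)
  expect_true(is.infinite(v(perf, "plr")))
  worst <- confusion_metrics(0, 0, 1, 1)
  expect_equal(v(worst, "sensitivity"), 0)
  expect_equal(v(worst, "specificity"), 0)
  none <- confusion_metrics(0, 3, 0, 0)     # no positives: sens undefined
  expect_true(is.na(v(none, "sensitivity")))
  expect_error(confusion_metrics(1, 1, -1, 0), "non-negative")
})

test_that("confusion identities hold and CIs contain the estimate", {
  set.seed(5)
  for (k in 1:25) {
    cnt <- rbinom(4, 80, 0.4) + c(1, 1, 0, 0)
    r <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    v <- function(m) r$estimate[r$metric == m] / 100
    p <- cnt[1] + cnt[4]; n <- cnt[2] + cnt[3]
    expect_equal(v("accuracy"), (v("sensitivity") * p + v("specificity") * n) /
                   (p + n), tolerance = 1e-12)
    pr <- r[r$metric %in% c("accuracy", "sensitivity", "specificity",
                            "ppv", "npv"), ]
    ok <- !is.na(pr$lo)
    expect_true(all(pr$lo[ok] <= pr$estimate[ok] + 1e-9))
    expect_true(all(pr$hi[ok] >= pr$estimate[ok] - 1e-9))
  }
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.6, 0.7, 0.5, 0.4),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), "higher")
  expect_equal(r$auc, 8 / 9, tolerance = 1e-12)
  expect_equal(roc_auc(1:6, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                       "higher")$auc, 1)
  expect_equal(roc_auc(rep(1, 8), rep(c(TRUE, FALSE), 4), "higher")$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "classes")
  set.seed(7)
  for (k in 1:20) {
    n <- sample(8:50, 1)
    sc <- round(rnorm(n), sample(0:2, 1))      # induce ties
    lb <- runif(n) < 0.5
    if (!any(lb) || all(lb)) next
    expect_equal(roc_auc(sc, lb, "lower")$auc, auc_pairs(sc, lb, "lower"),
                 tolerance = 1e-12)
  }
})

test_that("DeLong variance agrees with a grouped jackknife oracle", {
  set.seed(11)
  for (k in 1:6) {
    n <- sample(12:20, 1)
    sc <- rnorm(n)
    lb <- c(rep(TRUE, 6), runif(n - 6) < 0.5)
    lb <- lb[sample(n)]
    if (sum(lb) < 3 || sum(!lb) < 3) next
    r <- roc_auc(sc, lb, "lower")
    vj <- auc_jackknife_var(sc, lb, "lower")
    expect_equal(r$var, vj, tolerance = 0.05)
  }
})

test_that("paired DeLong comparison behaves at its edge cases", {
  sc <- c(0.9, 0.8, 0.6, 0.7, 0.5, 0.4)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  same <- delong_compare(sc, sc, lb, "higher")
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  flip <- delong_compare(sc, -sc, lb, "higher")
  expect_equal(flip$delta, 2 * (8 / 9) - 1, tolerance = 1e-12)
  expect_error(delong_compare(sc, sc[-1], lb), "paired")
})

test_that("DeLong machinery cross-checks against pROC", {
  set.seed(19)
  sc_a <- rnorm(60); sc_b <- sc_a + rnorm(60, 0, 0.8)
  lb <- runif(60) < 0.45
  r <- roc_auc(sc_a, lb, "higher")
  pr <- pROC::roc(response = lb, predictor = sc_a, direction = "<",
                  quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$var, pROC::var(pr, method = "delong"), tolerance = 1e-9)
  cmp <- delong_compare(sc_a, sc_b, lb, "higher")
  pb <- pROC::roc(response = lb, predictor = sc_b, direction = "<",
                  quiet = TRUE)
  pt <- pROC::roc.test(pr, pb, method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, pt$p.value, tolerance = 1e-9)
})

test_that("Bland-Altman agreement and the LoA F-test", {
  x <- c(1, 2, 3, 4); y <- x
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 0); expect_equal(ba$sd_diff, 0)
  ba2 <- bland_altman(c(0.98, 1.02), c(1, 1))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd_diff, 0.0283, tolerance = 1e-3)
  expect_equal(ba2$loa_high, 0.0554, tolerance = 1e-3)
  expect_error(bland_altman(1, 1), "pairs")
  ft <- loa_f_test(0.05, 0.05, n_a = 30, n_b = 30)
  expect_equal(ft$f, 1)
  expect_equal(ft$p_value, 1, tolerance = 1e-9)
  ft2 <- loa_f_test(0.079, 0.065, n_a = 269, n_b = 269)
  expect_lt(ft2$p_value, 0.05)
})

test_that("ICC(A,1) behaves as an absolute-agreement index", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_absolute(x, x), 1)
  y <- x + 2                                # constant shift is penalised
  expect_lt(icc_absolute(x, y), cor(x, y))
  set.seed(13)
  a <- rnorm(4000); b <- rnorm(4000)
  expect_lt(abs(icc_absolute(a, b)), 0.05)  # independent pairs
  # approaches Pearson r when means and variances match (the finite-n
  # column mean square keeps ICC(A,1) from the exact identity)
  u <- c(-2, -1, 0, 1, 2)
  v <- c(-1, -2, 0, 2, 1)
  expect_lte(icc_absolute(u, v), 1)
  set.seed(29)
  n <- 4000
  z1 <- rnorm(n); z2 <- 0.7 * z1 + sqrt(1 - 0.49) * rnorm(n)
  z1 <- as.vector(scale(z1)); z2 <- as.vector(scale(z2))
  expect_equal(icc_absolute(z1, z2), cor(z1, z2), tolerance = 0.005)
  expect_error(icc_absolute(rep(1, 5), rep(1, 5)), "variance")
})

test_that("dependent-correlation comparison (Steiger) is sane", {
  same <- compare_dependent_correlations(0.8, 0.8, 0.7, 100)
  expect_equal(same$z, 0); expect_equal(same$p_value, 1)
  ex <- compare_dependent_correlations(0.83, 0.76, 0.8, 269)
  expect_lt(ex$p_value, 0.05)
  expect_gt(ex$z, 0)
  p_small <- compare_dependent_correlations(0.83, 0.76, 0.8, 50)$p_value
  p_big <- compare_dependent_correlations(0.83, 0.76, 0.8, 5000)$p_value
  expect_lt(p_big, p_small)                 # consistency in n
  expect_error(compare_dependent_correlations(1, 0.5, 0.5, 50), "-1,1")
})

test_that("accuracy comparison: chi-squared and McNemar variants", {
  a <- confusion_metrics(108, 138, 10, 13)   # 246/269 correct
  b <- confusion_metrics(98, 139, 9, 23)     # 237/269 correct
  same <- compare_accuracies(a, a)
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  cmp <- compare_accuracies(a, b)
  expect_equal(cmp$accuracy_a, 91.4, tolerance = 0.05)
  expect_equal(cmp$accuracy_b, 88.1, tolerance = 0.05)
  expect_gt(cmp$p_value, 0.05)               # 91.4% vs 88.1% not significant
  expect_lt(cmp$p_value, 0.5)
  ext <- compare_accuracies(confusion_metrics(100, 100, 0, 0),
                            confusion_metrics(0, 0, 100, 100))
  expect_lt(ext$p_value, 1e-10)
  mc <- compare_accuracies(correct_a = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                           correct_b = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                           method = "mcnemar")
  expect_true(is.finite(mc$p_value))
  expect_error(compare_accuracies(a, confusion_metrics(1, 1, 1, 1)),
               "totals")
})

test_that("cohort accounting applies the exclusion cascade", {
  ca <- cohort_accounting(339, c(41, 15, 2, 12))
  expect_identical(ca$remaining, 269)
  expect_identical(ca$percent_of_initial, 79.4)
  expect_equal(cohort_accounting(100, numeric())$percent_of_initial, 100)
  ze <- cohort_accounting(10, c(4, 6))
  expect_identical(ze$remaining, 0)
  expect_identical(ze$percent_of_initial, 0)
  expect_error(cohort_accounting(10, c(6, 6)), "exceed")
  expect_equal(percent_of(121, 269), 45.0)
})

test_that("cohort evaluation wires the statistics together", {
  set.seed(21)
  n <- 120
  truth <- runif(n, 0.4, 1)
  tab <- data.frame(ffr = pmin(truth + rnorm(n, 0, 0.03), 1),
                    oct_mufr = pmin(truth + rnorm(n, 0, 0.02), 1),
                    muqfr = pmin(truth + rnorm(n, 0, 0.05), 1),
                    ds_percent = 100 * (1 - truth) + rnorm(n, 0, 8),
                    as_percent = 100 * (1 - truth^2) + rnorm(n, 0, 8))
  ev <- evaluate_cohort(tab)
  expect_setequal(names(ev$methods),
                  c("oct_mufr", "muqfr", "ds_percent", "as_percent"))
  expect_gt(ev$methods$oct_mufr$auc$auc, ev$methods$muqfr$auc$auc)
  expect_gt(ev$delong$delta, 0)
  expect_gt(ev$agreement$r_oct_mufr, ev$agreement$r_muqfr)
  expect_lt(ev$agreement$oct_mufr$sd_diff, ev$agreement$muqfr$sd_diff)
  expect_output(print(ev), "Cohort evaluation")
})
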