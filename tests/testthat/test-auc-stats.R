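test_that("midrank AUC matches hand examples and handles ties", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_equal(auc_mann_whitney(c(0.9, 0.4, 0.6), c(1, 1, 0)), 0.5)
  expect_equal(auc_mann_whitney(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)), "both classes")
})

test_that("midrank AUC equals brute-force pair counting on random instances", {
  set.seed(19)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), sample(0:2, 1)))   # induce ties often
    expect_identical(auc_mann_whitney(s, y), auc_brute_force(s, y))
  }
})

test_that("DeLong test basics: identity, antisymmetry, degeneracy", {
  set.seed(7)
  y <- rep(0:1, each = 30)
  a <- rnorm(60, y)
  b <- rnorm(60, 0.5 * y)
  same <- delong_test(a, a, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delong_test(a, b, y)
  ba <- delong_test(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_gt(ab$p, 0); expect_lte(ab$p, 1)
  expect_equal(ab$auc_a, auc_mann_whitney(a, y))
  # both scores separate perfectly: degenerate comparison, flagged, p = 1
  deg <- delong_test(y + 0.1, y + 0.2, y)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("DeLong AUC variance agrees with pROC on a fixed sample", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- rep(0:1, each = 25)
  a <- rnorm(50, 0.8 * y)
  b <- rnorm(50, 0.6 * y)
  mine <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-10)
  expect_equal(unname(pROC::var(pROC::roc(y, a, quiet = TRUE))),
               mine$var_a, tolerance = 1e-10)
})

test_that("Hanley-McNeil variance matches plug-in arithmetic and limits", {
  expect_equal(hanley_mcneil_var(0.5, 1, 1), 0.25)
  theta <- 0.7
  q1 <- theta / (2 - theta); q2 <- 2 * theta^2 / (1 + theta)
  byhand <- (theta * (1 - theta) + 4 * (q1 - theta^2) + 2 * (q2 - theta^2)) /
    (5 * 3)
  expect_equal(hanley_mcneil_var(0.7, 5, 3), byhand)
  expect_equal(byhand, 0.0385, tolerance = 5e-3)
  expect_equal(sqrt(byhand), 0.196, tolerance = 1e-2)
  expect_lt(hanley_mcneil_var(0.7, 5000, 3000), 1e-4)
})

test_that("AUC bands follow the rounded two-decimal scheme and are monotone", {
  expect_equal(as.character(classify_auc_band(c(0.53, 0.66, 0.72, 0.81))),
               c("no", "moderate", "good", "very_good"))
  expect_equal(as.character(classify_auc_band(0.50)), "no")
  expect_equal(as.character(classify_auc_band(0.42)), "no")
  expect_equal(as.character(classify_auc_band(c(0.56, 0.57, 0.64, 0.65,
                                                0.70, 0.71, 0.75, 0.76))),
               c("no", "low", "low", "moderate", "moderate", "good", "good",
                 "very_good"))
  grid <- seq(0, 1, by = 0.001)
  expect_true(all(diff(as.integer(classify_auc_band(grid))) >= 0))
})

test_that("threshold metrics reproduce the stated confusion matrix", {
  # TP=3, FP=1, FN=1, TN=5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- threshold_metrics(scores, labels, 0.5)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$balanced_accuracy, (0.75 + 5 / 6) / 2, tolerance = 1e-12)
  expect_equal(round(m$balanced_accuracy, 3), 0.792)
  # all predicted positive: recall 1; none predicted positive: flagged NA
  expect_equal(threshold_metrics(rep(0.9, 4), c(1, 0, 1, 0))$recall, 1.0)
  none <- threshold_metrics(rep(0.1, 4), c(1, 0, 1, 0))
  expect_true(none$precision_undefined)
  expect_true(is.na(none$precision))
  # random scores, balanced labels: balanced accuracy ~ 0.5
  set.seed(3)
  r <- threshold_metrics(stats::runif(1e4), rep(0:1, 5000))
  expect_equal(r$balanced_accuracy, 0.5, tolerance = 0.03)
})

test_that("overfit summary counts per-rep gaps against the threshold", {
  tab <- tibble::tibble(
    model = "lr", group = "g", N = 100L, rep = 1:4,
    cv_mean_auc = c(0.72, 0.65, 0.71, 0.58),
    test_auc    = c(0.60, 0.60, 0.60, 0.60))
  ov <- overfit_summary(tab, threshold = 0.10)
  expect_equal(ov$share_ge_threshold, 0.5)   # gaps .12, .05, .11, -.02
  expect_equal(ov$mean_gap, mean(c(0.12, 0.05, 0.11, -0.02)))
  tab$test_auc <- tab$cv_mean_auc
  ov0 <- overfit_summary(tab, 0.10)
  expect_equal(ov0$share_ge_threshold, 0)
  expect_equal(ov0$mean_gap, 0)
})

test_that("variance summary pools fold AUCs and flags degenerate groups", {
  tab <- tibble::tibble(
    model = rep(c("a", "b"), each = 2), group = "g", N = 100L, rep = c(1:2, 1:2),
    fold_auc_01 = c(0.5, 0.7, 0.6, 0.8), fold_auc_02 = c(0.6, 0.8, 0.7, 0.9),
    cv_mean_auc = 0.6, test_auc = 0.6)
  vs <- variance_summary(tab)
  expect_equal(vs$per_group$fold_sd,
               sd(c(0.5, 0.7, 0.6, 0.8, 0.6, 0.8, 0.7, 0.9)))
  expect_equal(vs$per_n$mean_fold_sd, vs$per_group$fold_sd)
  const <- tab; const$fold_auc_01 <- 0.6; const$fold_auc_02 <- 0.6
  expect_equal(variance_summary(const)$per_group$fold_sd, 0)
})
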