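test_that("effect-size calibration matches the binormal closed form", {
  expect_equal(calibrate_effect_size(0.5, 3, 0.2), 0)
  # single feature, no correlation: delta = sqrt(2) * qnorm(auc)
  d <- calibrate_effect_size(0.7602, 1, 0)
  expect_equal(d, 1.000, tolerance = 1e-3)
  # Monte-Carlo oracle: empirical AUC of the optimal score on simulated pairs
  set.seed(42)
  n <- 5e5
  auc_mc <- mean(rnorm(n, mean = d) > rnorm(n)) # P(pos score > neg score)
  expect_equal(auc_mc, 0.7602, tolerance = 3 / sqrt(n) * 2)

  # correlated multivariate case, Monte-Carlo oracle at 1e5 users
  rho <- 0.3; f <- 7
  d2 <- calibrate_effect_size(0.72, f, rho)
  set.seed(43)
  n2 <- 1e5
  gen <- function(shift) {
    u <- rnorm(n2)
    sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n2 * f), n2, f) + shift
  }
  sigma <- matrix(rho, f, f); diag(sigma) <- 1
  w <- solve(sigma, rep(d2, f))
  s1 <- gen(d2) %*% w; s0 <- gen(0) %*% w
  auc_mc2 <- auc_mann_whitney(c(s1, s0), rep(1:0, each = n2))
  expect_equal(auc_mc2, 0.72, tolerance = 0.005)

  # round trip through the analytic inverse
  expect_equal(binormal_auc(d2, f, rho), 0.72, tolerance = 1e-10)
})

test_that("calibration rejects out-of-domain targets and correlations", {
  expect_error(calibrate_effect_size(0.49, 5, 0.2), "target_auc")
  expect_error(calibrate_effect_size(1.0, 5, 0.2), "target_auc")
  expect_error(calibrate_effect_size(0.7, 5, 1.0), "correlation")
  expect_error(calibrate_effect_size(0.7, 5, -0.1), "correlation")
})

test_that("default cohort reproduces arm structure and exact-count prevalence", {
  co <- generate_cohort(default_cohort_config(seed = 5))
  expect_equal(length(co$labels), 3654L)
  expect_equal(as.integer(table(co$arm_ids)), c(452L, 397L, 1386L, 80L, 1339L))
  # per-arm exact dropout counts: round(size * rate)
  per_arm <- tapply(co$labels, co$arm_ids, sum)
  expect_equal(as.integer(per_arm), c(253L, 254L, 970L, 49L, 777L))
  expect_equal(sum(co$labels), 2303L)
  expect_equal(mean(co$labels), 2303 / 3654)
})

test_that("cohorts are bit-identical under a fixed seed and differ across seeds", {
  a <- generate_cohort(tiny_config(seed = 9))
  b <- generate_cohort(tiny_config(seed = 9))
  expect_identical(a, b)
  c2 <- generate_cohort(tiny_config(seed = 10))
  expect_false(identical(a$blocks$sig5, c2$blocks$sig5))
})

test_that("composed group columns equal their source columns row-for-row", {
  co <- generate_cohort(tiny_config(seed = 3))
  expect_identical(co$blocks$both7[, 1:2], co$blocks$null2[, 1:2])
  expect_identical(co$blocks$both7[, 3:7], co$blocks$sig5[, 1:5])
  # and composition width checks are enforced at config time
  expect_error(
    cohort_config(list(arm_spec("A", 10, 0.5)),
                  list(feature_group_spec("g", 2, 0.6),
                       feature_group_spec("m", 5, composition = "g"))),
    "components supply")
  expect_error(
    cohort_config(list(arm_spec("A", 10, 0.5)),
                  list(feature_group_spec("m", 5, composition = "gone"))),
    "unresolvable")
})

test_that("oracle AUC recovers each group's implied population AUC", {
  co <- generate_cohort(default_cohort_config(seed = 21))
  audit <- audit_cohort(co)
  for (i in seq_len(nrow(audit))) {
    se <- sqrt(hanley_mcneil_var(max(audit$implied_auc[i], 0.51),
                                 2303, 1351))
    expect_lt(abs(audit$oracle_auc[i] - audit$implied_auc[i]), 3 * se + 1e-9)
  }
  # null generator: every group at target 0.5 gives oracle ~0.5
  null_cfg <- cohort_config(
    arms = list(arm_spec("A", 200, 0.6)),
    groups = list(feature_group_spec("g1", 3, 0.5, 0.2),
                  feature_group_spec("g2", 4, 0.5, 0)),
    seed = 2)
  nco <- generate_cohort(null_cfg)
  expect_equal(oracle_auc(nco, "g1"), 0.5)
  expect_equal(oracle_auc(nco, "g2"), 0.5)
})

test_that("oracle AUC is invariant under duplicating cohort rows", {
  co <- generate_cohort(tiny_config(seed = 4))
  dup <- co
  dup$labels <- c(co$labels, co$labels)
  dup$blocks <- lapply(co$blocks, function(b) rbind(b, b))
  expect_equal(oracle_auc(dup, "sig5"), oracle_auc(co, "sig5"))
})

test_that("missingness injection hits exact counts, blocks and indicators", {
  co <- generate_cohort(tiny_config(seed = 6, with_missing = TRUE))
  n <- length(co$labels)
  com <- apply_missingness(co)
  x <- com$blocks$sig5
  # scattered columns: exactly round(0.05 * n) missing each
  expect_equal(sum(is.na(x[, 1])), round(0.05 * n))
  expect_equal(sum(is.na(x[, 2])), round(0.05 * n))
  # voluntary block: all-or-none across its two columns
  expect_identical(is.na(x[, 3]), is.na(x[, 4]))
  expect_equal(sum(is.na(x[, 3])), round(0.15 * n))
  # indicators appended, 1 = answered
  expect_true(all(c("sig5_f003_answered", "sig5_f004_answered")
                  %in% colnames(x)))
  expect_equal(x[, "sig5_f003_answered"] == 0, unname(is.na(x[, 3])))
  # composed group re-uses the injected values but keeps its width
  expect_equal(ncol(com$blocks$both7), 7L + 3L)
  expect_identical(is.na(com$blocks$both7[, 5]), is.na(x[, 3]))
  # zero fraction leaves the cohort unchanged
  cfg0 <- tiny_config(seed = 6)
  cfg0$groups$sig5$missing_spec <- list(missing_col(1, 0))
  co0 <- generate_cohort(cfg0)
  expect_identical(inject_missingness(co0, "sig5")$blocks$sig5,
                   co0$blocks$sig5)
  expect_error(missing_col(1, 1.2), "fraction")
})

test_that("intervention-info columns ride along on every block", {
  co <- generate_cohort(tiny_config(seed = 2))
  for (b in co$blocks) {
    expect_true(all(c("arm_code", "weeks", "start_year") %in% colnames(b)))
    expect_setequal(unique(b[, "weeks"]), c(4, 8))
  }
  expect_equal(ncol(co$blocks$sig5), 5L + 3L)
})

test_that("cohorts round-trip through CSV + manifest", {
  co <- apply_missingness(generate_cohort(tiny_config(seed = 8,
                                                      with_missing = TRUE)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$labels, co$labels)
  expect_identical(back$arm_ids, co$arm_ids)
  for (g in names(co$blocks))
    expect_equal(back$blocks[[g]], co$blocks[[g]], tolerance = 1e-12)
  # oracle still works from the persisted effect vectors (pre-missingness
  # group)
  clean <- generate_cohort(tiny_config(seed = 8, with_missing = TRUE))
  dir2 <- withr::local_tempdir()
  write_cohort(clean, dir2)
  expect_equal(oracle_auc(read_cohort(dir2), "sig5"),
               oracle_auc(clean, "sig5"), tolerance = 1e-10)
})
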