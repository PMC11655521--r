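# Small cohort configurations and independent oracles shared across tests.

# Two-arm, three-group cohort small enough for fast harness runs.
tiny_config <- function(seed = 1L, with_missing = FALSE) {
  ms <- if (with_missing)
    c(lapply(1:2, function(j) missing_col(j, 0.05)),
      lapply(3:4, function(j)
        missing_col(j, 0.15, add_indicator = TRUE, block = "vol")))
  cohort_config(
    arms = list(arm_spec("A", 150, 0.60, 4, 2016),
                arm_spec("B", 100, 0.50, 8, 2017)),
    groups = list(
      feature_group_spec("null2", 2, target_auc = 0.50, correlation = 0.3),
      feature_group_spec("sig5", 5, target_auc = 0.75, correlation = 0.3,
                         missing_spec = ms),
      feature_group_spec("both7", 7, composition = c("null2", "sig5"))),
    seed = seed)
}

tiny_plan <- function(...) {
  defaults <- list(n_grid = c(50, 100), rep_schedule = 2L, cv_folds = 5L,
                   families = c("naive_bayes", "logistic_regression"),
                   grids = "reduced", base_seed = 11L)
  do.call(experiment_plan, utils::modifyList(defaults, list(...)))
}

# O(n^2) pair-counting AUC, the independent oracle for the midrank version.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Dense recomputation of the Kneedle difference curve: independent oracle
# for the global-knee selection.
knee_oracle <- function(x, y, S = 1) {
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  d <- yn - xn
  n <- length(d)
  cand <- integer(0)
  for (i in 2:(n - 1))
    if (d[i] > d[i - 1] && d[i] >= d[i + 1] && d[i] > S * mean(diff(xn)))
      cand <- c(cand, i)
  if (!length(cand)) return(NA_real_)
  x[cand[which.max(d[cand])]]
}
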