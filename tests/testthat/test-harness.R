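test_that("holdout split arithmetic and stratification", {
  co <- generate_cohort(default_cohort_config(seed = 2))
  sp <- make_holdout_split(co, 0.2, seed = 1)
  expect_length(sp$test, 731L)
  expect_length(sp$pool, 2923L)
  expect_length(intersect(sp$pool, sp$test), 0L)
  expect_setequal(c(sp$pool, sp$test), seq_along(co$labels))
  # dropout share in the test set within one user of the cohort share
  expect_lte(abs(sum(co$labels[sp$test]) - mean(co$labels) * 731), 1)

  tiny <- generate_cohort(tiny_config(seed = 2))
  expect_length(make_holdout_split(tiny, 0.2, 1)$test,
                round(0.2 * length(tiny$labels)))
  one_class <- tiny; one_class$labels <- rep(1L, length(tiny$labels))
  expect_error(make_holdout_split(one_class, 0.2, 1), "stratification")
})

test_that("training samples have exact size and arm-proportional composition", {
  co <- generate_cohort(default_cohort_config(seed = 2))
  sp <- make_holdout_split(co, 0.2, seed = 1)
  s100 <- draw_training_sample(co, sp$pool, 100, seed = 5)
  expect_length(s100, 80L)
  sfull <- draw_training_sample(co, sp$pool, 3654, seed = 5)
  expect_length(sfull, 2923L)
  expect_setequal(sfull, sp$pool)
  # arm counts proportional to pool shares within rounding
  pool_share <- table(co$arm_ids[sp$pool]) / length(sp$pool)
  got <- table(co$arm_ids[s100])
  expect_true(all(abs(got - 80 * pool_share) < 1))
  # different seeds give different samples; same seed identical
  expect_identical(draw_training_sample(co, sp$pool, 100, seed = 5), s100)
  expect_false(setequal(draw_training_sample(co, sp$pool, 100, seed = 6),
                        s100))
  expect_error(draw_training_sample(co, sp$pool, 4000, seed = 1), "plan error")
})

test_that("run_cell yields k fold AUCs, is deterministic, and disjointness is enforced", {
  co <- generate_cohort(tiny_config(seed = 3))
  plan <- tiny_plan(cv_folds = 10L)
  sp <- make_holdout_split(co, 0.2, seed = 4)
  s <- draw_training_sample(co, sp$pool, 100, seed = 4)
  cell <- run_cell(co, "sig5", "logistic_regression", s, sp$test, plan,
                   seed = 99, n = 100, rep = 1)
  folds <- unlist(cell[grep("^fold_auc_", names(cell))])
  expect_length(folds, 10L)
  expect_true(all(folds >= 0 & folds <= 1, na.rm = TRUE))
  expect_equal(cell$cv_mean_auc, mean(folds, na.rm = TRUE))
  expect_true(all(unlist(cell[c("test_auc", "test_recall",
                                "test_balanced_accuracy")]) >= 0))
  cell2 <- run_cell(co, "sig5", "logistic_regression", s, sp$test, plan,
                    seed = 99, n = 100, rep = 1)
  expect_identical(cell, cell2)
  expect_error(run_cell(co, "sig5", "logistic_regression", s,
                        c(sp$test, s[1]), plan, seed = 1), "disjoint")
})

test_that("run_experiment executes the factorial with order-independent seeds", {
  co <- generate_cohort(tiny_config(seed = 5))
  plan <- tiny_plan()
  tab <- run_experiment(co, plan)
  # 2 families x 3 groups x 2 sizes x 2 reps
  expect_equal(nrow(tab), 2 * 3 * 2 * 2)
  expect_equal(anyDuplicated(tab[, c("model", "group", "N", "rep")]), 0L)
  # shuffled plan order yields identical content
  plan2 <- tiny_plan(families = rev(plan$families))
  plan2$groups <- rev(names(co$blocks))
  tab2 <- run_experiment(co, plan2)
  key <- function(t) t[order(t$model, t$group, t$N, t$rep), ]
  expect_equal(key(as.data.frame(tab)), key(as.data.frame(tab2)),
               ignore_attr = TRUE)
  # resume: all keys done -> nothing new
  done <- paste(tab$model, tab$group, tab$N, tab$rep, sep = "|")
  expect_equal(nrow(run_experiment(co, plan, done_keys = done)), 0L)
  # restricted plan -> single row
  p1 <- tiny_plan(n_grid = 100, rep_schedule = 1L,
                  families = "naive_bayes", groups = "sig5")
  expect_equal(nrow(run_experiment(co, p1)), 1L)
})

test_that("test ids never enter training and the null group stays at chance", {
  co <- generate_cohort(tiny_config(seed = 6))
  plan <- tiny_plan(n_grid = c(50, 100), rep_schedule = 4L,
                    families = "logistic_regression", groups = "null2")
  sp <- make_holdout_split(co, plan$test_fraction,
                           seed = dropcurve:::hash32(plan$base_seed,
                                                     "holdout"))
  for (n in plan$n_grid) for (r in 1:4) {
    cs <- dropcurve:::hash32(plan$base_seed, "logistic_regression", "null2",
                             n, r)
    s <- draw_training_sample(co, sp$pool, n,
                              seed = dropcurve:::hash32(cs, "sample"))
    expect_length(intersect(s, sp$test), 0L)
  }
  tab <- run_experiment(co, plan)
  expect_equal(mean(tab$test_auc), 0.5, tolerance = 0.08)
})

test_that("mean test AUC grows with N for an informative group", {
  co <- generate_cohort(tiny_config(seed = 7))
  plan <- tiny_plan(n_grid = c(50, 250), rep_schedule = 3L,
                    families = "logistic_regression", groups = "sig5")
  tab <- run_experiment(co, plan)
  m <- tapply(tab$test_auc, tab$N, mean)
  expect_gt(m["250"], m["50"] - 0.02)
})

test_that("single-class folds are recorded missing with a warning", {
  co <- generate_cohort(tiny_config(seed = 8))
  # force an all-dropout training sample so some folds are single-class
  ids <- which(co$labels == 1L)[1:30]
  ids[1] <- which(co$labels == 0L)[1]          # one completer, k > 1 folds
  plan <- tiny_plan(cv_folds = 5L, families = "naive_bayes")
  test_ids <- setdiff(seq_along(co$labels), ids)[1:50]
  suppressWarnings(expect_warning(
    cell <- run_cell(co, "sig5", "naive_bayes", ids, test_ids, plan,
                     seed = 3),
    "single-class"))
  folds <- unlist(cell[grep("^fold_auc_", names(cell))])
  expect_true(anyNA(folds))
  expect_equal(cell$cv_mean_auc, mean(folds, na.rm = TRUE))
})
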