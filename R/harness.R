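#' Define a learning-curve experiment plan
#'
#' The default plan follows the standard schedule for this design: dataset
#' sizes N in \{100, 200, 300, 400, 500, 750, 1000, 1500, 2000, 2500,
#' 3000, 3654\}, with ten repetitions for small sizes (N <= 500), five for
#' mid sizes (N <= 2000) and three for the rest; a 20% dropout-stratified
#' holdout; 10-fold cross-validated grid search per cell; training on
#' `round(0.8 * N)` rows drawn (arm-stratified) from the fixed training
#' pool, so the holdout is identical across every N.
#'
#' @param n_grid Strictly increasing vector of assumed dataset sizes.
#' @param rep_schedule Either a function `N -> repetitions` or a single
#'   count. Default: 10 / 5 / 3 as above.
#' @param test_fraction Holdout fraction (default 0.2).
#' @param cv_folds Number of CV folds k (default 10).
#' @param families Model families to run (default all six).
#' @param groups Feature groups to run (default: all groups in the
#'   cohort at run time).
#' @param base_seed Base seed; every cell seed is derived from it and the
#'   cell's identity (family, group, N, rep), independent of loop order.
#' @param grids `"default"`, `"reduced"`, or a function
#'   `(family, n_features) -> grid`.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(n_grid = c(100, 200, 300, 400, 500, 750, 1000,
                                       1500, 2000, 2500, 3000, 3654),
                            rep_schedule = NULL,
                            test_fraction = 0.2, cv_folds = 10L,
                            families = names(model_families()),
                            groups = NULL, base_seed = 1L,
                            grids = "default") {
  if (any(diff(n_grid) <= 0)) stop("n_grid must be strictly increasing")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  if (is.null(rep_schedule))
    rep_schedule <- function(n) if (n <= 500) 10L else if (n <= 2000) 5L else 3L
  if (is.numeric(rep_schedule)) {
    k <- as.integer(rep_schedule)
    rep_schedule <- function(n) k
  }
  stopifnot(all(vapply(n_grid, rep_schedule, 0L) >= 1L))
  bad <- setdiff(families, names(model_families()))
  if (length(bad)) stop("unknown families: ", paste(bad, collapse = ", "))
  structure(list(n_grid = as.integer(n_grid), rep_schedule = rep_schedule,
                 test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 families = families, groups = groups,
                 base_seed = as.integer(base_seed), grids = grids),
            class = "experiment_plan")
}

plan_grid <- function(plan, family, n_features) {
  if (is.function(plan$grids)) return(plan$grids(family, n_features))
  switch(plan$grids,
         default = default_grid(family, n_features),
         reduced = reduced_grid(family, n_features),
         stop("grids must be 'default', 'reduced' or a function"))
}

#' Dropout-stratified holdout split
#'
#' Sets aside `round(test_fraction * n)` rows, apportioning the test
#' class counts by largest remainder so the test dropout share is within
#' one user of the cohort share. The remaining rows form the training
#' pool, which is fixed across all assumed dataset sizes.
#'
#' @param cohort A `dropcurve_cohort`.
#' @param test_fraction Holdout proportion in (0, 1).
#' @param seed Integer seed.
#' @return List with integer row ids `pool` and `test`.
#' @examples
#' co <- generate_cohort(default_cohort_config(seed = 1))
#' sp <- make_holdout_split(co, 0.2, seed = 1)
#' length(sp$test)   # 731
#' @export
make_holdout_split <- function(cohort, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  y <- cohort$labels
  n <- length(y)
  n_test <- round(test_fraction * n)
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("stratification error: a class is absent")
  per_class <- largest_remainder(n_test, as.numeric(counts))
  set.seed(seed)
  test <- integer(0)
  for (k in 1:2) {
    idx <- which(y == (k - 1L))
    test <- c(test, idx[sample.int(length(idx), per_class[k])])
  }
  test <- sort(test)
  if (length(test) == n || length(test) == 0L ||
      length(unique(y[-test])) < 2L || length(unique(y[test])) < 2L)
    stop("stratification error: a class is absent from one side")
  list(pool = setdiff(seq_len(n), test), test = test)
}

#' Draw one arm-stratified training sample
#'
#' Draws `round(0.8 * N)` rows from the training pool with per-arm counts
#' proportional to the pool's arm shares (largest-remainder rounding).
#' Draws with different seeds are independent, not nested.
#'
#' @param cohort A `dropcurve_cohort`.
#' @param pool Integer row ids of the training pool.
#' @param n Assumed dataset size N.
#' @param seed Integer seed.
#' @return Integer row ids of size `round(0.8 * n)`.
#' @export
draw_training_sample <- function(cohort, pool, n, seed = 1L) {
  n_draw <- round(0.8 * n)
  if (n_draw > length(pool))
    stop("plan error: N = ", n, " needs ", n_draw,
         " training rows but the pool has ", length(pool))
  arms <- droplevels(cohort$arm_ids[pool])
  per_arm <- largest_remainder(n_draw, as.numeric(table(arms)))
  set.seed(seed)
  out <- integer(0)
  for (k in seq_along(levels(arms))) {
    idx <- pool[arms == levels(arms)[k]]
    out <- c(out, idx[sample.int(length(idx), per_arm[k])])
  }
  sort(out)
}

#' Run one experiment cell
#'
#' One (family, group, N, repetition) cell: k stratified CV folds on the
#' training sample score every grid point by mean fold AUC (folds with a
#' single class yield an undefined AUC, which is recorded missing and
#' excluded from the mean with a warning); the best grid point is refit on
#' the whole sample and evaluated on the holdout.
#'
#' @param cohort A `dropcurve_cohort`.
#' @param group Feature group name.
#' @param family Model family name.
#' @param sample_ids Training sample row ids (disjoint from `test_ids`).
#' @param test_ids Holdout row ids.
#' @param plan An [experiment_plan()].
#' @param seed Integer seed for this cell.
#' @param n Assumed dataset size (recorded in the result).
#' @param rep Repetition index (recorded).
#' @param keep_scores Keep the holdout score vector (for DeLong
#'   comparisons)?
#' @return One-row tibble (a RunResult): fold AUCs in wide columns,
#'   `cv_mean_auc`, `test_auc`, threshold-0.5 metrics, and the chosen
#'   hyperparameters as a JSON string.
#' @export
run_cell <- function(cohort, group, family, sample_ids, test_ids, plan,
                     seed = 1L, n = length(sample_ids), rep = 1L,
                     keep_scores = FALSE) {
  if (length(intersect(sample_ids, test_ids)))
    stop("training sample and test set must be disjoint")
  x <- cohort$blocks[[group]]
  if (is.null(x)) stop("unknown group: ", group)
  y <- cohort$labels
  xs <- x[sample_ids, , drop = FALSE]
  ys <- y[sample_ids]
  k <- plan$cv_folds
  grid <- plan_grid(plan, family, ncol(xs))
  set.seed(seed)
  fold_ids <- stratified_fold_ids(ys, k)
  fold_auc <- matrix(NA_real_, nrow = length(grid), ncol = k)
  for (gi in seq_along(grid)) {
    for (fi in seq_len(k)) {
      tr <- fold_ids != fi
      if (length(unique(ys[!tr])) < 2L) {
        warning("single-class validation fold: AUC recorded missing ",
                "(group=", group, ", family=", family, ", N=", n, ")")
        next
      }
      fit <- fit_pipeline(family, grid[[gi]], xs[tr, , drop = FALSE],
                          ys[tr], seed = hash32(seed, gi, fi))
      sc <- predict_scores(fit, xs[!tr, , drop = FALSE])
      fold_auc[gi, fi] <- auc_mann_whitney(sc, ys[!tr])
    }
  }
  cv_means <- rowMeans(fold_auc, na.rm = TRUE)
  best <- which.max(cv_means)
  final <- fit_pipeline(family, grid[[best]], xs, ys,
                        seed = hash32(seed, "refit"))
  test_scores <- predict_scores(final, x[test_ids, , drop = FALSE])
  yt <- y[test_ids]
  tm <- threshold_metrics(test_scores, yt, 0.5)
  res <- tibble::tibble(
    model = family, group = group, N = as.integer(n), rep = as.integer(rep),
    seed = as.integer(seed), n_train = length(sample_ids),
    cv_mean_auc = cv_means[best],
    test_auc = auc_mann_whitney(test_scores, yt),
    test_recall = tm$recall, test_precision = tm$precision,
    test_f1 = tm$f1, test_balanced_accuracy = tm$balanced_accuracy,
    best_hyperparams = as.character(
      jsonlite::toJSON(grid[[best]], auto_unbox = TRUE)),
    n_warnings = length(final$warnings))
  fa <- as.list(fold_auc[best, ])
  names(fa) <- sprintf("fold_auc_%02d", seq_len(k))
  res <- tibble::add_column(res, !!!fa, .after = "n_train")
  if (keep_scores) attr(res, "test_scores") <- test_scores
  res
}

#' Run the full learning-curve experiment
#'
#' Full factorial over groups, families, the N grid and the repetition
#' schedule. Every cell's seed is `hash32(base_seed, family, group, N,
#' rep)`, so the result table is identical under any execution order and
#' fully determined by the configuration and base seed.
#'
#' @param cohort A `dropcurve_cohort`.
#' @param plan An [experiment_plan()].
#' @param keep_scores Keep per-cell holdout scores (attribute
#'   `"test_scores"`, a named list) for DeLong matrices?
#' @param progress Print one line per cell?
#' @param done_keys Character vector of `model|group|N|rep` keys to skip
#'   (resume support).
#' @return A tibble of RunResults (a ResultTable) with attributes
#'   `"split"` (the holdout ids) and, if requested, `"test_scores"` and
#'   `"test_labels"`.
#' @export
run_experiment <- function(cohort, plan, keep_scores = FALSE,
                           progress = FALSE, done_keys = character(0)) {
  groups <- plan$groups %||% names(cohort$blocks)
  split <- make_holdout_split(cohort, plan$test_fraction,
                              seed = hash32(plan$base_seed, "holdout"))
  if (max(plan$n_grid) > length(cohort$labels))
    stop("plan error: max(n_grid) exceeds cohort size")
  rows <- list()
  scores <- list()
  for (group in groups) {
    for (family in plan$families) {
      for (n in plan$n_grid) {
        for (r in seq_len(plan$rep_schedule(n))) {
          key <- paste(family, group, n, r, sep = "|")
          if (key %in% done_keys) next
          cell_seed <- hash32(plan$base_seed, family, group, n, r)
          sample_ids <- draw_training_sample(
            cohort, split$pool, n, seed = hash32(cell_seed, "sample"))
          cell <- tryCatch(
            run_cell(cohort, group, family, sample_ids, split$test, plan,
                     seed = cell_seed, n = n, rep = r,
                     keep_scores = keep_scores),
            error = function(e) {
              warning("cell failed (", key, "): ", conditionMessage(e))
              NULL
            })
          if (is.null(cell)) next
          if (keep_scores) scores[[key]] <- attr(cell, "test_scores")
          rows[[key]] <- cell
          if (progress)
            message(sprintf("%s  cv=%.3f test=%.3f", key,
                            cell$cv_mean_auc, cell$test_auc))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "split") <- split
  if (keep_scores) {
    attr(out, "test_scores") <- scores
    attr(out, "test_labels") <- cohort$labels[split$test]
  }
  out
}
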