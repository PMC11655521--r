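#' Overfitting summary per (model, group, N)
#'
#' For each cell the overfitting gap is its CV mean AUC minus its own
#' repetition's holdout AUC. Per (model, group, N) the summary reports the
#' mean gap and the share of repetitions with gap at or above the
#' threshold. The default threshold of +0.10 AUC is one full step of the
#' predictive-power band scheme (e.g. a "low" score misread as "good").
#'
#' @param table A ResultTable from [run_experiment()].
#' @param threshold Gap threshold (default 0.10).
#' @return Tibble with `model`, `group`, `N`, `mean_gap`,
#'   `share_ge_threshold`.
#' @export
overfit_summary <- function(table, threshold = 0.10) {
  stopifnot(nrow(table) > 0, threshold > 0)
  table |>
    dplyr::mutate(gap = .data$cv_mean_auc - .data$test_auc) |>
    dplyr::group_by(.data$model, .data$group, .data$N) |>
    dplyr::summarise(mean_gap = mean(.data$gap),
                     share_ge_threshold = mean(.data$gap >= threshold),
                     .groups = "drop")
}

#' Fold-level AUC variability per (group, N)
#'
#' Pools every single-fold validation AUC over repetitions and model
#' families and reports its standard deviation per (group, N), plus the
#' across-group mean per N (the headline variance curve). Pooling over
#' families as well as repetitions is recorded in the output metadata.
#'
#' @param table A ResultTable containing wide `fold_auc_*` columns.
#' @return List with tibbles `per_group` (`group`, `N`, `fold_sd`,
#'   `n_folds`) and `per_n` (`N`, `mean_fold_sd`). Groups/N with fewer
#'   than two fold values get `fold_sd = NA` and a flag.
#' @export
variance_summary <- function(table) {
  fold_cols <- grep("^fold_auc_", names(table), value = TRUE)
  if (!length(fold_cols)) stop("fold AUC columns absent from table")
  long <- table |>
    dplyr::select(dplyr::all_of(c("group", "N", fold_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(fold_cols), values_to = "fold_auc") |>
    dplyr::filter(!is.na(.data$fold_auc))
  per_group <- long |>
    dplyr::group_by(.data$group, .data$N) |>
    dplyr::summarise(fold_sd = if (dplyr::n() >= 2) sd(.data$fold_auc)
                               else NA_real_,
                     n_folds = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(flag_too_few = is.na(.data$fold_sd))
  per_n <- per_group |>
    dplyr::group_by(.data$N) |>
    dplyr::summarise(mean_fold_sd = mean(.data$fold_sd, na.rm = TRUE),
                     .groups = "drop")
  structure(list(per_group = per_group, per_n = per_n),
            pooling = "fold AUCs pooled over repetitions and model families")
}

#' Mean learning curves per (model, group)
#'
#' @param table A ResultTable.
#' @param metric `"test_auc"` (default) or `"cv_mean_auc"`.
#' @return Tibble with `model`, `group`, `N`, `y` (mean over reps),
#'   `y_sd` (SD over reps), `n_reps`.
#' @export
learning_curves <- function(table, metric = c("test_auc", "cv_mean_auc")) {
  metric <- match.arg(metric)
  table |>
    dplyr::group_by(.data$model, .data$group, .data$N) |>
    dplyr::summarise(y = mean(.data[[metric]]),
                     y_sd = if (dplyr::n() >= 2) sd(.data[[metric]])
                            else NA_real_,
                     n_reps = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$model, .data$group, .data$N)
}

#' Pairwise DeLong p-value matrix per (group, N)
#'
#' Requires holdout scores kept by `run_experiment(keep_scores = TRUE)`.
#' Within each (group, N), the first repetition's holdout scores of every
#' family are compared pairwise with [delong_test()].
#'
#' @param table A ResultTable carrying the `test_scores` attribute.
#' @param group,n Cell coordinates.
#' @return Symmetric matrix of two-sided p-values (diagonal 1).
#' @export
delong_matrix <- function(table, group, n) {
  scores <- attr(table, "test_scores")
  labels <- attr(table, "test_labels")
  if (is.null(scores))
    stop("run_experiment(keep_scores = TRUE) is required for DeLong matrices")
  fams <- unique(table$model)
  keys <- paste(fams, group, n, 1L, sep = "|")
  have <- keys %in% names(scores)
  fams <- fams[have]; keys <- keys[have]
  p <- matrix(1, length(fams), length(fams), dimnames = list(fams, fams))
  if (length(fams) < 2L) return(p)
  for (i in seq_along(fams)) for (j in seq_along(fams)) if (i < j) {
    d <- delong_test(scores[[keys[i]]], scores[[keys[j]]], labels)
    p[i, j] <- p[j, i] <- d$p
  }
  p
}
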