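#' Write the publication-style report bundle
#'
#' From a ResultTable, writes: the long learning-curve table; the
#' overfitting-share table (rows = feature group, one column per family,
#' one block per N); the fold-variance curve; the convergence table and
#' per-model median knees; pairwise DeLong p-value matrices per (group,
#' max N) when holdout scores were kept; and a JSON provenance manifest
#' naming the configuration hash behind every artifact. Figures (learning
#' curves per group, the variance curve, per-model test curves with knee
#' markers) are written as PNG.
#'
#' @param table A ResultTable from [run_experiment()].
#' @param out_dir Output directory.
#' @param overfit_threshold Gap threshold for the overfitting table.
#' @param S Kneedle sensitivity.
#' @param config_hash Provenance string stamped into the manifest.
#' @param figures Render PNG figures (default TRUE)?
#' @return Invisibly, the named vector of paths written.
#' @export
report_bundle <- function(table, out_dir, overfit_threshold = 0.10, S = 1,
                          config_hash = "unspecified", figures = TRUE) {
  if (nrow(table) == 0) stop("empty result table")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }

  curves_test <- learning_curves(table, "test_auc")
  curves_cv <- learning_curves(table, "cv_mean_auc")
  wr(dplyr::bind_rows(test = curves_test, cv = curves_cv, .id = "metric"),
     "learning_curves.csv")

  ov <- overfit_summary(table, overfit_threshold)
  ov_wide <- ov |>
    dplyr::select(dplyr::all_of(c("N", "group", "model",
                                  "share_ge_threshold"))) |>
    tidyr::pivot_wider(names_from = "model",
                       values_from = "share_ge_threshold") |>
    dplyr::arrange(.data$N, .data$group)
  wr(ov_wide, "overfit_share.csv")

  vs <- variance_summary(table)
  wr(vs$per_group, "fold_variance_per_group.csv")
  wr(vs$per_n, "fold_variance_curve.csv")

  conv <- convergence_table(table, S = S)
  wr(conv$per_group, "convergence.csv")
  wr(conv$per_model, "convergence_median_per_model.csv")

  if (!is.null(attr(table, "test_scores"))) {
    n_max <- max(table$N)
    for (g in unique(table$group)) {
      p <- delong_matrix(table, g, n_max)
      wr(as.data.frame(p), sprintf("delong_p_%s_N%d.csv", g, n_max))
    }
  }

  missing_cells <- table |>
    dplyr::count(.data$group, .data$model, .data$N) |>
    nrow()
  manifest <- list(config_hash = config_hash,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   n_cells = nrow(table),
                   n_cell_coords = missing_cells,
                   overfit_threshold = overfit_threshold,
                   kneedle_sensitivity = S,
                   variance_pooling = attr(variance_summary(table),
                                           "pooling"))
  mp <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  paths[["provenance.json"]] <- mp

  if (figures) {
    gp1 <- dplyr::bind_rows(test = curves_test, cv = curves_cv,
                            .id = "metric") |>
      ggplot2::ggplot(ggplot2::aes(x = .data$N, y = .data$y,
                                   color = .data$model,
                                   linetype = .data$metric)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(y = "mean AUC", title = "Learning curves per feature group")
    p1 <- file.path(out_dir, "learning_curves.png")
    ggplot2::ggsave(p1, gp1, width = 10, height = 6, dpi = 120)
    paths[["learning_curves.png"]] <- p1

    gp2 <- vs$per_group |>
      ggplot2::ggplot(ggplot2::aes(x = .data$N, y = .data$fold_sd,
                                   color = .data$group)) +
      ggplot2::geom_line(linetype = "dotted") +
      ggplot2::geom_line(data = vs$per_n,
                         mapping = ggplot2::aes(x = .data$N,
                                                y = .data$mean_fold_sd),
                         color = "black", inherit.aes = FALSE) +
      ggplot2::labs(y = "SD of single-fold AUCs",
                    title = "Cross-validation result variance")
    p2 <- file.path(out_dir, "variance_curve.png")
    ggplot2::ggsave(p2, gp2, width = 8, height = 5, dpi = 120)
    paths[["variance_curve.png"]] <- p2

    knees <- conv$per_group |> dplyr::filter(!is.na(.data$knee_x))
    knee_pts <- curves_test |>
      dplyr::inner_join(knees, by = c("model", "group")) |>
      dplyr::filter(.data$N == .data$knee_x)
    gp3 <- curves_test |>
      ggplot2::ggplot(ggplot2::aes(x = .data$N, y = .data$y,
                                   color = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(data = knee_pts, size = 3, shape = 1) +
      ggplot2::facet_wrap(~model) +
      ggplot2::labs(y = "mean test AUC",
                    title = "Test learning curves with knee points")
    p3 <- file.path(out_dir, "convergence_curves.png")
    ggplot2::ggsave(p3, gp3, width = 10, height = 6, dpi = 120)
    paths[["convergence_curves.png"]] <- p3
  }
  invisible(unlist(paths))
}

#' Persist / resume a ResultTable as CSV with a provenance sidecar
#'
#' @param table ResultTable.
#' @param path CSV path.
#' @param provenance List written alongside as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path, provenance = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}
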