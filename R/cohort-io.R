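#' Write a cohort to delimited text with a JSON manifest
#'
#' Unique columns across all blocks are written once to `<name>.csv`
#' (label and arm first), and `<name>_manifest.json` records the
#' group-to-column map, the generative effect vectors and the seed, so the
#' cohort round-trips exactly.
#'
#' @param cohort A `dropcurve_cohort`.
#' @param dir Output directory (created if absent).
#' @param name File stem (default `"cohort"`).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, name = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- list()
  for (b in cohort$blocks)
    for (j in colnames(b))
      if (is.null(cols[[j]])) cols[[j]] <- b[, j]
  df <- data.frame(dropout = cohort$labels, arm = as.character(cohort$arm_ids),
                   cols, check.names = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  write.csv(df, csv, row.names = FALSE)
  manifest <- list(
    seed = cohort$config$seed,
    label_assignment = cohort$config$label_assignment,
    arms = lapply(cohort$config$arms, unclass),
    groups = lapply(names(cohort$blocks), function(g)
      list(name = g, columns = colnames(cohort$blocks[[g]]),
           effect = cohort$effects[[g]])),
    dropout_fraction = mean(cohort$labels))
  js <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, manifest = js))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the files.
#' @param name File stem used at write time.
#' @return A `dropcurve_cohort`.
#' @export
read_cohort <- function(dir, name = "cohort") {
  df <- read.csv(file.path(dir, paste0(name, ".csv")), check.names = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, paste0(name, "_manifest.json")),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  arm_names <- vapply(manifest$arms, `[[`, "", "name")
  blocks <- list(); effects <- list()
  for (g in manifest$groups) {
    blocks[[g$name]] <- as.matrix(df[, unlist(g$columns), drop = FALSE])
    eff <- g$effect
    if (!is.null(eff$delta)) eff$delta <- as.numeric(unlist(eff$delta))
    effects[[g$name]] <- eff
  }
  arms <- lapply(manifest$arms, function(a)
    arm_spec(a$name, a$size, a$dropout_rate,
             a$intervention_length_weeks, a$start_year))
  structure(list(labels = as.integer(df$dropout),
                 arm_ids = factor(df$arm, levels = arm_names),
                 blocks = blocks, effects = effects,
                 config = list(seed = manifest$seed,
                               label_assignment = manifest$label_assignment,
                               arms = arms, groups = NULL)),
            class = "dropcurve_cohort")
}

#' Wrap a user-supplied tabular dataset as a cohort
#'
#' Lets the learning-curve harness run on any delimited dataset: provide a
#' data frame (or CSV path), the binary label column and a manifest
#' mapping group names to predictor column names.
#'
#' @param data A data frame or path to a delimited text file.
#' @param label_col Name of the binary (0/1) outcome column.
#' @param groups Named list: group name -> character vector of feature
#'   column names.
#' @param arm_col Optional stratification column (defaults to a single
#'   stratum).
#' @return A `dropcurve_cohort` without generative effect vectors (so
#'   [oracle_auc()] is unavailable, as the ground truth is unknown).
#' @export
as_cohort <- function(data, label_col, groups, arm_col = NULL) {
  if (is.character(data)) data <- read.csv(data, check.names = FALSE)
  if (!label_col %in% names(data)) stop("label column not found: ", label_col)
  labels <- as.integer(data[[label_col]])
  if (!all(labels %in% c(0L, 1L))) stop("label column must be binary 0/1")
  blocks <- lapply(groups, function(cols) {
    bad <- setdiff(cols, names(data))
    if (length(bad)) stop("columns not found: ", paste(bad, collapse = ", "))
    as.matrix(data[, cols, drop = FALSE])
  })
  arm_ids <- if (is.null(arm_col)) factor(rep("all", length(labels)))
             else factor(data[[arm_col]])
  structure(list(labels = labels, arm_ids = arm_ids, blocks = blocks,
                 effects = NULL, config = NULL),
            class = "dropcurve_cohort")
}
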