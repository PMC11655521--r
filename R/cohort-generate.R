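#' Generate a synthetic cohort
#'
#' Draws labels, arm membership, intervention-info columns and one feature
#' block per group from the calibrated equicorrelated binormal model.
#' Completers have feature mean 0; dropouts are shifted by the group's
#' calibrated `delta` on its informative columns. Composed groups are the
#' column concatenation of their components' blocks (same rows, no
#' re-draw). Every block additionally carries three intervention-info
#' columns (numeric arm code, length in weeks, per-user start year), which
#' hold only the weak arm-level dropout-rate signal.
#'
#' Missingness is not applied here; see [apply_missingness()]. The known
#' generative effect vectors are retained in the returned object so the
#' calibration can be audited with [oracle_auc()].
#'
#' @param config A [cohort_config()].
#' @return An object of class `dropcurve_cohort`: a list with elements
#'   `labels` (integer 0/1, 1 = dropout), `arm_ids` (factor), `blocks`
#'   (named list of numeric matrices), `effects` (named list of per-group
#'   generative ground truth), and `config`.
#' @examples
#' co <- generate_cohort(default_cohort_config(seed = 7))
#' length(co$labels)              # 3654
#' mean(co$labels)                # 0.630...
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  arm_sizes <- vapply(config$arms, `[[`, 0L, "size")
  n <- sum(arm_sizes)
  arm_names <- vapply(config$arms, `[[`, "", "name")
  arm_ids <- factor(rep(arm_names, arm_sizes), levels = arm_names)

  labels <- integer(n)
  offset <- 0L
  for (a in config$arms) {
    if (config$label_assignment == "exact_count") {
      k <- round(a$size * a$dropout_rate)
      drop_rows <- offset + sample.int(a$size, k)
      labels[drop_rows] <- 1L
    } else {
      labels[offset + seq_len(a$size)] <-
        as.integer(stats::runif(a$size) < a$dropout_rate)
    }
    offset <- offset + a$size
  }

  # shared intervention-info columns: arm code, weeks, per-user start year
  weeks <- vapply(config$arms, `[[`, 0L, "intervention_length_weeks")
  first_year <- vapply(config$arms, `[[`, 0L, "start_year")
  info <- cbind(
    arm_code = as.numeric(arm_ids),
    weeks = weeks[as.integer(arm_ids)],
    start_year = vapply(as.integer(arm_ids), function(i) {
      yrs <- first_year[i]:2019
      yrs[sample.int(length(yrs), 1L)]
    }, 0))

  blocks <- list()
  effects <- list()
  for (g in config$groups) {
    if (!is.null(g$composition)) next
    f <- g$n_features
    m <- g$n_informative
    rho <- g$correlation
    delta <- if (g$target_auc > 0.5 && m > 0)
      calibrate_effect_size(g$target_auc, m, rho) else 0
    x <- matrix(rnorm(n * f), n, f)
    if (rho > 0) {
      # one shared factor per sub-block keeps equicorrelation exact and the
      # informative and noise blocks mutually independent
      if (m > 0) {
        u <- rnorm(n)
        x[, seq_len(m)] <- sqrt(rho) * u + sqrt(1 - rho) * x[, seq_len(m)]
      }
      if (f > m) {
        v <- rnorm(n)
        x[, (m + 1):f] <- sqrt(rho) * v + sqrt(1 - rho) * x[, (m + 1):f]
      }
    }
    dvec <- c(rep(delta, m), rep(0, f - m))
    x[labels == 1L, seq_len(m)] <- x[labels == 1L, seq_len(m), drop = FALSE] + delta
    colnames(x) <- sprintf("%s_f%03d", g$name, seq_len(f))
    blocks[[g$name]] <- cbind(x, info)
    effects[[g$name]] <- list(delta = dvec, rho = rho, m = m, f = f)
  }
  for (g in config$groups) {
    if (is.null(g$composition)) next
    feat <- do.call(cbind, lapply(g$composition, function(nm)
      blocks[[nm]][, seq_len(config$groups[[nm]]$n_features), drop = FALSE]))
    blocks[[g$name]] <- cbind(feat, info)
    effects[[g$name]] <- list(composition = g$composition)
  }

  structure(list(labels = labels, arm_ids = arm_ids, blocks = blocks,
                 effects = effects, config = config),
            class = "dropcurve_cohort")
}

#' @export
print.dropcurve_cohort <- function(x, ...) {
  cat("<dropcurve_cohort> ", length(x$labels), " users, ",
      nlevels(x$arm_ids), " arms, ", length(x$blocks), " feature groups; ",
      "dropout ", sprintf("%.1f%%", 100 * mean(x$labels)), "\n", sep = "")
  for (nm in names(x$blocks))
    cat("  ", nm, ": ", ncol(x$blocks[[nm]]), " columns\n", sep = "")
  invisible(x)
}

#' Inject missing entries into one feature group
#'
#' Applies the group's `missing_spec` with exact-count masking:
#' `round(fraction * n)` users are set missing per column. Columns sharing
#' a `block` label are masked for the same users (all-or-none), emulating
#' voluntary questionnaire batteries. For columns flagged `add_indicator` a
#' binary answered (1) / not-answered (0) column named `<col>_answered` is
#' appended to the block.
#'
#' @param cohort A `dropcurve_cohort`.
#' @param group Name of a group with a `missing_spec`.
#' @return The cohort with the group's block modified.
#' @export
inject_missingness <- function(cohort, group) {
  spec <- cohort$config$groups[[group]]
  if (is.null(spec)) stop("unknown group: ", group)
  ms <- spec$missing_spec
  if (is.null(ms)) stop("group '", group, "' has no missing_spec")
  x <- cohort$blocks[[group]]
  n <- nrow(x)
  blocks <- vapply(ms, function(m) m$block %||% NA_character_, "")
  block_rows <- list()
  indicators <- list()
  for (i in seq_along(ms)) {
    m <- ms[[i]]
    k <- round(m$fraction * n)
    if (k > 0) {
      if (!is.na(blocks[i])) {
        if (is.null(block_rows[[blocks[i]]]))
          block_rows[[blocks[i]]] <- sample.int(n, k)
        rows <- block_rows[[blocks[i]]]
      } else {
        rows <- sample.int(n, k)
      }
      x[rows, m$col] <- NA_real_
    } else {
      rows <- integer(0)
    }
    if (m$add_indicator) {
      ind <- rep(1, n)
      ind[rows] <- 0
      indicators[[paste0(colnames(x)[m$col], "_answered")]] <- ind
    }
  }
  if (length(indicators))
    x <- cbind(x, do.call(cbind, indicators))
  cohort$blocks[[group]] <- x
  cohort
}

#' Apply all configured missingness and re-compose derived groups
#'
#' Runs [inject_missingness()] for every group with a `missing_spec`, then
#' rebuilds composed groups from their components' feature columns so the
#' missingness pattern is shared (indicator columns stay with the
#' component group only, preserving the composed group's declared width).
#'
#' @param cohort A `dropcurve_cohort`.
#' @return The cohort with missing entries injected.
#' @export
apply_missingness <- function(cohort) {
  set.seed(hash32(cohort$config$seed, "missingness"))
  for (g in cohort$config$groups)
    if (!is.null(g$missing_spec))
      cohort <- inject_missingness(cohort, g$name)
  n_info <- 3L
  for (g in cohort$config$groups) {
    if (is.null(g$composition)) next
    feat <- do.call(cbind, lapply(g$composition, function(nm)
      cohort$blocks[[nm]][, seq_len(cohort$config$groups[[nm]]$n_features),
                          drop = FALSE]))
    info <- cohort$blocks[[g$name]][, ncol(cohort$blocks[[g$name]]) -
                                      (n_info - 1):0, drop = FALSE]
    cohort$blocks[[g$name]] <- cbind(feat, info)
  }
  cohort
}

# Bayes-optimal linear weights for a group's feature columns (zero on the
# noise padding; Sigma^-1 delta over the informative equicorrelated block).
oracle_weights <- function(cohort, group) {
  eff <- cohort$effects[[group]]
  if (is.null(eff)) stop("unknown group: ", group)
  if (!is.null(eff$composition))
    return(unlist(lapply(eff$composition, function(nm)
      oracle_weights(cohort, nm))))
  w <- numeric(eff$f)
  if (eff$m > 0 && any(eff$delta != 0)) {
    sigma <- matrix(eff$rho, eff$m, eff$m)
    diag(sigma) <- 1
    w[seq_len(eff$m)] <- solve(sigma, eff$delta[seq_len(eff$m)])
  }
  w
}

#' Empirical AUC of the Bayes-optimal linear score (calibration audit)
#'
#' Scores every user with `Sigma^-1 delta . x` using the generator's known
#' effect vector and covariance structure, and returns the Mann-Whitney
#' AUC of that score against the dropout labels. On a cohort of the
#' default size this should sit within Monte-Carlo error of the group's
#' population AUC; it is the generator's self-audit.
#'
#' @param cohort A `dropcurve_cohort` with no missingness applied to the
#'   requested group.
#' @param group Group name.
#' @return Empirical AUC of the oracle score.
#' @export
oracle_auc <- function(cohort, group) {
  x <- cohort$blocks[[group]]
  if (is.null(x)) stop("unknown group: ", group)
  w <- oracle_weights(cohort, group)
  xf <- x[, seq_along(w), drop = FALSE]
  if (anyNA(xf))
    stop("oracle_auc requires the group without missingness; ",
         "audit before apply_missingness()")
  score <- as.numeric(xf %*% w)
  if (all(w == 0)) score <- rep(0, nrow(xf))
  auc_mann_whitney(score, cohort$labels)
}

#' Audit every group's calibration
#'
#' @param cohort A `dropcurve_cohort` (pre-missingness).
#' @return A tibble with the configured target, the analytically implied
#'   population AUC and the empirical oracle AUC per group.
#' @export
audit_cohort <- function(cohort) {
  implied <- implied_group_auc(cohort$config)
  tibble::tibble(
    group = names(cohort$blocks),
    target_auc = vapply(cohort$config$groups[names(cohort$blocks)],
                        function(g) if (is.null(g$composition))
                          g$target_auc else NA_real_, 0),
    implied_auc = implied[names(cohort$blocks)],
    oracle_auc = vapply(names(cohort$blocks),
                        function(g) oracle_auc(cohort, g), 0))
}
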