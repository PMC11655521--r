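#' Mann-Whitney AUC from scores and binary labels
#'
#' The empirical area under the ROC curve, computed via midranks in
#' O(n log n): the fraction of (positive, negative) pairs where the
#' positive outscores the negative, counting ties as one half.
#'
#' @param scores Numeric vector, higher = more positive-like.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_mann_whitney(c(0.9, 0.8, 0.1), c(1, 1, 0))   # 1
#' auc_mann_whitney(c(0.9, 0.4, 0.6), c(1, 1, 0))   # 0.5
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  n1 <- as.numeric(sum(labels == 1L))   # numeric: n1*(n1+1) can pass 2^31
  n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)                       # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties half); for each negative, the fraction of positives it beats.
# mean(v10) is the AUC. Computed via midranks, O(n log n).
placements <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  r_all <- rank(scores)
  v10 <- (r_all[pos] - rank(scores[pos])) / n0
  v01 <- 1 - (r_all[!pos] - rank(scores[!pos])) / n1
  list(v10 = v10, v01 = v01, n1 = n1, n0 = n0)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors evaluated on
#' the same test rows, via the covariance of their placement values
#' (DeLong's structural components). The statistic
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)` is referred to
#' the standard normal; `p` is two-sided. Degenerate comparisons (zero
#' variance of the difference, e.g. both AUCs equal 1) are flagged and
#' reported with `p = 1`.
#'
#' @param scores_a,scores_b Score vectors on the same rows.
#' @param labels Binary labels shared by both.
#' @return A list of class `delong_result`: `auc_a`, `auc_b`, `var_a`,
#'   `var_b`, `cov_ab`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length")
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  smat <- s10 / pa$n1 + s01 / pa$n0
  var_a <- smat[1, 1]; var_b <- smat[2, 2]; cov_ab <- smat[1, 2]
  dvar <- var_a + var_b - 2 * cov_ab
  if (!is.finite(dvar) || dvar <= .Machine$double.eps) {
    z <- if (abs(auc_a - auc_b) < 1e-12) 0 else NA_real_
    res <- list(auc_a = auc_a, auc_b = auc_b, var_a = var_a, var_b = var_b,
                cov_ab = cov_ab, z = z, p = 1, degenerate = TRUE)
  } else {
    z <- (auc_a - auc_b) / sqrt(dvar)
    res <- list(auc_a = auc_a, auc_b = auc_b, var_a = var_a, var_b = var_b,
                cov_ab = cov_ab, z = z, p = 2 * pnorm(-abs(z)),
                degenerate = FALSE)
  }
  structure(res, class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: %.4f vs %.4f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$z, x$p,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Hanley-McNeil closed-form variance of an empirical AUC
#'
#' `[theta(1-theta) + (n1-1)(Q1-theta^2) + (n0-1)(Q2-theta^2)] / (n1 n0)`
#' with `Q1 = theta/(2-theta)` and `Q2 = 2 theta^2/(1+theta)`. Used as an
#' independent magnitude oracle for fold-level AUC variability at small
#' fold sizes.
#'
#' @param auc AUC value `theta` in `(0, 1)`.
#' @param n_pos,n_neg Class counts.
#' @return Approximate sampling variance of the empirical AUC.
#' @export
hanley_mcneil_var <- function(auc, n_pos, n_neg) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Classify an AUC into predictive-power bands
#'
#' Bands on the AUC rounded to two decimals: no (<= 0.56, including
#' anything below 0.5), low (0.57-0.64), moderate (0.65-0.70), good
#' (0.71-0.75) and very good (> 0.75). The map is total and monotone.
#'
#' @param auc Numeric vector of AUCs in `[0, 1]`.
#' @return Ordered factor with levels no < low < moderate < good <
#'   very_good.
#' @examples
#' classify_auc_band(c(0.53, 0.66, 0.72, 0.81))
#' @export
classify_auc_band <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  r <- round(auc, 2)
  lab <- c("no", "low", "moderate", "good", "very_good")
  idx <- findInterval(r, c(-Inf, 0.565, 0.645, 0.705, 0.755))
  factor(lab[idx], levels = lab, ordered = TRUE)
}

#' Confusion-matrix metrics at a score threshold
#'
#' @param scores Probability-like scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5; scores `>=` threshold
#'   predict positive).
#' @return Named list: `recall`, `precision` (`NA` with a
#'   `precision_undefined` flag when nothing is predicted positive), `f1`,
#'   `balanced_accuracy`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  precision_undefined <- (tp + fp) == 0L
  precision <- if (precision_undefined) NA_real_ else tp / (tp + fp)
  f1 <- if (precision_undefined || (precision + recall) == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  list(recall = recall, precision = precision, f1 = f1,
       balanced_accuracy = (recall + specificity) / 2,
       precision_undefined = precision_undefined)
}
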