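#' Calibrate the per-feature class-mean shift for a target AUC
#'
#' Under the generator's binormal model the two classes are Gaussian with
#' unit variances, equicorrelation `rho` among the `n_features` informative
#' columns, and a uniform mean shift `delta` on each informative column.
#' The Bayes-optimal linear score then has population AUC
#' `Phi(Delta / sqrt(2))` where `Delta^2 = delta^2 * 1' Sigma^-1 1` is the
#' squared Mahalanobis separation. For the equicorrelation matrix
#' `1' Sigma^-1 1 = F / (1 - rho + rho F)`, so the inversion is closed
#' form:
#' `delta = sqrt(2) * qnorm(auc) * sqrt((1 - rho + rho F) / F)`.
#'
#' @param target_auc Desired population AUC in `[0.5, 1)`.
#' @param n_features Number of informative features `F`.
#' @param correlation Equicorrelation `rho` in `[0, 1)`.
#' @return Scalar mean shift `delta` (0 when `target_auc == 0.5`).
#' @examples
#' calibrate_effect_size(0.7602, 1, 0)   # ~1.000
#' calibrate_effect_size(0.72, 7, 0.3)
#' @export
calibrate_effect_size <- function(target_auc, n_features, correlation = 0) {
  if (!is.numeric(target_auc) || target_auc < 0.5 || target_auc >= 1)
    stop("target_auc must lie in [0.5, 1)")
  if (n_features < 1) stop("n_features must be >= 1")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  f <- n_features
  sqrt(2) * qnorm(target_auc) * sqrt((1 - correlation + correlation * f) / f)
}

#' Population AUC implied by a binormal mean-shift configuration
#'
#' Inverse of [calibrate_effect_size()]: the AUC of the optimal linear
#' score for a uniform shift `delta` on `n_features` equicorrelated
#' features.
#'
#' @inheritParams calibrate_effect_size
#' @param delta Per-feature mean shift.
#' @return Population AUC.
#' @export
binormal_auc <- function(delta, n_features, correlation = 0) {
  f <- n_features
  pnorm(abs(delta) * sqrt(f / (1 - correlation + correlation * f)) / sqrt(2))
}

#' Population AUC implied for each group of a configuration
#'
#' Equals `target_auc` for directly generated groups. For a composed group
#' the components' blocks are independent, Mahalanobis separations add in
#' quadrature, and the implied AUC is
#' `pnorm(sqrt(sum(qnorm(auc_i)^2)))` over its components.
#'
#' @param config A [cohort_config()].
#' @return Named numeric vector of population AUCs, one per group.
#' @export
implied_group_auc <- function(config) {
  vapply(config$groups, function(g) {
    if (is.null(g$composition)) return(g$target_auc)
    comps <- vapply(config$groups[g$composition], `[[`, 0, "target_auc")
    pnorm(sqrt(sum(qnorm(comps)^2)))
  }, 0)
}
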