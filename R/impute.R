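# Multivariate iterative (chained-equations) imputer with ridge
# regressions: initialize missing entries at training column means, then
# sweep over incomplete columns regressing each on all others, refreshing
# the fills, for up to max_iter sweeps or until the fills stabilize. The
# fitted state (column means + final per-column ridge coefficients) is
# applied to new data with the same sweep schedule, so no statistic ever
# leaks from rows not passed to fit.

fit_imputer <- function(x, max_iter = 10L, ridge = 1e-3, tol = 1e-3) {
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.na(mu)] <- 0                      # column entirely missing
  miss_cols <- which(colSums(is.na(x)) > 0L)
  state <- list(mu = mu, models = NULL, n_iter = 0L, ridge = ridge)
  class(state) <- "dropcurve_imputer"
  if (length(miss_cols) == 0L || nrow(x) < 3L) return(state)

  xf <- x
  for (j in seq_len(ncol(xf))) xf[is.na(x[, j]), j] <- mu[j]
  models <- vector("list", length(miss_cols))
  names(models) <- as.character(miss_cols)
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (k in seq_along(miss_cols)) {
      j <- miss_cols[k]
      obs <- !is.na(x[, j])
      z <- xf[obs, -j, drop = FALSE]
      zc <- colMeans(z)
      zs <- sweep(z, 2, zc)
      yj <- x[obs, j]
      a <- crossprod(zs) + diag(ridge * nrow(zs), ncol(zs))
      beta <- solve(a, crossprod(zs, yj - mu[j]))
      models[[k]] <- list(j = j, beta = as.numeric(beta), center = zc,
                          intercept = mu[j])
      fill_rows <- which(!obs)
      if (length(fill_rows)) {
        pred <- mu[j] + as.numeric(
          sweep(xf[fill_rows, -j, drop = FALSE], 2, zc) %*% beta)
        delta <- max(delta, max(abs(pred - xf[fill_rows, j])))
        xf[fill_rows, j] <- pred
      }
    }
    state$n_iter <- iter
    if (delta < tol) break
  }
  state$models <- models
  state
}

impute_transform <- function(state, x) {
  if (!anyNA(x)) return(x)
  na_mask <- is.na(x)
  for (j in seq_len(ncol(x))) if (any(na_mask[, j])) x[na_mask[, j], j] <- state$mu[j]
  if (is.null(state$models)) return(x)
  for (iter in seq_len(max(1L, state$n_iter))) {
    for (m in state$models) {
      rows <- which(na_mask[, m$j])
      if (!length(rows)) next
      x[rows, m$j] <- m$intercept + as.numeric(
        sweep(x[rows, -m$j, drop = FALSE], 2, m$center) %*% m$beta)
    }
  }
  if (anyNA(x)) stop("non-finite values remain after imputation")
  x
}
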