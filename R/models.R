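#' Classifier families
#'
#' The six families covered by the suite, ordered by flexibility rank
#' (1 = simplest) as used for reporting.
#'
#' @return Character vector of family names.
#' @export
model_families <- function() {
  c(naive_bayes = 1L, logistic_regression = 2L, svm = 3L,
    random_forest = 4L, adaboost = 5L, mlp = 6L)
}

#' Default hyperparameter grid for a family
#'
#' Declared defaults (the grids are deliberately modest and fully
#' overridable through the run configuration): ridge-penalized logistic
#' regression over C in \{0.01, 0.1, 1, 10\}; SVM over linear and RBF
#' kernels with C in \{0.1, 1, 10\}; random forest over 100/300 trees,
#' depth \{3, 10, unlimited\} and minimum leaf \{1, 5\}; adaBoost (SAMME
#' decision stumps) over 50/200 rounds and learning rate \{0.1, 1\};
#' single-hidden-layer MLP over 8/32 units and weight decay
#' \{1e-4, 1e-2\}; Gaussian naive Bayes over variance smoothing
#' \{1e-9, 1e-6\}. For wide inputs (more than 100 columns) the
#' regularization range of the linear models is extended one step toward
#' stronger penalties.
#'
#' @param family One of [model_families()].
#' @param n_features Number of input columns (used to widen regularization
#'   ranges for wide inputs).
#' @return List of grid points (named lists of hyperparameters).
#' @export
default_grid <- function(family, n_features = 10L) {
  wide <- n_features > 100L
  switch(family,
    naive_bayes = lapply(c(1e-9, 1e-6), function(v)
      list(var_smoothing = v)),
    logistic_regression = lapply(
      if (wide) c(0.001, 0.01, 0.1, 1, 10) else c(0.01, 0.1, 1, 10),
      function(C) list(C = C)),
    svm = {
      cc <- if (wide) c(0.01, 0.1, 1, 10) else c(0.1, 1, 10)
      c(lapply(cc, function(C) list(kernel = "linear", C = C)),
        lapply(cc, function(C) list(kernel = "radial", C = C)))
    },
    random_forest = {
      g <- expand.grid(num_trees = c(100L, 300L), max_depth = c(3L, 10L, 0L),
                       min_leaf = c(1L, 5L))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    adaboost = {
      g <- expand.grid(n_estimators = c(50L, 200L), learning_rate = c(0.1, 1))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    mlp = {
      g <- expand.grid(hidden_units = c(8L, 32L), decay = c(1e-4, 1e-2))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    stop("unknown model family: ", family))
}

#' Reduced hyperparameter grid for a family
#'
#' A 2-point-per-family grid used for smoke suites and desk-scale runs.
#'
#' @inheritParams default_grid
#' @return List of grid points.
#' @export
reduced_grid <- function(family, n_features = 10L) {
  switch(family,
    naive_bayes = lapply(c(1e-9, 1e-6), function(v) list(var_smoothing = v)),
    logistic_regression = lapply(c(0.1, 1), function(C) list(C = C)),
    svm = list(list(kernel = "linear", C = 1), list(kernel = "radial", C = 1)),
    random_forest = lapply(c(3L, 0L), function(d)
      list(num_trees = 100L, max_depth = d, min_leaf = 1L)),
    adaboost = lapply(c(0.1, 1), function(lr)
      list(n_estimators = 50L, learning_rate = lr)),
    mlp = lapply(c(1e-4, 1e-2), function(d)
      list(hidden_units = 8L, decay = d)),
    stop("unknown model family: ", family))
}

# ---- individual learners ---------------------------------------------------
# Each fit_* consumes an imputed, standardized numeric matrix and 0/1
# labels, and returns an object whose score_* yields P(dropout)-like
# scores (higher = more dropout-like).

fit_gnb <- function(x, y, var_smoothing) {
  safe_var <- function(m) {
    v <- apply(m, 2, var)
    v[!is.finite(v)] <- 0                # single-row class
    v
  }
  eps <- var_smoothing * max(safe_var(x), .Machine$double.eps)
  eps <- max(eps, 1e-12)
  list(prior1 = mean(y),
       mu0 = colMeans(x[y == 0L, , drop = FALSE]),
       mu1 = colMeans(x[y == 1L, , drop = FALSE]),
       v0 = safe_var(x[y == 0L, , drop = FALSE]) + eps,
       v1 = safe_var(x[y == 1L, , drop = FALSE]) + eps)
}

score_gnb <- function(fit, x) {
  ll <- function(mu, v) {
    -0.5 * rowSums(sweep(sweep(x, 2, mu)^2, 2, v, "/")) -
      0.5 * sum(log(2 * pi * v))
  }
  l1 <- ll(fit$mu1, fit$v1) + log(fit$prior1)
  l0 <- ll(fit$mu0, fit$v0) + log(1 - fit$prior1)
  1 / (1 + exp(pmin(pmax(l0 - l1, -500), 500)))
}

# Exhaustive weighted decision stump: for every feature, scan all split
# positions of the presorted values with cumulative weight sums; pick the
# (feature, threshold, polarity) with minimal weighted error. Sort orders
# are precomputed once per boosting run.
fit_stump <- function(x, y, w, ord) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    o <- ord[[j]]
    v <- x[o, j]
    cw1 <- cumsum(w[o] * (y[o] == 1L))
    cw0 <- cumsum(w[o] * (y[o] == 0L))
    w1 <- cw1[length(cw1)]; w0 <- cw0[length(cw0)]
    pos <- which(diff(v) > 0)                  # splits between distinct values
    # rule "x > t -> 1": err = w(y=1, x<=t) + w(y=0, x>t); position 0 = no split
    err_r <- c(w0, cw1[pos] + (w0 - cw0[pos]))
    thr <- c(v[1] - 1, (v[pos] + v[pos + 1]) / 2)
    err <- pmin(err_r, (w0 + w1) - err_r)
    i <- which.min(err)
    if (err[i] < best$err)
      best <- list(err = err[i], j = j, threshold = thr[i],
                   flip = err_r[i] > (w0 + w1) - err_r[i])
  }
  best
}

predict_stump <- function(st, x) {
  p <- as.integer(x[, st$j] > st$threshold)
  if (st$flip) 1L - p else p
}

fit_adaboost <- function(x, y, n_estimators, learning_rate) {
  # discrete SAMME boosting of depth-1 stumps
  n <- nrow(x)
  w <- rep(1 / n, n)
  ord <- lapply(seq_len(ncol(x)), function(j) order(x[, j]))
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    st <- fit_stump(x, y, w, ord)
    if (!is.finite(st$err)) break
    pred <- predict_stump(st, x)
    err <- sum(w[pred != y])
    if (err <= 1e-10) { stumps[[m]] <- st; alphas[m] <- 10; break }
    if (err >= 0.5) break
    alpha <- learning_rate * log((1 - err) / err)
    stumps[[m]] <- st; alphas[m] <- alpha
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (!length(stumps))                  # no usable weak learner: prior vote
    return(list(stumps = list(), alphas = numeric(0), prior1 = mean(y)))
  list(stumps = stumps, alphas = alphas, prior1 = mean(y))
}

score_adaboost <- function(fit, x) {
  if (!length(fit$stumps)) return(rep(fit$prior1, nrow(x)))
  f <- numeric(nrow(x))
  for (m in seq_along(fit$stumps))
    f <- f + fit$alphas[m] * (2 * predict_stump(fit$stumps[[m]], x) - 1)
  1 / (1 + exp(-2 * f / sum(fit$alphas)))
}

# ---- pipeline --------------------------------------------------------------

#' Fit the impute -> standardize -> classify pipeline
#'
#' Fits the multivariate iterative imputer and the standard scaler on the
#' supplied rows only (no statistic is computed from rows not passed in,
#' so validation folds and the holdout never leak into preprocessing),
#' then trains the requested family at one hyperparameter point.
#'
#' @param family One of [model_families()].
#' @param hyper One grid point, e.g. an element of [default_grid()].
#' @param x Numeric feature matrix (may contain `NA`).
#' @param y Binary labels (0/1).
#' @param seed Integer seed for any stochastic learner.
#' @return An object of class `dropcurve_fit`; score new rows with
#'   [predict_scores()].
#' @export
fit_pipeline <- function(family, hyper, x, y, seed = 1L) {
  y <- as.integer(y)
  set.seed(seed)
  imp <- fit_imputer(x)
  xi <- impute_transform(imp, x)
  if (any(!is.finite(xi))) stop("non-finite values after imputation")
  center <- colMeans(xi)
  scale_ <- apply(xi, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(xi, 2, center), 2, scale_, "/")
  warn <- character(0)
  model <- switch(family,
    naive_bayes = fit_gnb(xs, y, hyper$var_smoothing),
    logistic_regression = {
      n <- nrow(xs)
      xg <- if (ncol(xs) == 1L) cbind(xs, `.pad` = 0) else xs  # glmnet needs >= 2 cols
      glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                     lambda = 1 / (hyper$C * n), standardize = FALSE)
    },
    svm = e1071::svm(xs, factor(y, levels = c(0L, 1L)),
                     kernel = hyper$kernel, cost = hyper$C,
                     gamma = 1 / ncol(xs), scale = FALSE),
    random_forest = ranger::ranger(
      x = xs, y = factor(y, levels = c(0L, 1L)),
      num.trees = hyper$num_trees,
      max.depth = if (hyper$max_depth == 0L) NULL else hyper$max_depth,
      min.node.size = hyper$min_leaf, probability = TRUE,
      num.threads = 1L, seed = seed),
    adaboost = fit_adaboost(xs, y, hyper$n_estimators, hyper$learning_rate),
    mlp = {
      fit <- withCallingHandlers(
        nnet::nnet(xs, y, size = hyper$hidden_units, decay = hyper$decay,
                   entropy = TRUE, maxit = 200, trace = FALSE,
                   MaxNWts = 100000),
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (fit$convergence != 0)
        warn <- c(warn, "mlp: optimizer stopped at maxit without convergence")
      fit
    },
    stop("unknown model family: ", family))
  structure(list(family = family, hyper = hyper, imputer = imp,
                 center = center, scale = scale_, model = model,
                 warnings = warn),
            class = "dropcurve_fit")
}

#' Score new rows with a fitted pipeline
#'
#' @param fit A `dropcurve_fit` from [fit_pipeline()].
#' @param x New feature matrix (same columns as at fit time).
#' @return Numeric vector of probability-like scores in `[0, 1]`, higher =
#'   more dropout-like.
#' @export
predict_scores <- function(fit, x) {
  xi <- impute_transform(fit$imputer, x)
  xs <- sweep(sweep(xi, 2, fit$center), 2, fit$scale, "/")
  s <- switch(fit$family,
    naive_bayes = score_gnb(fit$model, xs),
    logistic_regression = {
      if (ncol(xs) == 1L) xs <- cbind(xs, `.pad` = 0)
      as.numeric(predict(fit$model, xs, type = "response"))
    },
    svm = {
      # logistic link on the margin: monotone in the decision value, so the
      # AUC is that of the raw SVM score, and margin 0 maps to score 0.5
      dv <- attr(predict(fit$model, xs, decision.values = TRUE),
                 "decision.values")
      s <- as.numeric(dv[, 1])
      if (colnames(dv)[1] == "0/1") s <- -s   # positive margin = class "0"
      stats::plogis(s)
    },
    random_forest = {
      p <- predict(fit$model, data = xs, num.threads = 1L)$predictions
      as.numeric(p[, "1"])
    },
    adaboost = score_adaboost(fit$model, xs),
    mlp = as.numeric(predict(fit$model, xs)))
  unname(s)
}
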