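#' Global knee point of a concave-increasing curve (Kneedle)
#'
#' Min-max normalizes x and y, forms the difference curve
#' `d = y_norm - x_norm`, takes candidate knees at interior local maxima
#' of `d` whose height exceeds the sensitivity-scaled mean grid spacing
#' `S * mean(diff(x_norm))`, and returns the candidate with the largest
#' difference (the global knee). Curves with no qualifying candidate --
#' including exactly linear and convex/decreasing curves -- return no
#' knee rather than fabricating one.
#'
#' @param x Strictly increasing numeric vector (>= 4 points).
#' @param y Curve values at `x` (e.g. mean test AUC per N).
#' @param S Sensitivity (default 1); larger demands a more pronounced
#'   knee.
#' @param interpolation `"raw"` (default) uses the points as given;
#'   `"smoothed"` applies a cubic smoothing spline first.
#' @return List of class `knee_result`: `knee_x` (or `NA` if none),
#'   `knee_index`, `d` (the difference curve), `S`, `interpolation`.
#' @examples
#' x <- c(100, 200, 300, 400, 500, 750, 1000, 1500, 2000, 2500, 3000, 3654)
#' y <- 1 - exp(-x / 400)
#' kneedle_global(x, y)$knee_x
#' @export
kneedle_global <- function(x, y, S = 1,
                           interpolation = c("raw", "smoothed")) {
  interpolation <- match.arg(interpolation)
  if (length(x) < 4L) stop("need at least 4 points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (interpolation == "smoothed")
    y <- stats::smooth.spline(x, y)$y
  res <- list(knee_x = NA_real_, knee_index = NA_integer_, d = NULL,
              S = S, interpolation = interpolation)
  class(res) <- "knee_result"
  if (diff(range(y)) == 0) return(res)
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  d <- yn - xn
  res$d <- d
  n <- length(d)
  i <- 2:(n - 1)
  is_lmx <- d[i] > d[i - 1] & d[i] >= d[i + 1]
  cand <- i[is_lmx]
  thr <- S * mean(diff(xn))
  cand <- cand[d[cand] > thr]
  if (!length(cand)) return(res)
  best <- cand[which.max(d[cand])]
  res$knee_x <- x[best]
  res$knee_index <- best
  res
}

#' @export
print.knee_result <- function(x, ...) {
  if (is.na(x$knee_x)) cat("<knee_result> no knee detected (S =", x$S, ")\n")
  else cat("<knee_result> knee at x =", x$knee_x, "(S =", x$S, ")\n")
  invisible(x)
}

#' Relative curve gain after the knee
#'
#' `100 * (y(max x) - y(knee)) / y(knee)`: the percentage AUC improvement
#' still available between the convergence point and the largest dataset
#' size.
#'
#' @param x,y The curve (as in [kneedle_global()]).
#' @param knee_x The detected knee (must be an element of `x`).
#' @return Percentage gain (0 for a flat tail).
#' @export
post_knee_gain <- function(x, y, knee_x) {
  if (is.na(knee_x)) stop("knee_x is missing")
  i <- match(knee_x, x)
  if (is.na(i)) stop("knee_x must be one of the curve's x values")
  100 * (y[length(y)] - y[i]) / y[i]
}

#' Convergence table: knees per (model, group) and per-model medians
#'
#' Computes the mean test learning curve per (model, group), detects its
#' global knee, and summarizes each model by the median knee across
#' informative groups. Groups whose curve never exceeds the "no"
#' predictive-power band are excluded from the medians (there is nothing
#' to converge towards); undetected knees are excluded with a flag. The
#' median of an even count is the lower of the two central values, so it
#' is always a grid point.
#'
#' @param table A ResultTable from [run_experiment()].
#' @param S Kneedle sensitivity (default 1).
#' @param informative_cutoff Curves with max mean test AUC at or below
#'   this value count as uninformative (default 0.565, the upper edge of
#'   the "no" band).
#' @return List with tibbles `per_group` (`model`, `group`, `knee_x`,
#'   `post_knee_gain_pct`, `informative`) and `per_model` (`model`,
#'   `median_knee`).
#' @export
convergence_table <- function(table, S = 1, informative_cutoff = 0.565) {
  curves <- learning_curves(table, "test_auc")
  per_group <- curves |>
    dplyr::group_by(.data$model, .data$group) |>
    dplyr::group_modify(function(df, key) {
      kr <- tryCatch(kneedle_global(df$N, df$y, S = S),
                     error = function(e) list(knee_x = NA_real_))
      tibble::tibble(
        knee_x = kr$knee_x,
        post_knee_gain_pct = if (is.na(kr$knee_x)) NA_real_
          else post_knee_gain(df$N, df$y, kr$knee_x),
        informative = max(df$y) > informative_cutoff)
    }) |>
    dplyr::ungroup()
  per_model <- per_group |>
    dplyr::filter(.data$informative, !is.na(.data$knee_x)) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(median_knee = lower_median(.data$knee_x),
                     n_groups = dplyr::n(), .groups = "drop")
  list(per_group = per_group, per_model = per_model)
}
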