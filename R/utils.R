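#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm rnorm sd var predict coef complete.cases
#' @importFrom utils write.csv read.csv head modifyList
#' @importFrom dplyr .data
NULL

# Deterministic 32-bit string hash (polynomial rolling hash mod a Mersenne
# prime). Used to derive per-cell RNG seeds that depend only on the cell's
# identity, never on loop order.
hash32 <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Largest-remainder apportionment of `total` into parts proportional to
# `weights`. Guarantees sum(result) == total and |result - exact| < 1.
largest_remainder <- function(total, weights) {
  if (total == 0) return(integer(length(weights)))
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Median that returns the lower of the two central values for even counts,
# so a median over grid positions is itself a grid position.
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  x[ceiling(n / 2)]
}

# Stratified k-fold assignment: within each class, shuffled row indices are
# dealt round-robin so fold class counts differ by at most one.
stratified_fold_ids <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
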