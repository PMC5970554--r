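#' Sample Entropy parameters
#'
#' @param m Embedding (template) dimension, default 1.
#' @param r_coeff Tolerance as a multiple of the window standard deviation,
#'   default 0.1.
#' @param N Window length in samples, default 3750 (30 s at 128 Hz).
#' @return An object of class `sampen_params`.
#' @export
sampen_params <- function(m = 1, r_coeff = 0.1, N = 3750) {
  stopifnot(m >= 1, r_coeff > 0, N > m + 1)
  structure(list(m = as.integer(m), r_coeff = r_coeff, N = as.integer(N)),
            class = "sampen_params")
}

#' Sample Entropy of a time series
#'
#' Negative log conditional probability that two template vectors matching
#' within tolerance `r` for `m` points (Chebyshev distance, self-matches
#' excluded) also match for `m + 1` points. Both template dimensions use
#' `N - m` vectors (Richman-Moorman convention), so the match counts are
#' comparable. Regular signals give low values; irregular signals high ones.
#'
#' The tolerance defaults to `r_coeff` times the population standard
#' deviation of the window itself, which makes the statistic invariant under
#' rescaling of the signal. A constant window therefore returns 0 (every
#' template matches every other at any dimension). If no `m + 1` match
#' exists the value is undefined and `NaN` is returned; downstream feature
#' extraction drops such windows.
#'
#' @param x Numeric signal of length >= m + 2.
#' @param m Template dimension (default 1).
#' @param r_coeff Tolerance multiplier on the window's population std
#'   (default 0.1). Ignored when `r` is given.
#' @param r Optional absolute tolerance override.
#' @return Non-negative scalar, or `NaN` when undefined.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(500))            # irregular: high
#' sample_entropy(sin(seq(0, 20, 0.1)))  # regular: low
#' @export
sample_entropy <- function(x, m = 1, r_coeff = 0.1, r = NULL) {
  x <- as.numeric(x)
  N <- length(x)
  m <- as.integer(m)
  if (N < m + 2) stop("series too short for sample entropy")
  if (is.null(r)) {
    s <- pop_sd(x)
    if (s == 0) return(0)
    r <- r_coeff * s
  }
  cnt <- .cpp_sampen_counts(x, m, r)
  if (cnt$B == 0 || cnt$A == 0) return(NaN)
  -log(cnt$A / cnt$B)
}

#' Permutation Entropy parameters
#'
#' @param m Ordinal pattern order, default 6.
#' @param tau Lag between pattern elements, default 1.
#' @return An object of class `pen_params`.
#' @export
pen_params <- function(m = 6, tau = 1) {
  stopifnot(m >= 2, tau >= 1)
  structure(list(m = as.integer(m), tau = as.integer(tau)),
            class = "pen_params")
}

#' Permutation Entropy of a time series
#'
#' Shannon entropy (natural log) of the empirical distribution of ordinal
#' patterns of order `m` at lag `tau`. Equal values are ranked by order of
#' occurrence (the earlier index ranks lower).
#'
#' @param x Numeric signal of length >= (m-1)*tau + 2.
#' @param m Pattern order (default 6).
#' @param tau Lag (default 1).
#' @param normalized Divide by `log(factorial(m))` so the value lies in
#'   \[0, 1\] (default `FALSE`).
#' @return Non-negative scalar; 0 for a strictly monotone series.
#' @export
permutation_entropy <- function(x, m = 6, tau = 1, normalized = FALSE) {
  x <- as.numeric(x)
  m <- as.integer(m)
  tau <- as.integer(tau)
  span <- (m - 1) * tau
  if (length(x) < span + 2) stop("series too short for permutation entropy")
  n_pat <- length(x) - span
  emb <- matrix(0, n_pat, m)
  for (k in seq_len(m)) emb[, k] <- x[seq_len(n_pat) + (k - 1) * tau]
  pats <- apply(emb, 1, function(v) paste(order(v), collapse = "."))
  p <- table(pats) / n_pat
  h <- -sum(p * log(p))
  if (normalized) h <- h / log(factorial(m))
  h
}
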