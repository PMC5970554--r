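#' Recurrence quantification parameters
#'
#' @param dim Embedding dimension (default 3).
#' @param delay Embedding delay in samples (default 5).
#' @param eps Recurrence threshold (default 0.5). With `zscore = TRUE` the
#'   window is standardised first, so the threshold is scale-free.
#' @param lmin Minimum diagonal line length for determinism (default 2).
#' @param zscore Standardise each window before embedding (default `TRUE`).
#' @return An object of class `rqa_params`.
#' @export
rqa_params <- function(dim = 3, delay = 5, eps = 0.5, lmin = 2,
                       zscore = TRUE) {
  stopifnot(dim >= 1, delay >= 1, eps > 0, lmin >= 2)
  structure(list(dim = as.integer(dim), delay = as.integer(delay),
                 eps = eps, lmin = as.integer(lmin), zscore = zscore),
            class = "rqa_params")
}

#' Time-delay embedding
#'
#' Point `i` is `(x_i, x_{i+delay}, ..., x_{i+(dim-1)*delay})`; the number of
#' points is `length(x) - (dim-1)*delay`.
#'
#' @param x Numeric signal.
#' @param dim Embedding dimension.
#' @param delay Delay in samples.
#' @return Matrix with one embedded point per row.
#' @export
delay_embed <- function(x, dim = 3, delay = 5) {
  x <- as.numeric(x)
  span <- (dim - 1) * delay
  if (length(x) < span + 1) stop("series too short for this embedding")
  np <- length(x) - span
  out <- matrix(0, np, dim)
  for (k in seq_len(dim)) out[, k] <- x[seq_len(np) + (k - 1) * delay]
  out
}

#' Recurrence matrix
#'
#' `R[i, j]` is `TRUE` when the Euclidean distance between embedded points
#' `i` and `j` is at most `eps`. The matrix is symmetric with a `TRUE`
#' diagonal (the line of identity), which downstream measures exclude.
#'
#' @param points Matrix of embedded points (rows), e.g. from
#'   [delay_embed()].
#' @param eps Distance threshold.
#' @return Logical matrix.
#' @export
recurrence_matrix <- function(points, eps) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  d <- as.matrix(stats::dist(points))
  d <= eps
}

#' Recurrence rate
#'
#' Fraction of off-diagonal cells of the recurrence matrix that are
#' recurrent: `RR = #\{R[i,j] = TRUE, i != j\} / (n (n-1))`.
#'
#' @param R Square logical matrix.
#' @return Fraction in \[0, 1\].
#' @export
recurrence_rate <- function(R) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (n < 2 || ncol(R) != n) stop("R must be a square matrix with n >= 2")
  (sum(R) - sum(diag(R))) / (n * (n - 1))
}

#' Determinism
#'
#' Fraction of off-diagonal recurrence points lying on diagonal lines of
#' length at least `lmin`. The line of identity is excluded. Returns 0 when
#' there are no off-diagonal recurrence points.
#'
#' @param R Square logical matrix.
#' @param lmin Minimum diagonal line length (default 2).
#' @return Fraction in \[0, 1\].
#' @export
determinism <- function(R, lmin = 2) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (n < 2 || ncol(R) != n) stop("R must be a square matrix with n >= 2")
  total <- 0
  on_lines <- 0
  for (off in c(-(n - 1):-1, 1:(n - 1))) {
    i <- if (off > 0) seq_len(n - off) else seq(1 - off, n)
    d <- R[cbind(i, i + off)]
    total <- total + sum(d)
    r <- rle(d)
    keep <- r$values & r$lengths >= lmin
    on_lines <- on_lines + sum(r$lengths[keep])
  }
  if (total == 0) return(0)
  on_lines / total
}

#' Window-level RQA features
#'
#' Convenience wrapper computing recurrence rate and determinism of one
#' analysis window without materialising the full recurrence matrix
#' (diagonal-scan, compiled). With `zscore = TRUE` the window is
#' standardised first so `eps` acts on a unit-variance signal.
#'
#' @param x Numeric window.
#' @param params An [rqa_params()].
#' @return List with elements `rr` and `det`.
#' @export
rqa_features <- function(x, params = rqa_params()) {
  x <- as.numeric(x)
  if (params$zscore) {
    s <- pop_sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  pts <- delay_embed(x, params$dim, params$delay)
  r <- .cpp_rqa_measures(pts, params$eps, params$lmin)
  list(rr = r$rr, det = r$det)
}
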