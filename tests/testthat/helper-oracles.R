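# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition by naive enumeration, sharing no code with
# the package implementations they check.

# Sample entropy by naive O(N^2) pair counting: N - m templates for both
# dimensions m and m + 1, Chebyshev distance, self-matches excluded.
oracle_sampen <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dmax <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dmax <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NaN)
  -log(A / B)
}

# strict three-point extrema scan (no plateau handling; use on continuous
# random data where plateaus have probability zero)
oracle_extrema <- function(x) {
  n <- length(x)
  mx <- integer(0)
  mn <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx <- c(mx, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn <- c(mn, i)
  }
  list(maxima = mx, minima = mn)
}

# permutation entropy by explicit pattern-histogram counting; ranks with
# earlier-index-wins tie breaking
oracle_pen <- function(x, m, tau) {
  np <- length(x) - (m - 1) * tau
  pats <- character(np)
  for (i in seq_len(np)) {
    v <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(rank(v, ties.method = "first"), collapse = "-")
  }
  p <- as.numeric(table(pats)) / np
  -sum(p * log(p))
}

# determinism by walking every diagonal of the recurrence matrix cell by
# cell and accumulating run lengths
oracle_det <- function(R, lmin = 2) {
  n <- nrow(R)
  total <- 0
  on_lines <- 0
  for (off in setdiff(-(n - 1):(n - 1), 0)) {
    run <- 0
    idx <- if (off > 0) seq_len(n - off) else seq(1 - off, n)
    for (i in idx) {
      if (R[i, i + off]) {
        total <- total + 1
        run <- run + 1
      } else {
        if (run >= lmin) on_lines <- on_lines + run
        run <- 0
      }
    }
    if (run >= lmin) on_lines <- on_lines + run
  }
  if (total == 0) return(0)
  on_lines / total
}

# AUC by exhaustive enumeration of positive/negative pairs, ties half
oracle_auc <- function(index, ref, threshold = 65) {
  pos <- index[ref >= threshold]
  neg <- index[ref < threshold]
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

pop_sd_test <- function(x) sqrt(mean((x - mean(x))^2))

# power fraction below f_hi via a plain periodogram (bare fft)
oracle_lowfreq_fraction <- function(x, fs, f_hi = 4) {
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  keep <- f > 0 & f <= fs / 2
  sum(p[keep & f < f_hi]) / sum(p[keep])
}
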