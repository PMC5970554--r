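#' Sifting configuration for empirical mode decomposition
#'
#' @param max_imfs Maximum number of intrinsic mode functions to extract
#'   (default 8).
#' @param max_sift_iters Maximum sifting iterations per IMF (default 100).
#' @param sd_threshold Cauchy-type stop criterion: sifting stops once
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` drops below this value (default
#'   0.2, the standard choice).
#' @param boundary Boundary handling; only `"mirror"` (extrema reflected
#'   about the signal ends) is implemented.
#' @return An object of class `sift_config`.
#' @export
sift_config <- function(max_imfs = 8, max_sift_iters = 100,
                        sd_threshold = 0.2, boundary = "mirror") {
  stopifnot(max_imfs >= 1, max_sift_iters >= 1, sd_threshold > 0)
  boundary <- match.arg(boundary, "mirror")
  structure(list(max_imfs = as.integer(max_imfs),
                 max_sift_iters = as.integer(max_sift_iters),
                 sd_threshold = sd_threshold, boundary = boundary),
            class = "sift_config")
}

#' Noise-assisted multivariate EMD configuration
#'
#' @param n_noise_channels Number of independent Gaussian noise channels
#'   appended to the data channel (default 2).
#' @param noise_std_rel Noise standard deviation as a fraction of the data
#'   channel's standard deviation (default 0.1).
#' @param n_directions Number of quasi-uniform direction vectors on the
#'   sphere used for the multivariate envelopes (default 64).
#' @param seed Seed controlling both the noise channels and the direction
#'   set; the decomposition is deterministic given the seed.
#' @return An object of class `memd_config`.
#' @export
memd_config <- function(n_noise_channels = 2, noise_std_rel = 0.1,
                        n_directions = 64, seed = 42L) {
  stopifnot(n_noise_channels >= 1, noise_std_rel > 0, n_directions >= 8)
  structure(list(n_noise_channels = as.integer(n_noise_channels),
                 noise_std_rel = noise_std_rel,
                 n_directions = as.integer(n_directions),
                 seed = as.integer(seed)),
            class = "memd_config")
}

#' Locate strict local extrema
#'
#' Strict local maxima and minima by neighbour comparison; a plateau of equal
#' values flanked by lower (higher) neighbours contributes its midpoint
#' index. Endpoints are never extrema.
#'
#' @param x Numeric signal of length >= 3.
#' @return List with integer vectors `maxima` and `minima` (1-based indices).
#' @export
find_extrema <- function(x) {
  if (length(x) < 3) stop("signal must have length >= 3")
  .cpp_find_extrema(as.numeric(x))
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' The upper (lower) envelope is a natural cubic spline through the local
#' maxima (minima), with up to two extrema mirror-reflected about each
#' signal end so the envelopes span the full signal.
#'
#' @param x Numeric signal.
#' @return The mean envelope, or `NULL` when the signal has fewer than two
#'   maxima or two minima (the signal to stop sifting).
#' @export
envelope_mean <- function(x) {
  m <- .cpp_envelope_mean(as.numeric(x))
  if (length(m) == 0) NULL else m
}

new_imf_set <- function(imfs, residual, source_length) {
  structure(list(imfs = imfs, residual = residual,
                 source_length = source_length),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual (length %d)\n",
              length(x$imfs), x$source_length))
  invisible(x)
}

#' Univariate empirical mode decomposition
#'
#' Iteratively sifts (subtracting the mean spline envelope) until the
#' Cauchy-type SD criterion or the iteration cap is met, extracts the IMF,
#' and repeats on the residual until it is monotone (fewer than two maxima
#' or minima) or `max_imfs` is reached. The IMFs plus the residual
#' reconstruct the input to numerical precision (completeness).
#'
#' @param x Finite numeric signal, length >= 8.
#' @param cfg A [sift_config()].
#' @return An object of class `imf_set`: list with `imfs` (list of signals,
#'   index 1 = fastest mode), `residual`, `source_length`.
#' @export
emd_decompose <- function(x, cfg = sift_config()) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("input must be finite")
  if (length(x) < 8) stop("input too short for decomposition")
  r <- .cpp_emd(x, cfg$max_imfs, cfg$max_sift_iters, cfg$sd_threshold)
  new_imf_set(r$imfs, r$residual, length(x))
}

# first `n` primes, for Halton bases
first_primes <- function(n) {
  p <- integer(0)
  k <- 2L
  while (length(p) < n) {
    if (all(k %% p != 0)) p <- c(p, k)
    k <- k + 1L
  }
  p
}

halton_seq <- function(n, dims, start) {
  bases <- first_primes(dims)
  out <- matrix(0, n, dims)
  for (d in seq_len(dims)) {
    b <- bases[d]
    for (i in seq_len(n)) {
      k <- start + i - 1L
      f <- 1
      r <- 0
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      out[i, d] <- r
    }
  }
  out
}

#' Quasi-uniform direction vectors on the unit sphere
#'
#' Low-discrepancy set of unit vectors used to sample the multivariate
#' envelopes. In two dimensions the directions are equally spaced angles
#' with a seed-dependent offset; in higher dimensions a Halton sequence
#' (seed-dependent start index) is mapped through the inverse normal CDF and
#' normalised, giving quasi-uniform points on the sphere.
#'
#' @param n Number of directions (>= 8).
#' @param dims Ambient dimension (>= 2).
#' @param seed Integer seed; the same seed always returns the same set.
#' @return An `n` x `dims` matrix of unit row vectors.
#' @export
direction_vectors <- function(n, dims, seed = 42L) {
  stopifnot(n >= 8, dims >= 2)
  seed <- as.integer(seed)
  if (dims == 2) {
    offset <- (seed * 0.6180339887498949) %% 1
    th <- 2 * pi * (seq_len(n) - 1 + offset) / n
    return(cbind(cos(th), sin(th)))
  }
  u <- halton_seq(n, dims, start = 20L + (seed %% 1000L))
  z <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  z / sqrt(rowSums(z^2))
}

#' Noise-assisted multivariate EMD of a single-channel signal
#'
#' Appends `n_noise_channels` independent Gaussian noise channels (std =
#' `noise_std_rel` times the data std) to the signal, then applies
#' multivariate sifting: the signal is projected onto each direction vector,
#' every channel is spline-interpolated at the projection maxima, and the
#' local mean is the average of these envelopes over all directions. The
#' noise channels regularise the dyadic filter bank and curb mode mixing;
#' their IMFs are discarded and only the data channel's decomposition is
#' returned. Completeness holds for the data channel.
#'
#' @param x Finite numeric signal, length >= 8.
#' @param cfg A [memd_config()].
#' @param sift A [sift_config()].
#' @return An `imf_set` for the data channel.
#' @export
na_memd_decompose <- function(x, cfg = memd_config(), sift = sift_config()) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("input must be finite")
  if (length(x) < 8) stop("input too short for decomposition")
  n <- length(x)
  p <- 1L + cfg$n_noise_channels
  noise_sd <- cfg$noise_std_rel * pop_sd(x)
  if (noise_sd == 0) noise_sd <- cfg$noise_std_rel # constant input
  X <- with_seed(cfg$seed,
                 cbind(x, matrix(rnorm(n * cfg$n_noise_channels, sd = noise_sd),
                                 n, cfg$n_noise_channels)))
  dirs <- direction_vectors(cfg$n_directions, p, cfg$seed)
  res <- .cpp_memd(X, dirs, sift$max_imfs, sift$max_sift_iters,
                   sift$sd_threshold)
  ch1 <- res[[1]]
  new_imf_set(ch1$imfs, ch1$residual, n)
}

#' Reconstruct a signal from selected IMFs
#'
#' @param imfset An `imf_set`.
#' @param indices 1-based IMF indices to sum (default `c(2, 3)`, the
#'   band retained for artefact-filtered EEG).
#' @param include_residual Add the residual trend to the sum (default
#'   `FALSE`; the residual is never included implicitly).
#' @return Numeric signal: the elementwise sum of the selected components.
#' @export
reconstruct <- function(imfset, indices = c(2, 3), include_residual = FALSE) {
  if (!inherits(imfset, "imf_set")) stop("imfset must be an imf_set")
  if (length(indices) == 0 && !include_residual)
    stop("indices must be non-empty (or include_residual = TRUE)")
  if (length(indices) > 0 &&
      (any(indices < 1) || any(indices > length(imfset$imfs))))
    stop("IMF index out of range")
  out <- numeric(imfset$source_length)
  for (i in indices) out <- out + imfset$imfs[[i]]
  if (include_residual) out <- out + imfset$residual
  out
}

#' Epoch-wise N-A-MEMD filtering of an EEG record
#'
#' Splits the record into consecutive non-overlapping epochs of
#' `memd_epoch_s`, decomposes each with [na_memd_decompose()], reconstructs
#' the selected IMFs (default IMF2+IMF3), and concatenates the filtered
#' epochs. Epochs from which none of the requested IMFs can be extracted are
#' output as zeros and fully masked; a trailing partial epoch is passed
#' through unfiltered and fully masked. The existing mask is carried through
#' unchanged; the per-epoch noise seed is derived from `cfg$seed` plus the
#' epoch index, so the whole record filters deterministically.
#'
#' @param record An [eeg_record()].
#' @param spec A [window_spec()]; `memd_epoch_s` sets the epoch length.
#' @param cfg A [memd_config()].
#' @param sift A [sift_config()].
#' @param indices IMFs retained in the reconstruction (default `c(2, 3)`).
#' @return A filtered [eeg_record()].
#' @export
filter_epochwise <- function(record, spec = window_spec(),
                             cfg = memd_config(), sift = sift_config(),
                             indices = c(2, 3)) {
  ne <- round(spec$memd_epoch_s * record$fs)
  n <- length(record$samples)
  if (n < ne) stop("record shorter than one decomposition epoch")
  n_full <- n %/% ne
  out <- numeric(n)
  mask <- record$artefact_mask
  for (e in seq_len(n_full)) {
    i0 <- (e - 1L) * ne + 1L
    i1 <- e * ne
    ecfg <- cfg
    ecfg$seed <- as.integer((cfg$seed + e) %% .Machine$integer.max)
    dec <- na_memd_decompose(record$samples[i0:i1], ecfg, sift)
    avail <- intersect(indices, seq_along(dec$imfs))
    filt <- if (length(avail) > 0) reconstruct(dec, avail) else numeric(ne)
    out[i0:i1] <- filt
    # no requested IMF, or a degenerate (zero-variance) reconstruction:
    # the epoch carries no signal for feature extraction, so mask it
    if (length(avail) == 0 || pop_sd(filt) == 0) mask[i0:i1] <- TRUE
  }
  if (n_full * ne < n) {
    tail_idx <- (n_full * ne + 1L):n
    out[tail_idx] <- record$samples[tail_idx]
    mask[tail_idx] <- TRUE
  }
  eeg_record(out, fs = record$fs, start_time = record$start_time,
             artefact_mask = mask)
}
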