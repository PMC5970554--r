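#' Single-channel EEG record
#'
#' Container for a uniformly sampled EEG signal in µV, with its sampling
#' rate, start time and a per-sample artefact mask (`TRUE` = excluded from
#' analysis).
#'
#' @param samples Numeric vector of samples in µV. Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample, seconds (default 0).
#' @param artefact_mask Logical vector the same length as `samples`; defaults
#'   to all `FALSE`.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, start_time = 0, artefact_mask = NULL) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite (no NaN/NA)")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (is.null(artefact_mask)) artefact_mask <- rep(FALSE, length(samples))
  if (length(artefact_mask) != length(samples))
    stop("artefact_mask length must equal samples length")
  structure(list(samples = samples, fs = fs, start_time = start_time,
                 artefact_mask = as.logical(artefact_mask)),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d samples at %g Hz (%.1f s), %d masked\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              sum(x$artefact_mask)))
  invisible(x)
}

#' Sliding-window specification
#'
#' The analysis geometry used throughout the pipeline: decomposition is done
#' on short consecutive epochs (`memd_epoch_s`), entropy features on longer
#' sliding windows (`win_s`) advanced by `step_s` so each window lines up
#' with one reference-index sample.
#'
#' @param win_s Feature window length, seconds (default 30).
#' @param step_s Window step, seconds (default 5, the reference-index
#'   sampling interval).
#' @param memd_epoch_s Decomposition epoch length, seconds (default 5). Must
#'   divide `win_s`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(win_s = 30, step_s = 5, memd_epoch_s = 5) {
  if (!(win_s >= step_s && step_s > 0))
    stop("need win_s >= step_s > 0")
  if (abs(win_s / memd_epoch_s - round(win_s / memd_epoch_s)) > 1e-9)
    stop("win_s must be an integer multiple of memd_epoch_s")
  structure(list(win_s = win_s, step_s = step_s, memd_epoch_s = memd_epoch_s),
            class = "window_spec")
}

#' Read an EEG file
#'
#' Reads a single-channel EEG record from either a two-column CSV
#' (`time_s,uV`, header required) or a single-channel EDF file. For CSV the
#' sampling rate is inferred from the time column, which must be uniform to
#' within 1e-6 relative; for EDF it is taken from the header.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param channel EDF channel to use (default 1, the first).
#' @return An [eeg_record()] with an all-`FALSE` artefact mask.
#' @export
read_eeg <- function(path, format = c("auto", "csv", "edf"), channel = 1L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(read_edf(path, channel = channel))
  df <- read.csv(path)
  if (ncol(df) < 2) stop("CSV must have columns time_s,uV")
  tm <- as.numeric(df[[1]])
  x <- as.numeric(df[[2]])
  if (length(tm) < 2) stop("CSV too short to infer sampling rate")
  dt <- diff(tm)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  if ((max(dt) - min(dt)) / mean(dt) > 1e-6)
    stop("non-uniform CSV timebase (relative jitter > 1e-6)")
  eeg_record(x, fs = 1 / mean(dt), start_time = tm[1])
}

#' Write an EEG record
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`. EDF uses 16-bit
#'   samples, so values round-trip only to the 16-bit quantisation of the
#'   record's amplitude range, and requires an integer sampling rate.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(record, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(write_edf(record, path))
  n <- length(record$samples)
  df <- data.frame(time_s = record$start_time + (seq_len(n) - 1) / record$fs,
                   uV = record$samples)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a reference-index trace
#'
#' CSV dialect `time_s,index` (header required): an intermittent BIS-like
#' index on the 0-100 scale, one value every 5 s.
#'
#' @param path File path.
#' @return `read_reference`: data.frame with columns `time_s`, `index`.
#' @export
read_reference <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2) stop("reference CSV must have columns time_s,index")
  out <- data.frame(time_s = as.numeric(df[[1]]), index = as.numeric(df[[2]]))
  if (any(diff(out$time_s) <= 0)) stop("reference timestamps must increase")
  if (any(out$index < 0 | out$index > 100))
    stop("reference index values must lie in [0, 100]")
  out
}

#' @param ref Data.frame with columns `time_s`, `index`.
#' @rdname read_reference
#' @export
write_reference <- function(ref, path) {
  write.csv(data.frame(time_s = ref$time_s, index = ref$index), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Zero-phase notch filter for mains interference
#'
#' Applies a second-order IIR notch (biquad, standard audio-cookbook design)
#' forward and backward, so the filter has zero phase and unit DC gain. The
#' artefact mask is unchanged.
#'
#' @param record An [eeg_record()].
#' @param freq Notch centre frequency in Hz (default 60). Must be below the
#'   Nyquist frequency.
#' @param q Quality factor (centre frequency / -3 dB bandwidth), default 30.
#' @return A filtered [eeg_record()].
#' @export
notch_filter <- function(record, freq = 60, q = 30) {
  if (freq >= record$fs / 2)
    stop("notch frequency must be below the Nyquist frequency fs/2")
  w0 <- 2 * pi * freq / record$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  # filter around the mean: the DC component passes exactly and start-up
  # transients act on the zero-mean part only
  mu <- mean(record$samples)
  y <- signal::filtfilt(signal::Arma(b = b, a = a),
                        record$samples - mu) + mu
  eeg_record(y, fs = record$fs, start_time = record$start_time,
             artefact_mask = record$artefact_mask)
}

#' Mask saturated and flatlined segments
#'
#' Marks as artefact every run of at least `min_run` consecutive samples that
#' are either at the amplitude rails (absolute value >= `rail_fraction` times
#' the session absolute maximum) or flat (equal to a neighbouring sample).
#' Previously masked samples are never unmasked.
#'
#' @param record An [eeg_record()].
#' @param rail_fraction Fraction of the session absolute maximum regarded as
#'   the rail (default 0.99).
#' @param min_run Minimum run length, in samples, for masking (default 16).
#' @return A new [eeg_record()] with the enlarged mask.
#' @export
mask_saturation <- function(record, rail_fraction = 0.99, min_run = 16) {
  x <- record$samples
  n <- length(x)
  if (n == 0) stop("record is empty")
  rail <- rail_fraction * max(abs(x))
  flat <- rep(FALSE, n)
  if (n > 1) {
    eq <- diff(x) == 0
    flat[which(eq)] <- TRUE
    flat[which(eq) + 1L] <- TRUE
  }
  flag <- (abs(x) >= rail) | flat
  mask <- record$artefact_mask
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  for (k in which(keep)) mask[starts[k]:ends[k]] <- TRUE
  eeg_record(x, fs = record$fs, start_time = record$start_time,
             artefact_mask = mask)
}

#' Cut sliding analysis windows
#'
#' Windows start at 0, `step_s`, 2·`step_s`, ... (relative to the record
#' start) and contain exactly `win_s * fs` samples. Windows whose masked
#' fraction exceeds `max_masked` are dropped; the number dropped is attached
#' as attribute `"dropped"`. The window end time is the key later used to
#' align windows to reference-index timestamps.
#'
#' @param record An [eeg_record()].
#' @param spec A [window_spec()].
#' @param max_masked Maximum tolerated masked fraction per window (default
#'   0.25).
#' @return A list of windows, each a list with `start_s`, `end_s`, `samples`
#'   and `masked_frac`; empty (with a warning) if the record is shorter than
#'   one window.
#' @export
segment_windows <- function(record, spec = window_spec(), max_masked = 0.25) {
  nwin <- round(spec$win_s * record$fs)
  n <- length(record$samples)
  if (n < nwin) {
    warning("record shorter than one window; returning empty list")
    out <- list()
    attr(out, "dropped") <- 0L
    return(out)
  }
  starts_s <- seq(0, n / record$fs - spec$win_s + 1e-9, by = spec$step_s)
  out <- list()
  dropped <- 0L
  for (s in starts_s) {
    i0 <- round(s * record$fs) + 1L
    i1 <- i0 + nwin - 1L
    if (i1 > n) break
    mf <- mean(record$artefact_mask[i0:i1])
    if (mf > max_masked) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- list(
      start_s = record$start_time + s,
      end_s = record$start_time + s + spec$win_s,
      samples = record$samples[i0:i1],
      masked_frac = mf)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Align windows to a reference-index trace
#'
#' Each window is paired with the reference value whose timestamp is nearest
#' to the window end time, provided the gap is at most `tol_s`; unmatched
#' windows are dropped.
#'
#' @param windows Output of [segment_windows()].
#' @param ref Data.frame with columns `time_s`, `index` (see
#'   [read_reference()]).
#' @param tol_s Matching tolerance in seconds (default 2.5, half the
#'   reference sampling interval).
#' @return A list of windows, each with an added `ref` element.
#' @export
align_to_reference <- function(windows, ref, tol_s = 2.5) {
  out <- list()
  for (w in windows) {
    d <- abs(ref$time_s - w$end_s)
    k <- which.min(d)
    if (length(k) == 1 && d[k] <= tol_s) {
      w$ref <- ref$index[k]
      w$ref_time_s <- ref$time_s[k]
      out[[length(out) + 1L]] <- w
    }
  }
  if (length(windows) > 0 && length(out) == 0)
    stop("no window could be aligned to the reference trace")
  out
}
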