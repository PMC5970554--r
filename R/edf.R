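# Minimal EDF (European Data Format) support: enough of the format to
# round-trip the single-channel records this package works with. EDF stores
# 16-bit samples with a per-signal linear calibration, so amplitudes survive
# only to the quantisation of the physical range. No pre-installed R package
# in this stack reads EDF, hence the hand-rolled subset here.

pad_field <- function(x, width) {
  s <- substr(format(x), 1, width)
  formatC(s, width = -width) # left-justified, space padded
}

write_edf <- function(record, path) {
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF output requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- record$samples
  n_rec <- ceiling(length(x) / fs)
  # pad the trailing partial record (if any) with zeros
  x <- c(x, numeric(n_rec * fs - length(x)))
  pm <- max(abs(x), 1e-6)
  dig <- as.integer(round(x / pm * 32767))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),                     # version
    pad_field("synthetic subject", 80),    # patient id
    pad_field("doaEEG recording", 80),     # recording id
    pad_field("01.01.00", 8),              # start date
    pad_field("00.00.00", 8),              # start time
    pad_field(256 + 256, 8),               # header bytes (1 signal)
    pad_field("", 44),                     # reserved
    pad_field(n_rec, 8),                   # number of data records
    pad_field("1", 8),                     # record duration (s)
    pad_field(1, 4),                       # number of signals
    pad_field("EEG", 16),                  # label
    pad_field("synthetic", 80),            # transducer
    pad_field("uV", 8),                    # physical dimension
    pad_field(sprintf("%.6g", -pm), 8),    # physical minimum
    pad_field(sprintf("%.6g", pm), 8),     # physical maximum
    pad_field(-32767, 8),                  # digital minimum
    pad_field(32767, 8),                   # digital maximum
    pad_field("", 80),                     # prefiltering
    pad_field(fs, 8),                      # samples per data record
    pad_field("", 32)                      # reserved
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

read_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes (recomputed from ns below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header")
  if (channel < 1 || channel > ns) stop("EDF channel out of range")
  fld <- function(k) vapply(seq_len(ns), function(i) rd(k), "")
  fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr))))
    stop("unreadable EDF header")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- numeric(n_rec * spr[channel])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      if (s == channel) {
        out[pos + seq_along(v)] <- phys_min[s] + gain[s] * (v - dig_min[s])
        pos <- pos + length(v)
      }
    }
  }
  eeg_record(out, fs = spr[channel] / rec_dur)
}
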