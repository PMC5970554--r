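# Shared fixtures built once per test run. The ten 300-s synthetic sessions
# (seeds 1..10) and their window features are used by several property and
# acceptance tests; computing them lazily here keeps the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

ten_sessions <- function() {
  if (is.null(.fixture_cache$sessions)) {
    .fixture_cache$sessions <- lapply(1:10, function(sd)
      generate_session(session_profile(duration_s = 300, seed = sd)))
  }
  .fixture_cache$sessions
}

# raw (notch + mask) and MEMD-filtered records for each session
ten_records <- function() {
  if (is.null(.fixture_cache$records)) {
    .fixture_cache$records <- lapply(ten_sessions(), function(s) {
      rec <- mask_saturation(notch_filter(s$eeg))
      list(raw = rec, filtered = filter_epochwise(rec))
    })
  }
  .fixture_cache$records
}

# SampEn feature series, raw and filtered, per session
ten_features <- function() {
  if (is.null(.fixture_cache$features)) {
    sessions <- ten_sessions()
    recs <- ten_records()
    .fixture_cache$features <- lapply(1:10, function(i) list(
      raw = compute_feature_series(recs[[i]]$raw, sessions[[i]]$truth_index,
                                   session_id = sprintf("s%02d", i)),
      filtered = compute_feature_series(recs[[i]]$filtered,
                                        sessions[[i]]$truth_index,
                                        session_id = sprintf("s%02d", i))))
  }
  .fixture_cache$features
}

two_tone <- function(phase20 = 0, phase2 = 0, fs = 128, dur = 10) {
  t <- (0:(dur * fs - 1)) / fs
  list(t = t,
       tone20 = sin(2 * pi * 20 * t + phase20),
       tone2 = sin(2 * pi * 2 * t + phase2))
}

completeness_err <- function(x, dec) {
  recon <- dec$residual
  for (imf in dec$imfs) recon <- recon + imf
  max(abs(x - recon)) / max(abs(x))
}
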