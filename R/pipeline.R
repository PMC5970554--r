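#' Window-wise feature series aligned to the reference index
#'
#' Cuts sliding windows from a (typically notch-filtered, artefact-masked
#' and, optionally, N-A-MEMD-filtered) record, computes one scalar feature
#' per window, and pairs each window with the nearest reference-index value.
#' Windows with an undefined feature (`NaN`, e.g. Sample Entropy with no
#' template match) are dropped; the number dropped is recorded in attribute
#' `"dropped_nan"`.
#'
#' @param record An [eeg_record()].
#' @param ref Reference trace: data.frame `time_s`, `index`.
#' @param spec A [window_spec()].
#' @param feature One of `"sampen"`, `"pen"`, `"rr"`, `"det"`.
#' @param sampen,pen,rqa Parameter objects for the respective features.
#' @param session_id Optional label attached to every row.
#' @return Data.frame with columns `session_id`, `time_s` (window end),
#'   `feature`, `ref`.
#' @export
compute_feature_series <- function(record, ref, spec = window_spec(),
                                   feature = c("sampen", "pen", "rr", "det"),
                                   sampen = sampen_params(),
                                   pen = pen_params(),
                                   rqa = rqa_params(),
                                   session_id = "session1") {
  feature <- match.arg(feature)
  wins <- segment_windows(record, spec)
  wins <- align_to_reference(wins, ref)
  fun <- switch(feature,
    sampen = function(x) sample_entropy(x, m = sampen$m,
                                        r_coeff = sampen$r_coeff),
    pen = function(x) permutation_entropy(x, m = pen$m, tau = pen$tau),
    rr = function(x) rqa_features(x, rqa)$rr,
    det = function(x) rqa_features(x, rqa)$det)
  vals <- vapply(wins, function(w) fun(w$samples), numeric(1))
  out <- data.frame(session_id = session_id,
                    time_s = vapply(wins, function(w) w$end_s, numeric(1)),
                    feature = vals,
                    ref = vapply(wins, function(w) w$ref, numeric(1)))
  keep <- is.finite(out$feature)
  res <- out[keep, , drop = FALSE]
  attr(res, "dropped_nan") <- sum(!keep)
  res
}

#' Preprocess a record for feature extraction
#'
#' Standard preprocessing chain: 60-Hz notch, saturation masking and,
#' optionally, epoch-wise N-A-MEMD filtering with IMF2+IMF3 reconstruction.
#'
#' @param record An [eeg_record()].
#' @param spec A [window_spec()].
#' @param memd_filter Apply the N-A-MEMD stage (default `TRUE`).
#' @param memd A [memd_config()].
#' @param sift A [sift_config()].
#' @param notch_freq Mains frequency in Hz (default 60).
#' @return A preprocessed [eeg_record()].
#' @export
preprocess_record <- function(record, spec = window_spec(),
                              memd_filter = TRUE, memd = memd_config(),
                              sift = sift_config(), notch_freq = 60) {
  rec <- notch_filter(record, freq = notch_freq)
  rec <- mask_saturation(rec)
  if (memd_filter)
    rec <- filter_epochwise(rec, spec, memd, sift)
  rec
}

#' Run the full DoA pipeline on one or more sessions
#'
#' End-to-end convenience wrapper: preprocess each session's EEG (notch,
#' artefact masking, optional N-A-MEMD filtering), extract the window
#' feature aligned to the session's reference index, pool all sessions,
#' split 70/15/15, fit the regression model on the training split (the ANN
#' uses the validation split for early stopping), and evaluate held-out
#' predictions on the test split.
#'
#' @param sessions A `doa_session` or list of them (see
#'   [generate_session()]).
#' @param feature Window feature (default `"sampen"`).
#' @param family Regression family (default `"rf"`).
#' @param memd_filter Apply N-A-MEMD filtering (default `TRUE`).
#' @param spec,memd,sift,sampen Parameter objects.
#' @param seed Seed for the split and model fit.
#' @return List with `features` (pooled series), `split`, `model`,
#'   `pred_test`, `report` (an `evaluation_report` on the test split).
#' @export
run_pipeline <- function(sessions, feature = "sampen", family = "rf",
                         memd_filter = TRUE, spec = window_spec(),
                         memd = memd_config(), sift = sift_config(),
                         sampen = sampen_params(), seed = 1L) {
  if (inherits(sessions, "doa_session")) sessions <- list(sessions)
  feats <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    rec <- preprocess_record(s$eeg, spec, memd_filter = memd_filter,
                             memd = memd, sift = sift)
    compute_feature_series(rec, s$truth_index, spec, feature = feature,
                           sampen = sampen,
                           session_id = sprintf("session%02d", i))
  }))
  sp <- split_data(feats, seed = seed)
  model <- fit_doa_model(sp$train, family = family, seed = seed,
                         val = sp$val, feature_name = feature)
  pred <- predict(model, sp$test)
  report <- evaluate_session(pred, sp$test$ref)
  list(features = feats, split = sp, model = model, pred_test = pred,
       report = report)
}
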