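# doaEEG

Estimating depth of anaesthesia (DoA) from a single frontal EEG channel.

Anaesthetists titrate drug against an estimate of how deeply unconscious a
patient is. Commercial monitors (most prominently BIS) compress the frontal
EEG into a proprietary 0–100 index, one value every 5 s. `doaEEG`
implements an open pipeline that tracks such an index from raw
single-channel EEG sampled at 128 Hz:

1. **Preprocess** — 60-Hz notch filter (zero-phase biquad), automated
   masking of rail-clipped / flatlined artefact segments.
2. **Filter** — noise-assisted multivariate empirical mode decomposition
   (N-A-MEMD) on consecutive 5-s epochs; the EEG is re-assembled as
   IMF2 + IMF3, which keeps the 8–32 Hz band that carries the anaesthetic
   signal and discards EMG, mains residue and baseline wander.
3. **Extract features** — window-wise Sample Entropy

   SampEn(m, r, N) = −ln [ Aᵐ(r) / Bᵐ(r) ]

   on 30-s windows (N = 3750 samples) advanced by 5 s, with m = 1 and
   r = 0.1·σ of the window (Chebyshev distance, self-matches excluded,
   N − m templates for both dimensions). Permutation Entropy (m = 6, τ = 1)
   and recurrence measures (RR and DET at dimension 3, delay 5, threshold
   0.5 on the z-scored window) are available as comparators.
4. **Regress** — map the feature onto the 0–100 reference with Random
   Forest (1,000 trees; default), RBF support-vector regression, or a
   1–9–18–1 backpropagation network, using a seeded 70/15/15
   train/validation/test split; predictions are clipped to [0, 100].
5. **Evaluate** — Pearson correlation, mean absolute error, ROC/AUC at the
   awake boundary (reference ≥ 65), a four-phase output-distribution table
   (0–40 / 40–65 / 65–85 / 85–100), and one-way ANOVA on ranks with
   Student–Newman–Keuls pairwise comparisons.

No clinical recordings ship with the package. Instead a synthetic session
generator (`generate_session()`) produces EEG-like signals whose
composition is a deterministic function of a known consciousness
trajectory — broadband activity while awake, growing slow-delta and frontal
alpha with depth, burst suppression below index 40, plus mains noise, EMG,
baseline wander and saturation artefacts — together with a co-sampled
BIS-like reference. Every downstream stage is testable against this known
ground truth; see the methods vignette (`vignettes/doa-methods.Rmd`) for
what that does and does not demonstrate.

## Worked example

```r
library(doaEEG)

session <- generate_session(session_profile(duration_s = 300, seed = 1))
session
#> <doa_session> 300 s at 128 Hz (38400 samples), 60 reference points, 1 artefact events

rec   <- preprocess_record(session$eeg)   # notch + mask + N-A-MEMD filter
feats <- compute_feature_series(rec, session$truth_index)
head(feats, 3)
#>   session_id time_s  feature      ref
#> 1   session1     30 2.444550 94.91119
#> 2   session1     35 2.449939 94.02760
#> 3   session1     40 2.455960 89.12286

sp     <- split_data(feats, seed = 1)
model  <- fit_doa_model(sp$train, family = "rf", seed = 1, val = sp$val)
report <- evaluate_session(predict(model, sp$test), sp$test$ref)
report
#> <evaluation_report> n=8  CC=0.987  MAE=5.88  AUC=1.000
#>   ANOVA on ranks: H=5.83, p=0.0157
#>   phase counts (reference): 5 / 0 / 1 / 2
```

Each feature row is one 30-s window keyed by its end time and paired with
the reference value nearest that time; `feature` is the window's Sample
Entropy (high ≈ awake, low ≈ deep), `ref` the 0–100 reference. The report
summarises the held-out windows of this single short session: correlation
with the reference, mean absolute error in index units, AUC for
discriminating awake (≥ 65) from anaesthetised windows, and the
Kruskal–Wallis statistic across the occupied phases.

A thin command-line front end over the same functions is installed at
`inst/scripts/doa` (`doa simulate | features | train | predict |
evaluate`), reading/writing CSV (`time_s,uV` and `time_s,index`) and
single-channel EDF.

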