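# thermalbreath

Non-contact respiratory analysis and COPD screening from side-view
thermal video, in R.

## The problem

Spirometry — the standard pulmonary function test — needs a clinic
visit, a mouthpiece and good patient compliance, all problematic for
the elderly population in which chronic obstructive pulmonary
disease (COPD) is most prevalent. A thermal camera pointed at a
seated subject's profile offers a contact-free alternative: the
chest wall visibly rises and falls with breathing, and each
exhalation paints a warm plume in front of the mouth. This package
turns those two signals into quantitative breath features and a
screening score.

**Who it is for:** researchers working on camera-based vital-sign
monitoring who need a tested, scriptable reference pipeline — plus a
synthetic thermal-video generator with exact ground truth, since no
public clinical thermal cohort exists.

## Method at a glance

Per subject, with two manually placed rectangles (ROI 1 chest,
ROI 2 mouth-front):

1. **Preprocess** each frame: percentile normalization, median 5×5,
   Gaussian 5×5, bilateral 9×9 (in that order).
2. **Phase detection**: mean vertical Lucas–Kanade flow `v` over
   ROI 1 drives a two-state machine — `|v| ≤ 0.05` px/frame holds
   the phase, `v < 0` (chest rising) switches to inspiration,
   `v > 0` to expiration.
3. **Plume counting**: on expiration frames, count ROI 2 pixels with
   `I_t − I_{t−1} ≥ 1`; zero elsewhere. Analyze `t ∈ [0, 40)` s.
4. **Features**: TRV (summed plume pixels), ADE / ADI (mean spacing
   of expiration / inspiration starts, s), TRR (completed cycles).
5. **Score**: Z-scale each feature on the cohort, then
   `Score = Σ w_i z_i` with integer weights `w ∈ [1, 50]` chosen by
   a seeded 1000-draw random search (admission: Youden's
   `J = sensitivity + specificity − 1 > 0.70`, specificity ≥ 0.5;
   selection: accuracy, then COPD recall). The classification
   threshold is the Youden optimum of the score's ROC curve;
   `score ≥ threshold ⇒ COPD`.

## Worked example

```r
library(thermalbreath)

# A synthetic subject: 15 breaths/min, visible plume, mild noise
v <- render_thermal_video(
  breath_program(n_breaths = 12, expiration_durations = 2,
                 inspiration_durations = 2, plume_intensity = 60),
  noise_spec(rng_seed = 1),
  frame_shape = c(96, 128), fps = 10, duration = 40)

seq <- preprocess_sequence(v$seq)          # denoising chain
tr  <- track(seq, v$chest_roi, v$mouth_roi)
tr
#> <breath_trace> 400 frames @ 10 Hz, window [0, 40) s
#>   10 expiration starts, 10 inspiration starts, total plume 50129 px
extract_features(tr)
#> <feature_vector> TRV=50129 ADE=4s ADI=4s TRR=10/window
```

Ten expirations in 40 s is the programmed 15 breaths/min; ADE = ADI
= 4 s is the programmed period; TRV is the plume area accumulated
over all expirations (pixels — an uncalibrated volume proxy).

```r
# Cohort-level scoring on a sampled two-group feature table
tab   <- sample_feature_table(20, rng_seed = 1)   # 20 COPD + 20 control
model <- weight_search(tab, n_iter = 1000, rng_seed = 1)
model
#> <score_model>
#>   features: trv, ade_s, adi_s, trr
#>   weights:  trv=37  ade_s=4  adi_s=6  trr=22
#>   threshold 7.5739 (Youden 0.800), sigma convention: population
model$evaluation
#> <evaluation_report>  (COPD = positive class)
#>   confusion: TP=18 FN=2 TN=18 FP=2
#>   COPD:     precision 0.90  recall 0.90  F1 0.90
#>   control:  precision 0.90  recall 0.90  F1 0.90
#>   sensitivity 0.90  specificity 0.90  accuracy 0.90  Youden 0.80
#>   note: fitted and evaluated in-sample (no held-out data)
```

The search put its heaviest weights on TRV and TRR — the two
features with the strongest class signal in the sampled cohort —
and the fitted threshold separates 36 of 40 subjects in-sample.

## Command line

```sh
./exec/thermalbreath simulate --out v.tiff --duration 40 --fps 10 --seed 1
./exec/thermalbreath track --in v.tiff --rois rois.yaml --out trace.csv --fps 10
./exec/thermalbreath features --trace trace.csv --out features.csv
./exec/thermalbreath search --features features.csv --out model.json
./exec/thermalbreath run --config pipeline.yaml      # whole pipeline
```

Video IO is multi-page uncompressed TIFF or PNG frame directories
(MP4/AVI would need a codec this runtime does not ship).

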