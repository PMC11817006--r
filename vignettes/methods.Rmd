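---
title: "Respiratory pattern analysis from thermal video: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory pattern analysis from thermal video: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

A thermal camera filming a seated subject from the side sees two
respiration signals at once. The chest wall rises during inspiration
and sinks during expiration — a geometric signal. And exhaled air,
warmer than an 18 °C room, appears as a transient bright plume in
front of the mouth and nose — a radiometric signal. `thermalbreath`
quantifies both from 8-bit grayscale video and combines four derived
features into a composite score that screens for chronic obstructive
pulmonary disease (COPD), whose hallmark is altered resting
respiration (faster, shallower cycles with larger exhaled-plume
areas in the patient group).

The pipeline is: preprocessing → dual-ROI tracking → feature
extraction → Z-score weighted scoring → ROC/Youden thresholding.
Every stage is a documented function; `run_pipeline()` chains them.

## Preprocessing chain

Thermal recordings carry salt-and-pepper impulses, sensor noise and
drifting warm pockets of ambient air. The chain is fixed in order:

1. **Percentile normalization** — the sequence-global 1st/99th
   intensity percentiles map linearly to 0/255 (clipped). This
   replaces the manual dynamic-range scaling done at acquisition
   time with a deterministic rule. It is computed over the whole
   sequence, not per frame, so frame-to-frame differences remain
   meaningful.
2. **Median filter, 5×5** — removes impulses.
3. **Gaussian filter, 5×5** — smooths residual speckle. The source
   procedure fixes only the kernel; σ defaults to the conventional
   `0.3·((k−1)/2 − 1) + 0.8` rule (≈ 1.1 px at k = 5).
4. **Bilateral filter, 9×9** — smooths while preserving the
   plume/background edge. Only the kernel is prescribed upstream;
   σ_space = 2 px and σ_range = 25 gray are package defaults chosen
   to smooth sensor noise (σ ≈ 1–2 gray) without bridging the
   plume edge (tens of gray).

All three filters use symmetric reflect padding: the borders are
otherwise darkened, and a darkened border registers as spurious
positive frame differences in the plume counter. Each filter output
is rounded back to 8-bit, mirroring an integer-image pipeline.
Because σ values and the border rule are package choices, the
golden-file regression test is anchored to this implementation, not
to any external reference.

## Dual-ROI tracking

Two rectangles are placed per subject (manually, as in the clinical
protocol): ROI 1 on the chest, ROI 2 in front of the mouth
(250 × 200 px at the clinical 640 × 512 geometry).

**Phase detection.** Dense two-frame Lucas–Kanade optical flow is
computed for every chest-ROI pixel with a well-conditioned 5×5
structure tensor and averaged. The contract is only "mean vertical
displacement in pixels/frame"; any estimator passing the known-shift
tests (a 1 px shift must read in [0.8, 1.2]) is conforming. A
two-state machine turns flow into phase: |flow| ≤ 0.05 px/frame
holds the current state (suppressing coughs and micro-vibrations);
stronger flow sets inspiration when negative (image y grows
downward, so a rising chest is negative flow) and expiration when
positive. The convention is a flag because up/down encodings are
easy to invert between plotting and image coordinates. The state
before the first supra-threshold flow is `undetermined`.

**Plume counting.** On each frame labelled expiration, the number of
mouth-ROI pixels whose intensity rose by ≥ 1 gray since the previous
frame is recorded; on all other frames the count is 0 by definition.
"Resetting ROI 2 at inspiration" is interpreted as resetting the
difference reference and the per-breath accumulation — mutating
stored pixel values, read literally, is not meaningful. A
`reset_on_inspiration = FALSE` variant freezes the reference across
non-expiration frames instead.

Analysis is windowed to the first 40 s (`[0, 40)`, 1200 frames at
30 Hz), where resting breathing is most regular; shorter videos are
rejected with the required duration in the message.

## The four features

* **TRV** — total respiratory volume: the summed plume counts. An
  uncalibrated area proxy (pixels, not litres).
* **ADE / ADI** — mean spacing of consecutive expiration /
  inspiration starts, in seconds. With fewer than two starts the
  feature is *undefined* and propagates as a flagged `NA`, never as
  a zero.
* **TRR** — completed expiration→inspiration cycles in the window.
  Whether the clinical summary tables report this per-window or
  per-minute is ambiguous upstream, so both conventions are exposed
  (`trr_per_minute`) and reports label which was used.

## Scoring model

Each feature column is Z-scaled on the full cohort
(`z = (x − μ)/σ`); the population-σ (divide by n) convention is the
default since the plain Z-score definition is quoted upstream, with
`sd_type = "sample"` available. The score is `Σ w_i z_i` with
positive integer weights in [1, 50] (the published weights print as
whole numbers, suggesting an integer grid). The classification
threshold is the Youden-index optimum (J = TPR − FPR) of the
score's ROC curve, ties broken toward higher specificity; a score
meeting or exceeding the threshold is called COPD.

`weight_search()` draws `n_iter = 1000` weight vectors uniformly,
admits candidates with J > 0.70 **and** specificity ≥ 0.5 — the
latter operationalizes the otherwise-undefined "balanced tendency"
requirement and can be disabled — and selects by maximal accuracy,
then higher COPD recall, then higher J, then earliest draw. With no
admissible candidate the best-J model is returned carrying a
`below_criterion` flag. Everything is fit and evaluated in-sample
(the clinical study had 40 subjects and no held-out set); every
report prints that caveat.

A subtlety worth stating: after Z-scaling, *every* column has unit
variance, including ones carrying no class signal. A cohort in which
only one feature separates the classes is therefore **not**
guaranteed to be separated by every positive-weight composite — an
adverse draw can let an uninformative column outvote the separated
one. Guaranteed separation requires consistently oriented gaps
across the active features; the test suite constructs its separable
cohorts that way.

MCID comparisons (`auc_difference_table()`) take the per-feature
thresholds as user inputs and compute composite-minus-feature AUC
differences from first principles; the package does not attempt to
reproduce any published difference column, whose internal arithmetic
is inconsistent.

## Synthetic world

No public thermal-video cohort exists, so the generator *is* the
test bed. It renders:

* a horizontal high-contrast chest band (Gaussian vertical profile,
  σ = 3 px, contrast 170 over a base level of 20) translating
  rigidly with phase, with a ±15 % sinusoidal intensity modulation
  along x so 8-bit quantization dithers instead of snapping whole
  rows — keeping sub-pixel motion visible to optical flow;
* a mouth-front plume: 2-D Gaussian footprint (σ ≈ 15 % of the
  mouth ROI's short side) whose amplitude follows a raised-cosine
  envelope over each expiration, peaking at `plume_intensity`;
* noise: salt-and-pepper fraction, Gaussian σ, and Poisson-arriving
  warm blobs drifting with Gaussian random velocities.

**Chest motion is piecewise-linear, not sinusoidal.** With the
0.05 px/frame flow threshold, a smooth (raised-cosine) displacement
would cross threshold only well into each phase — tens of frames at
resting rates — making ±1-frame start-time recovery impossible for
*any* detector. Constant within-phase velocity
(`amplitude / duration`) keeps the flow magnitude above threshold
from the first frame pair of a phase, which is the behavioural claim
the tracker tests need. Default amplitude is 10 px: at the slowest
tested rate (6 breaths/min, 5 s phases) this gives
10/(5·fps) ≈ 0.13 px/frame at 15 Hz, comfortably supra-threshold.

Defaults not quantified anywhere upstream (plume peak 60 gray,
footprint size, amplitude 10 px, 15 breaths/min, moderate noise
levels) were chosen once as a realistic resting-breathing scene and
are not tuned against tests.

Ground-truth plume counts are computed from the clean quantized
frames by the same positive-difference rule the tracker applies,
gated by the true phase — so in the noiseless case the tracker must
reproduce the total *exactly*, and does. Start times are continuous
seconds; the first frame of a segment is `ceiling(t·fps)` under the
frame-time convention `t_i = i/fps`.

The two-group feature sampler defaults to the clinical cohort's
group means, with spreads calibrated so each feature's standalone
normal-model AUC matches the published per-feature AUCs
(σ = |Δμ| / (√2·Φ⁻¹(AUC))). Durations and counts are floored at
small non-negative values after sampling, a slight truncation bias
acknowledged in the sampler's documentation.

**What a green test does not establish:** the generator has no
radiometric calibration, no emissivity model, no subject motion
other than breathing, and its plume is a smooth Gaussian rather
than turbulent exhalate. Perfect synthetic recovery therefore
validates the *algorithmic* contracts, not clinical performance;
the published cohort-level AUCs are not reproducible without the
40 clinical recordings.

## Numerical and degenerate-input choices

* Constant-intensity sequences normalize to all-zero frames with a
  warning rather than dividing by zero.
* A constant feature column raises an error naming the feature; it
  cannot be Z-scaled.
* ROC thresholds are the distinct scores plus an `Inf` sentinel
  under the ≥ rule; AUC is computed by ranks (Mann–Whitney),
  identical to the trapezoid under that curve, and ties contribute
  ½.
* Printed metrics round half-up at 2 decimals at report time only.
* All randomness flows through one locally seeded RNG
  (`with_seed()`), which restores the caller's RNG state — no
  package function perturbs the global stream.

## Scale of the shipped tests

The clinical geometry is 640 × 512 at 30 Hz; the test suite renders
80–128 px frames at 8–15 Hz (keeping the 40 s window for the
acceptance runs) to fit a single-CPU budget. The contracts under
test are resolution-independent: thresholds are expressed in
pixels/frame and gray units, and the scene geometry scales with the
frame.

## Known limitations

* No MP4/AVI decoding (no codec available in the deployment image);
  use multi-page TIFF or PNG frame directories.
* ROI placement is manual, per subject, as in the clinical
  protocol.
* In-sample fitting only; no cross-validation.
* The optical-flow estimator is single-level Lucas–Kanade: adequate
  for sub-pixel breathing motion, not for displacements ≫ the 5×5
  window.
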