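---
title: "Heart-rate assessment from drone video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate assessment from drone video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerorate)
```

## The problem

Remote photoplethysmography (rPPG) estimates the cardiac pulse from the
minute colour variations that blood volume changes impose on skin in RGB
video. On a drone the signal, already 2–3 orders of magnitude below ambient
variation, must additionally survive wind-driven platform motion, a
two-axis gimbal that leaves the roll of the optical plane uncompensated,
and uncontrolled outdoor lighting. `aerorate` implements a five-stage
pipeline for a *single-value* heart-rate assessment under these conditions
— the quantity that matters in triage, where the question is whether the
rate is grossly abnormal, not its beat-to-beat variability.

The stages:

1. **Stabilization** (`stabilize_sequence`): for each frame, the nearest
   (in time) gimbal sample is selected; the residual roll is
   `atan2(h_z, v_z)` of the left-facing and down-facing view vectors; the
   frame is digitally rotated by the negated roll with bilinear
   interpolation into a square, zero-padded canvas.
2. **Exposure control** (`adjust_exposure`): the 98th percentile `v` of the
   face-region pixel values is driven into the open band (190, 230) of the
   8-bit range — as bright as possible without clipping — by the
   multiplicative update `l <- (190+230)/(2v) * l`, at most 10 iterations.
   For a noiseless linear sensor a single step lands `v` at 210 exactly;
   under clipping the update contracts by at least 420/510 per step, which
   bounds how over-exposed a feasible start may be (about 4x).
3. **ROI tracking** (`detect_face_series`, `segment_timeframes`,
   `extract_roi_signals`): a pluggable detector yields a face box per
   frame; maximal runs of consecutive detections at least 5 s long become
   the analysis segments (none: the assessment fails); within a segment, 30
   forehead/cheek polygons and 4 bloodless regions (nostrils and eyes,
   center/right) are rasterized (pixel-center, even-odd rule) and their
   mean colours recorded, together with vertex coordinates, vertex-average
   center-of-mass and pixel counts.
4. **De-noising and colour mixing** (`assemble_noise_matrix`,
   `glm_denoise`, `chrom_signal`, `pos_signal`): each ROI channel is
   modelled as `Y = X M + P + E`, where the columns of X are 15 known
   nuisance sources — tracking geometry and its first derivatives, flight
   sensors (height, longitude, latitude, velocity), the bloodless-region
   colours, and the gimbal vectors with derivatives (K = 4V + 27 columns
   for V polygon vertices). `M` is the least-squares solution (minimum
   norm under rank deficiency), and `Y - X M` the de-noised signal. The
   CHROM and POS chrominance projections then map the three channels to
   one pulse signal each.
5. **Spectral estimation** (`estimate_hr`): 45-sample windows with stride
   2; each window's zero-padded power spectrum (grid ≤ 1 bpm) is gated by
   (a) a local peak in 50–180 bpm with band-power SNR ≥ 0.025 at ±3 bpm
   width, and (b) no low-band (0–50 bpm, DC excluded) power above the
   in-band maximum; accepted spectra are pooled per method by a
   per-frequency median; each method's HR is the argmax of its median
   spectrum; the final HR is the mean of the two.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `roi$min_segment_s` | 5 | s | minimum continuous face run; shorter runs carry too few windows |
| `hr$window_samples` | 45 | samples | analysis window; at 15 fps this is 3 s, the operative constant |
| `hr$stride_samples` | 2 | samples | window hop; dense overlap feeds the median |
| `hr$snr_min` | 0.025 | ratio | minimum peak band-power SNR (2.5%) |
| `hr$alpha_bpm` | 3 | bpm | peak half-width in the SNR numerator |
| `hr$band_bpm` | [50, 180] | bpm | physiological target band, edges inclusive |
| `hr$grid_bpm` | 1 | bpm | spectral grid after zero-padding |
| `exposure$target` | (190, 230) | 8-bit | strict-inequality exposure band |
| `exposure$max_iter` | 10 | — | exposure loop bound |
| `evaluation$motion_threshold_samples` | 225 | samples | high/low-motion split (15 s at 15 fps) |
| `evaluation$exposure_bounds` | [190, 250] | 8-bit | inside/outside exposure split, closed interval |

A note on the window length: the pipeline's constants pair "45 samples"
with a 5 s parenthetical, which conflicts with 15 fps (45 samples = 3 s).
The sample count is taken as operative, because stride, thresholds and the
segment arithmetic are all expressed in samples.

## The noise design matrix

Column order is fixed and labelled: vertex coordinates (2V), their first
derivatives (2V), center-of-mass (2) and derivative (2), pixel count (1),
height (1), longitude (1), latitude (1), velocity u,v,w (3), the four
bloodless-region means (4), h (3), v (3), dh/dt (3), dv/dt (3) — K = 43 for
quads, 51 for hexagons. Enumerating every component of the 15 sources gives
this count; a published tally of "42 to 50" is one lower and cannot be
reproduced by any complete enumeration, so the full set is kept rather than
silently dropping a source.

Two deliberate choices here:

* **Channel matching.** The bloodless regions have three colour channels
  each, but the model assumes one noise-source set per channel. When
  channel *c* is de-noised, the four bloodless columns carry channel *c* of
  those regions: lighting noise is channel-specific, and this keeps exactly
  four such columns per solve.
* **Centering.** Y and the columns of X are mean-centered before solving
  (equivalently, an intercept), so the DC colour level cannot absorb noise
  weights. The removed channel means are restored before chrominance
  normalization, which needs a physical DC.

Derivatives use central differences with one-sided ends, unit step — the
sensor series are already matched to frames by the same nearest-timestamp
rule as the gimbal data.

## What least squares can and cannot do here

The de-noised output is exactly the orthogonal-projection residual, so any
noise that truly lies in the span of X is removed to machine precision —
the simulator constructs its signals that way and the tests verify it.
Three caveats are intrinsic and documented by tests rather than hidden:

* **Pulse absorption by overfitting.** With K ≈ 43 regressors on T samples,
  least squares absorbs a K/T-order fraction of *any* target, pulse
  included. At the study-typical 20 s (T = 300) that is a few percent of
  pulse amplitude; segments near the 5 s minimum (T ≈ 75–120) lose so much
  that the windowed spectra may be noise-dominated. The recovered HR is
  robust well before the waveform is: the spectral argmax survives partial
  absorption.
* **Nonlinear leakage into the HR band.** The gimbal vectors are
  trigonometric in the roll, so their columns contain quadratic harmonics
  at twice the motion bandwidth. With motion up to 50 bpm-equivalent these
  harmonics reach 100 bpm and can correlate with the pulse by chance. This
  is a property of the physical design matrix, not an implementation
  artifact.
* **Correlated sources remove the signal.** A noise column correlated with
  the pulse removes it — the classic failure mode. The simulator originally
  exhibited it end-to-end: bloodless regions whose borders blur into
  pulsing skin under rotation resampling become pulse-correlated
  regressors. The renderer therefore paints the bloodless patches with a
  margin, and a test documents the failure mode explicitly (adding the true
  pulse as a column drives output pulse power to ~0).

## Colour mixing

CHROM: with mean-normalized channels, `Xs = 3Rn - 2Gn`,
`Ys = 1.5Rn + Gn - 1.5Bn`, output `Xs - (sd(Xs)/sd(Ys)) Ys`. POS:
`S1 = Gn - Bn`, `S2 = Gn + Bn - 2Rn`, output
`S1 + (sd(S1)/sd(S2)) S2`. Both are applied once per segment (the windowing
of stage 5 then slices the mixed signal); applying POS's original
overlap-add window inside segments is a known variant not adopted, because
the pipeline order is segment-mix-then-window. Constant channels map to a
zero signal; a degenerate denominator projection (`sd < 1e-12` relative)
with a non-degenerate numerator is an error, not a silent zero. Both
mixings are invariant to per-channel rescaling, and POS maps pure
common-mode intensity modulation to exactly zero.

## Spectral estimation choices

* The bare 45-sample transform at 15 fps has 20 bpm bins; zero-padding to a
  ≤ 1 bpm grid interpolates the spectrum (no information added) so the
  argmax can be reported at bpm resolution.
* Peak search: any strictly-local maximum qualifies; gating condition (a)
  asks for *at least one* qualifying peak with SNR ≥ 0.025. The universal
  reading ("every peak must pass") would reject nearly all realistic
  spectra, so the existential reading is used.
* The Eq-7 denominator is all remaining spectral power; if it is zero the
  SNR is `+Inf`.
* Low-band check: open interval (0, 50) bpm — the DC bin is excluded
  because windows are mean-removed.
* Medians over even counts use the arithmetic mid; argmax ties resolve to
  the lower frequency; band edges are inclusive.
* If only one method yields accepted spectra, its HR is reported as the
  final value; if neither does, the status is `failed_no_accepted_spectra`.

## The synthetic world

`scene_config()` states the recording conditions: 15 fps video, sensor logs
at twice the frame rate, 20 s duration, a G-dominant pulsatile direction
(R, G, B) = (0.5, 1, 0.7) at 1% relative strength on a (200, 160, 140) skin
base, band-limited (< 50 bpm-equivalent) Gaussian drift processes for roll,
face-box jitter, lighting and flight sensors, a linear noise mixture scaled
to 2 8-bit units per channel, and white sensor noise of 0.3. The roll std
is 0.08 rad (~4.6°) of wind-driven motion. Where the recording conditions
state a value (frame rate, pleth rate 100 Hz, recording length, exposure
band) the generator uses it; the remaining levels are fixed once at
magnitudes a field recording would show and are not revisited.

`simulate_roi_signals` builds the noise design through
`assemble_noise_matrix` itself, so generated signals decompose exactly as
the de-noising model assumes — the machine-precision decomposition test
rests on that. `simulate_frames` renders the scene-level world (face
rectangle, bloodless patches, roll-rotated frames, dropouts, linear clipped
camera). What the simulator does **not** emulate: real facial geometry and
specularities, skin-tone diversity, H.264/H.265 compression, rolling-shutter
effects, or detector misses on visible faces. A green end-to-end test
therefore establishes correctness of the pipeline's mathematics on its
stated signal model, not field performance.

## Evaluation

`reference_hr` detects beats in the 100 Hz pleth trace (upper-half local
maxima, 0.33 s refractory), converts inter-beat intervals to instantaneous
HR and averages over the valid video spans. `hr_rmse`, `bland_altman`
(bias ± 1.96 × population SD of differences — the 95% interval is read as
limits of agreement) and `subset_split` (high/low motion at < 225 valid
samples; inside/outside exposure on the closed [190, 250] band) mirror the
published evaluation design. The pooled MSE identity — total MSE equals the
record-weighted mean of the four cell MSEs — is tested exactly.

## Degenerate inputs and numerical conventions

* Timestamp ties in nearest matching break to the earlier sensor sample.
* Rotation pivots on the image center ((W−1)/2, (H−1)/2); quarter turns on
  square frames are exact index permutations, which anchors the
  interpolation tolerance used in round-trip tests.
* Gimbal vectors are not normalized before `atan2` (scale-invariant);
  both z-components zero is a degeneracy error.
* Rank-deficient design matrices are solved in the minimum-norm sense via
  SVD with the standard `max(dim) * eps * max(singular value)` tolerance;
  constant columns are kept but flagged.
* Under-determined de-noising (T ≤ K) is refused with guidance to lengthen
  the segment, never silently regularized.
* Zero-area ROI polygons drop the ROI for the whole segment with a warning.
* Exposure updates that leave the camera bounds are clamped, flagged, and
  the loop continues (real cameras saturate; failing would abort a
  recoverable recording).

## Known limitations

Single-value output only (no HR variability); the detector and landmark
providers are contracts with synthetic defaults, not trained models; the
GLM is unregularized by design, so very short segments are intrinsically
fragile; and accuracy on real recordings is bounded by everything the
simulator does not model.
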