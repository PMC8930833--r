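---
title: "Measuring arteriole dilation from two-photon kymographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring arteriole dilation from two-photon kymographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Neurovascular coupling experiments monitor the diameter of a cortical
arteriole while a vasoactive agent is pressure-ejected from a micropipette
nearby. Each recording is episodic: a short pre-pulse baseline (5 s by
default), a brief pressure pulse, and a two-minute acquisition at 10–20 Hz.
The lumen is labelled with a circulating green dye; a red dye in the pipette
confirms that each pulse actually ejected (a rise in red fluorescence at the
pipette tip) and exposes leaks before the pulse. The quantity of interest is
the percent change in lumen diameter relative to the pre-pulse baseline,
summarized per dilation peak as an area under the curve (AUC, %·s), a
maximum change (%), and timing.

vasokymo implements the full measurement chain plus the downstream
statistics, and pairs it with a seeded synthetic scene generator so that
every stage can be validated against known ground truth without animal
recordings.

## Pipeline

1. **Standardization** (`standardize_video`). Recordings are resampled to a
   common geometry (544 × 336 px × 1400 frames by default): bilinear
   interpolation in space, non-overlapping block averaging when
   downsampling in time and linear interpolation when upsampling. Output is
   re-quantized to 8 bits.
2. **Segmentation** (`segment_vessels`). The temporal-mean image is
   thresholded (Otsu), closed morphologically (disc of 5 px), and connected
   components below 200 px² are dropped. Each remaining component is
   thinned to a skeleton (Zhang–Suen) and the longest geodesic path through
   the skeleton becomes the centerline; tangents are smoothed over ±5
   centerline points by a local principal-direction fit so normals are
   stable on pixelated skeletons. When several usable arterioles are found
   one is chosen uniformly at random (`select_arteriole`), reproducibly for
   a given seed.
3. **Scan lines** (`place_scan_lines`). Up to 8 lines are placed at equally
   spaced stations along the central 80 % of the centerline (end effects at
   skeleton tips make the outer 10 % unreliable), each perpendicular to the
   smoothed tangent, with length 3 × the local mask width so the profile
   always contains background on both sides. Lines whose mask profile lacks
   a foreground run of ≥ 3 px do not cross the vessel and are eliminated;
   if none survive, the recording is excluded ("unable to draw lines").
4. **Kymographs** (`build_kymograph`). Per frame, intensity is sampled by
   bilinear interpolation at unit-spaced positions along each line,
   building a position × time grid.
5. **Artifact rejection** (`flag_artifact_frames`). A per-frame focus
   feature (Tenengrad: mean squared Sobel gradient magnitude) is z-scored
   against the pre-pulse baseline window; frames with |z| > 3 are
   excluded, not corrected. The feature is evaluated on the background —
   outside a generously dilated vessel mask — because blur and motion
   degrade the whole field while a genuine dilation changes the gradient
   content of the vessel itself (through sub-pixel edge shifts) and must
   not be flagged; without a segmentable vessel the whole frame is used.
   On artifact-free noise the nominal two-sided exceedance is ≈ 0.27 %,
   and the pipeline's observed false-positive rate stays below 1 %.
6. **Binarization and widths** (`fit_intensity_mixture`,
   `width_per_frame`). After a 3 × 3 box mean filter (excluded frames
   neither contribute nor receive smoothing), a two-component Gaussian
   mixture is fitted by EM to the pooled pixel intensities of each
   kymograph, and each line profile is binarized at the posterior-equality
   threshold between the component means. The per-frame width is the extent
   of the longest contiguous foreground run, with run boundaries refined to
   sub-pixel positions (see *Numerical choices*).
7. **Normalization** (`bin_and_normalize`). Widths are averaged into
   non-overlapping 1-s bins whose edges are anchored at the pulse time, so
   "3 s before the pulse" is exactly three whole bins; the baseline width
   w₀ is the mean of those three bins and every bin becomes
   100 · (w − w₀)/w₀.
8. **Peaks and QC** (`detect_peaks`, `apply_qc`). Only dilations are
   quantified: peaks are maximal positive excursions of the post-pulse
   trace, with start/end at linear zero-crossings, exact trapezoid AUC, and
   a minimum-height filter at 10 % of the trace's global maximum. Single
   missing bins inside a peak are bridged by linear interpolation; gaps of
   two or more bins split peaks. The largest peak (by AUC, earlier start on
   ties) summarizes each line. The dataset rules then drop lines with a
   missing-data gap > 20 s, less than 60 s of data out of 120 s, a trace
   maximum above 30 % (an artifact guard — the rule is evaluated on the
   whole trace, not just the selected peak), or no positive peak; a pulse
   is dropped entirely when fewer than 5 lines survive, and a recording
   when no lines could be drawn. Rules are evaluated independently, so the
   retained set cannot depend on their order, and every exclusion is logged
   with all the rules it violated.
9. **Statistics** (`fit_lmm`, `contrast`, `dod_contrast`). AUC and maximum
   change are strongly right-skewed, so models are fitted on the natural
   log. The model is `ln(y) ~ agent * pulse + field + (1 | animal)` by
   REML: a random intercept per animal makes the animal the independent
   unit while all lines, pulses and fields enter as repeated measures, and
   one model spans all agents so every contrast shares the same controls.
   Contrasts are built from estimated cell means (so the coding of the
   factors cannot change any result), tested two-sided with Satterthwaite
   degrees of freedom, exponentiated to ratios with 95 % CIs, and reported
   per pulse and averaged over the three pulses. No multiplicity
   adjustment is applied. For agents dissolved in DMSO the treatment effect
   is a difference of differences: (agent + substrate − DMSO vehicle) −
   (substrate − saline), which removes both vehicle effects in one linear
   contrast whose SE comes from the combined contrast vector. The
   agent-by-pulse interaction is assessed by a likelihood-ratio test on ML
   refits.

## The synthetic scene generator

`scene_config` + `simulate_diameter_trace` + `render_vessel_video` produce
a ground-truthed recording: a single bright tube (foreground 200,
background 30 — a cleanly bimodal histogram) around a configurable
polyline centerline, convolved with a Gaussian PSF, plus Gaussian noise,
quantized to 8 bits. The diameter follows a programmable trace: each
dilation peak rises linearly over its time-to-max and decays exponentially,
and peaks superpose additively on the percent scale. A half-cosine rise is
available; the default is linear because observed dilations are slow and
asymmetric. Default peak timing (onset 35 s after the pulse, 10 s rise,
6 s decay) reproduces the scale of observed responses — apex roughly 45 s
after the pulse and above-zero durations of a few tens of seconds. The red
channel carries only what ejection verification needs: a static pipette
wedge and a transient dye puff at the tip spanning the pulse frame (or an
earlier frame, to emulate a leak). Artifact frames are rendered with extra
blur and translation. Everything is drawn from one seeded generator per
call, so identical configs and seeds give bit-identical stacks.

The tube edge is rendered with partial-volume coverage (pixel intensity
proportional to the fraction of the pixel inside the tube), which makes the
ground-truth width well defined for both readouts: the half-maximum
crossing and the binarization threshold both sit at exactly half the
plateau difference when the PSF is narrow.

`simulate_lnauc_table` generates the statistical layer directly: per-line
ln-AUC values from the random-intercept model with configurable cell means
per agent and pulse, a field effect, and Normal between-animal
(default 1.24 (ln units)²) and within-animal (default 4.51 (ln units)²)
variance components — the estimated components of the study design this
package targets; their sum, 5.75, is the marginal variance of a single
line measurement.

**What the generator does not emulate:** depth-dependent scattering, red
blood cell shadows, photobleaching, slow drift, vessel branching or
occlusion, pulsatility, and realistic motion (artifacts are blur +
translation only). Passing tests therefore demonstrate the correctness of
the measurement chain — geometry, binarization, normalization, peak
arithmetic, QC logic, and estimator calibration — not robustness to every
degradation seen in vivo.

## Numerical choices

* **Tied-variance EM.** The two mixture components share a pooled SD. With
  free variances the maximum-likelihood fit puts a near-zero-SD spike on
  the background plateau while the foreground component absorbs the
  partial-volume edge ramp; its mean is dragged far below the foreground
  plateau and the posterior crossing lands close to the background level,
  inflating binarized widths by ~2 px at small diameters. The pooled fit
  keeps both means on the plateaus. Component SDs are floored at the 8-bit
  quantization scale (0.3 intensity units) so noise-free plateaus remain
  fittable; a zero-range histogram is still rejected as unimodal.
* **Threshold guard.** The posterior-equality threshold is accepted only
  inside the central 60 % band between the two means; outside it (which
  happens only for strongly unequal component variances) the midpoint of
  the means is used. Symmetric mixtures are unaffected — their crossing is
  the midpoint exactly.
* **Sub-pixel run boundaries.** A raw foreground-run count quantizes widths
  to whole samples and, for a symmetric vessel, jumps in steps of 2 px as
  the vessel dilates; interpolating the threshold crossing at the run
  boundaries removes this discretization. With both choices, end-to-end
  width error on noise-free scenes is about 0.1 px across diameters
  8–40 px (tested against ground truth at every frame).
* **EM settings.** k-means initialization at the lower/upper intensity
  quartiles, log-likelihood tolerance 1e-6, at most 500 iterations; the
  fit uses raw pixel values pooled over each kymograph's retained frames
  (one threshold per kymograph — per-frame fits are noisier and drift).
* **Binning.** Bin edges anchored at the pulse time; w₀ uses whichever of
  the three pre-pulse bins are present and errors only when all are
  missing or w₀ ≤ 0. When all three are present, the baseline bins of the
  normalized trace average to zero exactly (tested at 1e-9).
* **Peaks.** AUC is the exact integral of the positive part of the
  piecewise-linear trace (trapezoids split at interpolated
  zero-crossings), verified against a dense Riemann oracle at 1e-6 and
  additive across interior zero-crossings at 1e-9. The 10 % minimum-height
  filter is configurable and 0 disables it.
* **Mixed models.** Fitting is done through lme4 with lmerTest's
  Satterthwaite machinery (the gradient-based approximation of the
  effective degrees of freedom for each contrast); REML for estimation, ML
  refits only for the likelihood-ratio test, variances bounded at zero
  (boundary fits are reported as a zero between-animal component with a
  warning). In the degenerate one-row-per-animal case the contrast
  reproduces the pooled two-sample t-test exactly (estimate, SE, df and
  p), which the suite asserts. Reference levels (saline, pulse 1, field 1)
  are a reporting convention only: contrasts are differences of cell
  means.
* **Field.** Enters as an additive two-level fixed factor; it cancels in
  every between-agent contrast, and no field interaction is fitted.

## Problem sizes used by the test suite

Synthetic videos in the suite use a reduced geometry (128 × 96 px, 10 Hz,
tens of seconds) so that the full imaging pipeline runs end to end many
times within a routine test run; the measurement code is scale-free, and
the standardization step is exercised on the same reduced geometry.
Statistical suites use 200 replicates at 50 animals per group for effect
recovery, 4 × 200 animals for variance-component recovery, and 500
replicates for confidence-interval coverage (observed ≈ 95 %, asserted
within ±2 %).

## Known limitations

* The centerline detector assumes one dominant, roughly tubular vessel per
  component; branching vessels would need a graph-aware centerline choice.
* The focus-based artifact rule needs some background in the field of
  view; when the (dilated) vessel mask covers more than 80 % of the frame
  the feature falls back to the whole frame and becomes sensitive to
  genuine vasomotion on very quiet baselines.
* Widths are reported in pixels and percent change; absolute calibration
  to micrometres is metadata-level and cancels in the percent scale.
* The mixed model assumes a common residual variance across agents and
  pulses and a single random intercept; responder/non-responder structure
  and per-line correlation beyond the animal level are not modelled.
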