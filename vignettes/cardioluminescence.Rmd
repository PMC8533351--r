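---
title: "Cardioluminescence analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardioluminescence analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiolum)
```

## The measurement problem

The beating heart of a 3–5 dpf zebrafish larva can be imaged for hours with
the bioluminescent Ca²⁺ reporter GFP–aequorin: each photon is emitted when
Ca²⁺ binds the photoprotein, and the photoprotein is irreversibly consumed
by that emission. Raw luminescence therefore conflates two things — the
instantaneous Ca²⁺ level and the amount of functional aequorin left. The
classic correction divides the luminescence rate *L* (counts/s) by *Lmax*,
the emittable counts remaining at that moment, measured by releasing the
residual pool with Triton X-100 at the end of the recording. L/Lmax is
monotone in Ca²⁺ and independent of how much reporter the larva happened to
carry, which is what makes drug and disease-model comparisons possible.

`cardiolum` implements that pipeline — ROI extraction from 16-bit image
stacks, background SNR, the aequorin budget, beat/transient kinetics, and
ellipsoid hemodynamics — together with a forward simulator of the whole
physics, so every analysis stage can be validated against known ground
truth at desk scale.

## The aequorin budget

For a background-subtracted recording of per-frame counts `raw[t]`
(negative residuals clipped at zero, since photon counts cannot be
negative):

* `Ltotal = sum(raw)` over the whole experiment, Triton frames included;
* `Lconsumed[t] = sum(raw[1..t])`, the aequorin already spent;
* `Lmax[t] = Ltotal − Lconsumed[t−1]`, the pool *entering* frame `t`;
* `L[t] = raw[t] · f` (counts/s at acquisition rate `f`), and
  `ratio[t] = L[t]/Lmax[t]`.

Two conventions are worth spelling out. First, the budget can be written
with `Lconsumed` taken inclusively or exclusively of the current frame; we
take `Lmax` as the pool available entering the frame, so a fully consumed
pool ends with `ratio·Δ = 1` rather than an undefined value, and the
identity `Lmax[t] + Lconsumed[t−1] = Ltotal` holds at every frame. Second,
the ratio is masked once the remaining pool falls below
`max(0.1% of Ltotal, 10 counts)`: near exhaustion the denominator is
noise-dominated and the ratio explodes without physiological meaning. Both
floors are exposed (`mask_floor_frac`, `mask_floor_counts`) and can be set
to zero, e.g. to follow a textbook toy budget to completion.

Without a Triton segment the recorded counts understate the remaining pool
and `Lmax` is biased low; `calibrate_luminescence()` warns rather than
refuses, because short exploratory recordings are still useful for beat
timing. Whether background should be subtracted before forming `Ltotal`
is not universally agreed; subtraction is the default, with
`subtract_background = FALSE` available.

The per-frame SNR follows the six-background-region protocol: regions of
the same pixel area as the chamber ROI are placed far from the larva, and
for each frame `SNR = (Signal − mean(backgrounds)) / sd(backgrounds)` with
the sample SD across regions at that frame (not pooled over time). Frames
where the background SD is zero are masked with a warning.

## The forward simulator

The simulator generates what the camera would see, from the ground truth
up, so that recovery can be asserted quantitatively:

1. **Beats.** An atrial beat grid at `atrial_rate` is thinned by the
   conduction rule (every *N*-th beat reaches the ventricle); `N = 2`
   reproduces a 2:1 atrio-ventricular block.
2. **Ca²⁺.** Each beat adds a difference-of-exponentials transient
   `g(u) = (1 − e^{−u/τ_rise}) e^{−u/τ_decay}` rescaled to unit peak, on
   top of the diastolic level. The shape is a standard cardiac-transient
   parameterisation; the published traces show but do not parameterise it.
3. **Light.** The fractional consumption rate follows a Hill law,
   `λ = λ_max · Ca³/(Kd³ + Ca³)`: the bioluminescence reaction is triggered
   by three Ca²⁺ ions, and Hill saturation is the standard aequorin model
   for turning that cooperativity into a rate. The pool decays stepwise as
   `A(t+δ) = A(t)·e^{−λ(t)δ}` on a fine grid, so underflow is impossible by
   construction.
4. **Camera.** Expected detected counts per frame are
   `detect_eff · (A(frame start) − A(frame end)) + bg_rate/f`; observed
   counts are Poisson with that mean plus optional Gaussian read noise,
   clamped at zero. EM gain and 4×4 binning are not modelled separately;
   they are absorbed into `detect_eff` and `read_noise_sd`. Rendered
   stacks spread each chamber's expected counts uniformly over an ellipse
   mask and draw Poisson per pixel, with per-pixel background everywhere.
5. **Triton.** From `triton_time` the consumption rate is replaced by a
   release constant (2 s⁻¹ by default — the published protocol states only
   that all remaining counts are emitted), so the residual pool drains in
   a few seconds.

The fine integration step is the frame interval divided so it is at most
`1/(20f)` and at most 1 ms, and divides the frame exactly; this keeps the
pool-decay discretisation error below 0.1% and puts frame boundaries on
grid nodes, which is why the noise-free identity
`ratio[t]/f = 1 − exp(−∫ λ dt)` holds to numerical precision and the
consumption rate is recovered frame by frame at 25 Hz.

### Default study conditions

No absolute Ca²⁺ concentrations or pool sizes are published for the larval
heart, so the defaults are free parameters chosen once to be physiologically
plausible and then left alone: diastolic Ca²⁺ 0.1 µM, transient amplitude
1 µM, τ_rise 30 ms, τ_decay 150 ms, Hill Kd 10 µM with n = 3, λ_max 1 s⁻¹,
pool 10⁶ photons, background 50 counts/s per ROI, atrial rate 180 bpm.
With Kd far above systolic Ca²⁺ the mean consumption rate stays well below
1 s⁻¹, which is exactly the regime in which L/Lmax is acquisition-frequency
invariant (the frame-integration bias of the ratio at 1 Hz is second order,
`≈ λ̄/2f`). Validation scenarios raise `λ_max` or the pool when a check
needs more photons per frame, and state so locally; the generator defaults
are not tuned per test.

What the simulator deliberately omits: optics point-spread, motion
artifacts from overlapping chambers, and the EM-CCD gain-register
stochastic model. Passing tests therefore demonstrate correctness of the
analysis given the photon-statistics model, not robustness to optical
cross-talk between atrium and ventricle — on real larvae that is handled
by ROI placement.

## Beat detection and kinetics

Detection is deliberately simple and fully parameterised, since the
published analysis was done interactively in Clampfit and specifies no
algorithm. Two passes: the beat period is first estimated from the trace
autocorrelation (largest interior peak; if it is below 0.2 the trace is
declared aperiodic, with a warning and a single-pass fallback); local
maxima above the diastolic floor (5th percentile) plus 30% of the 5th–95th
percentile span, separated by at least 0.3 periods, are kept. Candidates
not separated by a valley below the threshold are merged — a noise bump on
a transient's decay is not a second beat. This merging step proved
necessary at both extremes of sampling: at 200 Hz fluorescence with
realistic noise, and at 9 Hz where 3 Hz beats leave only three samples per
cycle.

Each peak is paired with the preceding minimum as its baseline (for
trend-free luminescence-ratio traces; for ΔF/F₀ traces the global-minimum
convention `(F_systole − F₀)/F₀` is selected with `baseline = "global"`).
Rise 10→90% and decay 90→10% times are linear interpolations at the
crossing levels, which makes them exact on a ramp and invariant under
affine transforms of the signal.

Two heart-rate estimators are reported. `heart_rate` is
`60/median(inter-peak interval)`, robust to a single missed beat;
`heart_rate_span` is `60·(n−1)/(t_n − t_1)`. Peak times are refined to
sub-sample precision by parabolic interpolation, but the median estimator
still shows a small (<1%) bias when the sampling grid beats against the
cardiac period, because the interval distribution becomes bimodal and the
median picks a mode; the span estimator averages this out and is the one
used for rate-recovery claims. The systolic and diastolic levels are means
of the per-beat extrema (one plausible reading of the published "average
systolic and diastolic levels"; envelope percentiles are the alternative we
did not take).

ΔF/F₀ uses the published convention: optional exponentially weighted
moving-average smoothing with factor 0.7, then normalisation to the
recording's minimum. The factor is taken as the weight of the *current*
sample — the published analysis does not define the convention — which at
200 Hz is mild smoothing; `current_weight = FALSE` selects the opposite
reading.

## Hemodynamics

From end-diastolic/end-systolic major and minor diameters and cavity
areas, averaged over three labelled frame pairs per larva (as in the
published three-image protocol): `FS = (D_dia − D_sys)/D_dia` per axis,
`FAC = (A_dia − A_sys)/A_dia`, ellipsoid-of-revolution volumes
`V = (π/6)·major·minor²`, `SV = EDV − ESV`, `EF = SV/EDV` (the standard
definition; it reproduces the published EF values), and `CO = SV·HR` in
nL/min. Volumes are reported in picolitres with 1 pL = 1000 µm³ — the
conversion consistent with published larval EDV values of ~400 pL for a
~130 × 80 µm ventricle.

Group reports use means, sample SDs, the fold change of means, and
two-tailed Student's t-tests (pooled variance unpaired, or paired). When
matching printed table cells the fold change is rounded half away from
zero to 2 decimal places. Per-larva metrics are computed first and then
averaged across larvae, which is why a printed mean CO need not equal mean
SV × mean HR; fold-change checks against the packaged reference table use
the printed group means directly, because that is what the reproducible
cells equal. A few printed fold-change cells (the FS-minor, FAC and EF
cells) are not consistent with their own printed means at 2 d.p. —
presumably per-larva averaging — and are excluded from exact checks.

## Numerical choices and degenerate inputs

* Budget identity and ratio scale invariance are exact up to one
  floating-point reconstruction ulp; tests assert 1e-14 relative.
* `simulate_geometry` emits the exact extremal diameters at the frames it
  labels end-systole/end-diastole (those frames represent the captured
  extrema), so the FS/FAC/volume round trip is exact to machine precision;
  between labelled frames the kernel is sampled on the 50 Hz frame grid.
* Zero-luminescence traces error; recordings with >50% of frames below
  background warn; empty ROI masks error; frame-shape mismatches error.
* Paired identical groups (zero-variance differences) are reported as
  `t = 0, p = 1` rather than erroring.
* Saturated rendered pixels (>65535) are clamped with a warning.
* Seeded configurations make every stochastic stage bit-reproducible.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen for statistical adequacy: the
budget identity over 100 seeded 6-s recordings across the full acquisition
grid (1–25 Hz); consumption-rate recovery on 30–40 s recordings at 25 Hz
with a 10⁶-photon pool (per-frame noise-free, 5-s windows under Poisson
noise); frequency invariance on 60-s recordings at the six published
rates; rate recovery on 60-s trains and the 2:1 block on one hundred 15-s
seeded recordings; and the ellipsoid formula on 10⁴ random diameter pairs.
Published per-larva absolute values (HR ≈ 170–250 bpm, 20-fold L/Lmax drug
responses, absolute SNR magnitudes) depend on real animals and instrument
throughput and are validated only as property surrogates and direction
checks on simulated drug events.

## Known limitations

L/Lmax can be dominated by high-Ca²⁺ microdomains because of the cubic
cooperativity, so it tracks but does not linearly report bulk cytosolic
Ca²⁺; no absolute Ca²⁺ calibration (rate-constant vs pCa tables) is
attempted. Atrial luminescence is usually below detection in real larvae;
the simulator can generate it, but the analysis defaults assume a
ventricular ROI. No automated ventricle segmentation is provided — the
published measurements were manual — and no flat-field or dark-frame
correction is applied.
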