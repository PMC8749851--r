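---
title: "Estimating sprint stride lengths from foot-mounted IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sprint stride lengths from foot-mounted IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridesense)
```

## The problem

A stride is the movement from touch-down (TD) of one foot to the next
touch-down of the same foot; stride length (SL) is the horizontal
displacement of the foot over that interval. During maximal linear sprint
acceleration a recreational athlete passes 5 m·s⁻¹ within a few strides and
peaks near 7–9 m·s⁻¹, which makes SL estimation from foot-mounted inertial
sensors much harder than in walking: foot accelerations are violent,
orientation changes quickly, and the impact at every touch-down produces
large, partly non-physical acceleration transients — often beyond a ±16 g
sensor range — that corrupt the double-integration of acceleration into
displacement.

`stridesense` implements a complete pipeline for this regime:

1. **Orientation** — a gradient-descent (Madgwick) quaternion filter fuses
   gyroscope and accelerometer (optionally magnetometer) to estimate the
   sensor-to-global rotation; body-frame specific force is rotated into an
   earth-fixed frame (y up, x along the horizontal reference direction,
   z transverse) and gravity subtracted.
2. **Gait events** — TD and toe-off (TO) are detected on the medial–lateral
   gyroscope axis.
3. **Stride engine** — per stride, the horizontal acceleration is
   double-integrated with a zero-velocity update (ZVU) that removes the
   touch-down artefact's velocity offset.
4. **Agreement statistics** — Bland–Altman bias and limits of agreement
   (LOA) against a reference, with a repeated-measures variance
   decomposition over participants.
5. **Sprint simulator** — synthetic sprints with exact ground truth, used by
   the test suite and usable for power/robustness studies.

## The core algorithm

For each foot, events must start with a toe-off: the athlete starts from
standstill, so the first stride has no preceding touch-down. Integration of
stride 1 starts 280 ms before the first TO (a window that, empirically,
contains all pre-start foot movement) with zero initial velocity, and ends
at the first TD. Every later stride spans TD$_{k-1}$ → TD$_k$ and is
processed per horizontal axis:

1. **Integrate & mirror.** The unfiltered acceleration over the stride is
   cumulatively integrated (trapezoid, $dt = 1/f_s$) from zero initial
   velocity. An axis whose mean velocity is negative is negated so both
   axes run positive; the flag is recorded. Stride length is a norm, so
   mirroring cannot change it.
2. **Temporary velocity.** A 40 Hz zero-phase low-passed copy of the
   velocity is made (removing impact-driven oscillation), and its first
   20 ms (10 samples at 500 Hz) are replaced by the value of the last
   clamped sample plus a 1 m·s⁻¹ guard, guaranteeing a decline after
   20 ms.
3. **Offset search.** The minimum of the temporary velocity over the
   inclusive window 20–100 ms after TD (20–160 ms for stride 2, whose
   ground contact is the longest, usually >150 ms) marks the first instant
   after the touch-down artefact that is followed by a consistent velocity
   increase. Ties take the earliest sample.
4. **Zero-velocity update.** The offset value is subtracted from the
   *unfiltered* velocity and all samples strictly before the detected index
   are set to zero — the foot is taken as stationary until that instant
   (early-stance amortisation).
5. **Length.** The corrected velocities are integrated once more to the
   displacement components $(d_x, d_z)$; $SL = \sqrt{d_x^2 + d_z^2}$.
   Stride speed is $SL$ divided by the TD-to-TD duration, and the sprint's
   maximal stride speed is the largest of these.

The physical premise of step 4 is that even in maximal sprinting there is a
short window in early stance where foot (sensor) velocity is close to zero,
while the large acceleration peaks of the first ~20 ms of contact carry no
meaningful horizontal foot motion. A nonzero *net* integral of that impact
transient shifts the whole velocity trace of the stride; uncorrected, a
0.4 m·s⁻¹ offset biases a stride by roughly 0.4 × duration metres — around
5–8 % — which is exactly what the ZVU removes.

```{r mechanism, eval = FALSE}
art <- artefact_config(net_dv_x = 0.4, net_dv_z = 0.2)
sp <- simulate_sprint(make_profile("60"), seed = 1, artefact = art,
                      noise = noise_off())
median(abs(stride_recovery_errors(sp)))                       # corrected
median(abs(stride_recovery_errors(sp,
       ss_config("zvu.enabled" = FALSE))))                    # bypassed
```

## Parameters that matter

| Key | Default | Unit | Role |
|---|---|---|---|
| `madgwick.beta` | 0.043 | – | orientation filter gain |
| `madgwick.init_s` | 0.5 | s | quiet-standing window for the initial quaternion |
| `gravity.g` | 9.81 | m·s⁻² | g-to-SI conversion and gravity subtraction |
| `start.pre_toeoff_s` | 0.280 | s | integration start of stride 1 before the first TO |
| `zvu.window_lo_s` / `zvu.window_hi_s` | 0.020 / 0.100 | s | offset-search window after TD |
| `zvu.window_hi_stride2_s` | 0.160 | s | extended upper bound for stride 2 |
| `zvu.guard_m_s` | 1.0 | m·s⁻¹ | clamp guard forcing a post-20 ms decline |
| `zvu.lowpass_hz` | 40 | Hz | temporary-velocity low-pass cutoff |
| `events.lowpass_hz` | 10 | Hz | swing-peak localization band |
| `events.swing_prominence` | 3.0 | rad·s⁻¹ | minimum mid-swing peak height |
| `dedrift.linear` | off | – | optional linear velocity dedrift per stride |

All keys live in one flat configuration (`ss_config()`, YAML-loadable via
`load_config()`); unknown keys are rejected so typos cannot silently fall
back to defaults.

## Numerical choices

* **Quadrature.** Both integration stages use the cumulative trapezoid with
  $dt = 1/f_s$; at 500 Hz its error on smooth swing kinematics is orders of
  magnitude below the method's other error sources (the suite checks
  < 0.5 % per stride against exact simulator truth, and equality within
  10⁻⁹ against a refined-grid oracle).
* **Zero-phase filtering.** The 40 Hz low-pass is a 2nd-order Butterworth
  applied forward–backward (`signal::filtfilt`), so filtering cannot lag
  the timing of the offset minimum.
* **Filter before clamp.** The temporary velocity is built by filtering the
  original velocity *first* and applying the 20 ms clamp + 1 m·s⁻¹ guard to
  the filtered copy. Applying the filter after the clamp would let the
  guard step itself ring through the Butterworth (≈ −0.04 m·s⁻¹ undershoot
  inside the 20–100 ms search window), planting a spurious offset of about
  +0.5–1 % of stride length on otherwise clean strides. Filtering first
  removes the high-frequency impact oscillation — its purpose — while the
  guard retains its only role of keeping the minimum out of the first
  20 ms. On artefact-free strides the detected offset is then exactly the
  near-zero early-stance velocity.
* **Windows and ties.** Window endpoints are converted with
  `round(x * fs)` and are inclusive on both ends; tied minima take the
  earliest sample (`which.min`), and a flat extremum in event detection
  resolves to its first sample.
* **Zeroing convention.** "Before the moment of offset detection" is read
  exclusively: sample `offset_idx` itself takes
  `v_orig[offset_idx] - offset`, samples strictly before it become zero.
* **Per-axis independence.** Mirroring, the temporary velocity, the offset
  search and the ZVU run independently on x and z; offsets genuinely differ
  in sign and size between axes and between strides. A consequence is that
  stride length is exactly heading-invariant only for the raw double
  integration; through the per-axis correction it is heading-stable to well
  below the method's noise floor (checked at 10⁻³ relative).
* **Degenerate inputs.** Saturated samples are flagged, never clipped;
  an all-zero accelerometer stream is an error naming the first offending
  sample (the gravity observation cannot be normalized); stances shorter
  than the 20 ms window lower bound are flagged and skipped; strides
  truncated by the end of the signal are dropped with a warning; an empty
  stride table still writes a valid header-only CSV.

## Open design decisions

* **IMU vs MARG.** Whether the original processing used the magnetometer
  variant is unstated; without magnetometer data the global x-axis is the
  initial horizontal heading instead of magnetic north. Stride length is
  the norm of the horizontal displacement, hence heading-invariant, so the
  choice cannot affect SL. The MARG update is available
  (`madgwick.use_magnetometer`) when magnetometer columns are present.
* **Initialization.** The initial quaternion comes from the mean
  accelerometer direction over the first 0.5 s of quiet standing (smallest
  rotation aligning sensed gravity with global +y), configurable; the gain
  β = 0.043 is far too small to recover from a deliberately wrong `q0`
  within a sprint, so recordings should include the standing phase.
* **Event rule.** The published event detector is only named, not
  specified. The rule implemented here — swing peaks on a 10 Hz zero-phase
  low-passed medial–lateral angular rate, TD as the first deep raw trough
  after a swing peak, TO as the last deep trough before the next swing
  peak, with the first TO taken before the first swing (standing start) —
  is validated against simulator ground truth (100 % recall, ≤ 2 ms) but
  equivalence with the original operator cannot be asserted.
* **Mirroring scale.** "Average stride velocity was negative" is evaluated
  per axis (the published examples show per-axis offsets of differing
  sign), not on the resultant.
* **Stride-1 duration.** Stride 1 has no starting TD; its duration is the
  length of its integration segment (280 ms pre-TO through first TD) and is
  flagged `stride1_no_td` in `qc_flags`.
* **Repeated-measures Bland–Altman.** The variance of the differences is
  decomposed by one-way random-effects ANOVA over participants
  (between-component scaled by the effective cluster size
  $m_0 = (N - \sum n_i^2/N)/(k-1)$ for unbalanced data);
  LOA = 1.96 × total SD. With one participant or one stride per
  participant this degrades, with a warning, to the classic SD of the
  differences — which is also the limit of the decomposition when every
  cluster has size one. Differences are analysed on the percentage scale
  by default (the reporting scale of sprint SL validation); an absolute
  (metre) mode is provided.

## What the simulator emulates — and what it does not

`simulate_sprint()` builds both feet of a sprint from a mono-exponential
body-speed profile $v(t) = v_{max}(1 - e^{-t/\tau})$ (defaults
$v_{max}$ = 7.0 / 7.65 / 8.4 m·s⁻¹ for the 60 / 80 / 100 % effort levels,
$\tau$ = 1.3 s, 35 m distance). Footfalls alternate between feet with a
stride frequency that rises linearly with speed (1.4 + 0.08·v Hz) while
ground contact shortens (0.25 − 0.015·v s, clamped to 90–300 ms), echoing
the usual speed–cadence–contact coupling of sprinting. Each foot is
*exactly* stationary during stance — the ZVU premise holds by construction
— and swings between footfalls along a minimum-jerk trajectory whose
closed-form second derivative provides the noise-free acceleration. On top
of this the generator injects: a damped 120 Hz touch-down burst (peak 25 g)
confined to the first 15 ms of contact with a configurable *net velocity
integral* (per-TD N(0, 0.3) m·s⁻¹ on x by default — the quantity that
makes the ZVU necessary); white accelerometer noise (0.3 m·s⁻²); a
per-sprint accelerometer bias (0.15 m·s⁻²) standing in for residual
orientation error; lateral footfall jitter (2 cm); and optional ±16 g
clipping. A synthetic medial–lateral angular-rate trace carries a positive
mid-swing burst and sharp negative troughs exactly at TD and TO.

The simulator does **not** model: true body-frame sensor signals during
running (orientation estimation is validated on prescribed rotations
instead), shoe/soft-tissue deformation near toe-off, sensor-fixation
slippage, real impact spectra, curved running paths, or reference-system
(video digitization) error. Passing the recovery criteria on simulated
sprints therefore demonstrates the *algorithmic* correctness and the
artefact-correction mechanism, not the field accuracy of the method on
real athletes, where fixation and orientation errors dominate the error
budget and widen the limits of agreement well beyond the simulator's.

## Validation problem sizes

The test-suite and acceptance-script checks run at the study's nominal
500 Hz on full 35 m sprints (≈ 10 strides per foot): three clean sprints
(one per effort) for noiseless recovery; 20 seeded sprints with default
artefacts and noise for the noisy error distribution; six sprints with a
fixed 0.4 m·s⁻¹ artefact net integral for the ZVU mechanism contrast;
10 replicates of 20 participants × 50 strides for the Bland–Altman
recovery; and 1000 random windows for the offset-search oracle. These
sizes keep the full validation in the tens of seconds while leaving every
statistical margin wide.

## Known limitations

* The first 20 ms of contact are discarded by design, so genuine
  horizontal foot acceleration inside that window (more likely in elite
  sprinters with shorter contacts) biases SL low; the same discard is what
  makes common linear dedrifting inapplicable, and the optional
  `dedrift.linear` mode exists mainly to demonstrate that it does not
  rescue uncorrected strides.
* Stride 1 receives no offset correction (no TD exists); its accuracy
  rests entirely on the standing-start assumption.
* Event detection assumes the characteristic swing/trough signature of
  sprinting on the medial–lateral axis; walking or shuffling gaits are out
  of scope.
* At 500 Hz the synchronization and event resolution is 2 ms; sub-sample
  alignment is deliberately not attempted.
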