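---
title: "Gait stability and muscle synergies on the treadmill: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait stability and muscle synergies on the treadmill: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitsyn)
```

`gaitsyn` implements the analysis pipeline of a balance-training treadmill
study design: older adults walk at a fixed 3.5 km/h in a *normal* and a
*narrow-base* condition (foot placement constrained to a 12 cm projected
beam), at three time-points (Pre, Post1, Post2). From surface EMG, marker
kinematics and the force-plate centre of pressure it computes neuromuscular
and biomechanical outcomes and their statistics. This vignette explains the
models, the tunable parameters, the synthetic-data generator used for
validation, and the numerical choices a maintainer would want justified.

## Pipeline overview

Per trial:

1. **Trim** the first 30 s (habituation).
2. **Gait events**: heel strikes are the anterior extrema of the AP
   centre-of-pressure trace (the tips of the treadmill "butterfly" figure),
   detected after 10 Hz zero-phase smoothing with a 0.4 s refractory period.
   Because the butterfly collapses in narrow-base walking, the leg is
   assigned from foot kinematics: the foot whose reference marker is most
   anterior at the event is the landing foot. Alternation is enforced;
   violations are dropped and logged, and more than 10 % of violations is
   treated as a detection failure.
3. **Gait metrics** over 160 strides: step width (each placement against the
   most recent contralateral placement) and its SD; for narrow-base trials
   the foot placement error (overshoot of the furthest-protruding foot edge
   beyond the nearer beam edge, zero when the whole foot is inside) and the
   percentage of steps placed wholly inside the beam; peak-to-peak
   mediolateral trunk CoM displacement, its SD, and mean absolute ML CoM
   velocity per stride; single/double-support times as % of the stride.
4. **Local divergence exponent (LDE)** of trunk CoM velocity by
   Rosenstein's method: 160 strides time-normalized to 16000 samples
   (100/stride, between-stride variability preserved), delay embedding with
   dimension 5 and delay 10 samples, nearest neighbours under a temporal
   exclusion window, mean log divergence tracked over offsets, and a linear
   fit over half a stride. Reported in ln-units per stride.
5. **EMG**: 50 Hz high-pass (4th-order Butterworth, zero-phase), 1 Hz-wide
   notches at 50 Hz and all harmonics below Nyquist (1st order), envelope as
   the magnitude of the analytic signal low-passed at 20 Hz (2nd order),
   per-trial per-channel maximum normalization, and stride-time
   normalization to the matrix **E** (11 muscles x strides*100).
6. **Synergies**: non-negative matrix factorization E = W A with Lee-Seung
   multiplicative updates (squared Frobenius objective), 50 random restarts,
   at most 1000 iterations, stopping when the relative objective decrease
   falls below 1e-6. Muscle weightings are held fixed across the six
   condition/time-point blocks of a subject by factorizing the
   column-concatenated E once and slicing the activations back per block.
   Five synergies are used (the smallest number reaching 85 % VAF on the
   synthetic reference data; a six-synergy sensitivity configuration is one
   `nnmf(E, 6)` call away).
7. **Timing metrics** per synergy and stride: FWHM (samples above half the
   min-subtracted maximum) and CoA (angle of the circular first moment of
   the activation profile, gait cycle mapped to $[0, 2\pi)$ with the
   dominant heel strike at 0). FWHM averages arithmetically across strides,
   CoA by the circular mean.
8. **Statistics**: two-way repeated-measures ANOVAs
   (Training x Condition) for gait metrics and FWHM, one-way for the
   narrow-base-only beam scores, with Mauchly's test per within factor and
   Greenhouse-Geisser scaling of both degrees of freedom when sphericity is
   rejected at p < 0.05; Holm-corrected paired-t post-hocs (family:
   Pre vs Post1, Pre vs Post2); and the Harrison-Kanji two-way circular
   ANOVA for CoA.

## The synthetic-data generator

No recordings ship with the package; every stage is validated against a
generator whose ground truth is known exactly and stored
(`ground_truth()`, `gen_emg()`, `gen_kinematics()`, `gen_cohort()`).

**Events and placements.** Stride durations are log-normal with mean 1.08 s
(typical cadence at 3.5 km/h) and CV 3 % — nonzero so that stride-time
normalization is exercised with genuine between-stride variability.
Contralateral strikes fall at 50 % phase (SD 0.5 %). Foot centres lie at
half the target step width on either side of the midline (the beam centre
in narrow trials) with per-placement noise of SD `step_width_sd`/sqrt(2);
edges sit at +/- half a 10 cm foot width. Defaults: step width 0.12 m
(normal) and 0.05 m (narrow), SD 0.02 m. With the 12 cm beam these defaults
put the narrow-base foot placement error near 1.5 cm and the share of
wholly-in-beam steps in the tens of percent — the performance regime of
older adults on this task.

**EMG.** Each channel is
$\sum_j W_{mj} A_j(t)$ + tonic baseline, amplitude-modulating unit-variance
20–450 Hz Gaussian carrier noise, plus white noise at the requested SNR
(default 20 dB) and an optional mains sinusoid. The activation profiles
$A_j$ are circular Gaussian bumps in % gait cycle (centres 30, 5, 55, 90,
45; SDs 5, 4, 5, 4, 4; amplitudes 0.65–1, balanced so no synergy dominates
the variance). Two realism terms set the factorization's unexplained
variance: log-normal per-stride, per-synergy recruitment jitter (CV 0.15)
and slow muscle-specific activity outside the synergy model (squared
Ornstein-Uhlenbeck processes, amplitude 0.13). With these, the VAF curve of
the reference data crosses 85 % exactly at k = 5 with VAF(5) ≈ 0.85–0.88 —
the regime the pipeline's k-selection is designed for. The weighting matrix
mirrors the usual organisation of treadmill-walking synergies
(dominant-leg push-off, dominant-leg weight acceptance, non-dominant
stance, and the two pre-heel-strike hamstring synergies).

**Kinematics and CoP.** The trunk ML trajectory is a stochastic limit-cycle
oscillator: $a(1 + 0.35 g \eta_a)\sin(2\pi\phi + 0.6 g \eta_p)$ with
$\phi$ the gait phase, $\eta$ Ornstein-Uhlenbeck noise (time constant
0.6 s) and $g$ the divergence gain, plus fixed marker noise (0.4 mm RMS) —
fixed because it belongs to the measurement system, not the gait dynamics.
This split matters: the gain scales the dynamic cloud relative to a
gain-independent noise floor, which is what makes the estimated LDE
increase monotonically with $g$ (with purely multiplicative noise both the
nearest-neighbour distance and the saturation level scale together and the
slope would be flat). At $g = 0$ and zero marker noise the trunk is an
exact function of phase, i.e. strictly periodic in stride-normalized time.
The CoP AP component is a $\cos^2$ arch per step, so every heel strike is
an anterior maximum exactly at its ground-truth time (virtual events extend
the pattern past the trial edges so first and last strikes remain interior
maxima); the ML component blends between stance feet, crossing their
midline at `ds_frac` (default 0.2) of each step — the basis of the
CoP-derived toe-off approximation used for support times.

**What the generator does not emulate:** vertical ground reaction forces,
anatomical segment models (trunk CoM is the marker-cluster ML trajectory),
electromechanical delay, EMG crosstalk between channels, and non-stationary
fatigue drift. Passing tests therefore demonstrate algorithmic correctness
and recoverability under controlled, realistic noise — not robustness to
every artefact of a real laboratory recording.

## Numerical choices

* **Zero-phase filtering** pads with the odd reflection of the signal and
  runs the Butterworth cascade forward and backward in compiled code. The
  result is symmetrized with the time-reversed conjugate pass, so the chain
  commutes with time reversal to machine precision — the property that
  guarantees activation-timing metrics are not biased by filter delay. The
  19-section notch cascade rings for hundreds of samples, hence the
  generous (2 s) padding.
* **Hilbert transform** by a 401-tap windowed antisymmetric FIR
  transformer rather than an FFT: the FIR version has no length
  restrictions (R's mixed-radix FFT degrades badly on awkward signal
  lengths) and anticommutes with time reversal exactly. Its response rolls
  off below ~10 Hz, irrelevant after the 50 Hz high-pass.
* **NNMF** restarts draw uniform(0,1] initial factors from a seed stream;
  the best of 50 restarts is kept. The W/A scale ambiguity is fixed by
  max-normalizing W columns (activation profiles then carry the amplitude,
  keeping FWHM/CoA scale-free). `select_k` warm-starts k from the k-1
  solution plus a random component, which keeps the VAF curve
  non-decreasing.
* **LDE**: the temporal exclusion window is half a stride (50 samples) — a
  Theiler-style guard against trivially-near-in-time neighbours; offsets
  where fewer than half of the tracked pairs survive are truncated; pairs
  with exactly coincident states carry no divergence information and are
  skipped. The fit window is offsets [0, 50), slope reported as ln/stride
  (x100). On a Lorenz benchmark (dt 0.04, 16000 samples) the estimate
  agrees with a Benettin variational oracle within 20 %.
* **Sphericity**: Greenhouse-Geisser epsilon and Mauchly's W are computed
  from the orthonormalized effect-contrast covariance (cross-checked in the
  test suite against `stats::anova.mlm` and `stats::mauchly.test`); the
  correction is applied only when Mauchly rejects at 0.05 and the effect
  has more than one numerator df.
* **Harrison-Kanji** switches between the high-concentration F form (with
  the 1/(1 - 1/(5k) - 1/(10k^2)) bias correction) and the low-concentration
  chi-squared form at kappa = 2, with kappa estimated from the overall mean
  resultant length by Fisher's approximations.
* **Degenerate inputs**: flat activation profiles have FWHM 0; CoA and the
  circular mean error on zero resultant length; all-equal responses give
  F = 0; a narrow-base trial without beam geometry is an error naming the
  stage.

## Problem sizes used in validation

The packaged tests run the full study geometry where the check demands it
(synergy recovery and k-selection on 160 strides with 50 restarts; 200
replicate null cohorts for type-I error) and scaled-down versions elsewhere
(40-stride trials for unit tests; 20-subject, 30-stride cohorts with 3
restarts for end-to-end effect recovery). The reduced sizes were chosen so
the imposed effects are still comfortably detectable; they are analysis
choices, stated here so results can be reproduced exactly.

## Known limitations

* NMF identifiability: with the default generator geometry the two
  non-dominant-leg synergies overlap in time (activation centres 45 % and
  55 % of the cycle) and share rectus femoris loading. At occasional noise
  realizations the *lowest-error* factorization merges them and splits the
  dominant-stance synergy instead — more restarts cannot avoid this, since
  the merged basis genuinely fits better. Batch analyses should check
  matched weighting cosines (or replicate trials) rather than rely on VAF,
  which stays normal in these cases.

* The CoP peak-detection rule is a reconstruction of the butterfly-geometry
  idea; the exact algorithm of the original instrumentation literature is
  not reproduced.
* Toe-off (for support times) is approximated from the CoP mediolateral
  midline crossing; against force-plate toe-offs this is a proxy only.
* Leg assignment uses the anterior-position criterion; other foot-kinematic
  criteria (e.g. velocity reversal) are not implemented.
* The on-disk dialect is CSV plus a JSON header sidecar; motion-capture
  container formats (C3D) are not read.
* `rm_anova` covers balanced, complete, fully-within designs only —
  incomplete subjects are dropped upstream, mirroring the study's handling
  of a participant unable to complete the protocol.
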