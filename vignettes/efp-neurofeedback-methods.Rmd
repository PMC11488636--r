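---
title: "EEG-fingerprint amygdala neurofeedback: models, simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-fingerprint amygdala neurofeedback: models, simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efpnf)
```

## Overview

`efpnf` reimplements, as testable code, the computational core of a
scalable amygdala neurofeedback method: an *electrical fingerprint* (EFP)
model that predicts right-amygdala BOLD activity from a single EEG channel,
the closed-loop Watch/Regulate training protocol built on it, the
rt-fMRI transfer analysis, and the trial-level statistics of a randomized
add-on study in treatment-resistant PTSD. Because no raw recordings from
such trials are shared, the package pairs every stage with a synthetic
generator whose ground truth is known, so that each algorithm can be
validated by parameter recovery rather than by eye.

## The EFP model

The online estimate is produced every 3 s from the trailing 12 s of the Pz
channel sampled at 250 Hz:

1. **Notch filter.** 50-Hz line interference is removed with a zero-phase
   (magnitude-squared, i.e. two-pass equivalent) biquad notch of 1 Hz
   bandwidth, applied on the segment's DFT grid. We deliberately avoid a
   running forward-backward IIR pass here: on a 12-s segment the filter's
   onset transient (pole radius 0.9905 at 250 Hz) leaves more residual
   energy than the line component itself, whereas the spectral application
   attains the steady-state response exactly — an on-grid tone is removed
   to machine precision, and the filter deviates from the identity by
   under 0.1% RMS on broadband signals.
2. **Stockwell transform.** The segment is converted to a time-frequency
   representation with a Gaussian window whose width scales inversely with
   frequency (`sigma_t = 1/f`), computed through the FFT identity: the
   voice at `v` cycles per segment is the inverse DFT of the shifted
   spectrum times `exp(-2 pi^2 m^2 / v^2)`. The frequency-domain Gaussian
   includes its ±2 spectral aliases, which makes the implementation equal
   to the direct periodised double-sum definition to ~1e-13 relative — a
   property the test suite asserts against an independent O(N²) oracle.
3. **Feature reduction.** Amplitudes are averaged within 10 frequency
   bands chosen so that each carries one tenth of a calibration
   recording's spectral energy between 0.5 and 40 Hz (an
   *energy-uniformity* constraint, computed as deciles of the interpolated
   cumulative periodogram; band edges for analytic spectra match their
   closed-form quantiles within 1%). The time axis is reduced to 4 Hz by
   non-overlapping block means, giving a 10 x 48 window per estimate; the
   window convention is half-open, `(t - 12, t]`, and requested times snap
   to the nearest EEG sample.
4. **Linear read-out.** The estimate is `b0 + <W, X(t)>`. The published
   weight set is proprietary and not printed anywhere, so the package
   *fits* `W` by ridge regression of the flattened 480-vector features on
   a hemodynamically lagged target, with the penalty chosen from a
   logarithmic grid (1e-3..1e3) by blocked cross-validation over
   contiguous thirds — plain k-fold would leak information through the
   strong temporal autocorrelation of both features and target.

Two target conventions are supported: the default convolves the latent
arousal with the canonical HRF and samples it at window end times
("current fMRI activity" lives on a hemodynamic timescale); the
alternative lags the raw latent by a fixed 6 s. A consequence worth
knowing: with the HRF target, even a noise-free linear sensing chain tops
out near r = 0.98, because the HRF integrates latent history older than
the 12-s feature window — no linear read-out of a 12-s window can do
better, in any implementation. Exact-recovery checks therefore use targets
constructed as linear functionals of the features themselves, where the
regression identity applies.

## The closed-loop engine

The standard training session is a 3-min resting baseline followed by five
cycles of Watch (60 s) and Regulate (180 s); an rt-fMRI assessment variant
(54-s rest, then two cycles of Watch 60 s / Regulate 60 s / Washout 9 s /
Fixation 15 s) is also built in. During Regulate, each 3-s EFP sample is
standardised against the sample mean and (n-1) SD of the *immediately
preceding* Watch block — never a running aggregate, and never the
Regulate block's own statistics — and mapped to a discrete feedback level:

```
level = clamp(round(5.5 + 2 Z), 1, 10)      (round half up)
```

The mapping is a design choice (no published parameterisation exists): the
slope-2, centre-5.5 affine rule spans the scale at ±2.25 SD, puts Z = 0 at
mid-scale (level 6), and is monotone. Feedback couples back to the
simulated participant multiplicatively: the agent's Regulate drift is
scaled by `(11 - level)/10`, so rewarding feedback sustains regulation.
Watch blocks and the first samples of a session (before 12 s of EEG
history exist) receive no feedback; missing-history estimates are flagged
rather than silently dropped.

Per cycle, regulation success is
`SI = (mean(Regulate) - mean(Watch)) / sd(Watch)`; a session's success is
the mean over its five cycles. A cycle in which nothing varies at all
(constant Watch *and* equal means — the 0/0 case of a completely inert
simulation) is reported as 0; a constant Watch with a genuine mean shift
stays flagged as degenerate.

## The synthetic-data layer

*Latent arousal* is an Ornstein-Uhlenbeck process at 4 Hz (matching the
feature grid), upsampled linearly to 250 Hz where needed. *EEG* is built
from 1/f background noise, a 50-Hz line component, white sensor noise and
narrow-band oscillations whose instantaneous amplitudes are affine in the
latent: by default theta (4-8 Hz) couples positively and beta (13-30 Hz)
negatively — an arbitrary but fixed ground-truth convention the EFP
learner must not (and does not) assume. Amplitudes are clipped at zero,
since an oscillation cannot have negative amplitude; the affine relation
holds in the operating range. Carriers are phase-diffusing sinusoids, so
their envelope is the amplitude itself and coupling slopes are recoverable
from noise-free data within 5%. *BOLD* is the latent convolved with an
SPM-style double-gamma HRF (response gamma shape 6, undershoot shape 16,
ratio 6, 32-s kernel, peak-normalised; the response peaks near 5 s).

*The regulating agent* drifts downward during Regulate at
`gain * (1 + learning_rate * (session - 1))` units/s and relaxes to
baseline with a 5-s time constant elsewhere, plus diffusion noise. The
defaults (`regulate_gain = 0.0035`, `noise_sd = 0.35`,
`learning_rate = 0.1`) were chosen once so that simulated cohorts
reproduce the noisy group-level regulation trajectory reported for real
patients: simulated mean success is about -0.57 (SD 0.88) over sessions
1-5 and -0.80 over sessions 6-10, against published group values of -0.58
(0.46) and -0.82 (0.85). Under those realistic conditions the paired
first-half/last-half contrast is only marginally powered — exactly as in
the real cohort — so property checks of the learning *machinery* (the
requirement that a positive learning rate produces near-universal
improvement) use the documented high-signal `skilled_agent()`
configuration (`gain = 0.02`, `learning_rate = 0.3`, `noise_sd = 0.1`)
instead. The relaxation constant matters more than it looks: with slow
relaxation (tens of seconds) the Watch baseline after a deep Regulate
block is dominated by the recovery transient, the next block's feedback
turns punitive, and the multiplicative coupling can collapse regulation
entirely — a genuine failure mode of preceding-Watch normalisation that
the 5-s default avoids.

*Clinical cohorts* are drawn per subject and timepoint (pre, post, 1, 3
and 6 months) for three instruments — clinician-administered PTSD
interview (0-80), PTSD self-report checklist (0-80) and a dissociation
scale (0-100) — as Gaussian scores around group trajectory means with a
subject random intercept (ICC 0.6) and clipping to the instrument range.
Default pre-treatment means/SDs, arm sizes (40/15, the trial's 2.5/1
allocation), the immediate reductions (8.86 vs 3.28 points) and
loss-of-diagnosis probabilities (0.40 vs 0.15, an absolute risk reduction
of 25%) follow the published group table and results; follow-up
trajectory means were set once to land on the published 6-month
self-report means. Dropout is missing-at-random per timepoint (0, 3.5%,
25%, 35%, 50%), which is the missingness regime a REML likelihood handles
correctly.

What the generators do *not* emulate: volume conduction or multichannel
structure (only Pz carries signal), artifacts (blinks, EMG), non-Gaussian
score distributions, informative dropout, or any dissociation-specific
mechanism beyond a score trajectory. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under a known model —
not clinical validity on real recordings.

## The inferential layer

* **Immediate effect** — ANCOVA: `post ~ pre + group` on listwise-complete
  cases; group F on (1, n-3) df; partial eta squared
  `SS_group / (SS_group + SS_residual)` (the identity
  `eta^2 = F df1 / (F df1 + df2)` is asserted on every fit).
* **Follow-up** — REML linear mixed model `score ~ group * time` with a
  subject random intercept, which *is* the compound-symmetry covariance
  structure (the test suite checks REML log-likelihood equality against a
  marginal compound-symmetry fit to 1e-6 on balanced data). Time enters as
  a numeric 0..4 covariate by default (the five assessments), with a
  categorical option for sensitivity. Intention-to-treat uses all
  randomized subjects through the likelihood; the per-protocol variant
  refits on completers.
* **Training modulation** — classical two-way within-subject ANOVA
  (condition x session) with each effect tested against its own
  subject-interaction stratum; on a two-level reduction the condition F
  equals the squared paired t exactly.
* **Learning contrast** — paired t of per-subject means over sessions 1-5
  vs 6-10, halves averaged over available sessions.
* **Multiplicity** — Benjamini-Hochberg step-up FDR via `p.adjust`.
* **Clinical efficacy** — ARR and NNT from loss-of-diagnosis counts; the
  ARR interval uses the Newcombe hybrid score method (Wilson limits per
  arm), which behaves well at these sample sizes; a Wald variant is
  available for comparison. When the ARR interval straddles zero no
  reciprocal NNT interval is reported (the reciprocal of an interval
  containing zero is disjoint half-lines).
* All p-values are two-tailed.

A power utility reproduces a conventional a-priori computation (partial
eta squared 0.16, alpha 0.05, power 0.8 gives a total N in the low 40s;
published calculators differ by a few subjects depending on the assumed
test family, which is why this is a utility rather than a validated
quantity).

## Numerical and design choices

* OU paths use the exact discretisation (no Euler error) and start from
  the stationary distribution; all generators take explicit seeds and
  restore the caller's RNG state.
* The S-transform zero-frequency row carries the segment mean; band
  assignment is half-open `(e_k, e_k+1]` with the first band closed below;
  the 4-Hz time reduction uses non-overlapping blocks of 62/63 samples
  (3000 samples do not divide evenly into 48 blocks).
* Ridge fitting centres features and target but does not rescale
  features — the weights keep physical units (prediction units per µV),
  and exact recovery at small penalties is preserved.
* The GLM convolves condition boxcars on a 0.1-s grid, scales by the grid
  step (so regressor amplitude is grid-independent), and samples at volume
  onsets; TR defaults to 3 s and is configurable, since acquisition
  details are not part of the modelled text. Rank deficiency fails loudly,
  naming the collinear columns. The contrast sign convention (positive
  Watch-Regulate = down-regulation) is asserted to be consistent with the
  negative success index on the same synthetic subject.
* BrainVision output is binary multiplexed little-endian IEEE float32 with
  1-based marker positions; INT_16 input is accepted with per-channel
  resolution scaling, other encodings are rejected by name. The dialect is
  cross-checked against an independent reader (MNE-Python) in the test
  suite. An EDF export is not provided.
* The CLI is a thin wrapper over exported functions; logging goes to
  stderr and cannot alter numerical artifacts (asserted by a test).

## Problem sizes used in validation

The validation suite calibrates the EFP model on 20 minutes of synthetic
simultaneous EEG-BOLD (397 windows), runs one full-protocol closed-loop
session (460 estimates), checks the learning property on 200 simulated
subjects and the learning-contrast power on 200 cohorts of 30 subjects
(via the scalable open-loop path: success indices computed from the
agent's latent arousal on the 3-s grid — the full sensing loop is
exercised on single sessions), and estimates each type-I error rate from
1000 null replications. Unit tests use a shared 7-minute calibration and a
reduced two-cycle schedule.

## Known limitations

* The fitted weights are synthetic-data weights; nothing here reproduces
  the proprietary published model, only the architecture around it.
* The energy-uniform bands are computed per calibration recording; whether
  the deployed system froze population-level bands is not documented, so a
  fixed `band_definition` can be supplied where stability across subjects
  is wanted.
* The EEG-to-amygdala coupling spectrum of real data is uncharacterised in
  the modelled text; the theta/beta choice is a stand-in and is clearly
  flagged as generator ground truth, not neuroscience.
* Washout is modelled as the 9-s feedback display only; the 15-s fixation
  is unmodelled baseline.
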