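---
title: "Measuring attentional modulation along the visual hierarchy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring attentional modulation along the visual hierarchy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnmod)
```

## The scientific question and the measurement model

Covert spatial attention comes in two flavors: *endogenous* attention is
voluntary, deployed over roughly 300 ms in response to an informative
central cue, and sustainable; *exogenous* attention is involuntary,
captured within about 100 ms by a salient peripheral cue, and transient.
Both improve performance in a 2-AFC orientation discrimination, whether
the cue arrives before the stimulus (a *pre-cue*, acting on encoding) or
after it (a *post-cue*, acting on read-out). The question this package's
pipeline is built to answer on simulated data is how the accompanying
modulation of stimulus-evoked BOLD responses is distributed across the
visual hierarchy (V1, V2, V3, V3A, hV4, LO1) for each attention type and
cue epoch.

The response measure is the per-condition amplitude (percent signal
change) of each ROI's mean time course, estimated by an event-related
GLM, summarized by the **Attentional Modulation Index**

$$\mathrm{AMI} = \frac{V_c + k}{\tfrac14\left[(V_c+k) + (I_c+k) + (V_i+k) + (I_i+k)\right]},$$

where $V_c, I_c$ are the valid/invalid amplitudes contralateral to the
cue, $V_i, I_i$ the ipsilateral (distractor) ones, and $k$ a constant
(default 0.2) added to every condition value so the ratio is formed on
positive quantities. AMI = 1 means no modulation; the index is invariant
to overall response magnitude, which differs strongly between V1 and
later areas. Summing the AMI over the four possible numerator choices
gives exactly 4 for any amplitudes and constant — a useful conservation
check that the tests exploit.

Group-level inference then asks which regimes hold: the hypothesis
structure is that the valid−invalid difference *increases* along the
hierarchy for endogenous pre-cues, is *flat* for exogenous pre-cues,
*flat positive* for endogenous post-cues and *absent* for exogenous
post-cues. Three tools address it: per-ROI paired one-tailed t-tests
(valid > invalid), ordinary regressions of the group-mean difference on
hierarchy rank (six points, slope tested with F(1, 4)), and linear mixed
models of the participant-level differences.

## Trial design

Sessions mix 40% pre-cue, 40% post-cue, 10% cue-only and 10% blank
trials, counterbalanced exactly (session-level by default; per-run
optionally, since the mixture is only stated per session). Validity is
0.75 for endogenous and 0.50 for exogenous sessions, and the response
cue points left on exactly half of the stimulus trials. Cues last 67 ms,
the cue–stimulus ISI is 50 ms (exogenous) or 250 ms (endogenous) — SOAs
of 117 and 317 ms — the gratings last 50 ms, and an 800 ms response cue
ends the 1.7 s (exogenous) or 1.9 s (endogenous) trial; post-cue trials
swap the cue and stimulus intervals with identical durations.

The inter-trial interval is not dictated by the design above, so the
generator places each trial in a fixed slot of 7 s (4 TRs at TR =
1.75 s) after a 14 s lead-in (the 8 volumes later discarded), making
every run an integer number of volumes. Fixed slots keep onsets exactly
known for the GLM; randomized jitter would improve design efficiency for
real scanning but adds nothing to correctness checks.

## The behavioral observer

The simulated observer's accuracy is a cumulative Gaussian in tilt
$\theta$ with lapse rate $\lambda$:
$p(\text{correct}) = \lambda/2 + (1-\lambda)\,\Phi(\theta s_v/\sigma)$,
with sensitivity factor $s_v = 1$ on valid and `validity_effect` < 1 on
invalid trials — attention as a sensitivity gain. Defaults
($\sigma = 1.5^\circ$, validity effect 0.7, lapse 0.01) put the 79%
threshold near 1.2° of tilt, a realistic value for brief peripheral
gratings. Reaction times are shifted log-normals, slower on invalid
trials, so that valid cues are both faster and more accurate (no
speed–accuracy trade-off, checked as a sign constraint).

Tilt is titrated by a 3-down-1-up staircase (three consecutive correct
valid trials step down, each error steps up), whose equilibrium is the
79.4% point — the standard way to hold performance near 80% correct.
Steps halve after every second reversal down to a floor of 0.1°. The
returned estimate is the mean tilt over the stationary stretch (all
trials after the step first reaches its floor), which is less variable
than a reversal average. Two properties matter for interpreting tests:
the estimate is unbiased (mean accuracy at the returned tilt ≈ 80%), but
a single 400-trial staircase carries an intrinsic spread of about 2
percentage points in achieved accuracy — the binomial information limit
near p = 0.8, which no estimator can beat. Non-convergence (a drifting
stationary stretch, or tilt pinned at the ceiling because lapse or a
tilt bound caps accuracy below target) is flagged and warned about, not
silently accepted.

d′ uses the clockwise-as-signal convention: CW responses to CW targets
are hits, to CCW targets false alarms, $d' = z(H) - z(F)$, with extreme
rates replaced by $1/(2N)$ and $1 - 1/(2N)$. Target orientations are
counterbalanced within epoch × validity cells; if exclusions still
empty one orientation in a small cell, the symmetric-observer identity
$d' = 2\,z(p_c)$ is used for that cell.

## The synthetic BOLD generator

Each stimulus-responsive voxel's series is baseline (100) plus, per
trial, its condition amplitude times a canonical double-gamma HRF
(peak 5 s, undershoot 15 s at 1/6 amplitude, peak-normalized so betas
are peak amplitudes in percent signal change) shifted to the event
anchor — stimulus onset for stimulus trials, cue onset for cue-only,
response-cue onset for blank trials — plus a random linear drift (up to
±0.5% per run) and AR(1) noise (innovation SD 0.3%, coefficient 0.3).
Laterality follows the cue: a left cue drives right-hemisphere voxels at
the contralateral amplitude and left-hemisphere voxels at the lower
ipsilateral amplitude. Per-voxel amplitudes scatter around the ROI mean
(SD 0.05%), and per-participant effect sizes carry a multiplicative gain
(SD 0.15) so mixed-model random slopes have something real to estimate.

Ground-truth amplitudes place the contralateral baseline at 0.8% and the
ipsilateral at 0.5% signal change, with the valid−invalid difference
following the regime profile: 0.05% per rank unit ("increasing"), a
constant 0.15% ("flat"), or zero ("null"); cue-only responses are
0.3%/0.15% (contra/ipsi) and blank (response-cue-evoked) responses 0.1%.
These are ordinary magnitudes for extrastriate attention effects and
leave the exactly-null exogenous-post regime as the negative control.

The localizer is a block protocol: 16 cycles of 17.5 s (8.75 s on /
8.75 s off), 280 s and 160 volumes per run; responsive voxels carry an
HRF-convolved boxcar (plateau 1.5%) plus the same noise. The generator
deliberately includes the drift and serial correlation that the
preprocessing is supposed to remove, so the filters are testable.

What the generator does *not* emulate: spatial autocorrelation and
voxel-to-voxel noise correlations, motion and physiological artifacts,
field inhomogeneity, and surface geometry. Passing tests therefore show
that the analysis recovers what it claims from data satisfying its own
model — parameter recovery and calibration — not that it is robust to
every artifact of real scanning.

## Voxel selection from the localizer

Runs are averaged voxel-wise and each voxel fit with a sinusoid at the
cycle frequency (1/17.5 Hz), which for a whole number of cycles is the
discrete Fourier component. *Coherence* is the spectral amplitude at the
stimulus frequency divided by the root-sum-square over all non-DC
frequencies up to Nyquist: 1 for a pure sinusoid, $1/\sqrt{2}$ when an
equal-amplitude second component is present, and for white noise its
square follows a Beta(1, M−1) law over M frequency bins — giving a
closed-form null rate for the selection threshold that the tests check
against.

Selection keeps voxels with coherence strictly greater than 0.2 and
phase strictly inside (0, π), both thresholds deliberately strict.
The phase is reported relative to the stimulus-on fundamental: the
on-block starting at t = 0 makes the fundamental sine-like
(cosine-phase π/2), and subtracting that reference turns the fitted
phase into the response's hemodynamic lag, which lands near 2 rad —
inside (0, π) — for a 5–6 s delay. (The raw best-fit cosine phase at run
start would sit near 3.6 rad and escape the window; referencing to the
stimulus is what makes the (0, π) criterion mean "responds during the
on-block".) An ROI whose voxels all fail selection triggers a warning
naming the ROI and falls back to all of its voxels, so an analysis never
silently loses an area.

## Preprocessing and the event-related GLM

Per run: the first 8 volumes are discarded, a per-voxel linear trend is
removed, frequencies below 0.01 Hz are projected out on a discrete-cosine
basis (chosen because its transfer behavior is exactly characterizable —
a 0.001 Hz drift loses well over 90% of its variance), and the data are
converted to percent signal change about the voxel mean. The orthonormal
nuisance basis is stored with the run and the design matrix is pushed
through the same projection (the Frisch–Waugh device), so filtering the
data cannot bias the condition betas; per-run intercepts are annihilated
by that projection and therefore omitted. For simulated data the
percent-signal-change conversion can be taken about the nominal baseline
of 100 instead of the voxel mean, which makes the whole pipeline exactly
linear — noiseless recovery is then exact to machine precision, while
the voxel-mean convention carries a small (~0.4%) multiplicative bias
from task signal leaking into the mean, far below the 5% recovery
tolerance used at default noise.

The GLM has twelve condition regressors — cue side × validity × epoch
(8), left/right cue-only, blank, and eye-movement — built as exact sums
of HRF kernels at the event anchors, sampled at the post-discard volume
times. Fixation-break trials load only on the eye-movement regressor
(one pooled regressor; per-side variants would add two columns but the
pooled form matches how exclusion nuisances are usually modeled).
Incorrect trials are diverted to a separate nuisance column rather than
deleted, so the condition betas reflect correct trials only while the
baseline structure of cue-only and blank trials is preserved. Absent
conditions yield flagged all-zero columns that are dropped before the
fit; any remaining rank deficiency is an error naming the offending
columns. Estimation is ordinary least squares; serial correlation in the
noise costs efficiency but not consistency, and no prewhitening or
external denoising is applied — the synthetic noise is controlled, and
denoising would add a fitted component the recovery tests could not
separate from the estimator itself.

## AMI construction and group inference

For each participant × ROI × attention type × cue epoch, $V_c$ and $I_c$
are the epoch-specific contralateral amplitudes (averaged over the two
cue sides) and $V_i, I_i$ the ipsilateral amplitudes pooled over pre and
post cues — the distractor terms are epoch-unspecific by construction of
the display (the ipsilateral stimulus is a distractor in both epochs); a
fully epoch-specific variant is available via `ipsi_epoch_specific`. The
constant is added per participant to all condition values. Downstream:

* **AMI vs 1**: participant means over all conditions and ROIs, two-sided
  one-sample t-test against 1, Cohen's d = (mean − 1)/SD.
* **Per-ROI tests**: paired one-tailed t (valid > invalid), no
  multiple-comparison correction by default (Holm available) — matching
  how such per-area tests are conventionally reported.
* **Hierarchy regressions**: the six group-mean differences on ranks
  1–6; the slope's F statistic has (1, 4) degrees of freedom (with six
  points a simple regression leaves four residual df).
* **Mixed models**, one per cue epoch: difference ~ rank × attention with
  by-participant random intercepts and *independent* random slopes for
  rank and attention (no random interaction; the correlated structure is
  available, but with five participants independent slopes are the
  least-fragile choice). Attention is coded ±½ so the intercept is the
  grand mean; note that under ±½ coding the interaction coefficient
  equals the *full* difference between the two attention conditions'
  rank slopes. Fits use maximum likelihood; p-values come from
  likelihood-ratio tests of nested models; t statistics are reported
  with df = observations − fixed effects (56 for 5 × 6 × 2). Singular
  fits — inevitable in noiseless checks — are reported, and on outright
  non-convergence the structure falls back to random intercepts with the
  fallback logged in the result.

Hierarchy ranks are V1 < V2 < V3 < V3A < hV4 < LO1 (1–6). There is no
consensus ordering beyond V3; the mapping is a package constant that
every consumer accepts as an argument, so alternative orderings are a
one-line change.

## Numerical and degenerate-input choices

* Coherence thresholds and the phase window are strict inequalities;
  equality at 0.2 or at 0/π excludes the voxel.
* Exactly linear hierarchy differences give R² = 1 with an infinite F
  (p = 0); exactly constant differences give slope 0, R² = 0, F = 0
  (p = 1), handled explicitly rather than through lm's near-singular
  summary.
* All-zero paired differences put the one-tailed test at its null
  midpoint (t = 0, p = 0.5); constant non-zero differences are
  sign-determined limits.
* Zero-variance participant AMI means make the one-sample test
  degenerate; it is reported as such instead of producing an infinite t.
* d′ extreme rates are clamped at 1/(2N); the staircase reports rather
  than hides non-convergence; the AMI errors with guidance when the
  offset denominator is non-positive.

## Problem sizes

The package defaults and test fixtures are desk-scale by choice: 5
participants, 2 event-related runs of 40 trials per attention condition,
12–20 voxels per ROI/hemisphere, 1–2 localizer runs, 200-replicate
Monte-Carlo loops for recovery and calibration checks. The study design
these emulate used 14 runs × 3 sessions per condition and whole visual
areas; all scale parameters are config fields, and nothing in the code
depends on the desk-scale values.

## Known limitations

OLS without prewhitening is inefficient under AR(1) noise (standard
errors of single-run betas are approximate; group inference rests on
participant-level variability, not on those standard errors). The
coherence null is exact only for white noise — serial correlation
reshapes the null spectrum, raising the false-positive rate at a fixed
threshold (observable with the generator's AR noise switched on). The
behavioral observer has no criterion shifts, no response-window misses
beyond the exclusion flag, and the between-run tilt adjustment of a real
experiment is reduced to a single titration. Five participants make the
mixed models small by construction; singular fits at that size are a
property of the design, not a bug in the estimator.
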