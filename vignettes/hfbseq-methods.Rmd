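---
title: "Methods: single-trial HFB activation analysis and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial HFB activation analysis and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `hfbseq`, the
assumptions it makes, every tunable parameter that matters, and the
numerical design decisions taken where the underlying procedure was
genuinely open. It is the authoritative account of *why* the package
computes what it computes; the README shows *how* to run it.

## 1. Signal model and preprocessing

ECoG voltage is modelled as a multichannel series sampled at ≥ 1000 Hz
containing (i) a 1/f "pink" background, (ii) power-line contamination at
60 Hz and harmonics, and (iii) task-evoked broadband bursts in the
70–180 Hz high-frequency band (HFB), a proxy for aggregate population
spiking. The preprocessing order is fixed and matters:

1. **Notch filtering** — zero-phase (forward–backward) Butterworth
   band-stops at 57–63, 117–123 and 177–183 Hz, with 2 s of reflected
   signal at each edge to damp transients. The 177–183 Hz band sits
   *inside* the HFB range, so skipping it would leak line harmonics into
   the signal of interest.
2. **Common-average re-referencing** — each retained channel minus the
   mean of retained channels; clinically excluded channels are dropped
   before the mean and from all downstream analysis.
3. **Morlet decomposition** — 5-cycle Morlet wavelet power per analysis
   band, implemented as FFT convolution with an analytic gaussian kernel
   (spectral SD = f/5). The band grid within the HFB range is 70, 80,
   …, 180 Hz (12 bands, 10-Hz spacing). A finer low-frequency grid is
   irrelevant here because only bands with centers in [70, 180] Hz enter
   any result.
4. **Per-band z-transform across the whole recording.** The z-scope
   (whole recording rather than per run) is a documented choice: it
   stabilises the normalisation and is the conservative reading of
   "z-transformed across time".
5. **Epoching** to [−200, 5000] ms around stimulus onset; **per-trial,
   per-band baseline correction** by the mean over [−200, 0) ms; **band
   averaging** to a single HFB trace. Both operations are linear, so the
   implementation averages bands first and subtracts the averaged
   baseline once — algebraically identical and cheaper.
6. **Gaussian smoothing**, "width = 50 ms" interpreted as total kernel
   support (SD = 50/6 ms, truncated at ±25 ms). The alternative reading
   (SD = 50 ms) would smear activations by hundreds of milliseconds and
   make 50-ms persistence meaningless.
7. **Masking**: timepoints at or after RT + 200 ms belong to the next
   trial and are invalid. Per (site, condition, timepoint), observations
   more than 3 *scaled* MADs (consistency constant 1.4826) from the
   cross-trial median are masked; with the unscaled MAD the rule would
   over-mask gaussian data by construction. A zero MAD skips the rule at
   that timepoint; conditions with fewer than 5 trials are skipped.
   Baseline samples are never masked, so every trial keeps a valid
   reference.

Trial exclusions: epileptic high-frequency oscillations, missing
responses, irrelevant button presses, RT < 400 ms (exactly 400 ms is
retained), and cued-rest trials. Exclusion reasons are logged per trial.

## 2. The single-trial detector

Each trial's trace is tested at every valid timepoint in
[0, RT + 200] ms with a sliding ±10 ms window against the same trial's
baseline. Windows shrink at range edges rather than pad; windows with
fewer than 3 valid samples get p = 1.

**Why not a textbook two-sample Welch test here?** Smoothed HFB samples
are strongly serially correlated (wavelet support plus the 50-ms
kernel). A Welch test that counts the ~21 window samples and 200
baseline samples as independent under-estimates the standard error
several-fold, and under joint FDR correction the step-up then cascades:
on a pure-noise recording most timepoints end up "significant". The
detector therefore keeps the same architecture (window mean vs per-trial
baseline mean, two tails, joint BY-FDR, 50-ms persistence) but
standardises honestly:

\[ T(t) = \frac{\bar{x}_{w(t)} - \bar{x}_b}
              {\sqrt{\hat\sigma^2(\kappa_w + \kappa_b)}} \]

- \(\hat\sigma^2\): the site's baseline variance pooled across trials
  (each trial's baseline centered first), corrected for the variance
  lost to per-segment centering (factor \(1/(1-\tau/n_b)\));
- \(\kappa_w, \kappa_b\): effective-sample-size factors
  \(\kappa = n^{-2}\sum_{i,j}\hat\rho(|i-j|)\) from the baseline
  autocorrelation function, averaged over trials and de-biased by the
  short-segment acf bias (+1/n per lag);
- degrees of freedom: the pooled baseline's effective sample count
  (pooled samples divided by the integrated autocorrelation time, minus
  one per centered trial).

On independent noise the correction factors reduce to 1/n and the test
is uniform-calibrated (verified in the suite, which allows a small band
around the nominal rate because \(\hat\kappa\) itself is estimated). On
smoothed traces the test stays calibrated where the naive statistic is
degenerate. In-burst variance exceeds baseline variance, so the test is
mildly anticonservative exactly where true effects live — acceptable for
a detector whose null behavior is what needs guarding.

**Correction and persistence.** P-values are pooled over all tested
timepoints × trials × sites of one participant (the correction family;
both tails pooled) and adjusted by Benjamini–Yekutieli, which is valid
under arbitrary dependence. The family is per participant because
participants are analysed on native anatomy with independent pipelines;
a global family is a one-line change. Significant timepoints must
persist 50 ms consecutively (a run of exactly 50 ms is kept; 49 ms is
cleared; invalid timepoints break runs).

**Metrics.** For activation-polarity (positive) significant runs: onset
= first significant ms, offset = last, duration = significant-timepoint
count × sample period (multiple runs accumulate), peak = argmax of the
smoothed trace over significant timepoints (ties to the earliest), peak
power = trace at the peak. Deactivation time is recorded per trial but
produces no latency metrics. Trials with no significant activation keep
`peak_power_z` = max of the valid trace over [0, RT] — required by the
peak-power comparisons, which include non-activated trials.

Detection timing behavior, measured by the suite on calibrated
amplitude-3 bursts: median absolute onset error ≈ 10 ms and median
duration error well under 15%. The smoothing kernel is symmetric, so
detected onsets can slightly *lead* the true envelope onset (by up to
roughly the kernel half-width) as well as lag it; the recovery tests
bound the absolute error rather than assuming a one-sided lag.

## 3. Trial-averaged analysis

The per-timepoint evoked effect is defined by a mixed model: baseline
samples as the intercept's null distribution, one dummy per peri-stimulus
timepoint, intercept nested within trial. Because every trial
contributes the same balanced design, the GLS estimate of each dummy
equals the mean over trials of (timepoint value − trial baseline mean) —
a paired comparison. The package computes that closed form directly
(the epochs are already baseline-corrected) with a paired t per
timepoint; the equivalence to the lme4 fit is asserted to 1e−6 in the
test suite. The full-scale alternative (one joint model with thousands
of dummies and an unconstrained covariance) estimates identical betas
under this structure but is computationally prohibitive and estimates a
joint covariance nothing downstream consumes; this is a deviation in
kind, documented here.

Estimates run on a 2-ms grid by default (configurable), BY-corrected per
condition across timepoints × sites, with the 50-ms persistence rule on
the estimation grid. Site labels: `active` if only positive significant
timepoints, `deactive` if only negative, mixed polarity decided by the
greatest |β|, otherwise `nonresponsive`. "Mentalizing" labels pool self
and other trials.

Time-window summaries use the same paired construction per half-open
window [a, b) (boundaries at 250/500/750/1000 ms assumed half-open), BY
across sites × windows per condition. Grand-average ROI timecourses pool
responsive sites with site- (and participant-) level random intercepts
via lme4 on a 20-ms grid, falling back to the paired estimate for a
single site.

## 4. Site classification

Peak-power comparisons (mentalizing vs cognitive; self vs other) use
bisquare robust regression of single-trial peak power on a ±½ condition
indicator, per site, including non-activated trials; p-values are
BY-corrected across sites separately per comparison family. The
decision rules are total functions and are enumerated exhaustively in
tests:

- **Specificity** (mentalizing-active sites, collapsed self+other):
  cognitive-active ⇒ `non_specific` regardless of power; otherwise
  `mentalizing_specific` iff the power excess is significant and
  positive; otherwise `non_specific`.
- **Selectivity**: both types active ⇒ `self_greater` / `other_greater`
  / `non_selective` by the sign of a significant self−other power
  difference; exactly one type active ⇒ `self_only` / `other_only` only
  with a significant power advantage, else `non_selective`; neither ⇒
  `not_applicable`.

Self-selective (self_only + self_greater) vs other-selective counts
enter McNemar's χ² with a *clamped* Yates correction,
χ² = max(|n01−n10|−1, 0)²/(n01+n10): the clamp prevents the continuity
correction from manufacturing a positive statistic when the discordant
counts are equal (equal splits must give χ² = 0).

## 5. ROI inference

The stage-1 outlier rule in the source procedure ("two-dimensional
distance between stimulus onset and RT") is not exactly recoverable from
its description; it is implemented as bisquare robust regression of each
metric on RT with residuals beyond 3 scaled MADs discarded — the reading
that makes the rule well-defined for every metric. Stage 2 repeats the
rule pooled over each ROI's mentalizing-active sites and removes sites
with > 50% flagged observations. Trials with RT > 5000 ms are removed
first (epochs end at 5000 ms).

Mixed models use lme4/lmerTest (REML, Satterthwaite df). The original nesting-style
nesting is approximated at fixture scale by a fixed fallback ladder —
per-site random slope (correlated, then uncorrelated, for the focal
covariate) + participant intercept → intercepts only → fixed-effects
only — taking the first structure that fits; the structure used is
recorded in each result. Codings make fixed effects read as printed
differences: Type(Other−Self) and Choice(True−False) as ±½ indicators.
Per-site "random effect sizes" for second-level models are BLUPs
(fixed + conditional random slope).

Pairwise ROI comparisons code ROI as a ±½ indicator (hence exact
antisymmetry under swapping), control for RT, nest intercepts within
participant and trial-within-participant, restrict to participants with
mentalizing-active sites in both ROIs, and BY-correct across the unique
pairs per metric (per-metric correction assumed). The onset →
specificity classification is a participant-nested logistic mixed
model; under complete separation (or glmer failure) it falls back to
Firth-penalized logistic regression and flags the result. The mPFC
offset-vs-RT contrast models RT − offset with a ±½ non-mPFC/mPFC
indicator so a positive slope means non-mPFC offsets precede the
response by more.

## 6. The synthetic-data generator

The generator's defaults are the study conditions the pipeline targets:
16 participants; 50 self, 50 other, 80 arithmetic and 72 cued-rest
trials per session; 1000 Hz sampling; 1/f background (exponent 1,
20 µV SD) with 60 Hz line noise (5 µV) and harmonics; burst onset means
per ROI at 101 (Visual), 303 (TPJ), 316 (ATL), 322 (PMC), 465 (amPFC),
466 (dmPFC) and 537 ms (vmPFC); other-mentalizing bursts ~100 ms longer
than self bursts in DMN ROIs; cognitive activation probability falling
from visual cortex (0.95) to mPFC (≤ 0.1), which produces the
specificity gradient; trial-level onset SDs of 15–70 ms (tighter in
visual cortex), chosen as realistic single-trial jitter consistent with
the reported standard errors of the ROI means. RT = 1270 ms + 1.0 ×
(latest active burst offset) + 150 ms noise + a VD1 term, floored at
400 ms so simulated trials are not self-excluded by the RT rule; choices
follow logistic(0.931·valence + 0.326·valence·type) with ±½ codings
(valence is a property of the trait word). VD1 differs by condition
(longer prompts for other-mentalizing), VD2 is standard normal.

**Burst injection and calibration.** Bursts are band-limited (70–180 Hz)
noise with the background's spectral shape under a trapezoidal envelope
with 20-ms linear power ramps (an unambiguous ground-truth onset/offset
for recovery scoring; a sinusoidal carrier would produce single-band
wavelet artifacts). Because per-band Morlet power of gaussian noise is
exponentially distributed (SD = mean) and the z-transform normalises by
the *whole-recording* SD, injecting bursts inflates the normaliser. The
carrier-to-background power ratio r therefore solves a fixed point: with
per-burst duty ρⱼ and target amplitudes aⱼ, the pooled SD σ (in units of
the background mean) satisfies

\[ \sigma^2 = 2(1-P) + 2\sum_j \rho_j (1 + a_j\sigma)^2 -
   \big(1 + \sum_j \rho_j a_j \sigma\big)^2, \qquad r_j = a_j\sigma , \]

solved by `uniroot`. This implies a hard ceiling
\(z_{max} = 1/\sqrt{\rho(2-\rho)}\) at total duty ρ: amplitude-3 bursts
need duty ≲ 5%, which the default design provides via rest trials and
inter-trial intervals (fixtures use explicit gaps). Infeasible
combinations error with that diagnosis rather than silently
under-injecting. Common-average referencing attenuates each channel's
burst-to-background ratio by (n−1)/n, which the synthesis
pre-compensates. The suite verifies the calibration: measured in-burst
HFB z within 25% of the target for amplitudes 1–3.

**Determinism.** Every draw comes from a sub-stream seeded by hashing
(seed, participant, site, stage), so identical (config, seed) reproduce
bit-identical sessions and adding sites does not perturb existing draws.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: non-stationary background power (drowsy /
alert state changes), epileptiform transients, electrode artifacts,
heavy-tailed HFB distributions beyond the exponential wavelet-power
model, genuinely oscillatory (narrow-band) evoked responses, and
spatial correlation between neighbouring electrodes. In particular the
z-ceiling above is a property of the exponential-power model; real
recordings reach higher in-burst z because their baselines are not
ideal stationary pink noise.

## 7. Problem sizes used by the suite

Tests and the acceptance script run at deliberately small,
fully-simulated scales chosen to make every stochastic check
well-powered: detector recovery at 10 sites × 50 trials (amplitude 3 z)
plus an equal-sized null; latency-ordering recovery with one site per
ROI and 12 trials per mentalizing type across 20 seeds; behavioral and
metric-model recovery over 50 replicates at 8 simulated participants
(half the default cohort) × 25 trials per type, scored as 2-SE coverage
pooled over each model's generator slopes; grid fixtures of 8–12 sites
for the classification rules. Diagnostic replications behind these
choices showed the estimators unbiased with calibrated standard errors,
so the coverage criterion holds in expectation rather than by
construction.

## 8. Known limitations

- The detector's serial-correlation correction assumes the baseline is
  (locally) stationary; strong baseline drifts would need a longer
  baseline or a per-trial variance model.
- Wald standard errors from logistic mixed models are slightly narrow at
  very small cluster counts; the Firth fallback guards separation, not
  small-sample coverage.
- The per-timepoint trial-averaged model reproduces the joint model's
  point estimates but not its joint covariance (nothing downstream uses
  it).
- EDF import is not implemented; sessions use the package's native
  directory container (TSV + float32 binary + JSON sidecar).
- Arithmetic accuracy is not modelled: the event schema carries no
  ground-truth correctness field.
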