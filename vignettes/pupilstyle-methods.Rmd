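---
title: "Methods: switch-locked pupillometry of bistable perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: switch-locked pupillometry of bistable perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilstyle)
```

## The measurement problem

A structure-from-motion cylinder — two interleaved dot fields moving in
opposite horizontal directions, one black and one white — is perceived as a
3-D cylinder whose rotation direction is bistable: either the black or the
white dots are seen as the front surface, and the interpretation alternates
spontaneously every few seconds. Because the two surfaces differ in
luminance, where an observer deploys attention (only the front surface, or
both surfaces globally) should leave a signature in pupil diameter: pupils
dilate when a dark surface is attended and constrict for a bright one, even
at constant physical luminance.

`pupilstyle` implements the full analysis from raw pupil/percept streams to
two per-subject summary indices:

* **luminance-dependent pupil modulation** — the difference between
  baseline-corrected switch-locked pupil traces for black-front versus
  white-front perceptual phases, averaged over the index windows
  ($[-1,0)$ and $[0,1]$ s around the switch). Positive values mean the
  pupil is more dilated when the black surface is perceived in front.
* **general pupil dilation** — the post-switch dilation pooled over both
  percepts, averaged over $[0,1]$ s.

The first index is the quantity of interest: across subjects it correlates
with Autism-Spectrum Quotient (AQ) scores, consistent with a more local
(front-surface-focused) perceptual style in people with more autistic
traits. The second is a control: switch-locked arousal dilation that should
not (and does not) track AQ.

## Preprocessing rules

* **Sample exclusion.** Pupil samples below 1 mm (blinks) or above 7 mm
  (eyelash interference) are invalid; the bounds are strict inequalities,
  so samples at exactly 1 or 7 mm are kept. Invalid samples become `NA` and
  propagate through interpolation rather than being bridged.
* **Phase segmentation.** The continuous report stream (two keys or
  joystick) is segmented into maximal constant-percept runs. Report gaps
  ("no key") shorter than 0.2 s (configurable) are absorbed into the
  preceding phase — they are almost always key-transition artifacts — and
  longer gaps split phases. The switch time is the report-device change
  time, with no reaction-time correction.
* **Phase exclusion.** Phases shorter than 1 s (finger errors) or longer
  than 15 s (too few oscillations) are unusable; again the bounds are
  inclusive. A phase whose end is cut by the 59-s trial end is flagged
  `trial_boundary` and unusable because its duration is censored; the first
  phase of a trial starts with the stimulus and is treated as observed.
  Subjects with fewer than 10 usable phases are excluded (reported, never
  silently dropped).

## Epoching and baselines

Traces are linearly interpolated onto a 60-Hz analysis grid (the coarser of
the two supported tracker rates; 1000-Hz input is handled identically, and
the two rates agree on the indices to well under the tolerance of any test
here). Each switch yields an epoch over $[-1, +1]$ s. The two sides are
corrected independently: the pre-switch side by the mean over the 150 ms
immediately preceding the switch, the post-switch side by the 150 ms
immediately following it. A side is kept only when its flanking phase is
usable (so 1-s index windows never span excluded phases; the 1-s minimum
phase duration guarantees window support) and its baseline window has at
least 50% valid samples. The post side carries the destination percept's
label; the pre side belongs to the percept that is ending.

Two index modes are provided: `pre_post` (default; the pre and post window
means averaged) and `post_only`. On antisymmetric traces the two agree; on
real or simulated traces the pre side of a settled phase is absorbed by its
own baseline, so `post_only` values run about twice `pre_post` ones. The
default follows the two-window description of the index; both are exposed
because the narrower "first 1 s of each epoch" reading is equally
defensible.

Per-subject significance of the modulation (is this subject's index
positive beyond noise?) is assessed by a one-sided Welch t-test on
per-epoch post-window means, black versus white destinations, at
$\alpha = 0.05$. The source study does not state its per-subject test; the
Welch choice is this package's documented convention, and its type-I rate
is verified by simulation.

## The synthetic-data generator

Every pipeline stage is testable against ground truth via a generator whose
defaults are the study conditions:

* **AQ scores**: integers drawn from Normal(14.85, 6.73), redrawn (not
  clipped) outside $[0, 31]$ — the studied cohort all scored below the
  clinical-referral threshold of 32, and redrawing avoids a point mass at
  the bound. Item-level responses are generated to score back to the target
  totals under the standard 50-item key (five 10-item subscales), which
  ships as a versioned data file.
* **Percept dynamics**: a gamma renewal process with mean phase duration
  5.5 s and shape 2 — a common description of bistable alternation-duration
  distributions; the study reports only the mean, so the shape is a
  parameter (`Inf` gives deterministic durations). Labels alternate
  strictly; phases tile each 59-s trial (10 trials per session); the first
  label is black-front with probability 0.5. The study's companion number
  of 0.21 switches/s is a per-subject average dominated by faster
  switchers; the generator exposes the mean-duration parameterization and
  makes no attempt to force both numbers at once.
* **Pupil traces**: baseline 4 mm, plus a gamma-shaped impulse response
  (mode 0.4 s, SD 0.4 s, peak 0.03 mm) at every switch — the
  percept-independent arousal transient — plus a percept-dependent offset
  (positive in black-front phases) whose transitions are the same kernel
  applied to a step, so the pre-switch trace still reflects the outgoing
  percept; plus Ornstein–Uhlenbeck noise (SD 0.1 mm, the scale of
  spontaneous pupil fluctuation, autocorrelation time 0.5 s) so epoch
  averages behave like real pupillometry rather than white noise. Blinks
  arrive as a Poisson process (6/min, 0.25 s) and are written as sub-1-mm
  dropouts — what a video tracker records — so the 1-mm exclusion rule is
  genuinely exercised.
* **Detection data**: speed-increment events with exponential-plus-floor
  gaps (mean 3 s, minimum separation 2 s), answered with surface-dependent
  hit probabilities at gamma-distributed latencies, plus Poisson spurious
  presses.

**Amplitude semantics.** The generator's `modulation_amp` (and the
per-subject amplitudes produced by the AQ link) are expressed on the scale
of the *index itself*, in mm. This needs care: because each epoch side is
baseline-corrected by its own adjacent 150-ms window, a settled per-phase
offset is invisible — only the post-switch rise relative to its first
150 ms is measurable, and a switch arriving soon after the previous one
starts from an unsettled level and rises less. `realized_index_gain()`
therefore computes, in closed form from the kernel's cumulative
distribution and the actual phase sequence, the expected index per unit
offset swing under exactly the analysis rules, and the generator divides
the requested amplitude by this gain. The result is that a noise-free
subject's measured index equals the requested amplitude to within grid and
interpolation effects (well under 5%), and the cross-subject regression of
measured index on true amplitude has slope 1. The gain routine shares only
the kernel mathematics with the generator — not the epoching code — so the
recovery test still exercises masking, interpolation, labeling and baseline
arithmetic end to end.

**Cross-subject calibration.** True amplitudes follow
$\beta \cdot AQ + \varepsilon$ with $\beta = 0.002$ mm per AQ point and
$\sigma_\varepsilon = 0.01373$ mm, chosen so that
$\beta\sigma_{AQ}/\sqrt{\beta^2\sigma_{AQ}^2 + \sigma_\varepsilon^2}
\approx 0.70$ at $\sigma_{AQ} = 6.73$ — the benchmark cross-subject
correlation. Two caveats are worth recording. First, integer scores cannot
go below 0, so even without the clinical truncation the realized AQ SD is
about 6.50 and the expected mean sample correlation over many cohorts is
about 0.69, not 0.700; the calibration check in the test suite runs the
generator over the full 0–50 score range, matching the closed form above as
nearly as a bounded score permits. With the cohort default truncation at 31
the SD shrinks further (about 6.34) and the expectation drops to about
0.68. Second, trace-level noise attenuates the *measured* index's
correlation with AQ below the true-amplitude correlation (to roughly 0.6 at
the default noise level); the regression slope of index on AQ remains
unbiased because the noise lives in the dependent variable.

**What the generator does not emulate.** Gaze dynamics (fixation is
constant), the pupillary light reflex, smooth-pursuit or microsaccadic
artifacts, reaction-time lag and errors in the percept reports, drift in
baseline pupil diameter across a session, and any dependence of switch
dynamics on AQ (the study found none). Passing the recovery tests therefore
certifies the analysis arithmetic on data with realistic noise correlation
and artifact structure; it does not certify robustness to systematic
recording pathologies outside the model.

## Detection scoring conventions

A press is a hit for the most recent event no more than 2 s before it; each
event is credited at most one hit, and a press inside two event windows
(possible, since events can be 2–4 s apart) goes to the later, closer
event. Presses more than 2 s from every event are false alarms. The study
never defines the false-alarm denominator; this package counts
non-overlapping 2-s bins of reporting time containing no event, making hit
and false-alarm rates commensurate proportions. Sensitivity is
$d' = z(H) - z(F)$ with 0/1 rates corrected to $1/(2N)$. Events are split
into front/rear by comparing the event's dot colour with the perceived
foreground at event time; events inside unusable phases are dropped with a
count. For the cued counting task (0–3 increments per 6-s burst), percent
correct is the exact-match fraction and a d' is formed by collapsing counts
to per-opportunity detections (hits $=\sum\min(\text{reported},
\text{true})$ of $\sum\text{true}$; false alarms
$= \sum\max(\text{reported}-\text{true},0)$ of the unfilled slots) — a
documented stand-in, since the original computation is unspecified.

## Inferential layer

Correlations are Pearson's r with Fisher-z 95% confidence intervals,
$\tanh(\operatorname{atanh} r \pm z_{.975}/\sqrt{n-3})$, and two-tailed
p-values from $t = r\sqrt{(n-2)/(1-r^2)}$. Independent correlations are
compared with Fisher's Z. Paired comparisons use the standard paired t.

The Bayes factor for a correlation is the Jeffreys–Zellner–Siow (JZS)
default test computed by numerical integration of the regression-form
marginal-likelihood ratio over the g-prior mixing variable (integrated in
log-g space with a stabilizing offset; an independent fixed-grid quadrature
in a transformed variable serves as the test oracle, with agreement
required to three significant figures). The JZS prior has a free scale. The
package's default, `jzs_default_scale = 1.17`, is anchored so that the one
correlation for which the benchmark study prints r, n and BF together
(r = 0.68, n = 22, BF = 62.7) is reproduced exactly; the same scale
reproduces the study's null-side Bayes factors (printed 0.1) to the printed
precision, while the textbook unit scale gives 65.4 at the anchor. The
scale is an explicit argument everywhere, so the unit-scale convention is
one keyword away.

The Jarque–Bera normality check is $JB = \tfrac{n}{6}(S^2 + K^2/4)$ from
sample skewness and excess kurtosis. The $\chi^2_2$ asymptotic p-value is
anticonservative at cohort-sized samples (at $JB = 1.42$ it gives
$p \approx 0.49$ where small-sample tables give $\approx 0.37$), so a
Monte-Carlo mode simulating the null at the observed n is provided and used
by the analysis scripts.

Quartile summaries (index binned by AQ quartiles) use inverse-ECDF (type 1)
quantile edges with ties to the lower bin; 50 subjects split 13/12/13/12.

## Numerical choices and degenerate inputs

* Analysis grid 60 Hz; grid points are valid only when both bracketing raw
  samples are valid (interpolation never bridges artifacts).
* Baseline windows are closed on the switch side and require ≥ 50% valid
  samples, else the side is dropped with a reason.
* Identical pairs in the paired t (zero-variance differences) return
  t = 0, p = 1 rather than an error.
* `|r| = 1` is rejected by the Bayes factor (degenerate likelihood).
* Zero usable reporting time, missing labels, and zero false-alarm
  opportunities raise informative errors rather than NaNs.
* All generators are deterministic under a seed, with one RNG stream per
  cohort so a manifest (parameters + seed) reconstructs a dataset exactly.

## Problem sizes in the test suite

The tests run cohorts at the study's own scale where the property demands
it (one 50-subject, 10-trial, 60-Hz cohort for full-chain recovery; 200
cohorts of 50 for the link calibration, amplitudes only) and scaled-down
cohorts (3–6 subjects, 2–4 trials) where the property is structural —
schema validation, determinism, exclusion bookkeeping. Distributional
checks use 10⁴–2×10⁴ draws. These sizes are the package's choices for
precise yet quick verification.

## Known limitations

* The generator's percept dynamics are AQ-independent by design; tests of
  the switch-rate/AQ null are calibration checks, not power analyses.
* The pre-switch ("negative") side of real pupil traces shows anticipatory
  constriction that the causal kernel model cannot produce; the pre window
  contributes essentially zero index in simulation, so simulated `pre_post`
  indices estimate half the post-side swing. Real-data indices do not share
  this property.
* The counting-task d' convention is package-defined (see above) and not
  comparable in absolute terms to the original report.
* The JZS prior-scale anchor is an inference from a single printed value;
  analyses that must match the broader Bayes-factor literature should pass
  `prior_scale = 1`.
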