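# pupilstyle

Switch-locked pupillometry of bistable structure-from-motion perception.

When observers view an ambiguous rotating cylinder made of black dots
moving one way and white dots moving the other, perception alternates every
few seconds between "black surface in front" and "white surface in front".
Because the surfaces differ in luminance, pupil diameter tracks which
surface is attended: observers who focus locally on the front surface show
a pupil that oscillates in phase with their perception (more dilated during
black-front phases), while observers who attend globally to both surfaces
show little modulation. The magnitude of this **luminance-dependent pupil
modulation** is an objective index of local-versus-global perceptual style
and correlates strongly with autistic traits measured by the
Autism-Spectrum Quotient (AQ) in the general population.

`pupilstyle` is an R package plus analysis workflow for this paradigm. It
provides:

* **Preprocessing** — pupil-sample exclusion (valid range [1, 7] mm,
  strict bounds), percept-report segmentation into phases, phase exclusion
  (durations outside [1, 15] s, trial-boundary censoring), and subject
  exclusion (< 10 usable phases), with full QC reporting.
* **Epoching and indices** — switch-locked epochs over [-1, +1] s with
  independent 150-ms baselines per side, onset-locked epochs for cued
  attention runs, and the summary indices: luminance-dependent modulation
  (mean over the [-1, 0) and [0, 1] s windows of the black-front minus
  white-front trace), general post-switch dilation ([0, 1] s, pooled),
  feature-based attention modulation ([1, 3] s from onset), switch rates,
  and per-subject significance flags.
* **Detection scoring** — hit/false-alarm classification with the 2-s
  window, d' = z(H) − z(F) split by perceived surface (front/rear), and
  the cued counting task.
* **AQ scoring** — the standard 50-item key with five 10-item subscales,
  corrected totals, and Jarque–Bera normality checks (asymptotic and
  Monte-Carlo p-values).
* **Inference** — Pearson correlations with Fisher-z 95% CIs and t-based
  p-values; JZS default Bayes factors for correlations by numerical
  integration; Fisher-Z comparison of independent correlations; paired
  t-tests; subscale correlation matrices; quartile summaries.
* **A calibrated synthetic-data generator** — AQ cohorts (truncated
  normal, integer scores), gamma-renewal percept dynamics (mean 5.5 s),
  pupil traces with switch transients, percept-linked offsets,
  Ornstein–Uhlenbeck noise and blink artifacts, and detection
  events/responses — so the entire pipeline is tested against ground truth
  with no recorded data required.

The per-subject index in symbols: for switch-locked, baseline-corrected
label means `P_black(t)` and `P_white(t)`,

    modulation = mean_{t in [-1,0) ∪ [0,1]} [ P_black(t) − P_white(t) ]   (mm)

and the headline cross-subject result is Pearson's r between this index and
the AQ total, reported as `r [CI_low, CI_high], p, BF10`.

## Worked example

Simulate a 50-subject cohort under the study conditions, write it in the
pipeline's plain-text formats, and run the full analysis:

```r
library(pupilstyle)

cohort <- gen_cohort(cohort_params(n_subjects = 50, seed = 2026),
                     percept_dynamics_params(seed = 2026),
                     pupil_model_params())
write_cohort(cohort, "scratch/data/main")

cfg <- load_config(system.file("extdata", "paper_defaults.yaml",
                               package = "pupilstyle"))
res <- run_experiment("scratch/data/main", cfg)
res$stats$modulation_vs_aq
```

Running `analysis/01_simulate.R` followed by
`analysis/02_main_experiment.R` (which do exactly the above and write
`results/main_subjects.csv`, `results/main_stats.json` and the mean-trace
TSV) prints:

```
Main experiment (n = 50 analysed, 0 excluded):
  modulation vs AQ:      r = 0.61 [0.39, 0.76], p = 3.1e-06, BF10 = 5.04e+03
  dilation vs AQ:        r = 0.10, p = 0.50, BF10 = 0.12
  switch rate vs AQ:     r = -0.11, p = 0.45
  significantly positive modulation: 40 of 50 subjects
  mean switch rate 0.18 /s; dark-foreground time 49.2%
  excluded phases 16.1%; amplitude-recovery slope 1.03 [0.90, 1.16]
```

Reading the output: the luminance-dependent modulation tracks AQ strongly
(the true-amplitude/AQ correlation is calibrated to ≈ 0.69; measurement
noise attenuates the observed r to ≈ 0.6), while the general dilation — the
arousal response common to all switches — does not, and neither does the
switching rate. The amplitude-recovery slope near 1 shows the pipeline
returns each subject's generative modulation amplitude on the correct
scale. The remaining scripts reproduce the split-half and
swapped-direction replications with Fisher-Z comparisons and the subscale
correlation matrix (`03`), the feature-based attention experiment (`04`),
and the double-task detection experiment with front/rear d' (`05`).

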