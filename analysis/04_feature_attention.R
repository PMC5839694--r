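#!/usr/bin/env Rscript
# Feature-based attention experiment: brief (6 s) stimulus bursts preceded
# by a letter cue indicating which surface to attend. Onset-locked epochs
# are baselined on the 150 ms before stimulus onset; the attention index is
# the black-cued minus white-cued trace averaged over 1-3 s. In this
# simulation the attention effect is present in every subject but unrelated
# to AQ, mirroring the constrained-viewing logic of the task.
suppressPackageStartupMessages({library(pupilstyle); library(readr)})

dir.create("results", showWarnings = FALSE)
n_subjects <- 50
n_trials <- 40          # 2 runs x 20 scored trials per cue mix
trial_len <- 10         # 2 s cue + 6 s dots + 2 s response
onset <- 2
rate <- 60
attention_amp <- 0.04   # mm, cue-dependent separation, AQ-independent
dilation_amp <- 0.15    # mm, stimulus-onset dilation common to both cues

dir_out <- "scratch/data/feature_attention"
dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)

set.seed(2029)
aq_scores <- gen_aq_scores(cohort_params(n_subjects = n_subjects,
                                         seed = 2029))
write_csv(gen_aq_responses(aq_scores, seed = 2029),
          file.path(dir_out, "aq_responses.csv"))

samples <- list(); onsets <- list()
for (s in seq_len(n_subjects)) {
  amp_s <- attention_amp + rnorm(1, 0, 0.01)
  cues <- sample(rep(c("black_cued", "white_cued"), n_trials / 2))
  for (tr in seq_len(n_trials)) {
    t <- seq(0, trial_len - 1 / rate, by = 1 / rate)
    rise <- pupil_kernel_cdf(t - onset, latency = 0.8, width = 2)
    sgn <- if (cues[tr] == "black_cued") 1 else -1
    ar <- exp(-1 / (rate * 0.5))
    noise <- as.numeric(stats::filter(
      rnorm(length(t), 0, 0.08 * sqrt(1 - ar^2)), ar, method = "recursive"))
    pupil <- 4 + dilation_amp * rise + sgn * amp_s / 2 * rise + noise
    samples[[length(samples) + 1]] <- tibble::tibble(
      subject = s, trial = tr, t_s = t, pupil_mm = pupil,
      gaze_x_deg = 0, gaze_y_deg = 0)
    onsets[[length(onsets) + 1]] <- tibble::tibble(
      subject = s, trial = tr, t_s = onset, cue = cues[tr])
  }
}
write_tsv(dplyr::bind_rows(samples), file.path(dir_out, "samples.tsv"))
write_tsv(dplyr::bind_rows(onsets), file.path(dir_out, "onsets.tsv"))

res <- run_experiment(dir_out, analysis_config(experiment =
                                                 "feature_attention"))
write_csv(res$subjects, "results/attention_subjects.csv")
write_tsv(res$traces, "results/attention_mean_traces.tsv")
jsonlite::write_json(res$stats, "results/attention_stats.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

st <- res$stats$attention_vs_aq
cat(sprintf(paste0(
  "Feature-based attention (n = %d):\n",
  "  mean attention modulation: %.3f mm (cue-dependent dilation)\n",
  "  attention modulation vs AQ: r = %.2f [%.2f, %.2f], p = %.2f,",
  " BF10 = %.2g\n"),
  nrow(res$subjects), mean(res$subjects$attention_modulation),
  st$r, st$ci_low, st$ci_high, st$p, st$bf10))
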