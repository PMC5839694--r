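#!/usr/bin/env Rscript
# Simulate the synthetic study cohorts: a 50-subject main cohort, a
# 26-subject swapped-direction cohort, and a 25-subject double-task cohort
# (with speed-increment events and key presses). Datasets are written in
# the pipeline's plain-text input formats under scratch/data/ (large) and
# each one's manifest records every generator parameter.
suppressPackageStartupMessages(library(pupilstyle))

out_root <- "scratch/data"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

message("main cohort: 50 subjects, 10 x 59 s trials, 60 Hz")
main <- gen_cohort(cohort_params(n_subjects = 50, seed = 2026),
                   percept_dynamics_params(seed = 2026),
                   pupil_model_params())
write_cohort(main, file.path(out_root, "main"))

message("swapped-direction cohort: 26 subjects")
swapped <- gen_cohort(cohort_params(n_subjects = 26, seed = 2027),
                      percept_dynamics_params(seed = 2027),
                      pupil_model_params())
write_cohort(swapped, file.path(out_root, "swapped"))

message("double-task cohort: 25 subjects with detection events")
det <- list(mean_interval = 3, min_separation = 2,
            hit_rate_front = 0.85, hit_rate_rear = 0.55,
            fa_rate = 1, latency_mean = 0.6)
double <- gen_cohort(cohort_params(n_subjects = 25, seed = 2028),
                     percept_dynamics_params(seed = 2028),
                     pupil_model_params(), detection = det)
write_cohort(double, file.path(out_root, "double_task"))

message("done; datasets under ", out_root)
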