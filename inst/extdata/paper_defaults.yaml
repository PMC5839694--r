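# Default analysis configuration: the study's thresholds and windows.
experiment: main
min_pupil_mm: 1        # samples below are blink artifacts
max_pupil_mm: 7        # samples above are eyelash interference
min_phase_s: 1         # phases shorter are finger errors
max_phase_s: 15        # phases longer mark trials with too few oscillations
min_usable_phases: 10  # subjects under this are excluded
trial_duration_s: 59
gap_tolerance_s: 0.2
analysis_rate_hz: 60
baseline_s: 0.15
epoch_window_s: [-1, 1]
pre_window_s: [-1, 0]
post_window_s: [0, 1]
index_mode: pre_post
onset_window_s: [0, 6]
attention_window_s: [1, 3]
detection_window_s: 2
ci_level: 0.95
bf_prior_scale: 1.17
alpha: 0.05
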