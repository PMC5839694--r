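# Shared fixture builders. Everything is generated in code at test time.

# A constant-rate pupil recording for one trial.
flat_samples <- function(value = 3.2, duration = 20, rate = 60, trial = 1L) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  tibble::tibble(trial = trial, t_s = t, pupil_mm = value,
                 gaze_x_deg = 0, gaze_y_deg = 0)
}

# Deterministic alternating phases tiling one trial.
alternating_phases <- function(phase_s = 5, duration = 20, trial = 1L,
                               first = "black_front") {
  starts <- seq(0, duration - phase_s, by = phase_s)
  labs <- rep_len(c(first, setdiff(c("black_front", "white_front"), first)),
                  length(starts))
  tibble::tibble(trial = trial, start_s = starts,
                 end_s = starts + phase_s, label = labs)
}

with_usable <- function(phases, trial_duration = max(phases$end_s)) {
  filter_phases(phases, trial_duration = trial_duration)$phases
}

# Noise-free pupil model (no blinks) for deterministic epoch checks.
clean_pupil_params <- function(...) {
  pupil_model_params(noise_sd = 0, blink_rate = 0, ...)
}

# Small synthetic subject: phases + trace, defaults scaled down for speed.
small_subject <- function(seed = 1, amp = 0.05, n_trials = 4,
                          params = clean_pupil_params()) {
  dyn <- percept_dynamics_params(n_trials = n_trials, seed = seed)
  phases <- gen_percept_sequence(dyn)
  trace <- gen_pupil_trace(phases, params, modulation_amp = amp, seed = seed)
  list(phases = phases, samples = trace$samples, trace = trace,
       usable = filter_phases(phases)$phases)
}
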