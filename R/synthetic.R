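#' Cohort-level generator parameters
#'
#' Defaults reproduce the study conditions: AQ scores drawn from
#' Normal(14.85, 6.73), rounded to integers and redrawn when outside
#' \[0, 31\] (every tested subject scored below the clinical threshold of
#' 32), and a linear link from AQ to each subject's true luminance-dependent
#' pupil-modulation amplitude with slope 0.002 mm per AQ point and residual
#' SD 0.01373 mm. With the AQ SD of 6.73 this puts the population
#' correlation between AQ and true amplitude at
#' beta*sigma_AQ / sqrt(beta^2 sigma_AQ^2 + sigma_eps^2) ~ 0.70, the
#' cross-subject correlation the pipeline is calibrated against.
#'
#' @param n_subjects Number of subjects.
#' @param aq_mean,aq_sd Mean and SD of the AQ-generating normal (AQ points).
#' @param aq_max Upper truncation bound (redraw above it).
#' @param slope_beta Modulation amplitude per AQ point (mm).
#' @param residual_sd Residual SD of the amplitude around the linear link (mm).
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 50, aq_mean = 14.85, aq_sd = 6.73,
                          aq_max = 31, slope_beta = 0.002,
                          residual_sd = 0.01373, seed = 1L) {
  stopifnot(n_subjects >= 1, aq_sd > 0, aq_max > 0, aq_max <= 50,
            residual_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects), aq_mean = aq_mean,
                 aq_sd = aq_sd, aq_max = aq_max, slope_beta = slope_beta,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Percept-dynamics generator parameters
#'
#' Phase durations follow a gamma renewal process (shape 2 by default, a
#' common description of bistable alternation) with mean 5.5 s, matching the
#' observed average alternation. Trials last 59 s and there are 10 per
#' session. `phase_shape = Inf` gives deterministic durations.
#'
#' @param mean_phase_duration Mean phase duration, s.
#' @param phase_shape Gamma shape of the duration distribution
#'   (dimensionless); `Inf` for deterministic durations.
#' @param p_black_front Probability that the first phase of a trial is
#'   black-front.
#' @param trial_duration Trial duration, s.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @return A list of class `percept_dynamics_params`.
#' @export
percept_dynamics_params <- function(mean_phase_duration = 5.5,
                                    phase_shape = 2, p_black_front = 0.5,
                                    trial_duration = 59, n_trials = 10,
                                    seed = 1L) {
  stopifnot(mean_phase_duration > 0, p_black_front >= 0, p_black_front <= 1,
            trial_duration > 0, n_trials >= 1, phase_shape > 0)
  structure(list(mean_phase_duration = mean_phase_duration,
                 phase_shape = phase_shape, p_black_front = p_black_front,
                 trial_duration = trial_duration,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "percept_dynamics_params")
}

#' Pupil-trace generator parameters
#'
#' The generated trace is baseline + a transient dilation (gamma-shaped
#' impulse response, peak `transient_amp`) at every perceptual switch + a
#' percept-dependent offset (positive in black-front phases, negative in
#' white-front) whose transitions are the same kernel applied to a step, so
#' the pre-switch trace still reflects the previous percept +
#' Ornstein-Uhlenbeck noise. Blinks are simulated as sub-1-mm dropouts (what
#' the tracker records), exercising the 1-mm exclusion rule.
#'
#' `modulation_amp` is expressed on the scale of the luminance-dependent
#' modulation index itself (the quantity the analysis reports): the physical
#' offset swing is `modulation_amp / index_window_gain()`, so a noise-free
#' subject's index recovers `modulation_amp` up to grid/edge effects.
#'
#' @param baseline_mm Baseline pupil diameter, mm (must lie in (1, 7)).
#' @param transient_amp Peak of the switch-locked transient, mm.
#' @param transient_latency Kernel mode (time to peak), s.
#' @param transient_width Kernel width (2 SD of the gamma kernel), s.
#' @param modulation_amp Default luminance-dependent modulation amplitude on
#'   the index scale, mm (per-subject values usually come from the AQ link).
#' @param noise_sd Stationary SD of the OU noise, mm.
#' @param noise_ac_tau OU autocorrelation time, s.
#' @param sample_rate Sampling rate, Hz (60 or 1000).
#' @param blink_rate Blink events per minute.
#' @param blink_duration Blink duration, s.
#' @return A list of class `pupil_model_params`.
#' @export
pupil_model_params <- function(baseline_mm = 4, transient_amp = 0.03,
                               transient_latency = 0.4, transient_width = 0.8,
                               modulation_amp = 0.03, noise_sd = 0.1,
                               noise_ac_tau = 0.5, sample_rate = 60,
                               blink_rate = 6, blink_duration = 0.25) {
  stopifnot(baseline_mm > 1, baseline_mm < 7, sample_rate %in% c(60, 1000),
            transient_latency >= 0, transient_width > 0, blink_duration > 0,
            noise_sd >= 0, noise_ac_tau > 0, blink_rate >= 0)
  structure(list(baseline_mm = baseline_mm, transient_amp = transient_amp,
                 transient_latency = transient_latency,
                 transient_width = transient_width,
                 modulation_amp = modulation_amp, noise_sd = noise_sd,
                 noise_ac_tau = noise_ac_tau, sample_rate = sample_rate,
                 blink_rate = blink_rate, blink_duration = blink_duration),
            class = "pupil_model_params")
}

# gamma kernel shape/scale from mode (latency) and SD (width/2);
# latency 0 degenerates to shape 1 (exponential)
kernel_shape_scale <- function(latency, width) {
  sd <- width / 2
  rho <- latency / sd
  sqrt_s <- (rho + sqrt(rho^2 + 4)) / 2
  shape <- sqrt_s^2
  scale <- sd / sqrt_s
  list(shape = shape, scale = scale)
}

#' Pupil impulse-response kernel and its cumulative form
#'
#' Gamma-shaped kernel with mode `latency` and SD `width/2`. `pupil_kernel`
#' is peak-normalised (used for the switch transient, so `transient_amp` is
#' the peak in mm); `pupil_kernel_cdf` is the cumulative (area-normalised)
#' form used to smooth the percept-dependent offset step.
#'
#' @param t Times, s (values < 0 give 0: the kernel is causal).
#' @param latency Kernel mode, s.
#' @param width Kernel width (2 SD), s.
#' @return Numeric vector.
#' @export
pupil_kernel <- function(t, latency = 0.4, width = 0.8) {
  ks <- kernel_shape_scale(latency, width)
  peak_t <- if (latency > 0) latency else ks$scale * 1e-3
  peak <- stats::dgamma(max(peak_t, 1e-9), ks$shape, scale = ks$scale)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- stats::dgamma(t[pos], ks$shape, scale = ks$scale) / peak
  out
}

#' @rdname pupil_kernel
#' @export
pupil_kernel_cdf <- function(t, latency = 0.4, width = 0.8) {
  ks <- kernel_shape_scale(latency, width)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- stats::pgamma(t[pos], ks$shape, scale = ks$scale)
  out
}

#' Expected index per unit offset swing (window gain)
#'
#' Closed-form expectation of the luminance-dependent modulation index for a
#' unit percept-dependent offset swing, under the paper-style epoching rules
#' (own-side 150-ms baselines, analysis grid, index windows). Because each
#' side of an epoch is baseline-corrected by its own adjacent window, a
#' settled offset is absorbed on the pre side; the measurable part of the
#' swing is the post-side rise relative to its first 150 ms. The generator
#' divides the requested index-scale amplitude by this gain so that the
#' full pipeline recovers the requested amplitude.
#'
#' @param params A [pupil_model_params()].
#' @param post_window Post-switch index window, s.
#' @param baseline_s Baseline window length, s.
#' @param analysis_rate Analysis grid rate, Hz.
#' @param mode `"pre_post"` (default, both windows averaged) or
#'   `"post_only"`.
#' @return Scalar gain (dimensionless, in (0, 1\]).
#' @export
index_window_gain <- function(params, post_window = c(0, 1),
                              baseline_s = 0.15, analysis_rate = 60,
                              mode = c("pre_post", "post_only")) {
  mode <- match.arg(mode)
  dt <- 1 / analysis_rate
  tg <- seq(post_window[1], post_window[2], by = dt)
  tb <- tg[tg <= post_window[1] + baseline_s + 1e-9]
  C <- function(t) pupil_kernel_cdf(t, params$transient_latency,
                                    params$transient_width)
  post <- mean(C(tg)) - mean(C(tb))
  # pre side of a settled phase is absorbed by its own baseline: gain 0
  if (mode == "pre_post") (post * 2 + 0) / 2 else post * 2
}

#' Realized index gain for a phase sequence
#'
#' Exact expectation of the luminance-dependent modulation index per unit
#' offset swing for a *given* phase sequence, evaluated analytically from
#' the kernel's cumulative form (no noise, no transient: the transient
#' cancels in the black-white difference). Because the offset transitions
#' lag the switch, a switch following a short phase starts from an
#' unsettled level and yields a smaller measurable rise; this routine
#' accounts for the full within-trial switch history, applying the same
#' usability and window rules as the analysis. The generator divides the
#' requested index-scale amplitude by this gain, so `modulation_amp` is
#' expressed in the units the pipeline reports.
#'
#' @param phases Ground-truth phase tibble.
#' @param params A [pupil_model_params()].
#' @param window Epoch window, s.
#' @param analysis_rate Analysis grid rate, Hz.
#' @param baseline_s Baseline window length, s.
#' @param min_s,max_s Phase-duration usability bounds, s.
#' @param mode Index mode (see [luminance_modulation()]).
#' @return Scalar gain; falls back to [index_window_gain()] when the
#'   sequence has no qualifying switch.
#' @export
realized_index_gain <- function(phases, params, window = c(-1, 1),
                                analysis_rate = 60, baseline_s = 0.15,
                                min_s = 1, max_s = 15,
                                mode = c("pre_post", "post_only")) {
  mode <- match.arg(mode)
  dt <- 1 / analysis_rate
  tt <- seq(window[1], window[2], by = dt)
  pre_sel <- tt >= -1 & tt < 0
  post_sel <- tt >= 0 & tt <= 1
  pre_base <- tt >= -baseline_s & tt < 0
  post_base <- tt >= 0 & tt <= baseline_s
  lat <- params$transient_latency; wid <- params$transient_width
  pre_vals <- list(black_front = numeric(0), white_front = numeric(0))
  post_vals <- list(black_front = numeric(0), white_front = numeric(0))
  for (tr in unique(phases$trial)) {
    ph <- phases[phases$trial == tr, ]
    ph <- ph[order(ph$start_s), ]
    dur <- ph$end_s - ph$start_s
    trial_end <- max(ph$end_s)
    usable <- dur >= min_s & dur <= max_s & ph$end_s < trial_end - 1e-9
    if (nrow(ph) < 2) next
    sgn <- ifelse(ph$label == "black_front", 1, -1)
    # unit-swing modulation waveform for this trial, evaluated analytically
    m_fun <- function(t) {
      out <- rep(sgn[1] / 2, length(t))
      for (k in 2:nrow(ph)) {
        out <- out + sgn[k] * pupil_kernel_cdf(t - ph$start_s[k], lat, wid)
      }
      out
    }
    for (k in seq_len(nrow(ph) - 1)) {
      ts <- ph$end_s[k]
      m <- m_fun(ts + tt)
      if (usable[k + 1]) {
        v <- mean(m[post_sel]) - mean(m[post_base])
        lab <- ph$label[k + 1]
        post_vals[[lab]] <- c(post_vals[[lab]], v)
      }
      if (usable[k]) {
        v <- mean(m[pre_sel]) - mean(m[pre_base])
        lab <- ph$label[k]
        pre_vals[[lab]] <- c(pre_vals[[lab]], v)
      }
    }
  }
  ok <- length(post_vals$black_front) > 0 && length(post_vals$white_front) > 0
  if (!ok) return(index_window_gain(params, mode = mode))
  post <- mean(post_vals$black_front) - mean(post_vals$white_front)
  if (mode == "post_only") return(post)
  if (length(pre_vals$black_front) == 0 ||
      length(pre_vals$white_front) == 0) {
    return(index_window_gain(params, mode = mode))
  }
  pre <- mean(pre_vals$black_front) - mean(pre_vals$white_front)
  (pre + post) / 2
}

#' Generate integer AQ totals
#'
#' Draws from Normal(`aq_mean`, `aq_sd`), rounds to integers, and redraws
#' (rather than clips) any value outside \[0, `aq_max`\], avoiding a point
#' mass at the bounds.
#'
#' @param params A [cohort_params()].
#' @param n Number of scores (defaults to `params$n_subjects`).
#' @param seed Seed (defaults to `params$seed`).
#' @return Integer vector of AQ totals.
#' @export
gen_aq_scores <- function(params, n = params$n_subjects, seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  draw <- function() {
    out <- integer(0)
    while (length(out) < n) {
      x <- as.integer(round(stats::rnorm(n, params$aq_mean, params$aq_sd)))
      out <- c(out, x[x >= 0 & x <= params$aq_max])
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate per-subject true modulation amplitudes from AQ
#'
#' Linear link: `slope_beta * AQ + Normal(0, residual_sd)`, on the index
#' scale (mm).
#'
#' @param aq Integer AQ totals.
#' @param params A [cohort_params()].
#' @param seed Optional seed.
#' @return Numeric vector of amplitudes (mm).
#' @export
gen_true_amplitudes <- function(aq, params, seed = NULL) {
  draw <- function() params$slope_beta * aq +
    stats::rnorm(length(aq), 0, params$residual_sd)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate alternating percept phases
#'
#' Gamma renewal process per trial: durations are i.i.d. gamma with mean
#' `mean_phase_duration` and shape `phase_shape` (`Inf` = deterministic);
#' labels strictly alternate; the first label is black-front with
#' probability `p_black_front`; phases tile each trial exactly (the last is
#' truncated at the trial end).
#'
#' @param params A [percept_dynamics_params()].
#' @param seed Seed (defaults to `params$seed`).
#' @return Tibble with `trial`, `start_s`, `end_s`, `label`.
#' @export
gen_percept_sequence <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "percept_dynamics_params"))
  draw_durations <- function(n) {
    if (is.infinite(params$phase_shape)) rep(params$mean_phase_duration, n)
    else stats::rgamma(n, shape = params$phase_shape,
                       scale = params$mean_phase_duration / params$phase_shape)
  }
  run <- function() {
    out <- vector("list", params$n_trials)
    for (tr in seq_len(params$n_trials)) {
      durs <- numeric(0)
      while (sum(durs) < params$trial_duration) {
        durs <- c(durs, draw_durations(
          max(4L, ceiling(params$trial_duration /
                            params$mean_phase_duration))))
      }
      ends <- cumsum(durs)
      k <- which(ends >= params$trial_duration)[1]
      durs <- durs[seq_len(k)]
      ends <- ends[seq_len(k)]
      ends[k] <- params$trial_duration  # truncate last phase at trial end
      starts <- c(0, ends[-k])
      first_black <- stats::runif(1) < params$p_black_front
      labs <- if (first_black) {
        rep_len(c("black_front", "white_front"), k)
      } else {
        rep_len(c("white_front", "black_front"), k)
      }
      out[[tr]] <- tibble::tibble(trial = tr, start_s = starts, end_s = ends,
                                  label = labs)
    }
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a pupil trace for a phase sequence
#'
#' See [pupil_model_params()] for the trace model. Returns the sampled
#' recording, the injected blink intervals, and the physical offset swing
#' used.
#'
#' @param phases Ground-truth phase tibble (from [gen_percept_sequence()]).
#' @param params A [pupil_model_params()].
#' @param modulation_amp Index-scale modulation amplitude, mm (defaults to
#'   `params$modulation_amp`).
#' @param seed Optional seed.
#' @return List with `samples` (tibble: `trial`, `t_s`, `pupil_mm`,
#'   `gaze_x_deg`, `gaze_y_deg`), `artifacts` (tibble: `trial`, `start_s`,
#'   `end_s`), `modulation_amp`, `offset_swing`.
#' @export
gen_pupil_trace <- function(phases, params,
                            modulation_amp = params$modulation_amp,
                            seed = NULL) {
  stopifnot(inherits(params, "pupil_model_params"), nrow(phases) > 0)
  swing <- modulation_amp / realized_index_gain(phases, params)
  dt <- 1 / params$sample_rate
  lat <- params$transient_latency; wid <- params$transient_width
  run <- function() {
    trials <- unique(phases$trial)
    samp <- vector("list", length(trials))
    arts <- vector("list", length(trials))
    for (i in seq_along(trials)) {
      ph <- phases[phases$trial == trials[i], ]
      dur <- max(ph$end_s)
      t <- seq(0, dur - dt, by = dt)
      sgn <- ifelse(ph$label == "black_front", 1, -1)
      mod <- rep(swing / 2 * sgn[1], length(t))
      if (nrow(ph) > 1) {
        for (k in 2:nrow(ph)) {
          tau <- ph$start_s[k]
          mod <- mod + swing * sgn[k] * pupil_kernel_cdf(t - tau, lat, wid)
        }
      }
      trans <- rep(0, length(t))
      if (nrow(ph) > 1 && params$transient_amp != 0) {
        for (k in 2:nrow(ph)) {
          trans <- trans + params$transient_amp *
            pupil_kernel(t - ph$start_s[k], lat, wid)
        }
      }
      noise <- rep(0, length(t))
      if (params$noise_sd > 0) {
        a <- exp(-dt / params$noise_ac_tau)
        eps <- stats::rnorm(length(t), 0, params$noise_sd * sqrt(1 - a^2))
        noise <- stats::filter(eps, a, method = "recursive")
        noise[1] <- stats::rnorm(1, 0, params$noise_sd)
        noise <- as.numeric(noise)
      }
      pupil <- params$baseline_mm + mod + trans + noise
      n_blinks <- stats::rpois(1, params$blink_rate / 60 * dur)
      art <- tibble::tibble(trial = trials[i], start_s = numeric(0),
                            end_s = numeric(0))
      if (n_blinks > 0) {
        bs <- sort(stats::runif(n_blinks, 0, dur - params$blink_duration))
        be <- bs + params$blink_duration
        for (b in seq_len(n_blinks)) {
          pupil[t >= bs[b] & t < be[b]] <- 0.2  # tracker records sub-1-mm
        }
        art <- tibble::tibble(trial = trials[i], start_s = bs, end_s = be)
      }
      samp[[i]] <- tibble::tibble(trial = trials[i], t_s = t,
                                  pupil_mm = pupil, gaze_x_deg = 0,
                                  gaze_y_deg = 0)
      arts[[i]] <- art
    }
    list(samples = dplyr::bind_rows(samp), artifacts = dplyr::bind_rows(arts),
         modulation_amp = modulation_amp, offset_swing = swing)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate detection key presses for an event schedule
#'
#' Each event is answered independently with probability `hit_rate`, at the
#' event time plus a gamma-distributed latency (shape 4, mean
#' `latency_mean`, capped below the 2-s hit window); spurious presses form a
#' homogeneous Poisson process at `fa_rate` per minute.
#'
#' @param events Event tibble with `trial`, `t_s`.
#' @param hit_rate Probability of responding to an event.
#' @param fa_rate Spurious presses per minute.
#' @param latency_mean Mean response latency, s (must be < 2).
#' @param trial_duration Trial duration, s.
#' @param seed Optional seed.
#' @return Tibble with `trial`, `t_s`, sorted within trial.
#' @export
gen_detection_responses <- function(events, hit_rate, fa_rate,
                                    latency_mean = 0.5, trial_duration = 59,
                                    seed = NULL) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, latency_mean < 2, fa_rate >= 0)
  run <- function() {
    hit <- stats::runif(nrow(events)) < hit_rate
    lat <- pmin(stats::rgamma(nrow(events), shape = 4,
                              scale = latency_mean / 4), 1.9)
    presses <- tibble::tibble(trial = events$trial[hit],
                              t_s = events$t_s[hit] + lat[hit])
    trials <- unique(events$trial)
    if (length(trials) == 0) trials <- 1L  # event-free run: spurious only
    if (fa_rate > 0) {
      fa <- lapply(trials, function(tr) {
        n <- stats::rpois(1, fa_rate / 60 * trial_duration)
        tibble::tibble(trial = tr, t_s = sort(stats::runif(n, 0,
                                                           trial_duration)))
      })
      presses <- dplyr::bind_rows(presses, dplyr::bind_rows(fa))
    }
    dplyr::arrange(presses, trial, t_s)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate item-level AQ responses consistent with target totals
#'
#' For each subject a random set of `total` items is made ASD-characteristic
#' and coded accordingly (slight/strong chosen at random), so that standard
#' scoring recovers the target total exactly.
#'
#' @param totals Integer AQ totals (0-50).
#' @param key AQ key tibble (see [aq_key()]).
#' @param seed Optional seed.
#' @return Tibble with `subject` and `item_01`..`item_50` coded 1-4
#'   (1 = strongly agree ... 4 = strongly disagree).
#' @export
gen_aq_responses <- function(totals, key = aq_key(), seed = NULL) {
  stopifnot(all(totals >= 0), all(totals <= 50))
  run <- function() {
    rows <- lapply(seq_along(totals), function(i) {
      characteristic <- logical(50)
      characteristic[sample(50, totals[i])] <- TRUE
      strong <- stats::runif(50) < 0.5
      agree <- key$agree_scored == characteristic  # agree iff it scores (or anti)
      code <- ifelse(agree, ifelse(strong, 1L, 2L), ifelse(strong, 4L, 3L))
      stats::setNames(as.list(code), sprintf("item_%02d", 1:50))
    })
    out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    dplyr::bind_cols(tibble::tibble(subject = seq_along(totals)), out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a full synthetic cohort
#'
#' Draws AQ totals and AQ-linked true modulation amplitudes, simulates each
#' subject's percept phases, pupil trace (with blink artifacts) and, when
#' `detection` is given, speed-increment events and key presses. All
#' randomness derives from `cohort$seed`, so identical parameters reproduce
#' the dataset exactly.
#'
#' @param cohort A [cohort_params()].
#' @param dynamics A [percept_dynamics_params()].
#' @param pupil A [pupil_model_params()].
#' @param detection Optional list with `mean_interval`, `min_separation`,
#'   `hit_rate_front`, `hit_rate_rear`, `fa_rate`, `latency_mean` to also
#'   simulate the double-task detection data.
#' @param key AQ key (see [aq_key()]).
#' @return A list of class `synthetic_cohort`: `manifest` (all parameters),
#'   `subjects` (tibble with `subject`, `aq_total`, `true_modulation_amp`),
#'   `aq_responses`, and `data` (per-subject list of `phases`, `samples`,
#'   `artifacts`, and optionally `events`, `presses`).
#' @export
gen_cohort <- function(cohort, dynamics, pupil, detection = NULL,
                       key = aq_key()) {
  stopifnot(inherits(cohort, "cohort_params"),
            inherits(dynamics, "percept_dynamics_params"),
            inherits(pupil, "pupil_model_params"))
  withr::with_seed(cohort$seed, {
    aq <- gen_aq_scores(cohort, seed = NULL)
    amp <- gen_true_amplitudes(aq, cohort, seed = NULL)
    aq_resp <- gen_aq_responses(aq, key, seed = NULL)
    data <- vector("list", cohort$n_subjects)
    for (s in seq_len(cohort$n_subjects)) {
      phases <- gen_percept_sequence(dynamics, seed = NULL)
      trace <- gen_pupil_trace(phases, pupil, modulation_amp = amp[s],
                               seed = NULL)
      subj <- list(phases = phases, samples = trace$samples,
                   artifacts = trace$artifacts)
      if (!is.null(detection)) {
        ev <- lapply(seq_len(dynamics$n_trials), function(tr) {
          e <- schedule_increments(dynamics$trial_duration,
                                   detection$mean_interval,
                                   detection$min_separation, seed = NULL)
          e$trial <- tr
          e
        })
        events <- dplyr::bind_rows(ev)
        # per-event hit probability by perceived surface at event time
        front <- surface_of_event(events, phases)$surface == "front"
        front[is.na(front)] <- TRUE
        hr <- ifelse(front, detection$hit_rate_front, detection$hit_rate_rear)
        hit <- stats::runif(nrow(events)) < hr
        lat <- pmin(stats::rgamma(nrow(events), 4,
                                  scale = detection$latency_mean / 4), 1.9)
        presses <- tibble::tibble(trial = events$trial[hit],
                                  t_s = events$t_s[hit] + lat[hit])
        if (detection$fa_rate > 0) {
          fa <- lapply(seq_len(dynamics$n_trials), function(tr) {
            n <- stats::rpois(1, detection$fa_rate / 60 *
                                dynamics$trial_duration)
            tibble::tibble(trial = tr,
                           t_s = sort(stats::runif(n, 0,
                                                   dynamics$trial_duration)))
          })
          presses <- dplyr::bind_rows(presses, dplyr::bind_rows(fa))
        }
        subj$events <- events
        subj$presses <- dplyr::arrange(presses, trial, t_s)
      }
      data[[s]] <- subj
    }
    structure(list(
      manifest = list(cohort = unclass(cohort), dynamics = unclass(dynamics),
                      pupil = unclass(pupil), detection = detection,
                      package_version = as.character(
                        utils::packageVersion("pupilstyle"))),
      subjects = tibble::tibble(subject = seq_len(cohort$n_subjects),
                                aq_total = aq, true_modulation_amp = amp),
      aq_responses = aq_resp,
      data = data
    ), class = "synthetic_cohort")
  })
}
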