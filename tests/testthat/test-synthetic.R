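test_that("AQ scores are truncated integers with the target mean", {
  cp <- cohort_params(aq_mean = 15, aq_sd = 1e-12)
  expect_true(all(gen_aq_scores(cp, n = 20, seed = 1) == 15))
  cp <- cohort_params()
  s <- gen_aq_scores(cp, n = 100000, seed = 7)
  expect_true(all(s == round(s)))
  expect_true(all(s >= 0 & s <= 31))
  expect_lt(abs(mean(s) - 14.85), 0.15)
  expect_identical(gen_aq_scores(cp, seed = 3), gen_aq_scores(cp, seed = 3))
})

test_that("percept phases alternate, tile trials, and match the mean", {
  dyn <- percept_dynamics_params(phase_shape = Inf, mean_phase_duration = 5,
                                 trial_duration = 59, n_trials = 1, seed = 1)
  ph <- gen_percept_sequence(dyn)
  # deterministic 5-s renewal: switch rate exactly 0.2 /s over complete phases
  complete <- ph[ph$end_s - ph$start_s >= 5 - 1e-9, ]
  expect_equal(nrow(complete) - 1, floor(59 / 5) - 1)
  expect_equal(switch_rate(with_usable(ph)), (nrow(ph) - 1) / 59,
               tolerance = 1e-9)
  dyn <- percept_dynamics_params(n_trials = 1000, seed = 2)
  ph <- gen_percept_sequence(dyn)
  for (tr in unique(ph$trial)) {
    p <- ph[ph$trial == tr, ]
    expect_equal(p$start_s[-1], p$end_s[-nrow(p)])  # tiling
    expect_true(all(p$label[-1] != p$label[-nrow(p)]))  # alternation
    expect_equal(max(p$end_s), 59)
  }
  # complete (untruncated) durations: mean within 2% of 5.5 s
  durs <- (ph$end_s - ph$start_s)[ph$end_s < 59 - 1e-9]
  expect_gt(length(durs), 10000 * 0.9)
  expect_equal(mean(durs), 5.5, tolerance = 0.02 * 5.5)
})

test_that("pupil trace construction is symmetric, calibrated, deterministic", {
  # transient off: with no modulation the trace is exactly label-symmetric
  # (with transients on, residuals from the previous switch differ across
  # the random label subsets, so identity holds only in expectation)
  subj <- small_subject(seed = 3, amp = 0,
                        params = clean_pupil_params(transient_amp = 0))
  flt <- subj$usable
  ep <- extract_switch_epochs(subj$samples, flt)
  b <- label_trace(ep, "black_front"); w <- label_trace(ep, "white_front")
  # modulation_amp = 0, noise 0: label means identical up to grid error
  expect_lt(max(abs(b - w), na.rm = TRUE), 1e-9)
  # determinism of the full generation path
  s1 <- gen_pupil_trace(subj$phases, clean_pupil_params(), 0.04, seed = 9)
  s2 <- gen_pupil_trace(subj$phases, clean_pupil_params(), 0.04, seed = 9)
  expect_identical(s1, s2)
})

test_that("noise-free modulation is recovered by the downstream index", {
  subj <- small_subject(seed = 4, amp = 0.05, n_trials = 10)
  ep <- extract_switch_epochs(subj$samples, subj$usable)
  idx <- luminance_modulation(ep)
  expect_equal(idx, 0.05, tolerance = 0.05 * 0.05)
})

test_that("blink injection matches the Poisson expectation", {
  dyn <- percept_dynamics_params(n_trials = 10, seed = 5)
  ph <- gen_percept_sequence(dyn)
  pp <- pupil_model_params(noise_sd = 0, blink_rate = 6,
                           blink_duration = 0.25)
  tr <- gen_pupil_trace(ph, pp, seed = 5)
  n_blinks <- nrow(tr$artifacts)
  expect_gt(n_blinks, 59 * 0.6)      # ~59 expected over 590 s
  expect_lt(n_blinks, 59 * 1.4)
  frac <- mean(!mask_pupil_samples(tr$samples))
  expect_equal(frac, 6 * 0.25 / 60, tolerance = 0.35)
})

test_that("detection responses reflect hit rate and false-alarm process", {
  ev <- schedule_increments(590, seed = 11)
  ev$trial <- 1L
  pr <- gen_detection_responses(ev, hit_rate = 1, fa_rate = 0,
                                latency_mean = 0.5, trial_duration = 590,
                                seed = 1)
  cls <- classify_presses(ev, pr)
  expect_true(all(cls$events$hit))
  expect_equal(nrow(cls$false_alarms), 0)
  # zero events: everything is a false alarm
  pr0 <- gen_detection_responses(ev[0, ], hit_rate = 1, fa_rate = 6,
                                 trial_duration = 590, seed = 2)
  expect_gt(nrow(pr0), 0)
  cls0 <- classify_presses(ev[0, ], pr0)
  expect_equal(nrow(cls0$false_alarms), nrow(pr0))
})

test_that("cohort link: zero residual gives perfect AQ-amplitude correlation", {
  cp <- cohort_params(n_subjects = 30, residual_sd = 0, seed = 2)
  aq <- gen_aq_scores(cp)
  amp <- gen_true_amplitudes(aq, cp, seed = 3)
  expect_equal(cor(aq, amp), 1, tolerance = 1e-12)
})

test_that("gen_cohort is reproducible and carries ground truth", {
  cp <- cohort_params(n_subjects = 3, seed = 21)
  dyn <- percept_dynamics_params(n_trials = 2, seed = 21)
  pp <- clean_pupil_params()
  co1 <- gen_cohort(cp, dyn, pp)
  co2 <- gen_cohort(cp, dyn, pp)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$data, co2$data)
  expect_equal(nrow(co1$subjects), 3)
  expect_true(all(c("aq_total", "true_modulation_amp") %in%
                    names(co1$subjects)))
  # written dataset is byte-identical on regeneration
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next  # records package version only
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
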