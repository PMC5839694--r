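# three phases over 20 s; the switch at 8 s has usable phases on both sides
three_phase <- function() {
  with_usable(tibble::tibble(
    trial = 1L, start_s = c(0, 8, 14), end_s = c(8, 14, 20),
    label = c("black_front", "white_front", "black_front")))
}

test_that("constant and step traces correct to zero on both sides", {
  ph <- three_phase()
  const <- flat_samples(3.2)
  ep <- extract_switch_epochs(const, ph)
  expect_equal(nrow(ep$mat), 2)  # boundary phase contributes pre side only
  expect_lt(max(abs(ep$mat), na.rm = TRUE), 1e-12)
  # a step at the switch is absorbed by each side's own baseline
  step <- flat_samples(3.0)
  step$pupil_mm[step$t_s >= 8] <- 3.1
  eps <- extract_switch_epochs(step, ph)
  expect_lt(max(abs(eps$mat[1, ]), na.rm = TRUE), 1e-12)
})

test_that("a known kernel survives epoching minus its own baseline mean", {
  ph <- three_phase()
  tr <- flat_samples(4)
  k <- pupil_kernel(tr$t_s - 8)
  tr$pupil_mm <- 4 + 0.05 * k
  ep <- extract_switch_epochs(tr, ph)
  post <- ep$time >= 0
  expect_kernel <- 0.05 * pupil_kernel(ep$time[post])
  base <- mean(expect_kernel[ep$time[post] <= 0.15])
  expect_equal(unname(ep$mat[1, post]), expect_kernel - base,
               tolerance = 1e-6)
})

test_that("onset epochs baseline on the preceding 150 ms", {
  onsets <- tibble::tibble(trial = 1L, t_s = 5, cue = "black_cued")
  const <- flat_samples(3.5)
  ep <- extract_onset_epochs(const, onsets)
  expect_lt(max(abs(ep$mat)), 1e-12)
  # linear ramp a*t from onset: corrected trace ~ a*t
  ramp <- flat_samples(3)
  a <- 0.02
  ramp$pupil_mm <- 3 + a * pmax(ramp$t_s - 5, 0)
  epr <- extract_onset_epochs(ramp, onsets)
  expect_equal(unname(epr$mat[1, ]), a * epr$time, tolerance = 1e-9)
  expect_equal(epr$label, "black_cued")
})

test_that("baseline correction is idempotent", {
  subj <- small_subject(seed = 7, amp = 0.04)
  ep <- extract_switch_epochs(subj$samples, subj$usable)
  rebase <- ep
  post <- ep$time >= 0 & ep$time <= 0.15
  pre <- ep$time >= -0.15 & ep$time < 0
  for (i in seq_len(nrow(ep$mat))) {
    if (ep$pre_ok[i]) {
      rebase$mat[i, ep$time < 0] <- ep$mat[i, ep$time < 0] -
        mean(ep$mat[i, pre], na.rm = TRUE)
    }
    if (ep$post_ok[i]) {
      rebase$mat[i, ep$time >= 0] <- ep$mat[i, ep$time >= 0] -
        mean(ep$mat[i, post], na.rm = TRUE)
    }
  }
  expect_equal(rebase$mat, ep$mat, tolerance = 1e-12)
})

test_that("index sign conventions: label swap negates, offsets cancel", {
  subj <- small_subject(seed = 8, amp = 0.05, n_trials = 6)
  ep <- extract_switch_epochs(subj$samples, subj$usable)
  idx <- luminance_modulation(ep)
  swapped <- subj$usable
  swapped$label <- ifelse(swapped$label == "black_front",
                          "white_front", "black_front")
  ep_sw <- extract_switch_epochs(subj$samples, swapped)
  expect_equal(luminance_modulation(ep_sw), -idx, tolerance = 1e-12)
  # adding a constant to the whole recording changes nothing
  shifted <- subj$samples
  shifted$pupil_mm <- shifted$pupil_mm + 0.7
  ep_sh <- extract_switch_epochs(shifted, subj$usable)
  expect_equal(luminance_modulation(ep_sh), idx, tolerance = 1e-12)
  expect_equal(general_dilation(ep_sh), general_dilation(ep),
               tolerance = 1e-12)
})

test_that("modulation-only traces yield near-zero general dilation", {
  subj <- small_subject(seed = 9, amp = 0.05, n_trials = 10,
                        params = clean_pupil_params(transient_amp = 0))
  ep <- extract_switch_epochs(subj$samples, subj$usable)
  # black and white offsets cancel in the pooled post-switch trace
  expect_lt(abs(general_dilation(ep)), 0.05 * 0.05)
  # transient-only traces give positive general dilation
  subj2 <- small_subject(seed = 9, amp = 0, n_trials = 6,
                         params = clean_pupil_params(transient_amp = 0.05))
  ep2 <- extract_switch_epochs(subj2$samples, subj2$usable)
  expect_gt(general_dilation(ep2), 0)
})

test_that("1000-Hz recordings give the same indices after downsampling", {
  dyn <- percept_dynamics_params(n_trials = 3, seed = 13)
  ph <- gen_percept_sequence(dyn)
  flt <- filter_phases(ph)$phases
  tr60 <- gen_pupil_trace(ph, clean_pupil_params(sample_rate = 60), 0.05)
  tr1k <- gen_pupil_trace(ph, clean_pupil_params(sample_rate = 1000), 0.05)
  i60 <- luminance_modulation(extract_switch_epochs(tr60$samples, flt))
  i1k <- luminance_modulation(extract_switch_epochs(tr1k$samples, flt))
  expect_equal(i60, i1k, tolerance = 0.02 * 0.05)
})

test_that("mean traces aggregate within subject first", {
  s1 <- small_subject(seed = 10, amp = 0.05, n_trials = 3)
  s2 <- small_subject(seed = 11, amp = 0.01, n_trials = 3)
  eps <- list(extract_switch_epochs(s1$samples, s1$usable),
              extract_switch_epochs(s2$samples, s2$usable))
  mt <- mean_traces(eps)
  expect_setequal(unique(mt$label), c("black_front", "white_front"))
  expect_true(all(mt$n <= 2))
  # across-subject mean equals the mean of the two per-subject traces
  b1 <- label_trace(eps[[1]], "black_front")
  b2 <- label_trace(eps[[2]], "black_front")
  got <- mt$mean[mt$label == "black_front"]
  expect_equal(got, as.numeric((b1 + b2) / 2), tolerance = 1e-12)
  # single subject: s.e.m. undefined -> NA
  mt1 <- mean_traces(eps[[1]])
  expect_true(all(is.na(mt1$sem)))
  expect_error(mean_traces(eps, labels = "black_cued"), "absent")
})

test_that("attention modulation recovers a cue-dependent separation", {
  onsets <- tibble::tibble(trial = c(1L, 2L), t_s = c(2, 2),
                           cue = c("black_cued", "white_cued"))
  mk <- function(offset) {
    s <- flat_samples(4, duration = 10)
    s$pupil_mm <- 4 + offset * pupil_kernel_cdf(s$t_s - 2)
    s
  }
  samples <- dplyr::bind_rows(mk(0.04), dplyr::mutate(mk(-0.04),
                                                      trial = 2L))
  ep <- extract_onset_epochs(samples, onsets)
  got <- attention_modulation(ep)
  want <- 0.08 * mean(pupil_kernel_cdf(seq(1, 3, by = 1 / 60) - 0))
  expect_equal(got, want, tolerance = 0.01 * want)
  # identical cue traces -> 0
  same <- dplyr::bind_rows(mk(0.04), dplyr::mutate(mk(0.04), trial = 2L))
  expect_equal(attention_modulation(extract_onset_epochs(same, onsets)), 0,
               tolerance = 1e-9)
})

test_that("per-subject significance detects separation, calibrates to alpha", {
  subj <- small_subject(seed = 14, amp = 0.2, n_trials = 10)
  ep <- extract_switch_epochs(subj$samples, subj$usable)
  expect_true(per_subject_significance(ep)$significant)
  # null calibration: amplitude 0 with noise, flag rate ~ alpha
  flags <- vapply(1:40, function(k) {
    s <- small_subject(seed = 100 + k, amp = 0, n_trials = 2,
                       params = pupil_model_params(noise_sd = 0.1,
                                                   blink_rate = 0))
    ep <- extract_switch_epochs(s$samples, s$usable)
    isTRUE(per_subject_significance(ep)$significant)
  }, logical(1))
  expect_lte(mean(flags), 0.2)
})

test_that("switch rate counts within-trial switches over reported time", {
  ph <- with_usable(alternating_phases(5, 20))
  expect_equal(switch_rate(ph), 3 / 20)
  one <- with_usable(tibble::tibble(trial = 1:2, start_s = 0, end_s = 10,
                                    label = "black_front"))
  expect_equal(switch_rate(one), 0)
  expect_error(switch_rate(ph, total_time = 0), "zero")
})
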