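ev <- function(times, color = "black") {
  tibble::tibble(trial = 1L, t_s = times, dot_color = color)
}
pr <- function(times) tibble::tibble(trial = 1L, t_s = times)

test_that("press classification follows the 2-s window rule", {
  cls <- classify_presses(ev(c(10, 20)), pr(c(11.5, 30)))
  expect_equal(cls$events$hit, c(TRUE, FALSE))
  expect_equal(nrow(cls$false_alarms), 1)
  # press at 21.9 with event at 20: inside the window -> hit
  expect_true(classify_presses(ev(20), pr(21.9))$events$hit)
  # press at 22.5 with events {20, 26}: > 2 s from both -> false alarm
  cls2 <- classify_presses(ev(c(20, 26)), pr(22.5))
  expect_equal(nrow(cls2$false_alarms), 1)
  # one hit per event; attribution to the closer (later) event
  cls3 <- classify_presses(ev(c(20, 23)), pr(c(24, 24.5)))
  expect_equal(cls3$events$hit, c(FALSE, TRUE))
  expect_equal(cls3$n_ignored, 1L)
  # invariance to a global time shift
  cls4 <- classify_presses(ev(c(110, 120)), pr(c(111.5, 130)))
  expect_equal(cls4$events$hit, cls$events$hit)
})

test_that("classification agrees with a brute-force all-pairs scorer", {
  brute <- function(events, presses, window = 2) {
    hits <- rep(FALSE, nrow(events))
    n_fa <- 0
    for (p in sort(presses$t_s)) {
      d <- p - events$t_s
      cand <- which(d >= 0 & d <= window)
      if (length(cand) > 0) {
        k <- cand[which.min(d[cand])]
        if (!hits[k]) hits[k] <- TRUE
      } else if (all(abs(d) > window)) {
        n_fa <- n_fa + 1
      }
    }
    list(hits = hits, n_fa = n_fa)
  }
  withr::with_seed(99, {
    for (rep in 1:300) {
      events <- ev(sort(stats::runif(sample(3:15, 1), 0, 100)))
      presses <- pr(sort(stats::runif(sample(0:15, 1), 0, 100)))
      got <- classify_presses(events, presses)
      want <- brute(events, presses)
      expect_identical(got$events$hit, want$hits)
      expect_identical(nrow(got$false_alarms), as.integer(want$n_fa))
    }
  })
})

test_that("event surfaces resolve from the concurrent percept", {
  ph <- with_usable(alternating_phases(5, 20))  # black first
  events <- ev(c(1, 6), color = "black")
  out <- surface_of_event(events, ph)
  expect_equal(out$surface, c("front", "rear"))
  # event in an unusable phase is dropped
  ph$usable[1] <- FALSE
  out2 <- surface_of_event(events, ph)
  expect_true(is.na(out2$surface[1]))
})

test_that("d-prime matches the quantile oracle and correction rule", {
  expect_equal(dprime(84, 100, 16, 100)$dprime,
               stats::qnorm(0.84) - stats::qnorm(0.16), tolerance = 1e-12)
  expect_equal(dprime(84, 100, 16, 100)$dprime, 1.989, tolerance = 1e-3)
  # H = F -> 0
  expect_equal(dprime(50, 100, 50, 100)$dprime, 0)
  # perfect observer with 20 events/opportunities: 1/(2N) correction
  d <- dprime(20, 20, 0, 20)
  expect_equal(d$hit_rate, 0.975)
  expect_equal(d$fa_rate, 0.025)
  expect_equal(d$dprime, stats::qnorm(0.975) - stats::qnorm(0.025),
               tolerance = 1e-12)
  expect_equal(d$dprime, 3.92, tolerance = 0.005)
  # antisymmetry under swapping hit and false-alarm rates
  expect_equal(dprime(30, 100, 70, 100)$dprime,
               -dprime(70, 100, 30, 100)$dprime, tolerance = 1e-12)
  expect_error(dprime(1, 1, 0, 0), "opportunities")
})

test_that("simulated observers reproduce their analytic d-prime", {
  # sparse events so spurious presses rarely contaminate the hit windows
  withr::with_seed(7, {
    events <- tibble::tibble(trial = 1L,
                             t_s = seq(5, 10000, by = 10),
                             dot_color = "black")
    presses <- gen_detection_responses(events, hit_rate = 0.8, fa_rate = 0.6,
                                       latency_mean = 0.5,
                                       trial_duration = 10005, seed = 1)
    cls <- classify_presses(events, presses)
    n_opp <- fa_opportunities(events, trial_duration = 10005)
    d <- dprime(sum(cls$events$hit), nrow(events),
                nrow(cls$false_alarms), n_opp)
    # analytic: H = 0.8; FA per 2-s bin = 1 - exp(-rate * 2)
    fa_bin <- 1 - exp(-0.6 / 60 * 2)
    want <- stats::qnorm(0.8) - stats::qnorm(fa_bin)
    expect_equal(d$dprime, want, tolerance = 0.1)
  })
})

test_that("surface-split scoring shows a front advantage when generated", {
  dyn <- percept_dynamics_params(n_trials = 10, seed = 31)
  det <- list(mean_interval = 3, min_separation = 2, hit_rate_front = 0.9,
              hit_rate_rear = 0.5, fa_rate = 1, latency_mean = 0.5)
  co <- gen_cohort(cohort_params(n_subjects = 4, seed = 31), dyn,
                   clean_pupil_params(), detection = det)
  ds <- vapply(co$data, function(d) {
    ph <- filter_phases(d$phases)$phases
    s <- score_detection(d$events, d$presses, ph)
    c(front = s$dprime[s$surface == "front"],
      rear = s$dprime[s$surface == "rear"])
  }, c(front = 0, rear = 0))
  expect_gt(mean(ds["front", ]), mean(ds["rear", ]))
})

test_that("counting-task scoring: exact matches and chance level", {
  expect_equal(score_counting_task(c(1, 2, 0), c(1, 2, 0))$percent_correct,
               100)
  withr::with_seed(21, {
    true <- sample(0:3, 4000, replace = TRUE)
    guess <- sample(0:3, 4000, replace = TRUE)
    pc <- score_counting_task(guess, true)$percent_correct
    expect_equal(pc, 25, tolerance = 2.5)
  })
  expect_error(score_counting_task(c(4), c(1)), "0..3")
})
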