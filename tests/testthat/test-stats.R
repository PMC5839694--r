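test_that("pearson_full matches cor.test and the Fisher-z interval", {
  withr::with_seed(1, {
    x <- stats::rnorm(30)
    y <- 0.5 * x + stats::rnorm(30)
  })
  got <- pearson_full(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(c(got$ci_low, got$ci_high), unname(ref$conf.int),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(got$ci_low <= got$r && got$r <= got$ci_high)
  expect_error(pearson_full(rep(1, 10), y[1:10]), "variance")
})

test_that("correlation p-values are uniform under the null", {
  ps <- withr::with_seed(2, {
    vapply(1:1000, function(i) {
      pearson_p(stats::cor(stats::rnorm(50), stats::rnorm(50)), 50)
    }, 0)
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Bayes factor matches the quadrature oracle across (r, n)", {
  grid <- expand.grid(r = c(-0.5, 0, 0.2, 0.4, 0.68, 0.8),
                      n = c(10, 22, 50, 120))
  for (i in seq_len(nrow(grid))) {
    bf <- bayes_factor_r(grid$r[i], grid$n[i])
    oracle <- jzs_quadrature_oracle(grid$r[i], grid$n[i])
    expect_equal(bf, oracle, tolerance = 5e-4,
                 label = sprintf("r=%.2f n=%d", grid$r[i], grid$n[i]))
  }
})

test_that("Bayes factor behaves as evidence should", {
  # null-favoring at r = 0, moderate n
  expect_lt(bayes_factor_r(0, 30), 1)
  # monotone increasing in |r| at fixed n
  bfs <- vapply(seq(0, 0.9, by = 0.1), bayes_factor_r, 0, n = 25)
  expect_true(all(diff(bfs) > 0))
  expect_equal(bayes_factor_r(-0.6, 25), bayes_factor_r(0.6, 25),
               tolerance = 1e-9)
  expect_error(bayes_factor_r(1, 25), "degenerate")
})

test_that("Fisher-Z comparison: hand-computed value and antisymmetry", {
  # (0.75, 25) vs (0.64, 25): z ~ 0.71, two-tailed p ~ 0.48
  got <- fisher_z_compare(0.75, 25, 0.64, 25)
  z_hand <- (atanh(0.75) - atanh(0.64)) / sqrt(2 / 22)
  expect_equal(got$z, z_hand, tolerance = 1e-12)
  expect_equal(got$z, 0.71, tolerance = 0.01)
  expect_equal(got$p, 0.48, tolerance = 0.01)
  # equal correlations: z = 0, p = 1
  same <- fisher_z_compare(0.5, 30, 0.5, 30)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # swapping negates z, keeps p
  rev <- fisher_z_compare(0.64, 25, 0.75, 25)
  expect_equal(rev$z, -got$z)
  expect_equal(rev$p, got$p)
})

test_that("Fisher-Z comparison holds its type-I error rate", {
  reject <- withr::with_seed(3, {
    vapply(1:500, function(i) {
      x1 <- stats::rnorm(40); y1 <- 0.5 * x1 + stats::rnorm(40)
      x2 <- stats::rnorm(40); y2 <- 0.5 * x2 + stats::rnorm(40)
      fisher_z_compare(stats::cor(x1, y1), 40, stats::cor(x2, y2), 40)$p < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(reject) - 0.05), 0.035)
})

test_that("paired t matches t.test and a sign-flip resampling oracle", {
  withr::with_seed(40, {
    x <- stats::rnorm(25, 4.5, 0.5)
    y <- x - 0.15 + stats::rnorm(25, 0, 0.3)
  })
  got <- paired_t(x, y)
  expect_equal(got$df, 24)
  d <- x - y
  t_obs <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_obs, tolerance = 1e-12)
  # sign-flip null distribution of |t|
  p_flip <- withr::with_seed(4, {
    flips <- replicate(20000, {
      s <- sample(c(-1, 1), length(d), replace = TRUE)
      ds <- s * d
      abs(mean(ds) / (stats::sd(ds) / sqrt(length(ds))))
    })
    mean(flips >= abs(t_obs))
  })
  expect_equal(got$p, p_flip, tolerance = 0.01)
  expect_equal(paired_t(x, x)$t, 0)
  expect_error(paired_t(1, 2), "2 pairs")
})

test_that("subscale matrix recovers generative structure", {
  withr::with_seed(5, {
    n <- 200
    sub <- matrix(stats::rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("s", 1:5)))
    # index loads on subscale 1 strongly, subscale 2 weakly
    idx <- sub[, 1] + 0.3 * sub[, 2] + 0.3 * stats::rnorm(n)
  })
  m <- subscale_matrix(idx, sub)
  ridx <- m[m$measure == "pupil_index" & m$against != "total", ]
  expect_equal(ridx$against[which.max(ridx$r)], "s1")
  expect_true(all(m$stars[m$p < 0.001] == "***"))
  # corrected-total rows: each subscale vs the sum of the other four
  rc <- m[m$measure == "corrected_total" & m$against == "s1", ]
  expect_equal(rc$r, stats::cor(sub[, 1], rowSums(sub[, -1])),
               tolerance = 1e-12)
  expect_error(subscale_matrix(idx[1:10], sub), "misaligned")
})

test_that("quartile summary bins with inverse-ECDF edges, ties down", {
  x <- 1:50
  qs <- quartile_summary(x, x)
  expect_equal(qs$n, c(13, 12, 13, 12))
  expect_true(all(diff(qs$mean) > 0))
  # constant y: equal means, zero s.e.m.
  qc <- quartile_summary(x, rep(2, 50))
  expect_true(all(qc$mean == 2))
  expect_true(all(qc$sem == 0))
})
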