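# Independent fixed-grid Simpson quadrature of the JZS marginal-likelihood
# ratio, substituting u = g/(1+g) (no adaptive integration): a brute-force
# oracle for bayes_factor_r(). The integrand is evaluated through logs only
# to avoid overflow of (1+g)^((n-2)/2) at large n; the quadrature itself is
# a plain fixed grid in u.
jzs_quadrature_oracle <- function(r, n, prior_scale = 1.17,
                                  n_points = 400001) {
  s2 <- prior_scale^2
  u <- seq(1e-12, 1 - 1e-12, length.out = n_points)
  g <- u / (1 - u)
  logf <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) +
    0.5 * log(n * s2 / 2) - lgamma(0.5) - 1.5 * log(g) - n * s2 / (2 * g) -
    2 * log1p(-u)
  m <- max(logf)
  integrand <- exp(logf - m)
  h <- u[2] - u[1]
  w <- rep(c(2, 4), length.out = n_points)  # composite Simpson, odd n_points
  w[1] <- 1; w[n_points] <- 1
  exp(m) * sum(w * integrand) * h / 3
}
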