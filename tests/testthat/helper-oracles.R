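# Independent oracles and small fixtures used across the suite.

# Numeric inversion of the logit psychometric function by root finding;
# independent of the closed forms used in the package.
invert_logit_numeric <- function(p, mu, s) {
  f <- function(x) stats::plogis((x - mu) / s) - p
  span <- max(abs(mu), 1) + 50 * abs(s) + 10
  stats::uniroot(f, interval = c(mu - span, mu + span), tol = 1e-12)$root
}

# Weber ratio by brute-force inversion at the 25% and 75% points.
weber_ratio_numeric <- function(mu, s) {
  0.5 * (invert_logit_numeric(0.75, mu, s) -
           invert_logit_numeric(0.25, mu, s)) / mu
}

# Partial correlation via the regression-residual definition.
partial_corr_residual <- function(x, y, z) {
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Build a psychometric_fit object with known parameters (bypassing the
# estimation step) so that the PSE/WR extractors can be probed directly.
known_fit <- function(mu, s) {
  structure(list(mu = mu, s = s, pse = mu, wr = s * log(3) / mu,
                 gof_p = 0.5, n_trials = 72, converged = TRUE,
                 deviance = 1, levels = numeric(0),
                 plus_counts = numeric(0), n_per_level = numeric(0)),
            class = "psychometric_fit")
}

# Sample '+' counts from a known logit observer: the generating model of
# the parameter-recovery checks.
simulate_plus_counts <- function(levels, mu, s, n_per_level) {
  p <- stats::plogis((levels - mu) / s)
  stats::rbinom(length(levels), n_per_level, p)
}

expand_onsets <- function(sched) rep(sched$onset_ms, sched$n_dots)
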