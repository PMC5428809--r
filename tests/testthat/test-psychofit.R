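test_that("binarization follows the midpoint rule and mirrors polarity", {
  expect_equal(binarize(62, "plus_top"), "plus")
  expect_equal(binarize(62, "plus_bottom"), "minus")
  expect_equal(binarize(50, "plus_top"), "minus") # tie at the start position
  expect_equal(binarize(50, "plus_bottom"), "minus")
  expect_error(binarize(120, "plus_top"), "0, 100")
  expect_error(binarize(50, "sideways"), "polarity")

  # Exhaustive integer grid: both polarities assign 50 positions to '+',
  # and flipping the polarity flips every non-tie response.
  grid <- 0:100
  top <- binarize(grid, "plus_top")
  bottom <- binarize(grid, "plus_bottom")
  expect_equal(sum(top == "plus"), 50)
  expect_equal(sum(bottom == "plus"), 50)
  ties <- grid == 50
  expect_true(all(top[!ties] != bottom[!ties]))
})

test_that("logit fits recover generating parameters", {
  # Median-accuracy of the recovered parameters over 100 replicates: the
  # median recovered location lies within 3% of the truth and the median
  # recovered scale within 15% (the per-replicate sampling spread of the
  # scale at 72 Bernoulli trials is larger than that and is not the
  # property checked here).
  levels <- magnitude_levels(1)
  res <- withr::with_seed(42, t(replicate(100, {
    plus <- simulate_plus_counts(levels, 1.0, 0.08, rep(12, 6))
    f <- fit_logit(levels, plus, rep(12, 6))
    c(mu = f$mu, s = f$s)
  })))
  expect_lt(abs(stats::median(res[, "mu"]) - 1.0), 0.03)
  expect_lt(abs(stats::median(res[, "s"]) - 0.08) / 0.08, 0.15)
})

test_that("degenerate response patterns are flagged unusable", {
  levels <- magnitude_levels(1)
  sep <- fit_logit(levels, c(0, 0, 0, 12, 12, 12), rep(12, 6))
  expect_false(sep$converged)
  flat <- fit_logit(levels, rep(6, 6), rep(12, 6))
  expect_false(flat$converged)
  expect_error(pse(flat), "unusable")
  expect_error(weber_ratio(flat), "unusable")
  expect_error(fit_logit(c(1, 1), c(3, 4), c(6, 6)), "distinct")
  expect_error(fit_logit(levels, rep(0, 6), rep(1, 6)), "12 trials")
})

test_that("PSE and Weber ratio closed forms match numeric curve inversion", {
  pars <- withr::with_seed(7, data.frame(mu = stats::runif(100, 0.5, 1200),
                                         s = stats::runif(100, 0.01, 150)))
  for (i in seq_len(nrow(pars))) {
    f <- known_fit(pars$mu[i], pars$s[i])
    expect_equal(pse(f), invert_logit_numeric(0.5, pars$mu[i], pars$s[i]),
                 tolerance = 1e-9)
    expect_equal(weber_ratio(f),
                 weber_ratio_numeric(pars$mu[i], pars$s[i]),
                 tolerance = 1e-9)
  }
  # Closed form s*ln3/mu at a reference point (0.1098612...).
  expect_equal(weber_ratio(known_fit(1, 0.1)), 0.1 * log(3),
               tolerance = 1e-12)
  expect_equal(round(weber_ratio(known_fit(1, 0.1)), 7), 0.1098612)
  # Scale invariance: (mu, s) -> (c mu, c s) leaves the WR unchanged.
  for (c_scale in c(0.2, 3, 800)) {
    expect_equal(weber_ratio(known_fit(c_scale * 1, c_scale * 0.1)),
                 weber_ratio(known_fit(1, 0.1)), tolerance = 1e-12)
  }
})

test_that("fitted deviance is a local optimum of the Bernoulli likelihood", {
  levels <- magnitude_levels(1)
  dev_at <- function(mu, s, plus, n) {
    p <- stats::plogis((levels - mu) / s)
    -2 * sum(stats::dbinom(plus, n, p, log = TRUE) -
               stats::dbinom(plus, n, ifelse(n > 0, plus / n, 0), log = TRUE))
  }
  withr::with_seed(1, {
    for (rep in 1:20) {
      plus <- simulate_plus_counts(levels, 1.0, 0.08, rep(12, 6))
      f <- fit_logit(levels, plus, rep(12, 6))
      d0 <- dev_at(f$mu, f$s, plus, rep(12, 6))
      for (eps in c(-0.02, 0.02)) {
        expect_gte(dev_at(f$mu * (1 + eps), f$s, plus, rep(12, 6)), d0 - 1e-6)
        expect_gte(dev_at(f$mu, f$s * (1 + eps), plus, rep(12, 6)), d0 - 1e-6)
      }
    }
  })
})

test_that("participant exclusion drops exactly the engineered violators", {
  make_ctl <- function(id, prop_top, gof_p) {
    tibble::tibble(participant = id, target = DIMENSIONS,
                   condition = "control", pse = 1, wr = 0.1,
                   gof_p = gof_p, n = 72, converged = TRUE,
                   prop_plus_top = prop_top)
  }
  good <- lapply(sprintf("p%02d", 1:35), make_ctl, prop_top = 0.9,
                 gof_p = 0.5)
  bad_top <- lapply(sprintf("t%02d", 1:6), make_ctl, prop_top = 0.4,
                    gof_p = 0.5)
  bad_gof <- lapply(sprintf("g%02d", 1:4), make_ctl, prop_top = 0.9,
                    gof_p = 0.01)
  fits <- dplyr::bind_rows(c(good, bad_top, bad_gof))
  res <- exclude_participants(fits, gof_rule = "low")
  expect_setequal(res$dropped$participant,
                  c(sprintf("t%02d", 1:6), sprintf("g%02d", 1:4)))
  expect_equal(sort(res$kept), sprintf("p%02d", 1:35))
  expect_equal(res$dropped$reason[res$dropped$participant == "t01"],
               "max-level")
  # The published rule excludes high goodness-of-fit p-values instead.
  res_hi <- exclude_participants(fits, gof_rule = "high")
  expect_true(all(sprintf("g%02d", 1:4) %in% res_hi$kept))
  expect_true(all(sprintf("p%02d", 1:35) %in% res_hi$dropped$participant))
  # Idempotence: re-applying the rule to the kept set drops nobody.
  res2 <- exclude_participants(res$fits, gof_rule = "low")
  expect_equal(nrow(res2$dropped), 0)
  expect_error(exclude_participants(fits[fits$condition != "control", ]),
               "control")
})

test_that("2-SD outlier replacement uses the original group statistics", {
  # 10 sits 1.79 sd from the mean of (1,1,1,1,10): nothing is replaced.
  r <- outlier_replace(c(1, 1, 1, 1, 10))
  expect_equal(r$values, c(1, 1, 1, 1, 10))
  expect_equal(r$n_replaced, 0)
  # Constant lists are untouched (zero variance).
  expect_equal(outlier_replace(rep(3, 5))$n_replaced, 0)
  # Two clear outliers in a tight cluster are both replaced by the mean.
  v <- c(rep(10, 14), 30, -10)
  m <- mean(v)
  s <- stats::sd(v)
  expect_true(abs(30 - m) > 2 * s && abs(-10 - m) > 2 * s)
  r2 <- outlier_replace(v)
  expect_equal(r2$n_replaced, 2)
  expect_equal(r2$values[15], m)
  expect_equal(r2$values[16], m)
  # Idempotent on its own output.
  r3 <- outlier_replace(r2$values)
  expect_equal(r3$values, r2$values)
  expect_error(outlier_replace(c(1, 2)), "at least 3")
})

test_that("calibration converges to the observer's indifference point", {
  # Deterministic probe observers responding through a logit in the
  # perceived magnitude, with a fixed internal standard per dimension.
  probe_with_bias <- function(bias) {
    standards <- c(duration = 800, numerosity = 30, surface = 432)
    function(dim, levels, n_per_level) {
      b <- if (dim == "numerosity") bias else 1
      p <- stats::plogis((b * levels - standards[[dim]]) /
                           (0.08 * standards[[dim]]))
      round(n_per_level * p)
    }
  }
  ideal <- calibrate(probe_with_bias(1))
  expect_true(ideal$converged)
  expect_equal(ideal$iterations, 1)
  expect_equal(ideal$n_mean, 30, tolerance = 0.02)

  biased <- calibrate(probe_with_bias(1.10))
  expect_true(biased$converged)
  expect_equal(biased$n_mean, 30 / 1.10, tolerance = 0.03 * 30)
  expect_true(all(biased$pse / c(800, biased$n_mean, biased$s_mean) >= 0.95 &
                    biased$pse / c(800, biased$n_mean, biased$s_mean) <= 1.05))

  # An observer whose discrimination never sharpens violates the absolute
  # Weber-ratio cap and calibration reports failure after 50 iterations.
  shallow <- function(dim, levels, n_per_level) {
    standards <- c(duration = 800, numerosity = 30, surface = 432)
    p <- stats::plogis((levels - standards[[dim]]) / (0.6 * standards[[dim]]))
    round(n_per_level * p)
  }
  fail <- calibrate(shallow)
  expect_false(fail$converged)
  expect_equal(fail$iterations, 50)
})
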