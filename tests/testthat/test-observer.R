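test_that("perceived duration is the posterior mean under the duration prior", {
  # Near-noiseless likelihood: percept equals the true duration.
  sharp <- observer_params(sensory_cv = c(duration = 1e-9, numerosity = 0.15,
                                          surface = 0.2))
  expect_equal(perceive_duration(600, sharp, seed = 1), 600, tolerance = 1e-5)

  # At the prior mean the expectation is the prior mean (fixed point).
  p <- observer_params()
  draws <- withr::with_seed(2, replicate(4000, perceive_duration(800, p)))
  expect_equal(mean(draws), 800, tolerance = 5)

  # Closed-form posterior mean vs simulation away from the prior mean.
  p2 <- observer_params(prior_sd = c(duration = 120, numerosity = 9.6,
                                     surface = 142.8))
  draws <- withr::with_seed(3, replicate(20000, perceive_duration(600, p2)))
  w <- 120^2 / (120^2 + (0.15 * 600)^2)
  expected <- w * 600 + (1 - w) * 800
  expect_gt(mean(draws), 600)
  expect_lt(mean(draws), 800)
  expect_equal(mean(draws), expected, tolerance = 1.5)
  expect_error(perceive_duration(-1, p), "positive")
})

test_that("accumulated-magnitude percepts inherit duration and regime biases", {
  # Rate coupling off with vanishing noise returns the true magnitude.
  off <- observer_params(rate_coupling = FALSE,
                         sensory_cv = c(duration = 1e-9, numerosity = 1e-9,
                                        surface = 1e-9))
  expect_equal(perceive_accumulated(32, 800, NULL, "numerosity", off, seed = 1),
               32, tolerance = 1e-4)

  # Rate coupling on: short trials inflate, long trials deflate the
  # numerosity percept, because perceived duration regresses to 800 ms.
  p <- observer_params()
  mean_est <- function(d_ms, regime, n_sims = 800) {
    ests <- vapply(seq_len(n_sims), function(i) {
      ev <- realize_stimulus(d_ms, 32, 476, regime, seed = i,
                             place = FALSE)$events
      perceive_accumulated(32, d_ms, ev, "numerosity", p,
                           seed = combine_seeds(7, i))
    }, numeric(1))
    mean(ests)
  }
  expect_gt(mean_est(600, "linear"), 32)
  expect_lt(mean_est(1000, "linear"), 32)

  # Front-loaded evidence inflates the percept relative to back-loaded.
  expect_gt(mean_est(800, "fastslow", 400), mean_est(800, "slowfast", 400))

  expect_error(perceive_accumulated(32, 800, NULL, "numerosity", p),
               "non-empty event table")
  expect_error(perceive_accumulated(32, 800, NULL, "duration", p), "dim")
})

test_that("primacy weighting with a half-life of half the trial favours early dots", {
  p05 <- observer_params(primacy_halflife_frac = 0.5,
                         lapse_rate = 0)
  est_for <- function(regime) {
    ests <- vapply(1:300, function(i) {
      ev <- realize_stimulus(800, 32, 476, regime, seed = i,
                             place = FALSE)$events
      perceive_accumulated(32, 800, ev, "numerosity", p05,
                           seed = combine_seeds(13, i))
    }, numeric(1))
    mean(ests)
  }
  expect_gt(est_for("fastslow"), est_for("slowfast"))
})

test_that("slider responses map levels linearly and honour polarity", {
  levels <- magnitude_levels(32)
  top <- respond(40, levels, "plus_top")
  expect_equal(top$estimate_percent, 100)
  expect_equal(top$categorical, "plus")
  mid <- respond(32, levels, "plus_top")
  expect_equal(mid$estimate_percent, 50)
  expect_equal(mid$categorical, "minus") # midpoint tie rule
  bottom_pol <- respond(40, levels, "plus_bottom")
  expect_equal(bottom_pol$estimate_percent, 0) # '+' end is at the bottom
  expect_equal(bottom_pol$plus_percent, 100)
  expect_equal(bottom_pol$categorical, "plus")
  expect_equal(respond(1e6, levels, "plus_top")$plus_percent, 100) # clipped
  expect_error(respond(30, c(32), "plus_top"), "at least 2")

  # With small sensory noise, mean responses increase with true magnitude.
  sharp <- observer_params(rate_coupling = FALSE,
                           sensory_cv = c(duration = 0.01, numerosity = 0.01,
                                          surface = 0.01))
  mean_resp <- vapply(levels, function(m) {
    ests <- withr::with_seed(5, replicate(200, {
      perceive_accumulated(m, 800, NULL, "numerosity", sharp)
    }))
    mean(vapply(ests, function(e) respond(e, levels, "plus_top")$plus_percent,
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_resp) > 0))
})

test_that("sessions are deterministic and reproduce central tendency", {
  d1 <- enumerate_design(1)
  sub <- d1[d1$condition == "control" & d1$target == "duration", ]
  sched <- make_schedule(sub, seed = 5)
  p <- observer_params(seed = 9)
  r1 <- simulate_session(sched, p)
  r2 <- simulate_session(sched, p)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), nrow(sub))
  expect_true(all(r1$estimate_percent >= 0 & r1$estimate_percent <= 100))
  expect_true(all(r1$categorical ==
                    binarize(r1$estimate_percent, r1$polarity)))
  tf <- fit_tendencies(r1)
  expect_lt(tf$slope, 1)
  expect_gt(tf$slope, 0)
})

test_that("with shrinkage only, the tendency slope matches the closed-form weight", {
  # Gaussian-shrinkage observer in the scalar-noise limit: expected OLS
  # slope of estimates on magnitude equals sigma_p^2/(sigma_p^2 + cv^2 m^2)
  # evaluated near the session mean.
  cv <- 0.15
  sigma_p <- 9.6
  p <- observer_params(rate_coupling = FALSE, lapse_rate = 0,
                       sensory_cv = c(duration = cv, numerosity = cv,
                                      surface = cv))
  levels <- magnitude_levels(32)
  m <- rep(levels, each = 400)
  est <- withr::with_seed(11, vapply(m, function(mi) {
    perceive_accumulated(mi, 800, NULL, "numerosity", p)
  }, numeric(1)))
  mag_pct <- normalize_magnitude(levels, m)
  est_pct <- 100 * (est - levels[1]) / (levels[6] - levels[1])
  slope <- fit_tendency(mag_pct, est_pct)$slope
  w <- sigma_p^2 / (sigma_p^2 + cv^2 * 32^2)
  expect_equal(slope, w, tolerance = 0.05)
})

test_that("cohort sampling couples duration and numerosity precision only", {
  cohort <- sample_cohort_params(40, seed = 3, trait_sd = 0.4)
  cvs <- t(vapply(cohort, function(p) p$sensory_cv, numeric(3)))
  expect_equal(stats::cor(cvs[, "duration"], cvs[, "numerosity"]), 1,
               tolerance = 1e-9)
  expect_lt(abs(stats::cor(cvs[, "duration"], cvs[, "surface"])), 0.5)
  expect_identical(vapply(sample_cohort_params(3, seed = 5), function(p)
    p$sensory_cv[["surface"]], numeric(1)),
    vapply(sample_cohort_params(3, seed = 5), function(p)
      p$sensory_cv[["surface"]], numeric(1)))
})

test_that("observer parameter invariants are enforced", {
  expect_error(observer_params(prior_sd = c(duration = 0, numerosity = 9.6,
                                            surface = 142.8)), "positive")
  expect_error(observer_params(primacy_halflife_frac = 0), "primacy")
  expect_error(observer_params(primacy_halflife_frac = 1.5), "primacy")
  expect_error(observer_params(lapse_rate = 0.5), "lapse")
})
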