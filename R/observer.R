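# Bayesian synthetic observer. Each magnitude dimension carries its own
# Gaussian prior; a noisy sensory measurement is combined with the prior
# by precision weighting, producing central tendency (regression of
# estimates towards the prior mean). Numerosity and surface can be read
# out as accumulated-rate x perceived-duration, with early evidence
# weighted more strongly (primacy), which couples them to duration and to
# the accumulation regime while leaving duration itself immune.

#' Parameters of the Bayesian synthetic observer
#'
#' @param prior_mean Named vector of prior means per dimension
#'   (`duration` in ms, `numerosity` in dots, `surface` in mm^2). Defaults
#'   centre the priors on the session means, which is what produces the
#'   central-tendency regression towards the mean of the stimulus set.
#' @param prior_sd Named vector of prior standard deviations (same units).
#' @param sensory_cv Named vector of sensory coefficients of variation:
#'   the sd of the noisy measurement scales with the true magnitude
#'   (scalar, Weber-like noise).
#' @param rate_coupling If `TRUE`, numerosity and surface are estimated as
#'   primacy-weighted accumulation rate times perceived duration; if
#'   `FALSE`, each dimension is a pure prior-likelihood combination of its
#'   true magnitude.
#' @param primacy_halflife_frac Half-life of the exponential down-weighting
#'   of later evidence when estimating the accumulation rate, as a fraction
#'   of trial duration, in `(0, 1]`.
#' @param lapse_rate Probability that a response is replaced by a uniform
#'   random slider position, in `[0, 0.1]`.
#' @param log_space If `TRUE`, prior-likelihood combination operates on log
#'   magnitude (off by default; the slider analysis is linear in
#'   magnitude).
#' @param seed Integer seed consumed by [simulate_session()].
#' @return A list of class `"observer_params"`.
#' @export
observer_params <- function(prior_mean = c(duration = 800, numerosity = 32,
                                           surface = 476),
                            prior_sd = c(duration = 240, numerosity = 9.6,
                                         surface = 142.8),
                            sensory_cv = c(duration = 0.15, numerosity = 0.15,
                                           surface = 0.20),
                            rate_coupling = TRUE,
                            primacy_halflife_frac = 1,
                            lapse_rate = 0.02,
                            log_space = FALSE,
                            seed = 1L) {
  for (nm in DIMENSIONS) {
    if (is.na(prior_sd[nm]) || prior_sd[nm] <= 0) {
      stop_dotmag("prior_sd[%s] must be strictly positive", nm)
    }
    if (is.na(sensory_cv[nm]) || sensory_cv[nm] <= 0) {
      stop_dotmag("sensory_cv[%s] must be strictly positive", nm)
    }
  }
  if (primacy_halflife_frac <= 0 || primacy_halflife_frac > 1) {
    stop_dotmag("primacy_halflife_frac must lie in (0, 1]")
  }
  if (lapse_rate < 0 || lapse_rate > 0.1) {
    stop_dotmag("lapse_rate must lie in [0, 0.1]")
  }
  structure(list(prior_mean = prior_mean, prior_sd = prior_sd,
                 sensory_cv = sensory_cv, rate_coupling = rate_coupling,
                 primacy_halflife_frac = primacy_halflife_frac,
                 lapse_rate = lapse_rate, log_space = log_space,
                 seed = as.integer(seed)),
            class = "observer_params")
}

# Precision-weighted combination of a noisy measurement x (sd sigma_s)
# with a Gaussian prior (mu_p, sigma_p): posterior mean.
posterior_mean <- function(x, sigma_s, mu_p, sigma_p) {
  w <- sigma_p^2 / (sigma_p^2 + sigma_s^2)
  w * x + (1 - w) * mu_p
}

# Prior-likelihood combination of a true magnitude on the observer's
# internal scale (linear or log).
combine_with_prior <- function(m_true, dim, params, noisy = TRUE) {
  mu_p <- params$prior_mean[[dim]]
  sigma_p <- params$prior_sd[[dim]]
  cv <- params$sensory_cv[[dim]]
  if (params$log_space) {
    sigma_s <- cv # cv of a lognormal is ~ its log-sd for small cv
    x <- log(m_true) + if (noisy) stats::rnorm(1, 0, sigma_s) else 0
    exp(posterior_mean(x, sigma_s, log(mu_p), sigma_p / mu_p))
  } else {
    sigma_s <- cv * m_true
    x <- m_true + if (noisy) stats::rnorm(1, 0, sigma_s) else 0
    posterior_mean(x, sigma_s, mu_p, sigma_p)
  }
}

#' Perceive a trial duration
#'
#' Draws a noisy measurement `x ~ Normal(D, (cv * D)^2)` and returns the
#' posterior mean under the observer's Gaussian duration prior. In
#' expectation the percept lies strictly between the true duration and the
#' prior mean, which is the central-tendency signature.
#'
#' @param d_true True trial duration in ms (positive).
#' @param params An [observer_params()].
#' @param seed Optional integer seed.
#' @return Perceived duration in ms.
#' @export
perceive_duration <- function(d_true, params = observer_params(),
                              seed = NULL) {
  if (d_true <= 0) stop_dotmag("duration must be positive")
  with_seed(seed, combine_with_prior(d_true, "duration", params))
}

# Primacy-weighted accumulation rate of an event table: the weighted time
# average of the instantaneous delivery rate, with weights
# exp(-t * ln 2 / (halflife_frac * D)). For evenly delivered evidence this
# reduces to total / D; front-loaded delivery raises it, back-loaded
# delivery lowers it.
primacy_rate <- function(onsets_ms, magnitudes, d_ms, halflife_frac) {
  lambda <- log(2) / (halflife_frac * d_ms)
  weight_integral <- (1 - exp(-lambda * d_ms)) / lambda
  sum(exp(-lambda * onsets_ms) * magnitudes) / weight_integral
}

#' Perceive an accumulated magnitude (numerosity or surface)
#'
#' With rate coupling on, the observer estimates the primacy-weighted
#' accumulation rate from the event table, multiplies it by the perceived
#' (prior-shrunk) duration, perturbs the product with scalar sensory noise
#' and shrinks it towards the dimension's prior mean. Because perceived
#' duration regresses towards its prior mean, short trials inflate and
#' long trials deflate numerosity and surface estimates; because early
#' evidence is over-weighted, fast-slow delivery inflates and slow-fast
#' delivery deflates them. With rate coupling off, the estimate is a pure
#' prior-likelihood combination of the true magnitude and none of these
#' couplings exist.
#'
#' @param m_true True magnitude of the target dimension.
#' @param d_true True trial duration in ms.
#' @param events Per-dot event table (from [realize_stimulus()]) with
#'   `onset_ms` and, for surface, `area_mm2`. Ignored when
#'   `rate_coupling` is off.
#' @param dim `"numerosity"` or `"surface"`.
#' @param params An [observer_params()].
#' @param seed Optional integer seed.
#' @return Perceived magnitude (same units as `m_true`).
#' @export
perceive_accumulated <- function(m_true, d_true, events, dim, params = observer_params(),
                                 seed = NULL) {
  if (!dim %in% c("numerosity", "surface")) {
    stop_dotmag("dim must be numerosity or surface, got %s", dim)
  }
  if (params$rate_coupling && (is.null(events) || nrow(events) == 0)) {
    stop_dotmag("rate-coupled perception requires a non-empty event table")
  }
  with_seed(seed, {
    if (!params$rate_coupling) {
      combine_with_prior(m_true, dim, params)
    } else {
      magnitudes <- if (dim == "numerosity") rep(1, nrow(events)) else
        events$area_mm2
      r_hat <- primacy_rate(events$onset_ms, magnitudes, d_true,
                            params$primacy_halflife_frac)
      d_hat <- combine_with_prior(d_true, "duration", params)
      m_hat <- r_hat * d_hat *
        (1 + stats::rnorm(1, 0, params$sensory_cv[[dim]]))
      sigma_s <- params$sensory_cv[[dim]] * m_true
      posterior_mean(m_hat, sigma_s, params$prior_mean[[dim]],
                     params$prior_sd[[dim]])
    }
  })
}

#' Map a perceived magnitude onto the response slider
#'
#' The slider spans the minimal to maximal tested level of the target
#' dimension; the percept is mapped linearly (smallest level -> 0, largest
#' -> 100) and clipped. The physical position depends on which end carries
#' the '+' label; with probability `lapse` the physical position is
#' replaced by a uniform draw. The categorical response is derived from
#' the physical position by the midpoint binning rule (see [binarize()]).
#'
#' @param estimate Perceived magnitude.
#' @param dim_levels The 6 tested levels of the dimension, ascending.
#' @param polarity `"plus_top"` or `"plus_bottom"`.
#' @param lapse Lapse probability.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `estimate_percent` (physical slider position,
#'   0 = bottom), `plus_percent` (position re-expressed towards '+'),
#'   `categorical`, `polarity`, `lapsed`.
#' @export
respond <- function(estimate, dim_levels, polarity = c("plus_top", "plus_bottom"),
                    lapse = 0, seed = NULL) {
  polarity <- match.arg(polarity)
  if (length(dim_levels) < 2) stop_dotmag("need at least 2 levels")
  if (is.unsorted(dim_levels)) stop_dotmag("dim_levels must be ascending")
  with_seed(seed, {
    lo <- dim_levels[1]
    hi <- dim_levels[length(dim_levels)]
    plus_pct <- 100 * (estimate - lo) / (hi - lo)
    plus_pct <- min(max(plus_pct, 0), 100)
    phys <- if (polarity == "plus_top") plus_pct else 100 - plus_pct
    lapsed <- lapse > 0 && stats::runif(1) < lapse
    if (lapsed) {
      phys <- stats::runif(1, 0, 100)
      plus_pct <- if (polarity == "plus_top") phys else 100 - phys
    }
    tibble::tibble(
      estimate_percent = phys,
      plus_percent = plus_pct,
      categorical = binarize(phys, polarity),
      polarity = polarity,
      lapsed = lapsed
    )
  })
}

# Resolve a non-target setting label to a concrete magnitude.
setting_value <- function(setting, mean_value) {
  switch(setting,
         min = 0.75 * mean_value,
         mean = mean_value,
         max = 1.25 * mean_value,
         stop_dotmag("unknown non-target setting %s", setting))
}

#' Simulate a full session of one synthetic observer
#'
#' Walks a trial schedule, realizes the per-trial stimulus structure it
#' needs (onset times, and per-dot areas for surface targets; spatial
#' placement is irrelevant to the observer and skipped), perceives the
#' target magnitude and records the slider response. Fully deterministic
#' given the schedule seed and the observer seed.
#'
#' @param schedule A schedule from [make_schedule()].
#' @param params An [observer_params()].
#' @param means Named vector of session mean magnitudes.
#' @param geometry A [geometry_config()].
#' @param participant Participant label stored in the output.
#' @return Tibble with one row per trial: schedule columns plus
#'   `participant`, `true_magnitude`, `d_trial_ms`, `estimate`,
#'   `estimate_percent`, `plus_percent`, `categorical`, `polarity`.
#' @export
simulate_session <- function(schedule, params = observer_params(),
                             means = c(duration = 800, numerosity = 32,
                                       surface = 476),
                             geometry = geometry_config(),
                             participant = "obs1") {
  sched_seed <- attr(schedule, "seed") %||% 0L
  n_trials <- nrow(schedule)
  target_v <- schedule$target
  level_v <- schedule$level_factor
  regime_v <- schedule$regime
  nd1 <- schedule$nontarget_dim_1
  ns1 <- schedule$nontarget_setting_1
  nd2 <- schedule$nontarget_dim_2
  ns2 <- schedule$nontarget_setting_2
  est_v <- m_true_v <- d_trial_v <- phys_v <- plus_v <- numeric(n_trials)
  pol_v <- character(n_trials)
  bounds <- dot_area_bounds(geometry)
  with_seed(combine_seeds(sched_seed, params$seed), {
    for (i in seq_len(n_trials)) {
      target <- target_v[i]
      m_true <- level_v[i] * means[[target]]
      settings <- stats::setNames(c(ns1[i], ns2[i]), c(nd1[i], nd2[i]))
      d_trial <- if (target == "duration") m_true else
        setting_value(settings[["duration"]], means[["duration"]])
      if (target == "duration") {
        est <- combine_with_prior(d_trial, "duration", params)
      } else if (!params$rate_coupling) {
        est <- combine_with_prior(m_true, target, params)
      } else {
        n_dots <- as.integer(round(
          if (target == "numerosity") m_true else
            setting_value(settings[["numerosity"]], means[["numerosity"]])))
        iters <- onset_schedule(d_trial, n_dots, regime_v[i], seed = NULL,
                                geometry = geometry)
        onsets <- rep(iters$onset_ms, iters$n_dots)
        if (target == "surface") {
          s_use <- min(max(m_true, n_dots * bounds[1]), n_dots * bounds[2])
          diam <- partition_surface(s_use, n_dots, geometry, seed = NULL)
          mags <- dot_area_mm2(diam, geometry$viewing_distance_cm)
        } else {
          mags <- rep(1, n_dots)
        }
        r_hat <- primacy_rate(onsets, mags, d_trial,
                              params$primacy_halflife_frac)
        d_hat <- combine_with_prior(d_trial, "duration", params)
        m_hat <- r_hat * d_hat *
          (1 + stats::rnorm(1, 0, params$sensory_cv[[target]]))
        sigma_s <- params$sensory_cv[[target]] * m_true
        est <- posterior_mean(m_hat, sigma_s, params$prior_mean[[target]],
                              params$prior_sd[[target]])
      }
      # Slider mapping, polarity and lapse (same rules as respond()).
      lv <- magnitude_levels(means[[target]])
      plus_pct <- min(max(100 * (est - lv[1]) / (lv[6] - lv[1]), 0), 100)
      polarity <- if (stats::runif(1) < 0.5) "plus_top" else "plus_bottom"
      phys <- if (polarity == "plus_top") plus_pct else 100 - plus_pct
      if (params$lapse_rate > 0 && stats::runif(1) < params$lapse_rate) {
        phys <- stats::runif(1, 0, 100)
        plus_pct <- if (polarity == "plus_top") phys else 100 - phys
      }
      est_v[i] <- est
      m_true_v[i] <- m_true
      d_trial_v[i] <- d_trial
      phys_v[i] <- phys
      plus_v[i] <- plus_pct
      pol_v[i] <- polarity
    }
  })
  dplyr::bind_cols(
    schedule,
    tibble::tibble(participant = participant, true_magnitude = m_true_v,
                   d_trial_ms = d_trial_v, estimate = est_v,
                   estimate_percent = phys_v, plus_percent = plus_v,
                   categorical = binarize(phys_v, pol_v),
                   polarity = pol_v)
  )
}

#' Sample a cohort of observer parameter sets
#'
#' Observers differ in sensory precision. Duration and numerosity
#' precision share a common latent trait while surface precision varies
#' independently, so that across a cohort the degrees of central tendency
#' for duration and numerosity correlate with each other but not with
#' surface.
#'
#' @param n Number of observers.
#' @param seed Integer seed.
#' @param base An [observer_params()] supplying the cohort-mean parameters.
#' @param trait_sd Log-scale sd of the between-observer precision traits.
#' @return List of `n` [observer_params()] objects.
#' @export
sample_cohort_params <- function(n, seed = 1L, base = observer_params(),
                                 trait_sd = 0.25) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      eta_dn <- stats::rnorm(1, 0, trait_sd)
      eta_s <- stats::rnorm(1, 0, trait_sd)
      cv <- base$sensory_cv
      cv[["duration"]] <- cv[["duration"]] * exp(eta_dn)
      cv[["numerosity"]] <- cv[["numerosity"]] * exp(eta_dn)
      cv[["surface"]] <- cv[["surface"]] * exp(eta_s)
      observer_params(prior_mean = base$prior_mean, prior_sd = base$prior_sd,
                      sensory_cv = cv, rate_coupling = base$rate_coupling,
                      primacy_halflife_frac = base$primacy_halflife_frac,
                      lapse_rate = base$lapse_rate, log_space = base$log_space,
                      seed = combine_seeds(seed, i))
    })
  })
}
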