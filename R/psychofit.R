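# Categorical analysis chain: midpoint binning of slider responses,
# Bernoulli maximum-likelihood logit fits, PSE and Weber ratio, the
# participant exclusion and outlier-replacement rules, and the iterative
# calibration matching task difficulty across dimensions.

#' Bin a slider response into a categorical choice
#'
#' A click between the centre of the axis and the extreme carrying the '+'
#' label counts as a '+' response, otherwise '-'. A click exactly at the
#' midpoint (the cursor's start position) counts as '-'.
#'
#' @param estimate_percent Physical slider position(s) in `[0, 100]`
#'   (0 = bottom of the axis).
#' @param polarity `"plus_top"` or `"plus_bottom"`: which end carries '+'.
#' @return Character vector of `"plus"` / `"minus"`.
#' @export
binarize <- function(estimate_percent, polarity) {
  if (any(estimate_percent < 0 | estimate_percent > 100)) {
    stop_dotmag("slider positions must lie in [0, 100]")
  }
  polarity <- rep(polarity, length.out = length(estimate_percent))
  if (!all(polarity %in% c("plus_top", "plus_bottom"))) {
    stop_dotmag("polarity must be plus_top or plus_bottom")
  }
  ifelse(polarity == "plus_top",
         ifelse(estimate_percent > 50, "plus", "minus"),
         ifelse(estimate_percent < 50, "plus", "minus"))
}

#' Fit a logit psychometric function by Bernoulli maximum likelihood
#'
#' Fits `p(plus | x) = 1 / (1 + exp(-(x - mu) / s))` to per-level counts
#' of '+' responses via [stats::glm()] with a binomial logit link.
#' Goodness of fit is the residual-deviance test against the saturated
#' model on the level bins. Fits with a non-positive slope, failed
#' convergence or complete separation are flagged unusable.
#'
#' @param levels Tested magnitudes (>= 2 distinct values).
#' @param plus_counts Number of '+' responses per level.
#' @param n_per_level Number of trials per level.
#' @return An object of class `"psychometric_fit"` with elements `mu`
#'   (location), `s` (scale), `pse`, `wr`, `gof_p`, `n_trials`,
#'   `converged`, and the per-level data.
#' @export
fit_logit <- function(levels, plus_counts, n_per_level) {
  if (length(unique(levels)) < 2) stop_dotmag("need at least 2 distinct levels")
  if (length(plus_counts) != length(levels) ||
      length(n_per_level) != length(levels)) {
    stop_dotmag("levels, plus_counts and n_per_level must have equal length")
  }
  if (sum(n_per_level) < 12) stop_dotmag("need at least 12 trials in total")
  fit <- suppressWarnings(
    stats::glm(cbind(plus_counts, n_per_level - plus_counts) ~ levels,
               family = stats::binomial("logit"))
  )
  b <- stats::coef(fit)
  # Separation shows up as extreme coefficients with fitted probabilities
  # pinned to 0/1; a flat response profile as a ~zero slope.
  p_hat <- stats::fitted(fit)
  separated <- all(p_hat < 1e-6 | p_hat > 1 - 1e-6)
  usable <- isTRUE(fit$converged) && is.finite(b[2]) && b[2] > 1e-8 &&
    !separated
  mu <- unname(-b[1] / b[2])
  s <- unname(1 / b[2])
  gof_p <- stats::pchisq(stats::deviance(fit), stats::df.residual(fit),
                         lower.tail = FALSE)
  structure(list(
    mu = if (usable) mu else NA_real_,
    s = if (usable) s else NA_real_,
    pse = if (usable) mu else NA_real_,
    wr = if (usable && mu > 0) s * log(3) / mu else NA_real_,
    gof_p = gof_p,
    n_trials = sum(n_per_level),
    converged = usable,
    deviance = stats::deviance(fit),
    levels = levels,
    plus_counts = plus_counts,
    n_per_level = n_per_level
  ), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<psychometric_fit> PSE = %.4g, WR = %.4g (s = %.4g, gof p = %.3f, n = %d)\n",
      x$pse, x$wr, x$s, x$gof_p, x$n_trials))
  } else {
    cat("<psychometric_fit> unusable (non-convergence, separation or flat data)\n")
  }
  invisible(x)
}

#' Point of subjective equality of a fitted psychometric function
#'
#' The magnitude at which the fitted curve crosses 50% '+' responses;
#' equals the logit location parameter exactly.
#'
#' @param fit A converged [fit_logit()] object.
#' @return PSE in magnitude units.
#' @export
pse <- function(fit) {
  if (!inherits(fit, "psychometric_fit")) stop_dotmag("not a psychometric fit")
  if (!fit$converged) stop_dotmag("cannot extract the PSE of an unusable fit")
  fit$mu
}

#' Weber ratio of a fitted psychometric function
#'
#' Half the distance between the 25% and 75% points of the fitted curve,
#' normalized by the PSE; for the logit parameterization this equals
#' `s * ln(3) / mu`.
#'
#' @param fit A converged [fit_logit()] object with positive PSE.
#' @return Dimensionless Weber ratio.
#' @export
weber_ratio <- function(fit) {
  if (!inherits(fit, "psychometric_fit")) stop_dotmag("not a psychometric fit")
  if (!fit$converged) stop_dotmag("cannot extract the WR of an unusable fit")
  if (fit$mu <= 0) stop_dotmag("Weber ratio undefined for non-positive PSE")
  fit$s * log(3) / fit$mu
}

#' Fit psychometric functions across a response table
#'
#' Groups a response table by participant, target dimension, condition
#' (and regime where present), bins the trials by level and fits the
#' logit. The fitted location is expressed in level-factor units times the
#' session mean, i.e. in the magnitude units of each dimension.
#'
#' @param responses Response tibble from [simulate_session()] (or a user
#'   table with the same columns: `participant`, `target`, `condition`,
#'   `regime`, `level_factor`, `true_magnitude`, `categorical`).
#' @param by Extra grouping columns (default includes `regime` when it
#'   varies).
#' @return Tibble with one row per fit: grouping columns plus `pse`, `wr`,
#'   `gof_p`, `n`, `converged`, `prop_plus_top` (observed '+' proportion
#'   at the largest level) and a `fit` list-column.
#' @export
fit_psychometrics <- function(responses, by = NULL) {
  if (is.null(by)) {
    by <- c("participant", "target", "condition")
    if ("regime" %in% names(responses) &&
        length(unique(responses$regime)) > 1) {
      by <- c(by, "regime")
    }
  }
  responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      counts <- d |>
        dplyr::group_by(.data$true_magnitude) |>
        dplyr::summarise(plus = sum(.data$categorical == "plus"),
                         n = dplyr::n(), .groups = "drop") |>
        dplyr::arrange(.data$true_magnitude)
      f <- fit_logit(counts$true_magnitude, counts$plus, counts$n)
      tibble::tibble(
        pse = f$pse, wr = f$wr, gof_p = f$gof_p, n = f$n_trials,
        converged = f$converged,
        prop_plus_top = counts$plus[nrow(counts)] / counts$n[nrow(counts)],
        fit = list(f))
    }) |>
    dplyr::ungroup()
}

#' Apply the participant exclusion rules
#'
#' A participant is dropped when, in any dimension's control condition,
#' (a) the observed '+' proportion at the largest tested level never
#' reaches 50%, or (b) the goodness-of-fit p-value falls on the excluded
#' side of 0.05. The published rule excludes participants with control
#' goodness-of-fit p-values *above* 0.05 and is applied verbatim by
#' default (`gof_rule = "high"`); `gof_rule = "low"` flips it to the
#' deviance-test convention (exclude poor fits, p < 0.05), and
#' `gof_rule = "none"` disables criterion (b).
#'
#' @param fits Fit table from [fit_psychometrics()]; control-condition
#'   rows must be present for every participant.
#' @param gof_rule `"high"`, `"low"` or `"none"`.
#' @return List with `kept` (character vector of participants), `dropped`
#'   (tibble of participant, reason) and `fits` (the fit table restricted
#'   to kept participants).
#' @export
exclude_participants <- function(fits, gof_rule = c("high", "low", "none")) {
  gof_rule <- match.arg(gof_rule)
  ctl <- dplyr::filter(fits, .data$condition == "control")
  if (nrow(ctl) == 0) stop_dotmag("no control-condition fits present")
  missing <- setdiff(unique(fits$participant), unique(ctl$participant))
  if (length(missing) > 0) {
    stop_dotmag("participants without control fits: %s",
                paste(missing, collapse = ", "))
  }
  verdicts <- ctl |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      max_level_fail = any(.data$prop_plus_top < 0.5),
      unusable = any(!.data$converged),
      gof_fail = switch(gof_rule,
                        high = any(.data$gof_p > 0.05),
                        low = any(.data$gof_p < 0.05),
                        none = FALSE),
      .groups = "drop")
  dropped <- verdicts |>
    dplyr::filter(.data$max_level_fail | .data$unusable | .data$gof_fail) |>
    dplyr::mutate(reason = dplyr::case_when(
      .data$max_level_fail ~ "max-level",
      .data$unusable ~ "unusable-fit",
      TRUE ~ "goodness-of-fit")) |>
    dplyr::select("participant", "reason")
  kept <- setdiff(verdicts$participant, dropped$participant)
  list(kept = kept, dropped = dropped,
       fits = dplyr::filter(fits, .data$participant %in% kept))
}

#' Replace per-condition outliers by the group mean
#'
#' Values more than 2 standard deviations from the group mean (both
#' computed on the original values) are replaced by the original group
#' mean, in a single pass.
#'
#' @param values Numeric vector of one metric across participants within
#'   one condition (length >= 3).
#' @return List with `values` (after replacement) and `n_replaced`.
#' @export
outlier_replace <- function(values) {
  if (length(values) < 3) stop_dotmag("need at least 3 values")
  m <- mean(values)
  s <- stats::sd(values)
  out <- s > 0 & abs(values - m) > 2 * s
  values[out] <- m
  list(values = values, n_replaced = sum(out))
}

#' Calibration criteria for matching task difficulty across dimensions
#'
#' @param pse_band PSEs must fall within this band times the mean
#'   magnitude.
#' @param wr_ratio_max Largest admissible ratio of the largest to the
#'   smallest Weber ratio across dimensions.
#' @param wr_abs_max Largest admissible Weber ratio.
#' @param wr_spread_rule Optional function of the three WRs returning
#'   `TRUE` when their spread is acceptable; disabled (`NULL`) by default
#'   because the published spread criterion is not interpretable as
#'   printed.
#' @return List of class `"calibration_criteria"`.
#' @export
calibration_criteria <- function(pse_band = c(0.95, 1.05), wr_ratio_max = 3,
                                 wr_abs_max = 0.25, wr_spread_rule = NULL) {
  structure(list(pse_band = pse_band, wr_ratio_max = wr_ratio_max,
                 wr_abs_max = wr_abs_max, wr_spread_rule = wr_spread_rule),
            class = "calibration_criteria")
}

#' Calibrate session means to equalize task difficulty
#'
#' Iteratively probes an observer with 30-trial blocks per dimension
#' (5 trials at each of the 6 levels), fits the psychometric function,
#' and rescales the numerosity and surface means multiplicatively by
#' `PSE / mean` until every PSE lies within the criterion band of its
#' mean and the Weber-ratio rules hold. The duration mean is fixed.
#'
#' @param probe_fn Observer hook: `function(dimension, levels,
#'   n_per_level)` returning the number of '+' responses at each level.
#' @param criteria A [calibration_criteria()].
#' @param d_mean Fixed duration mean (ms).
#' @param n_mean,s_mean Starting numerosity and surface means.
#' @param max_iter Iteration cap before declaring failure.
#' @param trials_per_level Probe trials per level (5 in the paradigm).
#' @return List with `n_mean`, `s_mean`, `iterations`, `converged`, and
#'   the last per-dimension `pse` and `wr` values.
#' @export
calibrate <- function(probe_fn, criteria = calibration_criteria(),
                      d_mean = 800, n_mean = 30, s_mean = 432,
                      max_iter = 50, trials_per_level = 5) {
  means <- c(duration = d_mean, numerosity = n_mean, surface = s_mean)
  last <- NULL
  for (iter in seq_len(max_iter)) {
    pses <- wrs <- stats::setNames(numeric(3), DIMENSIONS)
    for (dim in DIMENSIONS) {
      levels <- magnitude_levels(means[[dim]])
      plus <- probe_fn(dim, levels, rep(trials_per_level, length(levels)))
      f <- fit_logit(levels, plus, rep(trials_per_level, length(levels)))
      if (!f$converged) {
        pses[dim] <- NA
        wrs[dim] <- NA
      } else {
        pses[dim] <- f$pse
        wrs[dim] <- f$wr
      }
    }
    last <- list(pse = pses, wr = wrs, means = means)
    rel <- pses / means
    pse_ok <- all(is.finite(rel)) &&
      all(rel >= criteria$pse_band[1] & rel <= criteria$pse_band[2])
    wr_ok <- all(is.finite(wrs)) &&
      max(wrs) / min(wrs) < criteria$wr_ratio_max &&
      all(wrs < criteria$wr_abs_max) &&
      (is.null(criteria$wr_spread_rule) || criteria$wr_spread_rule(wrs))
    if (pse_ok && wr_ok) {
      return(list(n_mean = unname(means[["numerosity"]]),
                  s_mean = unname(means[["surface"]]),
                  iterations = iter, converged = TRUE,
                  pse = pses, wr = wrs))
    }
    # Multiplicative update towards the observer's indifference points.
    if (is.finite(pses[["numerosity"]])) {
      means[["numerosity"]] <- means[["numerosity"]] *
        (pses[["numerosity"]] / means[["numerosity"]])
    }
    if (is.finite(pses[["surface"]])) {
      means[["surface"]] <- means[["surface"]] *
        (pses[["surface"]] / means[["surface"]])
    }
  }
  list(n_mean = unname(means[["numerosity"]]),
       s_mean = unname(means[["surface"]]),
       iterations = max_iter, converged = FALSE,
       pse = last$pse, wr = last$wr)
}
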