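# Continuous-estimate analysis: normalization of magnitudes and estimates
# to common percent scales and per-condition linear regression whose slope
# indexes central tendency (1 = veridical, 0 = complete regression to the
# mean) and whose intercept indexes global over/under-estimation.

#' Normalize a magnitude onto the 0-100 level scale
#'
#' Linear map sending the smallest tested level to 0 and the largest to
#' 100.
#'
#' @param levels The 6 tested levels of the dimension, ascending.
#' @param value Magnitude value(s) to normalize.
#' @return Percent value(s).
#' @export
normalize_magnitude <- function(levels, value) {
  if (length(levels) < 2 || is.unsorted(levels)) {
    stop_dotmag("levels must be at least 2 ascending values")
  }
  lo <- levels[1]
  hi <- levels[length(levels)]
  100 * (value - lo) / (hi - lo)
}

#' Regress continuous estimates on normalized magnitude
#'
#' Ordinary least squares of estimate percent on magnitude percent. The
#' slope measures central tendency; for an observer that shrinks noisy
#' measurements towards a prior mean the expected slope equals the
#' prior-likelihood weight and lies in (0, 1).
#'
#' @param magnitude_percent Normalized magnitudes (0-100).
#' @param estimate_percent Estimates on the '+'-referenced percent scale.
#' @return Object of class `"tendency_fit"`: `slope`, `intercept`, `r2`,
#'   `n`.
#' @export
fit_tendency <- function(magnitude_percent, estimate_percent) {
  if (length(magnitude_percent) != length(estimate_percent)) {
    stop_dotmag("input lengths differ")
  }
  if (length(magnitude_percent) < 6) stop_dotmag("need at least 6 trials")
  if (stats::sd(magnitude_percent) == 0) {
    stop_dotmag("magnitude percent has zero variance; slope undefined")
  }
  fit <- stats::lm(estimate_percent ~ magnitude_percent)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((estimate_percent - mean(estimate_percent))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = length(magnitude_percent)
  ), class = "tendency_fit")
}

#' @export
print.tendency_fit <- function(x, ...) {
  cat(sprintf("<tendency_fit> slope = %.3f, intercept = %.2f (r2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Fit central-tendency regressions across a response table
#'
#' Computes, per participant, target dimension and condition (and regime
#' where it varies), the OLS slope and intercept of '+'-referenced
#' estimate percent on normalized magnitude percent. By default trials
#' are pooled; `per_level_means = TRUE` first averages estimates within
#' each level.
#'
#' @param responses Response tibble (see [simulate_session()]); must
#'   carry `plus_percent` or `estimate_percent` + `polarity`.
#' @param by Grouping columns; defaults as in [fit_psychometrics()].
#' @param per_level_means Regress per-level mean estimates instead of
#'   pooled trials.
#' @return Tibble with grouping columns plus `slope`, `intercept`, `r2`,
#'   `n`.
#' @export
fit_tendencies <- function(responses, by = NULL, per_level_means = FALSE) {
  if (is.null(by)) {
    by <- c("participant", "target", "condition")
    if ("regime" %in% names(responses) &&
        length(unique(responses$regime)) > 1) {
      by <- c(by, "regime")
    }
  }
  if (!"plus_percent" %in% names(responses)) {
    responses <- dplyr::mutate(
      responses,
      plus_percent = ifelse(.data$polarity == "plus_top",
                            .data$estimate_percent,
                            100 - .data$estimate_percent))
  }
  responses |>
    dplyr::mutate(
      magnitude_percent = normalize_magnitude(
        range(MAGNITUDE_FACTORS), .data$level_factor)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      if (per_level_means) {
        d <- d |>
          dplyr::group_by(.data$magnitude_percent) |>
          dplyr::summarise(plus_percent = mean(.data$plus_percent),
                           .groups = "drop")
      }
      f <- fit_tendency(d$magnitude_percent, d$plus_percent)
      tibble::tibble(slope = f$slope, intercept = f$intercept, r2 = f$r2,
                     n = f$n)
    }) |>
    dplyr::ungroup()
}
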