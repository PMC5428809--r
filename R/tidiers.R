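# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A [fit_logit()] object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "s", "pse", "wr"),
                 estimate = c(x$mu, x$s, x$pse, x$wr))
}

#' One-row summary of a psychometric fit
#'
#' @param x A [fit_logit()] object.
#' @param ... Unused.
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(pse = x$pse, wr = x$wr, gof_p = x$gof_p,
                 deviance = x$deviance, n = x$n_trials,
                 converged = x$converged)
}

#' Tidy a central-tendency fit
#'
#' @param x A [fit_tendency()] object.
#' @param ... Unused.
#' @export
tidy.tendency_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of a central-tendency fit
#'
#' @param x A [fit_tendency()] object.
#' @param ... Unused.
#' @export
glance.tendency_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 n = x$n)
}
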