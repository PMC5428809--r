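# Correlation statistics on central-tendency slopes: Fisher z tests for
# differences of correlations, first-order partial correlations, and
# Bonferroni-masked correlation matrices across target x non-target cells.

#' Fisher z-test for the difference of two correlations
#'
#' Treats the two coefficients as coming from independent samples:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`. When the
#' two correlations share a sample and a variable, Steiger's test for
#' dependent correlations is available via `method = "steiger"`, which
#' additionally requires `r12`, the correlation between the two
#' non-shared variables.
#'
#' @param r1,r2 Correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (> 3).
#' @param method `"independent"` (default) or `"steiger"`.
#' @param r12 Correlation between the non-shared variables (Steiger only).
#' @return List with `z` and two-sided `p`.
#' @export
fisher_z_diff <- function(r1, r2, n1, n2 = n1,
                          method = c("independent", "steiger"), r12 = NULL) {
  method <- match.arg(method)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop_dotmag("correlations must be strictly inside (-1, 1)")
  }
  if (n1 <= 3 || n2 <= 3) stop_dotmag("need more than 3 observations")
  if (method == "independent") {
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(r12)) stop_dotmag("Steiger's test needs r12")
    n <- n1
    rbar <- (r1 + r2) / 2
    # Steiger (1980) Z1*, correlations sharing one variable in one sample.
    psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
      (1 - 2 * rbar^2 - r12^2)
    s <- psi / (1 - rbar^2)^2
    z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * s))
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' First-order partial correlation from zero-order correlations
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`.
#'
#' @param r_xy,r_xz,r_yz Zero-order Pearson correlations.
#' @return Partial correlation of x and y controlling for z.
#' @export
partial_corr <- function(r_xy, r_xz, r_yz) {
  denom <- (1 - r_xz^2) * (1 - r_yz^2)
  if (denom <= 0) {
    stop_dotmag("degenerate partial correlation: |r_xz| or |r_yz| is 1")
  }
  (r_xy - r_xz * r_yz) / sqrt(denom)
}

#' Correlation matrix of slopes with a Bonferroni significance mask
#'
#' Computes all pairwise Pearson correlations between the columns of a
#' per-participant slope table (columns = target x non-target cells),
#' their p-values, and a mask of the cells that survive a Bonferroni
#' correction over the number of unique off-diagonal pairs. Also reports
#' the |r| threshold that the corrected significance level implies at the
#' given sample size. Constant columns yield undefined correlations,
#' which are masked.
#'
#' @param slope_table Data frame or matrix, one row per participant, one
#'   column per cell.
#' @param alpha Family-wise significance level before correction.
#' @return List of class `"slope_correlations"`: `r` (correlation
#'   matrix), `p` (p-value matrix), `significant` (logical mask),
#'   `r_threshold`, `n`, `n_tests`.
#' @export
correlation_matrix <- function(slope_table, alpha = 0.05) {
  m <- as.matrix(slope_table)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 4) stop_dotmag("need at least 4 participants")
  if (k < 2) stop_dotmag("need at least 2 cells")
  r <- suppressWarnings(stats::cor(m))
  n_tests <- k * (k - 1) / 2
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        p[i, j] <- 0
      } else if (is.finite(r[i, j]) && abs(r[i, j]) < 1) {
        tstat <- r[i, j] * sqrt((n - 2) / (1 - r[i, j]^2))
        p[i, j] <- 2 * stats::pt(-abs(tstat), n - 2)
      } else if (is.finite(r[i, j])) {
        p[i, j] <- 0
      }
    }
  }
  sig <- !is.na(p) & p < alpha / n_tests
  diag(sig) <- FALSE
  t_crit <- stats::qt(1 - alpha / (2 * n_tests), n - 2)
  r_threshold <- t_crit / sqrt(n - 2 + t_crit^2)
  structure(list(r = r, p = p, significant = sig,
                 r_threshold = r_threshold, n = n, n_tests = n_tests),
            class = "slope_correlations")
}

#' @export
print.slope_correlations <- function(x, ...) {
  cat(sprintf(
    "<slope_correlations> %d participants, %d cells, Bonferroni over %d pairs (|r| threshold %.3f)\n",
    x$n, ncol(x$r), x$n_tests, x$r_threshold))
  print(round(x$r, 3))
  invisible(x)
}

#' Slope-correlation summary across the three dimensions
#'
#' Collapses a tendency-fit table to one slope per participant and target
#' dimension (mean across conditions), computes the three pairwise
#' Pearson correlations, the Fisher z-tests comparing the
#' duration-numerosity correlation against the other two, and the three
#' first-order partial correlations.
#'
#' @param tendency_table Output of [fit_tendencies()].
#' @return List with `triplet` (tibble of pairwise r), `z_tests` (tibble),
#'   `partials` (tibble) and `n`.
#' @export
slope_correlations <- function(tendency_table) {
  wide <- tendency_table |>
    dplyr::group_by(.data$participant, .data$target) |>
    dplyr::summarise(slope = mean(.data$slope), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "target", values_from = "slope")
  n <- nrow(wide)
  r_dn <- stats::cor(wide$duration, wide$numerosity)
  r_ds <- stats::cor(wide$duration, wide$surface)
  r_ns <- stats::cor(wide$numerosity, wide$surface)
  # z-tests and partials are only defined away from |r| = 1 and for n > 3.
  defined <- n > 3 && all(is.finite(c(r_dn, r_ds, r_ns))) &&
    all(abs(c(r_dn, r_ds, r_ns)) < 1)
  na_test <- list(z = NA_real_, p = NA_real_)
  z1 <- if (defined) fisher_z_diff(r_dn, r_ds, n, n) else na_test
  z2 <- if (defined) fisher_z_diff(r_dn, r_ns, n, n) else na_test
  partial_or_na <- function(a, b, c) {
    if (defined) partial_corr(a, b, c) else NA_real_
  }
  list(
    triplet = tibble::tibble(
      pair = c("duration-numerosity", "duration-surface",
               "numerosity-surface"),
      r = c(r_dn, r_ds, r_ns)),
    z_tests = tibble::tibble(
      comparison = c("dn_vs_ds", "dn_vs_ns"),
      z = c(z1$z, z2$z), p = c(z1$p, z2$p)),
    partials = tibble::tibble(
      pair = c("duration-numerosity | surface",
               "duration-surface | numerosity",
               "numerosity-surface | duration"),
      r = c(partial_or_na(r_dn, r_ds, r_ns),
            partial_or_na(r_ds, r_dn, r_ns),
            partial_or_na(r_ns, r_dn, r_ds))),
    n = n)
}
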