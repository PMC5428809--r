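# End-to-end pipeline: design -> stimulus/observer simulation (per cohort
# member) -> psychometric fits -> exclusion and outlier handling ->
# central-tendency fits -> correlation statistics, with CSV/JSON export.

#' Pipeline configuration
#'
#' @param experiment 1 or 2.
#' @param cohort_size Number of synthetic observers (default 17, the
#'   cohort size of the linear-regime experiment).
#' @param seed Master seed; per-observer schedule and observer seeds are
#'   derived from it.
#' @param observer Base [observer_params()] for the cohort.
#' @param means Session mean magnitudes.
#' @param geometry A [geometry_config()].
#' @param trait_sd Between-observer precision spread
#'   (see [sample_cohort_params()]).
#' @param first_regime Regime of the first block in Experiment 2.
#' @param gof_rule Exclusion rule for goodness of fit, see
#'   [exclude_participants()]; the pipeline defaults to the conventional
#'   `"low"` (drop poor fits).
#' @param out_dir Optional directory; when given, each stage writes its
#'   CSV there and the report is written as JSON.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(experiment = 1, cohort_size = 17, seed = 1L,
                            observer = observer_params(),
                            means = c(duration = 800, numerosity = 32,
                                      surface = 476),
                            geometry = geometry_config(),
                            trait_sd = 0.25,
                            first_regime = "fastslow",
                            gof_rule = "low",
                            out_dir = NULL) {
  if (cohort_size < 1) stop_dotmag("cohort_size must be >= 1")
  structure(list(experiment = experiment, cohort_size = cohort_size,
                 seed = as.integer(seed), observer = observer, means = means,
                 geometry = geometry, trait_sd = trait_sd,
                 first_regime = first_regime, gof_rule = gof_rule,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full simulation and analysis pipeline
#'
#' Enumerates the design, simulates a cohort of synthetic observers (one
#' pseudo-randomized schedule each), fits psychometric functions per
#' participant/dimension/condition, applies the exclusion and 2-SD
#' outlier-replacement rules, fits the central-tendency regressions, and
#' summarises PSE shifts and slope correlations. Deterministic given the
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @return List of class `"pipeline_report"` with elements `config_hash`,
#'   `responses`, `fits`, `exclusions`, `pse_summary`, `tendency`,
#'   `correlations` (Experiment 1) or `regime_contrasts` (Experiment 2),
#'   and `flags` (named logicals summarising the qualitative outcomes).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  design <- enumerate_design(config$experiment)
  cohort <- sample_cohort_params(config$cohort_size,
                                 seed = combine_seeds(config$seed, 101),
                                 base = config$observer,
                                 trait_sd = config$trait_sd)
  responses <- dplyr::bind_rows(lapply(seq_len(config$cohort_size), function(i) {
    sched <- make_schedule(design, seed = combine_seeds(config$seed, i),
                           first_regime = if (i %% 2 == 0) "fastslow" else
                             config$first_regime)
    simulate_session(sched, cohort[[i]], means = config$means,
                     geometry = config$geometry,
                     participant = sprintf("obs%02d", i))
  }))
  fits <- fit_psychometrics(responses)
  excl <- exclude_participants(fits, gof_rule = config$gof_rule)
  fits_kept <- excl$fits
  # 2-SD outlier replacement of PSE and WR within each condition cell.
  cell_cols <- intersect(c("target", "condition", "regime"), names(fits_kept))
  fits_kept <- fits_kept |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell_cols))) |>
    dplyr::mutate(
      pse = if (dplyr::n() >= 3) outlier_replace(.data$pse)$values else .data$pse,
      wr = if (dplyr::n() >= 3) outlier_replace(.data$wr)$values else .data$wr) |>
    dplyr::ungroup()
  responses_kept <- dplyr::filter(responses,
                                  .data$participant %in% excl$kept)
  tend <- fit_tendencies(responses_kept)
  pse_summary <- fits_kept |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell_cols))) |>
    dplyr::summarise(mean_pse = mean(.data$pse), sd_pse = stats::sd(.data$pse),
                     mean_wr = mean(.data$wr), n = dplyr::n(),
                     .groups = "drop")
  report <- list(config_hash = hash, responses = responses, fits = fits_kept,
                 exclusions = excl$dropped, pse_summary = pse_summary,
                 tendency = tend)
  # Per-participant paired PSE contrasts, mirroring the paired t-tests the
  # paradigm's analysis runs on the fitted PSEs.
  paired_pse <- function(target, cond_a, cond_b) {
    wide <- fits_kept |>
      dplyr::filter(.data$target == !!target,
                    .data$condition %in% c(cond_a, cond_b)) |>
      dplyr::group_by(.data$participant, .data$condition) |>
      dplyr::summarise(pse = mean(.data$pse), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "pse")
    wide[[cond_a]] - wide[[cond_b]]
  }
  contrast_test <- function(diffs) {
    diffs <- diffs[is.finite(diffs)]
    if (length(diffs) < 2 || stats::sd(diffs) == 0) {
      return(list(mean = mean(diffs), p = NA_real_))
    }
    tt <- stats::t.test(diffs)
    list(mean = mean(diffs), p = tt$p.value)
  }
  mean_slopes <- tend |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
  report$mean_slopes <- mean_slopes
  if (config$experiment == 1) {
    report$correlations <- slope_correlations(tend)
    n_c <- contrast_test(paired_pse("numerosity", "D_min", "D_max"))
    s_c <- contrast_test(paired_pse("surface", "D_min", "D_max"))
    # Duration: average PSE across the four non-control cells vs control.
    d_wide <- fits_kept |>
      dplyr::filter(.data$target == "duration") |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(
        shift = mean(.data$pse[.data$condition != "control"]) -
          mean(.data$pse[.data$condition == "control"]),
        .groups = "drop")
    d_c <- contrast_test(d_wide$shift)
    report$pse_contrasts <- tibble::tibble(
      contrast = c("numerosity D_min - D_max", "surface D_min - D_max",
                   "duration non-control - control"),
      mean = c(n_c$mean, s_c$mean, d_c$mean),
      p = c(n_c$p, s_c$p, d_c$p))
    report$flags <- c(
      # Overestimation at the shortest duration shows as a lower PSE.
      n_overestimated_at_dmin = n_c$mean < 0 && n_c$p < 0.05,
      s_overestimated_at_dmin = s_c$mean < 0 && s_c$p < 0.05,
      duration_immune = d_c$p > 0.01 ||
        abs(d_c$mean) < 0.02 * config$means[["duration"]],
      all_slopes_below_one = all(mean_slopes$slope < 1))
  } else {
    paired_regime <- function(target) {
      wide <- fits_kept |>
        dplyr::filter(.data$target == !!target,
                      .data$condition == "control") |>
        dplyr::select(dplyr::all_of(c("participant", "regime", "pse"))) |>
        tidyr::pivot_wider(names_from = "regime", values_from = "pse")
      wide$fastslow - wide$slowfast
    }
    n_c <- contrast_test(paired_regime("numerosity"))
    s_c <- contrast_test(paired_regime("surface"))
    d_c <- contrast_test(paired_regime("duration"))
    report$regime_contrasts <- tibble::tibble(
      target = c("numerosity", "surface", "duration"),
      fs_minus_sf = c(n_c$mean, s_c$mean, d_c$mean),
      p = c(n_c$p, s_c$p, d_c$p))
    report$flags <- c(
      # Overestimation under fast-slow shows as a lower PSE.
      n_fastslow_overestimated = n_c$mean < 0 && n_c$p < 0.05,
      s_fastslow_overestimated = s_c$mean < 0 && s_c$p < 0.05,
      duration_immune = d_c$p > 0.01 ||
        abs(d_c$mean) < 0.02 * config$means[["duration"]],
      all_slopes_below_one = all(mean_slopes$slope < 1))
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_pipeline_outputs(report, config)
  report
}

write_pipeline_outputs <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) dplyr::mutate(df, config_hash = report$config_hash)
  utils::write.csv(stamp(report$responses),
                   file.path(config$out_dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(dplyr::select(report$fits, -dplyr::any_of("fit"))),
                   file.path(config$out_dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(stamp(report$tendency),
                   file.path(config$out_dir, "tendency.csv"),
                   row.names = FALSE)
  summary <- list(config_hash = report$config_hash,
                  pse_summary = report$pse_summary,
                  flags = as.list(report$flags))
  if (!is.null(report$correlations)) {
    summary$correlations <- list(
      triplet = report$correlations$triplet,
      z_tests = report$correlations$z_tests,
      partials = report$correlations$partials)
  }
  if (!is.null(report$regime_contrasts)) {
    summary$regime_contrasts <- report$regime_contrasts
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s\n", x$config_hash))
  cat(sprintf("  %d responses, %d fits, %d excluded\n",
              nrow(x$responses), nrow(x$fits), nrow(x$exclusions)))
  for (nm in names(x$flags)) {
    cat(sprintf("  %-28s %s\n", nm, x$flags[[nm]]))
  }
  invisible(x)
}
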