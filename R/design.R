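# Factorial designs and pseudo-randomized trial schedules for the two
# dot-cloud magnitude-estimation experiments.

# Canonical constants of the paradigm.
MAGNITUDE_FACTORS <- c(0.75, 0.90, 0.95, 1.05, 1.10, 1.25)
DIMENSIONS <- c("duration", "numerosity", "surface")
REGIMES <- c("linear", "fastslow", "slowfast")

#' The six tested magnitude levels of a dimension
#'
#' Each dimension is probed at 75, 90, 95, 105, 110 and 125% of its mean
#' value.
#'
#' @param mean_value Positive mean magnitude of the dimension (ms for
#'   duration, dot count for numerosity, mm^2 for surface).
#' @return Numeric vector of 6 levels in ascending order.
#' @examples
#' magnitude_levels(800) # duration levels in ms
#' magnitude_levels(32)  # numerosity levels (dot counts are rounded only
#'                       # when a stimulus is realized)
#' @export
magnitude_levels <- function(mean_value) {
  if (!is.numeric(mean_value) || length(mean_value) != 1 || !is.finite(mean_value) ||
      mean_value <= 0) {
    stop_dotmag("`mean_value` must be a single positive number, got %s",
                deparse(mean_value))
  }
  mean_value * MAGNITUDE_FACTORS
}

# One target dimension's condition cells for Experiment 1: control plus the
# four non-target min/max settings (the manipulated non-target at its 0.75x
# or 1.25x value, the other non-target at its mean).
exp1_conditions <- function(target) {
  others <- setdiff(DIMENSIONS, target)
  cond <- list(stats::setNames(c("mean", "mean"), others))
  for (dim in others) {
    for (setting in c("min", "max")) {
      s <- stats::setNames(c("mean", "mean"), others)
      s[dim] <- setting
      cond <- c(cond, list(s))
    }
  }
  names(cond) <- c("control",
                   paste0(dim_abbrev(others[1]), c("_min", "_max")),
                   paste0(dim_abbrev(others[2]), c("_min", "_max")))
  cond
}

dim_abbrev <- function(dim) c(duration = "D", numerosity = "N", surface = "S")[dim]

#' Enumerate the full factorial design of an experiment
#'
#' Experiment 1 crosses 3 target dimensions x 5 conditions (control + four
#' non-target min/max manipulations) x 6 magnitude levels x 12 repetitions
#' under a linear accumulation regime (1080 trials). Experiment 2 crosses
#' the fast-slow and slow-fast accumulation regimes with duration tested in
#' its control condition only (144 trials) and numerosity and surface each
#' tested in control, D_min and D_max conditions (432 trials each; 1008
#' trials in total). Experiment 2 contains no cell in which numerosity or
#' surface is a manipulated non-target, nor N-S interference cells.
#'
#' @param experiment Experiment id, 1 or 2.
#' @return A tibble with one row per trial: `experiment`, `target`,
#'   `condition` (cell label such as `"control"` or `"D_min"`),
#'   `level_factor`, `regime`, `nontarget_dim_1`, `nontarget_setting_1`,
#'   `nontarget_dim_2`, `nontarget_setting_2`, `repetition_index`.
#' @examples
#' nrow(enumerate_design(1)) # 1080
#' nrow(enumerate_design(2)) # 1008
#' @export
enumerate_design <- function(experiment) {
  if (!length(experiment) == 1 || !experiment %in% c(1, 2)) {
    stop_dotmag("unknown experiment id %s; must be 1 or 2",
                deparse(experiment))
  }
  rows <- list()
  add_cells <- function(target, cond_name, settings, regime) {
    others <- names(settings)
    tidyr::expand_grid(
      level_factor = MAGNITUDE_FACTORS,
      repetition_index = seq_len(12)
    ) |>
      dplyr::mutate(
        experiment = as.integer(experiment),
        target = target,
        condition = cond_name,
        regime = regime,
        nontarget_dim_1 = others[1],
        nontarget_setting_1 = unname(settings[1]),
        nontarget_dim_2 = others[2],
        nontarget_setting_2 = unname(settings[2])
      )
  }
  if (experiment == 1) {
    for (target in DIMENSIONS) {
      conds <- exp1_conditions(target)
      for (i in seq_along(conds)) {
        rows <- c(rows, list(add_cells(target, names(conds)[i], conds[[i]],
                                       "linear")))
      }
    }
  } else {
    for (regime in c("fastslow", "slowfast")) {
      # Duration: control only.
      ctl <- stats::setNames(c("mean", "mean"), setdiff(DIMENSIONS, "duration"))
      rows <- c(rows, list(add_cells("duration", "control", ctl, regime)))
      # Numerosity and surface: control, D_min, D_max.
      for (target in c("numerosity", "surface")) {
        other <- setdiff(DIMENSIONS, c(target, "duration"))
        for (dsetting in c("mean", "min", "max")) {
          settings <- stats::setNames(c(dsetting, "mean"),
                                      c("duration", other))
          cond_name <- if (dsetting == "mean") "control" else
            paste0("D_", dsetting)
          rows <- c(rows, list(add_cells(target, cond_name, settings, regime)))
        }
      }
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("experiment", "target", "condition", "level_factor",
                  "regime", dplyr::starts_with("nontarget"),
                  "repetition_index")
}

#' Build a seeded pseudo-randomized trial schedule
#'
#' Returns a permutation of the supplied conditions. Experiment 2 trials
#' are dealt round-robin into five blocks per accumulation regime and the
#' ten blocks are interleaved so that regimes alternate; which regime opens
#' the session is a flag (counterbalanced across observers in practice).
#'
#' @param conditions Tibble of trial conditions from [enumerate_design()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param first_regime For Experiment 2, the regime of the first block
#'   (`"fastslow"` or `"slowfast"`).
#' @return The input rows in scheduled order with `block` and
#'   `trial_index` columns; the seed is kept in attribute `"seed"`.
#' @export
make_schedule <- function(conditions, seed,
                          first_regime = c("fastslow", "slowfast")) {
  if (!is.data.frame(conditions) || nrow(conditions) == 0) {
    stop_dotmag("`conditions` must be a non-empty data frame of trials")
  }
  first_regime <- match.arg(first_regime)
  experiment <- conditions$experiment[1]
  sched <- with_seed(seed, {
    if (experiment == 2 && length(unique(conditions$regime)) > 1) {
      per_regime <- 5L
      regimes <- if (first_regime == "fastslow") {
        rep(c("fastslow", "slowfast"), per_regime)
      } else {
        rep(c("slowfast", "fastslow"), per_regime)
      }
      blocks <- vector("list", length(regimes))
      for (regime in unique(regimes)) {
        sub <- conditions[conditions$regime == regime, , drop = FALSE]
        sub <- sub[sample.int(nrow(sub)), , drop = FALSE]
        slots <- which(regimes == regime)
        deal <- rep(slots, length.out = nrow(sub))
        for (b in slots) blocks[[b]] <- sub[deal == b, , drop = FALSE]
      }
      out <- dplyr::bind_rows(
        lapply(seq_along(blocks), function(b) {
          dplyr::mutate(blocks[[b]], block = as.integer(b))
        })
      )
      out
    } else {
      dplyr::mutate(conditions[sample.int(nrow(conditions)), , drop = FALSE],
                    block = 1L)
    }
  })
  sched <- dplyr::mutate(sched, trial_index = dplyr::row_number()) |>
    dplyr::relocate("block", "trial_index")
  attr(sched, "seed") <- as.integer(seed)
  sched
}

#' Block-level regime structure of a schedule
#'
#' @param schedule A schedule from [make_schedule()].
#' @return Tibble with one row per block: `block`, `regime`, `n_trials`.
#' @export
block_structure <- function(schedule) {
  dplyr::summarise(dplyr::group_by(schedule, .data$block),
                   regime = .data$regime[1],
                   n_trials = dplyr::n(), .groups = "drop")
}
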