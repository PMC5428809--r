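# Dynamic dot-cloud stimulus simulation: onset schedules under three
# evidence-accumulation regimes, cumulative-surface partitioning across
# dots, and non-overlapping placement inside the display annulus.

#' Display geometry of the dot-cloud stimulus
#'
#' Defaults follow the paradigm: dots appear inside a virtual disk of
#' 12.3-15.2 degrees of visual angle (a single working value is used per
#' configuration), outside an invisible central disk of 3.3 degrees
#' protecting fixation; dot diameters span 0.35-1.14 degrees, dot lifetimes
#' 35-294 ms, the display refreshes at 85 Hz, and dot grey levels are drawn
#' from six RGB values so luminance cannot cue the task.
#'
#' @param outer_diameter_deg Diameter of the outer virtual disk (degrees),
#'   in `[12.3, 15.2]`.
#' @param inner_diameter_deg Diameter of the protected central disk.
#' @param dot_diameter_deg_range Length-2 vector of min/max dot diameters.
#' @param dot_duration_ms_range Length-2 vector of min/max dot lifetimes.
#' @param refresh_hz Display refresh rate; onsets and lifetimes are
#'   quantized to this frame grid.
#' @param viewing_distance_cm Viewing distance used for the degree-to-mm
#'   conversion (surface is specified in mm^2).
#' @param screen_px Screen resolution (informational).
#' @param luminance_set Admissible dot grey levels (RGB code).
#' @return A list of class `"geometry_config"`.
#' @export
geometry_config <- function(outer_diameter_deg = 13.75,
                            inner_diameter_deg = 3.3,
                            dot_diameter_deg_range = c(0.35, 1.14),
                            dot_duration_ms_range = c(35, 294),
                            refresh_hz = 85,
                            viewing_distance_cm = 60,
                            screen_px = c(1024, 768),
                            luminance_set = c(57, 64, 73, 85, 102, 128)) {
  if (outer_diameter_deg < 12.3 || outer_diameter_deg > 15.2) {
    stop_dotmag("outer_diameter_deg must lie in [12.3, 15.2]")
  }
  if (inner_diameter_deg >= outer_diameter_deg) {
    stop_dotmag("inner disk must be smaller than the outer disk")
  }
  if (diff(dot_diameter_deg_range) <= 0 || diff(dot_duration_ms_range) <= 0 ||
      refresh_hz <= 0) {
    stop_dotmag("degenerate geometry ranges or refresh rate")
  }
  structure(list(
    outer_diameter_deg = outer_diameter_deg,
    inner_diameter_deg = inner_diameter_deg,
    dot_diameter_deg_range = dot_diameter_deg_range,
    dot_duration_ms_range = dot_duration_ms_range,
    refresh_hz = refresh_hz,
    viewing_distance_cm = viewing_distance_cm,
    screen_px = screen_px,
    luminance_set = luminance_set
  ), class = "geometry_config")
}

frame_ms <- function(geometry) 1000 / geometry$refresh_hz

# Feasible per-dot area interval (mm^2) implied by the diameter range.
dot_area_bounds <- function(geometry) {
  dot_area_mm2(geometry$dot_diameter_deg_range, geometry$viewing_distance_cm)
}

#' Schedule dot onsets under an accumulation regime
#'
#' Under the linear regime the dots arrive in 9-13 evenly spaced
#' iterations of 2-7 dots each, so the cumulative count grows
#' proportionally to elapsed time. Under fast-slow a fraction drawn
#' uniformly from 75 +/- 10% of the dots arrives within the first quarter
#' of the trial, the rest later; under slow-fast a fraction drawn uniformly
#' from 25 +/- 10% arrives within the first three quarters, the rest in
#' the final quarter. Onsets are floored to the frame grid and never start
#' later than `D - 3` frames so that the shortest admissible dot lifetime
#' still fits inside the trial.
#'
#' @param d_ms Trial duration in ms.
#' @param n Total number of dots (integer, >= 2).
#' @param regime `"linear"`, `"fastslow"` or `"slowfast"`.
#' @param seed Optional integer seed for a deterministic schedule.
#' @param geometry A [geometry_config()].
#' @return Tibble with one row per iteration: `onset_ms`, `n_dots`
#'   (non-linear regimes schedule dots individually, `n_dots = 1`).
#' @export
onset_schedule <- function(d_ms, n, regime = c("linear", "fastslow", "slowfast"),
                           seed = NULL, geometry = geometry_config()) {
  regime <- match.arg(regime)
  n <- as.integer(round(n))
  if (d_ms <= 0) stop_dotmag("trial duration must be positive")
  if (n < 2) stop_dotmag("at least 2 dots are required, got %d", n)
  fr <- frame_ms(geometry)
  quantize <- function(t) floor(t / fr) * fr
  latest <- d_ms - 3 * fr # leave room for the shortest (3-frame) lifetime
  with_seed(seed, {
    if (regime == "linear") {
      k_candidates <- 9:13
      feasible <- k_candidates[2 * k_candidates <= n & n <= 7 * k_candidates]
      if (length(feasible) == 0) {
        stop_dotmag(paste0(
          "no iteration count in 9..13 can deliver %d dots in groups of ",
          "2..7 (feasible dot counts are 18..91)"), n)
      }
      k <- if (length(feasible) == 1) feasible else sample(feasible, 1)
      sizes <- rep(2L, k)
      headroom <- n - 2L * k
      while (headroom > 0) {
        open <- which(sizes < 7L)
        pick <- if (length(open) == 1) open else sample(open, 1)
        sizes[pick] <- sizes[pick] + 1L
        headroom <- headroom - 1L
      }
      onsets <- quantize((seq_len(k) - 1) / k * d_ms)
      onsets <- pmin(onsets, quantize(latest))
      tibble::tibble(onset_ms = onsets, n_dots = sizes)
    } else {
      if (regime == "fastslow") {
        frac <- stats::runif(1, 0.65, 0.85)
        split_ms <- 0.25 * d_ms
      } else {
        frac <- stats::runif(1, 0.15, 0.35)
        split_ms <- 0.75 * d_ms
      }
      n_early <- max(1L, min(n - 1L, as.integer(round(frac * n))))
      early <- stats::runif(n_early, 0, min(split_ms, latest))
      late <- stats::runif(n - n_early, split_ms, latest)
      onsets <- sort(quantize(c(early, late)))
      tibble::tibble(onset_ms = onsets, n_dots = rep(1L, n))
    }
  })
}

#' Partition a cumulative surface across dots
#'
#' Draws per-dot areas uniformly within the feasible per-dot area interval
#' and affinely squeezes them towards the interval edge so that the areas
#' sum exactly to the requested cumulative surface while every diameter
#' stays within range.
#'
#' @param s_mm2 Target cumulative surface in mm^2.
#' @param n Number of dots.
#' @param geometry A [geometry_config()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` dot diameters in degrees whose circle
#'   areas (in mm^2) sum to `s_mm2` (well within 0.5%).
#' @export
partition_surface <- function(s_mm2, n, geometry = geometry_config(),
                              seed = NULL) {
  n <- as.integer(round(n))
  if (n < 1) stop_dotmag("need at least one dot")
  bounds <- dot_area_bounds(geometry)
  lo <- n * bounds[1]
  hi <- n * bounds[2]
  if (s_mm2 < lo || s_mm2 > hi) {
    stop_dotmag(paste0(
      "requested surface %.1f mm^2 is infeasible for %d dots; ",
      "the feasible interval is [%.1f, %.1f] mm^2"), s_mm2, n, lo, hi)
  }
  if (n == 1) {
    return(mm_to_deg(2 * sqrt(s_mm2 / pi), geometry$viewing_distance_cm))
  }
  areas <- with_seed(seed, {
    u <- stats::runif(n, bounds[1], bounds[2])
    if (sum(u) >= s_mm2) {
      # squeeze towards the lower bound until the sum hits the target
      t <- (s_mm2 - n * bounds[1]) / max(sum(u) - n * bounds[1], .Machine$double.eps)
      bounds[1] + (u - bounds[1]) * t
    } else {
      t <- (n * bounds[2] - s_mm2) / max(n * bounds[2] - sum(u), .Machine$double.eps)
      bounds[2] - (bounds[2] - u) * t
    }
  })
  mm_to_deg(2 * sqrt(areas / pi), geometry$viewing_distance_cm)
}

#' Place dots in the display annulus without simultaneous overlap
#'
#' Positions are sampled uniformly over the annulus between the protected
#' central disk and the outer virtual disk, wholly containing each dot.
#' Dots whose display intervals intersect in time must keep a
#' centre-to-centre distance larger than the sum of their radii; overlap
#' between dots that are never on screen together is allowed (cumulative
#' surface can exceed the annulus area). Placement is by rejection
#' sampling with a budget of 10,000 attempts per dot and up to 20 whole
#' trial restarts.
#'
#' @param events Tibble with `onset_ms`, `duration_ms`, `diameter_deg`.
#' @param geometry A [geometry_config()].
#' @param seed Optional integer seed.
#' @param max_attempts Placement attempts per dot before restarting.
#' @param max_restarts Whole-trial restarts before giving up.
#' @return `events` with `x_deg`, `y_deg` columns added (dot centres
#'   relative to fixation).
#' @export
place_dots <- function(events, geometry = geometry_config(), seed = NULL,
                       max_attempts = 10000L, max_restarts = 20L) {
  r_out <- geometry$outer_diameter_deg / 2
  r_in <- geometry$inner_diameter_deg / 2
  radii <- events$diameter_deg / 2
  if (any(events$diameter_deg > (r_out - r_in))) {
    stop_dotmag("a dot of diameter %.2f deg cannot fit inside the %.2f deg wide annulus",
                max(events$diameter_deg), r_out - r_in)
  }
  with_seed(seed,
            place_dots_impl(events, radii, r_in, r_out, max_attempts,
                            max_restarts))
}

place_dots_impl <- function(events, radii, r_in, r_out, max_attempts,
                            max_restarts) {
  n <- nrow(events)
  t0 <- events$onset_ms
  t1 <- events$onset_ms + events$duration_ms
  for (restart in seq_len(max_restarts + 1L)) {
    x <- y <- rep(NA_real_, n)
    ok <- TRUE
    for (i in seq_len(n)) {
      rmin <- r_in + radii[i]
      rmax <- r_out - radii[i]
      concurrent <- which(!is.na(x) & t0 < t1[i] & t1 > t0[i] &
                            seq_len(n) < i)
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        rr <- sqrt(stats::runif(1, rmin^2, rmax^2))
        th <- stats::runif(1, 0, 2 * pi)
        xi <- rr * cos(th)
        yi <- rr * sin(th)
        if (length(concurrent) == 0 ||
            all(sqrt((x[concurrent] - xi)^2 + (y[concurrent] - yi)^2) >
                  radii[concurrent] + radii[i])) {
          x[i] <- xi
          y[i] <- yi
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      return(dplyr::mutate(events, x_deg = x, y_deg = y))
    }
  }
  stop_dotmag(paste0(
    "dot placement failed after %d restarts with a budget of %d ",
    "attempts per dot"), max_restarts, max_attempts)
}

#' Realize one dot-cloud stimulus
#'
#' Composes the onset schedule, lifetime assignment, surface partition,
#' luminance assignment and (optionally) spatial placement into a full
#' per-dot event table for a trial with target duration `d_ms`, dot count
#' `n` and cumulative surface `s_mm2` under the given accumulation regime.
#'
#' Some extreme design cells (a maximal dot count paired with a minimal
#' cumulative surface) request a mean per-dot area below the smallest
#' admissible dot; with `surface_policy = "clip"` (the default) the
#' nearest feasible cumulative surface is realized instead and flagged,
#' with `"strict"` such a request is an error.
#'
#' @param d_ms Trial duration (ms).
#' @param n Dot count (rounded to an integer).
#' @param s_mm2 Cumulative surface (mm^2).
#' @param regime Accumulation regime.
#' @param geometry A [geometry_config()].
#' @param seed Optional integer seed.
#' @param place If `FALSE`, skip spatial placement (the event table then
#'   has no `x_deg`/`y_deg`); useful for bulk simulation where only onset
#'   times and areas matter.
#' @param surface_policy `"clip"` or `"strict"`, see above.
#' @return A list of class `"stimulus"`: `spec` (the requested
#'   `d_ms`/`n`/`s_mm2`/`regime`), `events` (per-dot tibble with
#'   `onset_ms`, `duration_ms`, `diameter_deg`, `area_mm2`, `luminance`
#'   and, when placed, `x_deg`, `y_deg`), `realized_surface_mm2` and
#'   `surface_clipped`.
#' @export
realize_stimulus <- function(d_ms, n, s_mm2,
                             regime = c("linear", "fastslow", "slowfast"),
                             geometry = geometry_config(), seed = NULL,
                             place = TRUE,
                             surface_policy = c("clip", "strict")) {
  regime <- match.arg(regime)
  surface_policy <- match.arg(surface_policy)
  n <- as.integer(round(n))
  bounds <- dot_area_bounds(geometry)
  s_req <- s_mm2
  clipped <- FALSE
  if (surface_policy == "clip") {
    s_use <- min(max(s_mm2, n * bounds[1]), n * bounds[2])
    clipped <- !isTRUE(all.equal(s_use, s_mm2))
  } else {
    s_use <- s_mm2
  }
  fr <- frame_ms(geometry)
  with_seed(seed, {
    iters <- onset_schedule(d_ms, n, regime, seed = NULL, geometry = geometry)
    onsets <- rep(iters$onset_ms, iters$n_dots)
    dur_range_frames <- c(ceiling(geometry$dot_duration_ms_range[1] / fr),
                          floor(geometry$dot_duration_ms_range[2] / fr))
    dur_frames <- sample(seq(dur_range_frames[1], dur_range_frames[2]),
                         n, replace = TRUE)
    dur_frames <- pmin(dur_frames, floor((d_ms - onsets) / fr))
    durations <- dur_frames * fr
    diameters <- partition_surface(s_use, n, geometry, seed = NULL)
    luminance <- sample(geometry$luminance_set, n, replace = TRUE)
    events <- tibble::tibble(
      onset_ms = onsets,
      duration_ms = durations,
      diameter_deg = diameters,
      area_mm2 = dot_area_mm2(diameters, geometry$viewing_distance_cm),
      luminance = luminance
    )
    if (place) events <- place_dots(events, geometry, seed = NULL)
    structure(list(
      spec = list(d_ms = d_ms, n = n, s_mm2 = s_req, regime = regime),
      events = events,
      realized_surface_mm2 = sum(events$area_mm2),
      surface_clipped = clipped
    ), class = "stimulus")
  })
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf(
    "<stimulus> %s regime: D = %g ms, N = %d dots, S = %.1f mm^2 (realized %.1f%s)\n",
    x$spec$regime, x$spec$d_ms, x$spec$n, x$spec$s_mm2,
    x$realized_surface_mm2, if (x$surface_clipped) ", clipped" else ""))
  invisible(x)
}
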