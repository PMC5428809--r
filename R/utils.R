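# Internal helpers shared across modules.

#' Convert a visual angle to millimetres on the screen
#'
#' Uses the exact tangent relation at the given viewing distance,
#' `mm = 10 * distance_cm * tan(deg * pi / 180)`. For the sub-degree dot
#' sizes used here this is numerically indistinguishable from the
#' small-angle approximation.
#'
#' @param deg Visual angle in degrees.
#' @param viewing_distance_cm Viewing distance in centimetres.
#' @return Length in millimetres.
#' @export
deg_to_mm <- function(deg, viewing_distance_cm = 60) {
  10 * viewing_distance_cm * tan(deg * pi / 180)
}

#' Convert a length on the screen to visual angle
#'
#' Inverse of [deg_to_mm()].
#'
#' @param mm Length in millimetres.
#' @inheritParams deg_to_mm
#' @return Visual angle in degrees.
#' @export
mm_to_deg <- function(mm, viewing_distance_cm = 60) {
  atan(mm / (10 * viewing_distance_cm)) * 180 / pi
}

# Area (mm^2) of a circular dot given its diameter in degrees.
dot_area_mm2 <- function(diameter_deg, viewing_distance_cm = 60) {
  pi * (deg_to_mm(diameter_deg, viewing_distance_cm) / 2)^2
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Fold two (or more) integer seeds into one valid 32-bit seed.
combine_seeds <- function(...) {
  parts <- vapply(list(...), as.numeric, numeric(1))
  acc <- 0
  for (p in parts) acc <- (acc * 69069 + (p %% 2147483647)) %% 2147483647
  as.integer(acc)
}

# FNV-1a style hash of a deparsed R object; used to stamp pipeline outputs
# so that re-runs can be matched to their configuration.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

stop_dotmag <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
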