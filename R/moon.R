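#' @name moonlight
#' @title Moonlight screening of daily radiance layers
#'
#' @description Daily low-light imagery is unusable for human-activity
#' monitoring on nights with substantial lunar illumination. Layers are
#' screened either by an explicit list of retained dates (the operational
#' default: three dark windows centred on the new moons of late January,
#' late February and late March 2020), or by an ephemeris rule keeping dates
#' whose lunar phase angle exceeds 90 degrees (less than half illuminated).
#'
#' The phase-angle convention is the sun-moon-observer angle: 0 degrees at
#' full moon, 180 degrees at new moon, so "greater than 90 degrees" selects
#' the dark half of the lunation.
NULL

deg2rad <- function(d) d * pi / 180

# Julian day number for a calendar date at a fixed evaluation hour (UT).
julian_day <- function(date, hour = 18) {
  as.numeric(as.Date(date)) + 2440587.5 + hour / 24
}

#' Lunar phase angle of a date
#'
#' Computes the geocentric lunar phase angle from truncated mean-element
#' series for the solar and lunar ecliptic longitudes (low-precision,
#' accurate to well under a degree of elongation over the 1950--2050 range,
#' which is ample for a 90-degree threshold rule). The layer is evaluated at
#' 18:00 UT, near local midnight for east-Asian longitudes.
#'
#' @param date `Date` vector (or coercible).
#' @return Phase angle in degrees, in `[0, 180]`: ~180 at new moon, ~0 at
#'   full moon.
#' @export
moon_phase_angle <- function(date) {
  jd <- julian_day(date)
  if (any(jd < 2415020 | jd > 2488070)) {  # ~1900..2100
    stop("date outside supported ephemeris range (1900-2100)", call. = FALSE)
  }
  t <- (jd - 2451545.0) / 36525
  # solar true longitude
  L0 <- 280.46646 + 36000.76983 * t
  M  <- deg2rad(357.52911 + 35999.05029 * t)
  C  <- (1.914602 - 0.004817 * t) * sin(M) + 0.019993 * sin(2 * M) +
    0.000289 * sin(3 * M)
  sun_lon <- L0 + C
  # lunar true longitude, principal perturbation terms
  Lp <- 218.3164477 + 481267.88123421 * t
  Mp <- deg2rad(134.9633964 + 477198.8675055 * t)
  D  <- deg2rad(297.8501921 + 445267.1114034 * t)
  F  <- deg2rad(93.2720950 + 483202.0175233 * t)
  moon_lon <- Lp + 6.288774 * sin(Mp) + 1.274027 * sin(2 * D - Mp) +
    0.658314 * sin(2 * D) + 0.213618 * sin(2 * Mp) - 0.185116 * sin(M) -
    0.114332 * sin(2 * F)
  elong <- (moon_lon - sun_lon) %% 360
  separation <- 180 - abs(180 - elong)   # angular distance sun-moon, 0..180
  180 - separation                        # phase angle: new = 180, full = 0
}

#' Lunar illuminated fraction of a date
#'
#' @param date `Date` vector.
#' @return Fraction of the lunar disc illuminated, in `[0, 1]`.
#' @export
moon_illuminated_fraction <- function(date) {
  (1 + cos(deg2rad(moon_phase_angle(date)))) / 2
}

#' Default moonless date windows (early 2020)
#'
#' The three dark windows used operationally for the January-March 2020
#' analysis period: 20 Jan-1 Feb, 16 Feb-2 Mar and 17 Mar-1 Apr 2020, each
#' bracketing a new moon.
#'
#' @return A `Date` vector of retained dates.
#' @export
moonless_default_dates <- function() {
  c(seq(as.Date("2020-01-20"), as.Date("2020-02-01"), by = "day"),
    seq(as.Date("2020-02-16"), as.Date("2020-03-02"), by = "day"),
    seq(as.Date("2020-03-17"), as.Date("2020-04-01"), by = "day"))
}

#' Drop moonlit layers from a stack
#'
#' @param stack An [ntl_stack()].
#' @param mode `"explicit"` keeps only dates in `dates` (default: the
#'   operational windows of [moonless_default_dates()]); `"ephemeris"` keeps
#'   dates whose [moon_phase_angle()] exceeds `threshold`; `"flags"` keeps
#'   dates not flagged moonlit in the stack metadata; `"all"` keeps
#'   everything.
#' @param dates Retained-date list for `mode = "explicit"`.
#' @param threshold Phase-angle threshold in degrees for ephemeris mode
#'   (default 90).
#' @return The filtered `ntl_stack` (warns if nothing is retained).
#' @export
filter_moonless <- function(stack,
                            mode = c("explicit", "ephemeris", "flags", "all"),
                            dates = NULL, threshold = 90) {
  mode <- match.arg(mode)
  keep <- switch(mode,
    explicit = {
      if (is.null(dates)) dates <- moonless_default_dates()
      stack$dates %in% as.Date(dates)
    },
    ephemeris = moon_phase_angle(stack$dates) > threshold,
    flags = !stack$moonlit,
    all = rep(TRUE, n_layers(stack))
  )
  if (!any(keep)) warning("no dates retained after moonlight filtering")
  stack_subset(stack, keep)
}
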