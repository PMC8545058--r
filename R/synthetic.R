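#' @name synthetic
#' @title Synthetic nighttime-light scenes with planted ground truth
#'
#' @description The generator builds a pair of daily radiance stacks (an
#' epidemic "analysis" year and a lunar-matched baseline year) on a shared
#' equal-area grid, plus a zone map, epidemic case tables, mobility series
#' and a full ground-truth record. Cities are CBD-centred bright cores whose
#' radiance decays exponentially outwards over a dark rural floor whose
#' pixels fluctuate in roughly 0-1 nW/cm2/sr. The epidemic dims each city's
#' lit pixels multiplicatively by a per-zone suppression profile s(t) in
#' (0, 1]; hospital pixels brighten instead. Injected noise — sparse bright
#' spikes (fires, scan-edge glints), rarer cloud drops, dark-floor
#' fluctuation, night-to-night jitter and additive moonlight on flagged
#' dates — is book-kept exactly in the ground truth so every downstream
#' stage can be scored against what was planted.
NULL

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Suppression profiles
#'
#' A suppression profile gives the multiplicative factor s(t) in (0, 1]
#' applied to a zone's lit radiance on each analysis date; s = 1 means
#' activity at its normal level.
#'
#' * `suppr_none()` — no epidemic effect.
#' * `suppr_window(level, start, end)` — constant suppression `level`
#'   inside a date window, 1 outside (used for parameter-recovery studies).
#' * `suppr_epidemic(trough, onset, drop_days, turning, end_level)` — the
#'   canonical outbreak shape: normal until `onset` (default 23 Jan 2020,
#'   the lockdown date), a linear drop over `drop_days` to `trough`, flat
#'   until the `turning` point (default 18 Feb 2020), then linear recovery
#'   to `end_level` at the last date.
#' * `suppr_trajectory(type, tail, depth)` — deficit profiles whose daily
#'   D-line is itself a fifth-order curve with one ("inverted-U") or two
#'   ("M") interior recovery peaks and a rising or falling window-end
#'   tail; used to plant trajectory-typing ground truth.
#'
#' @param level,trough,end_level,depth Suppression magnitudes in (0, 1).
#' @param start,end,onset,turning Dates.
#' @param drop_days Length of the initial collapse in days.
#' @param type `"M"` or `"inverted-U"`.
#' @param tail `"up"` or `"down"`.
#' @return A profile object understood by [compile_suppression()].
#' @export
suppr_none <- function() structure(list(kind = "none"), class = "ntl_suppr")

#' @rdname suppr_none
#' @export
suppr_window <- function(level, start, end) {
  stopifnot(level > 0, level <= 1)
  structure(list(kind = "window", level = level,
                 start = as.Date(start), end = as.Date(end)),
            class = "ntl_suppr")
}

#' @rdname suppr_none
#' @export
suppr_epidemic <- function(trough = 0.3, onset = "2020-01-23", drop_days = 5,
                           turning = "2020-02-18", end_level = 0.95) {
  stopifnot(trough > 0, trough <= 1, end_level > 0, end_level <= 1,
            drop_days >= 1)
  structure(list(kind = "epidemic", trough = trough, onset = as.Date(onset),
                 drop_days = drop_days, turning = as.Date(turning),
                 end_level = end_level),
            class = "ntl_suppr")
}

# Planted D-line shapes are themselves fifth-order curves — the model class
# of the typing method — built by prescribing the interior critical points
# (as roots of the quartic derivative, with off-window roots shaping the
# tail) and integrating. Peaks sit inside the moonless observation windows
# (u ~ [0, .18], [.38, .60], [.79, 1] for the default window set) so the
# planted recovery phases are observable. `sign` is the derivative's sign
# just before the first interior root.
trajectory_roots <- function(type, tail) {
  switch(paste(type, tail, sep = "/"),
    # one interior maximum; falling / rising tail
    "inverted-U/down" = list(roots = c(-0.30, 0.60, 1.25, 1.60), sign = -1),
    "inverted-U/up"   = list(roots = c(-0.40, 0.50, 0.85, 1.50), sign = -1),
    # two interior maxima (two recovery phases)
    "M/down" = list(roots = c(0.45, 0.65, 0.88, 1.30), sign = +1),
    "M/up"   = list(roots = c(0.42, 0.60, 0.80, 0.92), sign = +1),
    stop("unknown trajectory type/tail", call. = FALSE)
  )
}

# integrate c * prod(u - roots) to a monic-scaled quintic, ascending coefs
trajectory_qcoef <- function(spec) {
  dcoef <- 1
  for (r in spec$roots) dcoef <- c(0, dcoef) + c(-r * dcoef, 0)
  dcoef <- spec$sign * dcoef               # ascending, degree 4
  c(0, dcoef / seq_along(dcoef))           # antiderivative, degree 5
}

#' @rdname suppr_none
#' @export
suppr_trajectory <- function(type = c("inverted-U", "M"),
                             tail = c("down", "up"),
                             depth = 0.6) {
  type <- match.arg(type)
  tail <- match.arg(tail)
  stopifnot(depth > 0, depth < 1)
  spec <- trajectory_roots(type, tail)
  qc <- trajectory_qcoef(spec)
  # normalise the shape to [-1, 0] over the window so the deficit spans
  # [0, depth] (s touches 1 at the strongest recovery moment)
  uu <- seq(0, 1, length.out = 2001)
  qv <- poly_eval(qc, uu)
  structure(list(kind = "trajectory", type = type, tail = tail,
                 depth = depth, qcoef = qc,
                 qrange = range(qv)),
            class = "ntl_suppr")
}

# deficit delta(u) on the unit window for a trajectory profile
trajectory_deficit <- function(profile, u) {
  qv <- poly_eval(profile$qcoef, u)
  profile$depth * (profile$qrange[2] - qv) / diff(profile$qrange)
}

#' Evaluate a suppression profile on a date vector
#'
#' @param profile An `ntl_suppr` object.
#' @param dates `Date` vector (the analysis-year dates).
#' @return Numeric vector of s(t) values in (0, 1], one per date.
#' @export
compile_suppression <- function(profile, dates) {
  dates <- as.Date(dates)
  n <- length(dates)
  s <- rep(1, n)
  if (profile$kind == "none") return(s)
  if (profile$kind == "window") {
    inw <- dates >= profile$start & dates <= profile$end
    s[inw] <- profile$level
    return(s)
  }
  if (profile$kind == "epidemic") {
    t <- as.numeric(dates - profile$onset)
    drop_end <- profile$drop_days
    t_turn <- as.numeric(profile$turning - profile$onset)
    t_end <- as.numeric(max(dates) - profile$onset)
    ramp <- function(ti) {
      if (ti < 0) return(1)
      if (ti <= drop_end) {
        return(1 + (profile$trough - 1) * ti / drop_end)
      }
      if (ti <= t_turn) return(profile$trough)
      if (t_end <= t_turn) return(profile$trough)
      profile$trough + (profile$end_level - profile$trough) *
        (ti - t_turn) / (t_end - t_turn)
    }
    return(vapply(t, ramp, numeric(1)))
  }
  if (profile$kind == "trajectory") {
    u <- as.numeric(dates - min(dates)) / as.numeric(max(dates) - min(dates))
    return(pmax(1 - trajectory_deficit(profile, u), .Machine$double.eps))
  }
  stop("unknown suppression profile", call. = FALSE)
}

# realized trajectory shape of a profile: interior maxima of -delta and the
# end-tail direction, read off a dense evaluation of the continuous deficit
realized_trajectory <- function(profile, n_dense = 4001) {
  u <- seq(0, 1, length.out = n_dense)
  y <- -trajectory_deficit(profile, u)
  dy <- diff(y)
  sgn <- sign(dy)
  sgn <- sgn[sgn != 0]
  flips <- diff(sgn)
  n_max <- sum(flips < 0)
  type <- if (n_max >= 2) "M" else "inverted-U"
  tail <- if (dy[length(dy)] > 0) "up" else "down"
  list(type = type, tail = tail, n_maxima = n_max)
}

#' Zone specification for a synthetic scene
#'
#' @param zone_id Positive integer id.
#' @param centre `c(row, col)` of the CBD peak in pixels.
#' @param peak Peak radiance of the CBD in nW/cm2/sr.
#' @param decay Exponential decay length of the bright core, in pixels.
#' @param suppression A profile from [suppr_none()] and friends.
#' @param hospital_pixels Number of pixels near the CBD that brighten
#'   during the epidemic (treatment / screening infrastructure).
#' @param hospital_boost Additive radiance on hospital pixels while the
#'   zone is suppressed, nW/cm2/sr.
#' @param cases `NULL`, or `list(K, r, t0)` logistic cumulative-case
#'   parameters (final size, growth rate per day, midpoint date).
#' @param iict_level Mean intra-city travel-intensity index of the zone.
#' @param name,parent_id Metadata.
#' @return A zone-spec list.
#' @export
zone_spec <- function(zone_id, centre, peak, decay,
                      suppression = suppr_none(),
                      hospital_pixels = 0, hospital_boost = 6,
                      cases = NULL, iict_level = 5,
                      name = paste0("city_", zone_id), parent_id = NA) {
  if (decay <= 0) stop("decay length must be positive", call. = FALSE)
  stopifnot(peak > 0, length(centre) == 2)
  list(zone_id = as.integer(zone_id), centre = centre, peak = peak,
       decay = decay, suppression = suppression,
       hospital_pixels = as.integer(hospital_pixels),
       hospital_boost = hospital_boost, cases = cases,
       iict_level = iict_level, name = name, parent_id = parent_id)
}

default_scene_zones <- function() {
  list(
    zone_spec(1, c(12, 12), peak = 120, decay = 4,
              suppression = suppr_epidemic(trough = 0.15), hospital_pixels = 2,
              cases = list(K = 8000, r = 0.22, t0 = "2020-02-05"), iict_level = 6),
    zone_spec(2, c(12, 32), peak = 90, decay = 3.5,
              suppression = suppr_epidemic(trough = 0.30), hospital_pixels = 2,
              cases = list(K = 1500, r = 0.20, t0 = "2020-02-08"), iict_level = 5),
    zone_spec(3, c(12, 50), peak = 150, decay = 4.5,
              suppression = suppr_epidemic(trough = 0.45), hospital_pixels = 2,
              cases = list(K = 900, r = 0.18, t0 = "2020-02-10"), iict_level = 7),
    zone_spec(4, c(42, 12), peak = 60, decay = 3,
              suppression = suppr_epidemic(trough = 0.60), hospital_pixels = 1,
              cases = list(K = 300, r = 0.18, t0 = "2020-02-12"), iict_level = 4),
    zone_spec(5, c(42, 32), peak = 100, decay = 4,
              suppression = suppr_epidemic(trough = 0.75), hospital_pixels = 1,
              cases = list(K = 120, r = 0.15, t0 = "2020-02-12"), iict_level = 5),
    zone_spec(6, c(46, 50), peak = 75, decay = 3.5,
              suppression = suppr_epidemic(trough = 0.90), hospital_pixels = 0,
              cases = list(K = 40, r = 0.15, t0 = "2020-02-15"), iict_level = 4)
  )
}

#' Scene configuration
#'
#' Collects every knob of the synthetic generator. Defaults emulate the
#' study conditions of the January-March 2020 analysis: a 60 x 60 pixel
#' 500 m equal-area grid holding six cities of graded epidemic severity,
#' daily layers for 20 Jan-31 Mar 2020 with the dates outside the three
#' new-moon windows flagged moonlit, a lunar-matched baseline year, a 3%
#' year-over-year development increment on lit pixels, a 0-1 dark floor,
#' and sparse multiplicative spikes outnumbering cloud drops.
#'
#' @param grid An [ntl_grid()].
#' @param zones List of [zone_spec()]s (non-overlapping centres; every
#'   centre must lie on the grid).
#' @param dates Analysis-year `Date` vector.
#' @param moonlit_dates Dates of `dates` flagged (and contaminated) as
#'   moonlit; default: everything outside [moonless_default_dates()].
#' @param lunar `list(mode, offset)` passed to [match_lunar_dates()] to
#'   derive the baseline-year dates.
#' @param development `list(rate)`: additive increment between baseline and
#'   analysis year as a fraction of the lit signal (default 0.03).
#' @param noise `list(dark_range, lit_sd, spike_rate, spike_meanlog,
#'   spike_sdlog, spike_min_factor, cloud_drop_rate, drop_max, moon_glow)`.
#'   `spike_rate`/`cloud_drop_rate` are per pixel-day probabilities; spike
#'   factors are lognormal (median 10x) optionally truncated below at
#'   `spike_min_factor`; drops multiply by U(0, `drop_max`).
#' @param seed RNG seed; identical seed and config give bit-identical
#'   output.
#' @return An object of class `ntl_scene_config`.
#' @export
scene_config <- function(grid = ntl_grid(60, 60),
                         zones = default_scene_zones(),
                         dates = seq(as.Date("2020-01-20"),
                                     as.Date("2020-03-31"), by = "day"),
                         moonlit_dates = NULL,
                         lunar = list(mode = "offset", offset = 12),
                         development = list(rate = 0.03),
                         noise = list(),
                         seed = 1) {
  noise_def <- list(dark_range = c(0, 1), lit_sd = 0.10,
                    spike_rate = 0.005, spike_meanlog = log(10),
                    spike_sdlog = 0.5, spike_min_factor = NULL,
                    cloud_drop_rate = 0.002, drop_max = 0.2,
                    moon_glow = 0.5)
  noise <- utils::modifyList(noise_def, noise)
  stopifnot(noise$spike_rate >= 0, noise$spike_rate <= 1,
            noise$cloud_drop_rate >= 0, noise$cloud_drop_rate <= 1,
            noise$spike_rate + noise$cloud_drop_rate <= 1,
            diff(noise$dark_range) >= 0)
  dates <- as.Date(dates)
  if (is.null(moonlit_dates)) {
    moonlit_dates <- dates[!(dates %in% moonless_default_dates())]
  }
  centres <- t(vapply(zones, function(z) z$centre, numeric(2)))
  if (anyDuplicated(centres)) {
    stop("overlapping zones: duplicated CBD centres", call. = FALSE)
  }
  if (any(centres[, 1] < 1 | centres[, 1] > grid$rows |
          centres[, 2] < 1 | centres[, 2] > grid$cols)) {
    stop("zone centre outside the grid", call. = FALSE)
  }
  structure(list(grid = grid, zones = zones, dates = dates,
                 moonlit_dates = as.Date(moonlit_dates), lunar = lunar,
                 development = development, noise = noise, seed = seed),
            class = "ntl_scene_config")
}

# deterministic hospital pixel offsets around a CBD centre
hospital_offsets <- matrix(c(2, 2, -2, 2, 2, -2, -2, -2, 0, 3, 3, 0),
                           ncol = 2, byrow = TRUE)

#' Generate a synthetic scene
#'
#' Builds the full planted scene from a [scene_config()]: the clean radiance
#' field is `dark floor + sum over zones of peak * exp(-distance / decay)`;
#' the analysis year adds the development increment, applies each zone's
#' suppression profile to its lit pixels (hospital pixels brighten instead),
#' then injects noise; the baseline year is the same field without epidemic
#' or increment, with composite-grade noise (dark fluctuation and lit jitter
#' only). All randomness comes from the single seeded generator in the
#' config.
#'
#' @param config A [scene_config()].
#' @return An object of class `ntl_scene`: a list with `analysis` and
#'   `baseline` [ntl_stack()]s, `zones` ([zone_map()]), `truth` (ground
#'   truth: clean arrays, outlier flags, the s(t) matrix, planted per-zone
#'   deficit by date, lit/hospital masks, trajectory labels), `dev`
#'   (`pre`/`prev` development composites) and the `config`.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "ntl_scene_config"))
  g <- config$grid
  nz <- length(config$zones)
  dates <- config$dates
  nd <- length(dates)
  noise <- config$noise
  dark_mean <- mean(noise$dark_range)
  dark_max <- max(noise$dark_range)

  rows <- matrix(seq_len(g$rows), g$rows, g$cols)
  cols <- matrix(seq_len(g$cols), g$rows, g$cols, byrow = TRUE)

  # clean baseline field and Voronoi zone labels
  b <- matrix(dark_mean, g$rows, g$cols)
  dist2near <- matrix(Inf, g$rows, g$cols)
  labels <- matrix(0L, g$rows, g$cols)
  for (k in seq_len(nz)) {
    z <- config$zones[[k]]
    d <- sqrt((rows - z$centre[1])^2 + (cols - z$centre[2])^2)
    b <- b + z$peak * exp(-d / z$decay)
    upd <- d < dist2near
    labels[upd] <- z$zone_id
    dist2near[upd] <- d[upd]
  }
  lit <- b > dark_max

  hospital <- matrix(FALSE, g$rows, g$cols)
  for (z in config$zones) {
    if (z$hospital_pixels > 0) {
      off <- hospital_offsets[seq_len(min(z$hospital_pixels,
                                          nrow(hospital_offsets))), ,
                              drop = FALSE]
      hr <- pmin(pmax(z$centre[1] + off[, 1], 1), g$rows)
      hc <- pmin(pmax(z$centre[2] + off[, 2], 1), g$cols)
      hospital[cbind(hr, hc)] <- TRUE
    }
  }

  inc <- config$development$rate * (b - dark_mean)

  s <- matrix(1, nz, nd,
              dimnames = list(vapply(config$zones, function(z)
                as.character(z$zone_id), character(1)), format(dates)))
  for (k in seq_len(nz)) {
    s[k, ] <- compile_suppression(config$zones[[k]]$suppression, dates)
  }

  zone_of <- labels  # every pixel belongs to its nearest CBD
  zid <- vapply(config$zones, function(z) z$zone_id, integer(1))
  zrow <- match(zone_of, zid)  # matrix of zone row indices

  # one baseline layer per distinct matched date (the fixed-offset rule
  # collapses 29 Feb onto its neighbour's match in a leap year)
  dates_base <- sort(unique(match_lunar_dates(dates,
                                              mode = config$lunar$mode,
                                              offset = config$lunar$offset)))

  clean_a <- array(NA_real_, c(g$rows, g$cols, nd))
  for (t in seq_len(nd)) {
    st <- matrix(s[cbind(as.vector(zrow), t)], g$rows, g$cols)
    layer <- b + inc
    suppress <- lit & !hospital
    layer[suppress] <- layer[suppress] * st[suppress]
    boost_on <- hospital & (matrix(st, g$rows, g$cols) < 1)
    for (z in config$zones) {
      if (z$hospital_pixels > 0 && s[match(z$zone_id, zid), t] < 1) {
        hz <- hospital & zone_of == z$zone_id
        layer[hz] <- layer[hz] + z$hospital_boost
      }
    }
    clean_a[, , t] <- layer
  }

  res <- with_seed(config$seed, {
    av <- array(NA_real_, c(g$rows, g$cols, nd))
    flags <- array(0L, c(g$rows, g$cols, nd))
    moonlit <- dates %in% config$moonlit_dates
    npix <- g$rows * g$cols
    dark_idx <- which(!lit)
    lit_idx <- which(lit)
    for (t in seq_len(nd)) {
      layer <- clean_a[, , t]
      # dark-floor fluctuation replaces the constant floor component
      if (diff(noise$dark_range) > 0) {
        layer[dark_idx] <- layer[dark_idx] - dark_mean +
          stats::runif(length(dark_idx), noise$dark_range[1],
                       noise$dark_range[2])
      }
      # night-to-night jitter on lit pixels
      if (noise$lit_sd > 0) {
        layer[lit_idx] <- layer[lit_idx] *
          stats::rlnorm(length(lit_idx), 0, noise$lit_sd)
      }
      # spikes and drops (a pixel-day gets at most one perturbation)
      u <- stats::runif(npix)
      sp <- which(u < noise$spike_rate)
      dr <- which(u >= noise$spike_rate &
                  u < noise$spike_rate + noise$cloud_drop_rate)
      if (length(sp)) {
        f <- spike_factors(length(sp), noise)
        layer[sp] <- f * pmax(clean_a[, , t][sp], dark_max)
        fl <- flags[, , t]; fl[sp] <- 1L; flags[, , t] <- fl
      }
      if (length(dr)) {
        layer[dr] <- clean_a[, , t][dr] *
          stats::runif(length(dr), 0, noise$drop_max)
        fl <- flags[, , t]; fl[dr] <- 2L; flags[, , t] <- fl
      }
      if (moonlit[t] && noise$moon_glow > 0) {
        layer <- layer + noise$moon_glow
      }
      av[, , t] <- layer
    }

    nb <- length(dates_base)
    bv <- array(NA_real_, c(g$rows, g$cols, nb))
    for (t in seq_len(nb)) {
      layer <- b
      if (diff(noise$dark_range) > 0) {
        layer[dark_idx] <- layer[dark_idx] - dark_mean +
          stats::runif(length(dark_idx), noise$dark_range[1],
                       noise$dark_range[2])
      }
      if (noise$lit_sd > 0) {
        layer[lit_idx] <- layer[lit_idx] *
          stats::rlnorm(length(lit_idx), 0, noise$lit_sd)
      }
      bv[, , t] <- layer
    }
    list(av = av, flags = flags, bv = bv, moonlit = moonlit)
  })

  ztab <- data.frame(
    zone_id = zid,
    name = vapply(config$zones, function(z) z$name, character(1)),
    admin_level = "city",
    parent_id = vapply(config$zones, function(z)
      as.integer(z$parent_id %||% NA_integer_), integer(1)),
    stringsAsFactors = FALSE
  )
  zones <- zone_map(labels, ztab, g)

  # planted radiance deficit per zone and date (clean scale, lit pixels)
  deficit <- matrix(0, nz, nd, dimnames = dimnames(s))
  base_lit <- b + inc
  for (k in seq_len(nz)) {
    mask <- lit & !hospital & zone_of == zid[k]
    tot <- sum(base_lit[mask])
    deficit[k, ] <- (1 - s[k, ]) * tot
  }

  traj <- data.frame(zone_id = zid, planted_type = NA_character_,
                     planted_tail = NA_character_,
                     realized_type = NA_character_,
                     realized_tail = NA_character_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(nz)) {
    pr <- config$zones[[k]]$suppression
    if (pr$kind == "trajectory") {
      traj$planted_type[k] <- pr$type
      traj$planted_tail[k] <- pr$tail
      rl <- realized_trajectory(pr)
      traj$realized_type[k] <- rl$type
      traj$realized_tail[k] <- rl$tail
    }
  }

  truth <- list(clean_analysis = clean_a, clean_baseline = b,
                flags = res$flags, s = s, deficit = deficit, lit = lit,
                hospital = hospital, increment = inc, trajectory = traj)

  structure(list(
    analysis = ntl_stack(res$av, dates, g, moonlit = res$moonlit),
    baseline = ntl_stack(res$bv, dates_base, g),
    zones = zones,
    truth = truth,
    dev = list(pre = ntl_raster(b + inc, g), prev = ntl_raster(b, g)),
    config = config
  ), class = "ntl_scene")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

spike_factors <- function(n, noise) {
  if (is.null(noise$spike_min_factor)) {
    stats::rlnorm(n, noise$spike_meanlog, noise$spike_sdlog)
  } else {
    # truncated-below lognormal via inverse-CDF sampling
    p0 <- stats::plnorm(noise$spike_min_factor, noise$spike_meanlog,
                        noise$spike_sdlog)
    stats::qlnorm(stats::runif(n, p0, 1), noise$spike_meanlog,
                  noise$spike_sdlog)
  }
}

#' @export
print.ntl_scene <- function(x, ...) {
  cat(sprintf("<ntl_scene> %d zones, %d analysis dates, seed %d\n",
              nrow(x$zones$table), length(x$analysis$dates), x$config$seed))
  invisible(x)
}

#' Synthetic epidemic case table
#'
#' Cumulative confirmed cases follow each zone's logistic curve
#' `K / (1 + exp(-r (t - t0)))`; cured counts ramp up behind confirmed with
#' a lag, deaths are a small fixed fraction, and the suspected count is a
#' noisy hump around the growth phase. By construction confirmed is
#' nondecreasing and `cured + dead <= confirmed` on every date. Zones
#' without case parameters report zero on all dates.
#'
#' @param config A [scene_config()].
#' @param cfr Case-fatality fraction (default 0.04).
#' @param cure_lag Days between confirmation and resolution (default 14).
#' @return Data frame `(zone_id, date, confirmed, suspected, cured, dead,
#'   existing)` with `existing = confirmed - cured - dead`.
#' @export
make_case_table <- function(config, cfr = 0.04, cure_lag = 14) {
  dates <- config$dates
  t <- as.numeric(dates - min(dates))
  out <- list()
  with_seed(config$seed + 1L, {
    for (z in config$zones) {
      if (is.null(z$cases)) {
        con <- sus <- cur <- dd <- rep(0, length(dates))
      } else {
        t0 <- as.numeric(as.Date(z$cases$t0) - min(dates))
        con <- round(z$cases$K / (1 + exp(-z$cases$r * (t - t0))))
        con_lag <- round(z$cases$K /
                           (1 + exp(-z$cases$r * (t - cure_lag - t0))))
        dd <- floor(con_lag * cfr)
        cur <- floor(con_lag * (1 - cfr))
        growth <- c(0, diff(con))
        sus <- round(stats::rpois(length(dates), lambda = 2 * growth + 0.5))
      }
      out[[length(out) + 1L]] <- data.frame(
        zone_id = z$zone_id, date = dates, confirmed = con, suspected = sus,
        cured = cur, dead = dd, existing = con - cur - dd)
    }
  })
  do.call(rbind, out)
}

# Spring-Festival-anchored seasonality shared by matched lunar dates: a deep
# holiday dip around lunar new year plus a weekly cycle on the lunar day
# index, so the matched baseline cancels seasonality exactly.
iict_seasonality <- function(dates, cny = as.Date("2020-01-25")) {
  ld <- as.numeric(as.Date(dates) - cny)
  dip <- 1 - 0.45 * exp(-(ld + 1)^2 / (2 * 5^2))
  weekly <- 1 + 0.08 * sin(2 * pi * ld / 7)
  dip * weekly
}

#' Synthetic intra-city travel-intensity (IICT) series
#'
#' Generates dimensionless mobility-index series for both years: the
#' baseline year follows a Spring-Festival-anchored seasonal curve (deep
#' holiday dip plus a weekly cycle, indexed by lunar day so matched dates
#' share it exactly); the analysis year multiplies the same curve by the
#' zone's suppression profile s(t) and lognormal observation noise.
#'
#' @param config A [scene_config()].
#' @param noise_sd Lognormal sd of observation noise (default 0.03; 0 for
#'   noise-free series).
#' @return Data frame `(zone_id, date, year, iict)` where `year` is
#'   `"analysis"` or `"baseline"`; baseline rows carry the lunar-matched
#'   dates.
#' @export
make_mobility_series <- function(config, noise_sd = 0.03) {
  dates <- config$dates
  dates_base <- match_lunar_dates(dates, mode = config$lunar$mode,
                                  offset = config$lunar$offset)
  cny_a <- as.Date("2020-01-25")
  cny_b <- as.Date("2019-02-05")
  season <- iict_seasonality(dates, cny_a)
  # baseline seasonality evaluated at the matched dates' lunar position
  season_b <- iict_seasonality_base(dates_base, cny_b)
  out <- list()
  with_seed(config$seed + 2L, {
    for (z in config$zones) {
      s <- compile_suppression(z$suppression, dates)
      eps_a <- if (noise_sd > 0)
        stats::rlnorm(length(dates), 0, noise_sd) else 1
      eps_b <- if (noise_sd > 0)
        stats::rlnorm(length(dates), 0, noise_sd) else 1
      out[[length(out) + 1L]] <- rbind(
        data.frame(zone_id = z$zone_id, date = dates, year = "analysis",
                   iict = z$iict_level * season * s * eps_a),
        data.frame(zone_id = z$zone_id, date = dates_base, year = "baseline",
                   iict = z$iict_level * season_b * eps_b)
      )
    }
  })
  do.call(rbind, out)
}

iict_seasonality_base <- function(dates, cny) iict_seasonality(dates, cny)
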