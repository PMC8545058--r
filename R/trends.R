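#' Daily intensity-difference series per zone
#'
#' Builds the deficit (D) and excess (I) series that the trajectory typing
#' works on. Membership masks are fixed once per comparison period: a pixel
#' belongs to the deficit mask if its period-aggregate analysis-year mean is
#' below the matched baseline value, to the excess mask if above (supplying
#' `masks` overrides this). Then for each retained date `t`,
#' `D(t) = sum over deficit-mask pixels of (value(t) - baseline)` and
#' `I(t)` likewise over the excess mask; units nW/cm2/sr.
#'
#' @param stack Preprocessed analysis-year [ntl_stack()] (retained dates
#'   only).
#' @param baseline An [ntl_raster()]: the matched baseline composite
#'   (constant per pixel within the period).
#' @param zones A [zone_map()].
#' @param masks Optional list per zone id of `list(decrease =, increase =)`
#'   logical matrices; default derived from the period-aggregate sign.
#' @return Data frame `(zone_id, date, d_value, i_value)`, with the mask
#'   list in attribute `"masks"` and zones whose masks are empty flagged in
#'   attribute `"flagged"` (their series are identically zero).
#' @export
daily_difference_series <- function(stack, baseline, zones, masks = NULL) {
  check_same_grid(stack$grid, baseline$grid, "stack and baseline")
  check_same_grid(stack$grid, zones$grid, "stack and zone map")
  ids <- zone_ids(zones)
  if (is.null(masks)) {
    agg <- stack_mean(stack)$values
    diff_sign <- agg - baseline$values
    masks <- lapply(ids, function(id) {
      inzone <- zones$labels == id
      list(decrease = inzone & !is.na(diff_sign) & diff_sign < 0,
           increase = inzone & !is.na(diff_sign) & diff_sign > 0)
    })
    names(masks) <- as.character(ids)
  }
  nd <- n_layers(stack)
  out <- vector("list", length(ids))
  flagged <- logical(length(ids))
  for (k in seq_along(ids)) {
    mk <- masks[[as.character(ids[k])]]
    flagged[k] <- !any(mk$decrease) && !any(mk$increase)
    dvals <- ivals <- numeric(nd)
    for (t in seq_len(nd)) {
      layer <- stack$values[, , t]
      dif <- layer - baseline$values
      dvals[t] <- sum(dif[mk$decrease], na.rm = TRUE)
      ivals[t] <- sum(dif[mk$increase], na.rm = TRUE)
    }
    out[[k]] <- data.frame(zone_id = ids[k], date = stack$dates,
                           d_value = dvals, i_value = ivals)
  }
  res <- do.call(rbind, out)
  attr(res, "masks") <- masks
  attr(res, "flagged") <- ids[flagged]
  res
}

# compose polynomial p(a*t + b) given coefficients of p(u) (ascending)
poly_compose_linear <- function(coefs, a, b) {
  deg <- length(coefs) - 1L
  out <- numeric(deg + 1L)
  lin_pow <- 1  # (a t + b)^k coefficients, ascending
  for (k in 0:deg) {
    out[seq_along(lin_pow)] <- out[seq_along(lin_pow)] + coefs[k + 1] * lin_pow
    # multiply by (b + a t)
    lin_pow <- c(lin_pow * b, 0) + c(0, lin_pow * a)
  }
  out
}

poly_eval <- function(coefs, u) {
  drop(outer(u, 0:(length(coefs) - 1L), "^") %*% coefs)
}

poly_deriv <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  coefs[-1] * seq_len(length(coefs) - 1L)
}

#' Fit a fifth-order polynomial trend line
#'
#' Least-squares fit of a degree-`degree` polynomial to a dated series. For
#' numerical conditioning the day index is affinely mapped to `[-1, 1]`
#' before fitting; coefficients are reported in both the scaled basis and
#' the original day-offset basis (days since the first observation).
#'
#' @param dates Observation dates (`Date` or numeric day index).
#' @param values Series values (same length; at least `degree + 2`
#'   observations).
#' @param degree Polynomial degree (default 5).
#' @return List of class `ntl_polyfit`: `coef_scaled` (ascending powers of
#'   the scaled index `u`), `coef_days` (ascending powers of days since the
#'   first date), `r2`, `fitted`, `dates`, `window` (first/last date) and
#'   the affine map `u = a * day + b`.
#' @export
fit_polyline <- function(dates, values, degree = 5) {
  t <- if (inherits(dates, "Date")) as.numeric(dates - min(dates)) else
    as.numeric(dates) - min(as.numeric(dates))
  stopifnot(length(t) == length(values))
  keep <- is.finite(values)
  t <- t[keep]; y <- values[keep]
  if (length(y) < degree + 2) {
    stop(sprintf("need at least %d observations for a degree-%d fit",
                 degree + 2, degree), call. = FALSE)
  }
  a <- 2 / (max(t) - min(t))
  b <- -1 - a * min(t)
  u <- a * t + b
  X <- outer(u, 0:degree, "^")
  fit <- stats::lm.fit(X, y)
  cs <- fit$coefficients
  cs[is.na(cs)] <- 0
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    coef_scaled = unname(cs),
    coef_days = poly_compose_linear(unname(cs), a, b),
    r2 = if (sst > 0) 1 - ssr / sst else NA_real_,
    fitted = unname(fit$fitted.values),
    dates = if (inherits(dates, "Date")) dates[keep] else NULL,
    day_index = t,
    window = range(u),
    transform = c(a = a, b = b),
    degree = degree
  ), class = "ntl_polyfit")
}

#' Classify a recovery trajectory from its fitted deficit trend
#'
#' Types a zone from the shape of its fitted D-line on the observation
#' window: the fitted polynomial's strict local maxima strictly inside the
#' window are counted via the real roots of its derivative — two maxima is
#' an "M" trajectory (two recovery phases), one is "inverted-U" (a single
#' recovery phase). Zero or more than two maxima fall back to the nearest
#' class by maxima count and are flagged low-confidence. The tail is "up"
#' (further recovery expected) when the derivative at the window's right
#' end is positive, "down" (relapse) when negative; a derivative of exactly
#' zero defers to the second derivative's sign and is flagged.
#'
#' @param fit An `ntl_polyfit` from [fit_polyline()].
#' @param eps Root tolerances: imaginary parts below `eps` count as real,
#'   roots within `eps` of the window ends are endpoint extrema and never
#'   counted.
#' @return List `(type, tail, n_maxima, maxima_u, low_confidence)`.
#' @export
classify_trajectory <- function(fit, eps = 1e-8) {
  cs <- fit$coef_scaled
  d1 <- poly_deriv(cs)
  d2 <- poly_deriv(d1)
  win <- fit$window
  roots <- polyroot(d1)
  re <- Re(roots)[abs(Im(roots)) < eps]
  interior <- re[re > win[1] + eps & re < win[2] - eps]
  curv <- poly_eval(d2, interior)
  maxima <- sort(interior[curv < 0])
  n_max <- length(maxima)
  low_conf <- !(n_max %in% c(1L, 2L))
  type <- if (n_max >= 2) "M" else "inverted-U"
  slope_end <- poly_eval(d1, win[2])
  if (abs(slope_end) < eps) {
    tail <- if (poly_eval(d2, win[2]) > 0) "up" else "down"
    low_conf <- TRUE
  } else {
    tail <- if (slope_end > 0) "up" else "down"
  }
  list(type = type, tail = tail, n_maxima = n_max, maxima_u = maxima,
       low_confidence = low_conf)
}

#' Fit and classify trend lines for every zone
#'
#' Convenience wrapper running [fit_polyline()] on each zone's deficit
#' (D) and excess (I) series and [classify_trajectory()] on the D-line.
#'
#' @param series Data frame from [daily_difference_series()].
#' @param degree Polynomial degree (default 5).
#' @return Data frame `(zone_id, type, tail, n_maxima, low_confidence,
#'   r2_d, r2_i)` with the fit objects in attribute `"fits"`.
#' @export
zone_trends <- function(series, degree = 5) {
  ids <- unique(series$zone_id)
  fits <- list()
  out <- data.frame(zone_id = ids, type = NA_character_,
                    tail = NA_character_, n_maxima = NA_integer_,
                    low_confidence = NA, r2_d = NA_real_, r2_i = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    zs <- series[series$zone_id == ids[k], , drop = FALSE]
    fd <- fit_polyline(zs$date, zs$d_value, degree)
    fi <- fit_polyline(zs$date, zs$i_value, degree)
    cl <- classify_trajectory(fd)
    out$type[k] <- cl$type
    out$tail[k] <- cl$tail
    out$n_maxima[k] <- cl$n_maxima
    out$low_confidence[k] <- cl$low_confidence
    out$r2_d[k] <- fd$r2
    out$r2_i[k] <- fi$r2
    fits[[as.character(ids[k])]] <- list(d = fd, i = fi)
  }
  attr(out, "fits") <- fits
  out
}
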