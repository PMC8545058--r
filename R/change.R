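#' Existing infections from cumulative counts
#'
#' The number of infections under treatment: cumulative confirmed minus
#' cured minus dead. Rows violating `confirmed >= cured + dead` are data
#' errors; they are quarantined (returned separately), not silently fixed.
#'
#' @param confirmed,cured,dead Nonnegative cumulative counts (vectors of a
#'   common length).
#' @return Numeric vector of existing-infection counts.
#' @export
existing_infections <- function(confirmed, cured, dead) {
  stopifnot(length(cured) == length(confirmed),
            length(dead) == length(confirmed))
  if (any(confirmed < 0 | cured < 0 | dead < 0, na.rm = TRUE)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (any(confirmed < cured + dead, na.rm = TRUE)) {
    stop("validation error: confirmed < cured + dead", call. = FALSE)
  }
  confirmed - cured - dead
}

#' Validate and complete a case table
#'
#' Applies the existing-infection identity to a case table, quarantining
#' rows where `confirmed < cured + dead`.
#'
#' @param cases Data frame with columns `zone_id`, `date`, `confirmed`,
#'   `cured`, `dead` (extra columns pass through).
#' @return List of `clean` (with an `existing` column) and `quarantined`
#'   (invalid rows).
#' @export
clean_case_table <- function(cases) {
  bad <- with(cases, confirmed < cured + dead | confirmed < 0 |
                cured < 0 | dead < 0)
  bad[is.na(bad)] <- TRUE
  clean <- cases[!bad, , drop = FALSE]
  clean$existing <- clean$confirmed - clean$cured - clean$dead
  list(clean = clean, quarantined = cases[bad, , drop = FALSE])
}

#' Development index raster
#'
#' The per-pixel year-over-year radiance increment between two matched
#' pre-outbreak composites, used to remove secular growth from the change
#' signal: `D = d_pre - d_prev`. Nodata in either operand propagates.
#'
#' @param d_pre Pre-outbreak composite of the analysis winter
#'   ([ntl_raster()]).
#' @param d_prev Composite of the same lunar window one year earlier.
#' @return An [ntl_raster()] of development increments.
#' @export
development_index <- function(d_pre, d_prev) {
  check_same_grid(d_pre$grid, d_prev$grid, "development composites")
  ntl_raster(d_pre$values - d_prev$values, d_pre$grid)
}

CLASS_DECREASE <- -1L
CLASS_BACKGROUND <- 0L
CLASS_INCREASE <- 1L

#' Development-corrected radiance change
#'
#' Per-pixel change in nighttime light between the outbreak period and its
#' lunar-matched baseline, corrected for secular development:
#' `CNTL = R - r - D`. Pixels are then classified by two thresholds:
#' `CNTL < low` is a decrease (suppressed activity), `CNTL > high` an
#' increase (e.g. hospitals, control infrastructure), anything else
#' background fluctuation. Both inequalities are strict, so values exactly
#' at a threshold are background. Nodata in any operand gives nodata CNTL,
#' excluded from classes.
#'
#' @param R Mean outbreak-period raster ([ntl_raster()]).
#' @param r Matched baseline raster.
#' @param D Development index from [development_index()]; `NULL` for an
#'   uncorrected comparison.
#' @param thresholds `c(low, high)` in nW/cm2/sr, default `c(-1, 3)`.
#' @return An object of class `ntl_change`: `cntl` matrix, `class` matrix
#'   (-1 decrease, 0 background, +1 increase, NA nodata), `thresholds`,
#'   `grid`.
#' @export
cntl <- function(R, r, D = NULL, thresholds = c(-1, 3)) {
  check_same_grid(R$grid, r$grid, "outbreak and baseline rasters")
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  dv <- if (is.null(D)) 0 else {
    check_same_grid(R$grid, D$grid, "change and development rasters")
    D$values
  }
  v <- R$values - r$values - dv
  cls <- matrix(CLASS_BACKGROUND, nrow(v), ncol(v))
  cls[v < thresholds[1]] <- CLASS_DECREASE
  cls[v > thresholds[2]] <- CLASS_INCREASE
  cls[is.na(v)] <- NA_integer_
  structure(list(cntl = v, class = cls, thresholds = thresholds,
                 grid = R$grid),
            class = "ntl_change")
}

#' @export
print.ntl_change <- function(x, ...) {
  cat(sprintf(
    "<ntl_change> %d x %d, thresholds (%g, %g): %d decrease / %d background / %d increase\n",
    nrow(x$cntl), ncol(x$cntl), x$thresholds[1], x$thresholds[2],
    sum(x$class == CLASS_DECREASE, na.rm = TRUE),
    sum(x$class == CLASS_BACKGROUND, na.rm = TRUE),
    sum(x$class == CLASS_INCREASE, na.rm = TRUE)))
  invisible(x)
}

#' Per-zone affected areas
#'
#' Areas of the decrease and increase classes per zone, in km2. Requires an
#' equal-area grid (area is pixel count times pixel area). The affected
#' area of a zone is the sum of its decrease and increase areas.
#'
#' @param change An `ntl_change` from [cntl()].
#' @param zones A [zone_map()] on the same grid.
#' @return Data frame `(zone_id, area_decrease_km2, area_increase_km2,
#'   area_total_km2)`.
#' @export
affected_area <- function(change, zones) {
  check_same_grid(change$grid, zones$grid, "change raster and zone map")
  if (!change$grid$equal_area) {
    stop("area undefined on a non-equal-area grid", call. = FALSE)
  }
  km2 <- (change$grid$pixel_size^2) / 1e6
  ids <- zone_ids(zones)
  dec <- inc <- numeric(length(ids))
  for (k in seq_along(ids)) {
    inzone <- zones$labels == ids[k]
    dec[k] <- sum(change$class[inzone] == CLASS_DECREASE, na.rm = TRUE) * km2
    inc[k] <- sum(change$class[inzone] == CLASS_INCREASE, na.rm = TRUE) * km2
  }
  data.frame(zone_id = ids, area_decrease_km2 = dec, area_increase_km2 = inc,
             area_total_km2 = dec + inc)
}
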