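#' Match analysis-year dates to the lunar-calendar baseline year
#'
#' Pairs each 2020 date with the 2019 date occupying the same position in
#' the Chinese lunisolar calendar, so Spring-Festival effects cancel when
#' the two years are compared.
#'
#' Two modes:
#' * `"table"` — exact lunisolar correspondence, anchored at Chinese New
#'   Year (lunar 1/1): 25 Jan 2020 and 5 Feb 2019. The matched date keeps
#'   the analysis date's offset from New Year.
#' * `"offset"` — same calendar day of the previous year shifted by a fixed
#'   number of days (default +12). This reproduces the conventional period
#'   pairing (1 Mar 2020 -> 13 Mar 2019) but drifts one day from the true
#'   lunisolar table before 1 March because 2020 is a leap year.
#'
#' @param dates `Date` vector in the analysis year (supported range
#'   Dec 2019 - Jun 2020 for table mode).
#' @param mode `"offset"` (default) or `"table"`.
#' @param offset Day shift for offset mode (default 12).
#' @return `Date` vector of matched baseline-year dates.
#' @export
match_lunar_dates <- function(dates, mode = c("offset", "table"),
                              offset = 12) {
  mode <- match.arg(mode)
  dates <- as.Date(dates)
  if (mode == "table") {
    lo <- as.Date("2019-12-01"); hi <- as.Date("2020-06-30")
    if (any(dates < lo | dates > hi)) {
      stop("date outside the embedded lunisolar table (Dec 2019 - Jun 2020)",
           call. = FALSE)
    }
    return(as.Date("2019-02-05") + as.numeric(dates - as.Date("2020-01-25")))
  }
  # same calendar day, previous year (29 Feb maps to 1 Mar), plus offset
  lt <- as.POSIXlt(dates)
  lt$year <- lt$year - 1L
  prev <- as.Date(lt)
  prev[is.na(prev)] <- as.Date(sprintf("%d-03-01",
                                       1900L + as.POSIXlt(dates)$year - 1L))[is.na(prev)]
  prev + offset
}

#' Default analysis periods
#'
#' The standard period set: the outbreak period S1 (23 Jan - 18 Feb 2020),
#' the recovery period S2 (19 Feb - 31 Mar 2020), and its February
#' (19-29 Feb 2020, matched 3-12 Mar 2019) and March (1-31 Mar 2020,
#' matched 13 Mar - 12 Apr 2019) recovery windows. Matched baseline ranges
#' follow the +12-day lunar offset convention.
#'
#' @return Data frame `(name, role, start, end, start_matched, end_matched)`.
#' @export
period_defaults <- function() {
  data.frame(
    name = c("S1", "S2", "feb_recovery", "mar_recovery"),
    role = c("outbreak", "recovery", "feb-recovery", "mar-recovery"),
    start = as.Date(c("2020-01-23", "2020-02-19", "2020-02-19", "2020-03-01")),
    end = as.Date(c("2020-02-18", "2020-03-31", "2020-02-29", "2020-03-31")),
    start_matched = as.Date(c("2019-02-04", "2019-03-03", "2019-03-03",
                              "2019-03-13")),
    end_matched = as.Date(c("2019-03-02", "2019-04-12", "2019-03-12",
                            "2019-04-12")),
    stringsAsFactors = FALSE
  )
}

#' Per-zone recovery degree
#'
#' The recovery degree of a zone is the ratio of its summed radiance over
#' the analysis-year period to its summed radiance over the lunar-matched
#' baseline period: `RNTL = sum(R') / sum(r')`, summing over the zone's
#' pixels and the periods' days. `RNTL >= 1` means fully recovered. The
#' ratio of raw sums is used as defined; with `normalize = TRUE` each sum
#' is divided by its day count (for deliberately unequal window lengths).
#'
#' The caller supplies period-subset stacks; symmetric moonless filtering
#' (retaining only matched date pairs both of which survive screening) is
#' the responsibility of the pipeline when daily baselines are in use.
#'
#' @param stack_2020 [ntl_stack()] over the analysis period.
#' @param stack_2019 [ntl_stack()] over the matched baseline period.
#' @param zones A [zone_map()] on the same grid.
#' @param normalize Divide each sum by its day count (default `FALSE`).
#' @return Data frame `(zone_id, rntl, sum_2020, sum_2019, n_days_2020,
#'   n_days_2019, recovered, flagged)`; `rntl` is `NA` and `flagged` `TRUE`
#'   when the baseline sum is not positive.
#' @export
rntl <- function(stack_2020, stack_2019, zones, normalize = FALSE) {
  check_same_grid(stack_2020$grid, stack_2019$grid, "the two years' stacks")
  check_same_grid(stack_2020$grid, zones$grid, "stacks and zone map")
  if (n_layers(stack_2020) == 0L || n_layers(stack_2019) == 0L) {
    stop("both period stacks must be nonempty", call. = FALSE)
  }
  tot20 <- stack_sum(stack_2020)$values
  tot19 <- stack_sum(stack_2019)$values
  ids <- zone_ids(zones)
  num <- den <- numeric(length(ids))
  for (k in seq_along(ids)) {
    inzone <- zones$labels == ids[k]
    num[k] <- sum(tot20[inzone], na.rm = TRUE)
    den[k] <- sum(tot19[inzone], na.rm = TRUE)
  }
  if (normalize) {
    num <- num / n_layers(stack_2020)
    den <- den / n_layers(stack_2019)
  }
  flagged <- den <= 0
  value <- ifelse(flagged, NA_real_, num / den)
  data.frame(zone_id = ids, rntl = value, sum_2020 = num, sum_2019 = den,
             n_days_2020 = n_layers(stack_2020),
             n_days_2019 = n_layers(stack_2019),
             recovered = !flagged & value >= 1, flagged = flagged)
}

#' Mobility recovery ratio
#'
#' Daily ratio of the analysis-year intra-city travel intensity to the
#' lunar-matched baseline value: `m = P / p`. Days with a nonpositive
#' baseline are undefined and flagged.
#'
#' @param P Analysis-year IICT values.
#' @param p Matched baseline-year IICT values (same length).
#' @return Numeric vector of ratios (`NA` where `p <= 0`).
#' @export
iict_recovery <- function(P, p) {
  stopifnot(length(P) == length(p))
  ifelse(is.finite(p) & p > 0, P / p, NA_real_)
}

#' Period-level mobility recovery per zone
#'
#' Averages the daily [iict_recovery()] ratios over a period for each zone,
#' pairing each analysis date with its lunar-matched baseline date.
#'
#' @param mobility Long data frame from [make_mobility_series()] (columns
#'   `zone_id`, `date`, `year`, `iict`).
#' @param period_start,period_end Analysis-year period bounds (`Date`).
#' @param lunar_mode,offset Matching rule (see [match_lunar_dates()]).
#' @return Data frame `(zone_id, m, n_days)`.
#' @export
iict_period_recovery <- function(mobility, period_start, period_end,
                                 lunar_mode = "offset", offset = 12) {
  period_start <- as.Date(period_start); period_end <- as.Date(period_end)
  a <- mobility[mobility$year == "analysis" &
                  mobility$date >= period_start &
                  mobility$date <= period_end, , drop = FALSE]
  b <- mobility[mobility$year == "baseline", , drop = FALSE]
  a$date_matched <- match_lunar_dates(a$date, mode = lunar_mode,
                                      offset = offset)
  key_a <- paste(a$zone_id, a$date_matched)
  key_b <- paste(b$zone_id, b$date)
  a$p <- b$iict[match(key_a, key_b)]
  a$m <- iict_recovery(a$iict, a$p)
  agg <- stats::aggregate(m ~ zone_id, data = a, FUN = mean, na.rm = TRUE)
  n <- stats::aggregate(cbind(n_days = !is.na(a$m)) ~ zone_id, data = a,
                        FUN = sum)
  merge(agg, n, by = "zone_id")
}

#' Agreement cross-tabulation of the two recovery measures
#'
#' Bins the light-based (RNTL) and mobility-based (m) recovery degrees into
#' shared bands and counts zones per cell; the diagonal mass measures
#' agreement. Also reports, for a cut-off recovery level, the fraction of
#' zones above it by light that are also above it by mobility (the
#' verification statistic used for recovery maps).
#'
#' @param rntl_table Data frame with `zone_id` and `rntl`.
#' @param m_table Data frame with `zone_id` and `m`.
#' @param edges Ascending bin edges; default `c(0.3, 0.6, 0.8, 1, Inf)`
#'   giving bands \[0.3, 0.6), \[0.6, 0.8), \[0.8, 1), \[1, Inf).
#' @param threshold Cut-off for the agreement fraction (default 0.6).
#' @return List: `table` (NTL bins x IICT bins), `agreement`
#'   (`n_ntl_above`, `n_both_above`, `fraction`), `excluded` (zone ids
#'   present in only one input or outside the binned range).
#' @export
recovery_crosstab <- function(rntl_table, m_table,
                              edges = c(0.3, 0.6, 0.8, 1, Inf),
                              threshold = 0.6) {
  stopifnot(length(edges) >= 2, !is.unsorted(edges))
  shared <- merge(rntl_table[, c("zone_id", "rntl")],
                  m_table[, c("zone_id", "m")], by = "zone_id")
  shared <- shared[is.finite(shared$rntl) & is.finite(shared$m), ,
                   drop = FALSE]
  if (nrow(shared) == 0L) {
    stop("no zones shared between the two recovery tables", call. = FALSE)
  }
  excluded <- setdiff(union(rntl_table$zone_id, m_table$zone_id),
                      shared$zone_id)
  lab <- paste0("[", utils::head(edges, -1), ",", utils::tail(edges, -1), ")")
  bin_ntl <- cut(shared$rntl, edges, right = FALSE, labels = lab)
  bin_m <- cut(shared$m, edges, right = FALSE, labels = lab)
  oob <- is.na(bin_ntl) | is.na(bin_m)
  excluded <- c(excluded, shared$zone_id[oob])
  tab <- table(ntl = bin_ntl[!oob], iict = bin_m[!oob])
  above <- shared$rntl >= threshold
  both <- above & shared$m >= threshold
  list(table = tab,
       agreement = list(n_ntl_above = sum(above), n_both_above = sum(both),
                        fraction = if (sum(above) > 0)
                          sum(both) / sum(above) else NA_real_),
       excluded = excluded)
}

#' Recovery-fluctuation D-value
#'
#' Difference between a zone's March and February recovery degrees,
#' `RNTL_mar - RNTL_feb`. Negative values mark fluctuating recovery (a city
#' whose March recovery fell back below its February level).
#'
#' @param rntl_mar,rntl_feb Data frames with `zone_id` and `rntl` for the
#'   two recovery windows.
#' @return Data frame `(zone_id, rntl_feb, rntl_mar, d_value)`; `d_value`
#'   is `NA` when either period is missing.
#' @export
d_value <- function(rntl_mar, rntl_feb) {
  m <- merge(rntl_feb[, c("zone_id", "rntl")],
             rntl_mar[, c("zone_id", "rntl")],
             by = "zone_id", all = TRUE, suffixes = c("_feb", "_mar"))
  m$d_value <- m$rntl_mar - m$rntl_feb
  m[, c("zone_id", "rntl_feb", "rntl_mar", "d_value")]
}
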