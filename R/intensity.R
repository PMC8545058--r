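#' Zone-level influence intensity
#'
#' Sums the development-corrected change (CNTL) over each zone to the
#' influence-intensity statistic `SCNTL = sum(CNTL_i)`; the more negative,
#' the harder the zone was hit. By default the sum runs over the zone's
#' classified (decrease or increase) pixels only — the affected area —
#' reported together with its decrease-only and increase-only components;
#' `mode = "raw"` sums CNTL over all valid pixels instead.
#'
#' @param change An `ntl_change` from [cntl()].
#' @param zones A [zone_map()] on the same grid.
#' @param mode `"classified"` (default) or `"raw"`.
#' @return Data frame `(zone_id, scntl, sum_decrease, sum_increase,
#'   n_classified, flagged)`; `flagged` marks zones with no classified
#'   pixel (SCNTL 0 by convention).
#' @export
scntl <- function(change, zones, mode = c("classified", "raw")) {
  mode <- match.arg(mode)
  check_same_grid(change$grid, zones$grid, "change raster and zone map")
  ids <- zone_ids(zones)
  out <- data.frame(zone_id = ids, scntl = 0, sum_decrease = 0,
                    sum_increase = 0, n_classified = 0L, flagged = FALSE)
  for (k in seq_along(ids)) {
    inzone <- zones$labels == ids[k]
    dec <- inzone & !is.na(change$class) & change$class == CLASS_DECREASE
    inc <- inzone & !is.na(change$class) & change$class == CLASS_INCREASE
    out$sum_decrease[k] <- sum(change$cntl[dec])
    out$sum_increase[k] <- sum(change$cntl[inc])
    out$n_classified[k] <- sum(dec) + sum(inc)
    out$scntl[k] <- if (mode == "classified") {
      out$sum_decrease[k] + out$sum_increase[k]
    } else {
      sum(change$cntl[inzone], na.rm = TRUE)
    }
    out$flagged[k] <- out$n_classified[k] == 0L
  }
  out
}

#' Jenks natural-breaks classification
#'
#' Exact one-dimensional natural breaks: partitions sorted values into `k`
#' contiguous classes minimising the total within-class sum of squared
#' deviations (Fisher's dynamic programme, so the optimum is global, not
#' the heuristic reallocation variant). Returned edges are
#' `c(min, class maxima)`: `k + 1` monotone edges whose interior entries
#' are the largest value of each class.
#'
#' @param values Numeric vector (at least `k` distinct values).
#' @param k Number of classes (default 5).
#' @param round_to Optional rounding unit for the edges (e.g. `1e4` to
#'   present edges as multiples of 10 000); `NULL` (default) leaves edges
#'   at the data values.
#' @return Numeric vector of `k + 1` ascending edges, with attribute
#'   `"assignment"` giving each input value's class (1 = lowest band).
#' @export
jenks_breaks <- function(values, k = 5, round_to = NULL) {
  x <- sort(values)
  n <- length(x)
  if (length(unique(x)) < k) {
    stop(sprintf("need at least %d distinct values for %d classes", k, k),
         call. = FALSE)
  }
  # prefix sums for O(1) within-class SSD of x[i..j]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # dp[m, j]: minimal total SSD splitting x[1..j] into m classes
  dp <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in seq_len(n)) dp[1, j] <- ssd(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf; arg <- 0L
        for (i in m:j) {  # class m is x[i..j]
          v <- dp[m - 1, i - 1] + ssd(i, j)
          if (v < best) { best <- v; arg <- i }
        }
        dp[m, j] <- best
        cut[m, j] <- arg
      }
    }
  }
  # backtrack class boundaries
  upper <- integer(k)
  j <- n
  for (m in k:1) {
    upper[m] <- j
    j <- cut[m, j] - 1L
  }
  edges <- c(x[1], x[upper])
  if (!is.null(round_to)) edges <- round(edges / round_to) * round_to
  assignment <- findInterval(values, x[upper[-k]] + 0,
                             left.open = TRUE) + 1L
  attr(edges, "assignment") <- assignment
  attr(edges, "gvf") <- 1 - dp[k, n] / ssd(1, n)
  edges
}

#' Preset intensity-level edges
#'
#' The published five-level banding of zone influence intensity, in
#' nW/cm2/sr: I (very high impact) −240 000 to −150 000, II −150 000 to
#' −60 000, III −60 000 to −30 000, IV −30 000 to −10 000, V −10 000 to 0.
#'
#' @return Numeric vector of 6 ascending edges.
#' @export
intensity_breaks_preset <- function() {
  c(-240000, -150000, -60000, -30000, -10000, 0)
}

#' Grade an influence intensity into levels I-V
#'
#' Level I is the most negative band (very high impact), level V the band
#' nearest zero (very low). Bands are half-open `(lower, upper]` with the
#' lowest band closed at both ends, so a value exactly on a shared edge
#' belongs to the more severe (more negative) band. Values outside the
#' edge range are clamped to the nearest band with a warning.
#'
#' @param values Numeric vector of SCNTL values.
#' @param edges `k + 1` ascending band edges (default the preset of
#'   [intensity_breaks_preset()]).
#' @return Integer vector of levels (1 = I most severe), with class labels
#'   as a `"roman"` attribute.
#' @export
classify_level <- function(values, edges = intensity_breaks_preset()) {
  stopifnot(!is.unsorted(edges), length(edges) >= 3)
  k <- length(edges) - 1L
  out_of_range <- values < edges[1] | values > edges[k + 1]
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sprintf("%d value(s) outside the band range; clamped",
                    sum(out_of_range, na.rm = TRUE)))
  }
  # (lower, upper] bands: count edges strictly below the value
  lev <- findInterval(values, edges, left.open = TRUE)
  lev[values <= edges[1]] <- 1L
  lev[values > edges[k + 1]] <- k
  lev <- pmin(pmax(lev, 1L), k)
  lev[is.na(values)] <- NA_integer_
  attr(lev, "roman") <- as.character(utils::as.roman(lev))
  lev
}

# inverse-distance spatial weights on planar centroids
inverse_distance_weights <- function(coords, power = 1,
                                     row_standardize = TRUE) {
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) {
    stop("coincident centroids: inverse-distance weights undefined",
         call. = FALSE)
  }
  w <- 1 / d^power
  diag(w) <- 0
  if (row_standardize) w <- w / rowSums(w)
  w
}

#' Anselin Local Moran's I with conditional-permutation inference
#'
#' Computes the local spatial-autocorrelation statistic
#' `I_i = (x_i - X̄) / S_i^2 * sum_j w_ij (x_j - X̄)` with
#' `S_i^2 = sum_{j != i} (x_j - X̄)^2 / (n - 1)`, using inverse-distance
#' spatial weights on zone centroids. Significance is assessed by
#' conditional permutation: holding `x_i` in place, the remaining values
#' are randomly reassigned to the other zones `n_perm` times and a
#' two-sided pseudo p-value is taken from the rank of the observed `I_i`.
#' Significant zones are typed by the quadrant of the Moran scatterplot:
#' HH / LL clusters (value and spatial lag on the same side of the mean)
#' and HL / LH outliers.
#'
#' @param values Per-zone intensity values (length >= 3, non-constant).
#' @param coords Two-column matrix of zone centroid coordinates.
#' @param zone_id Optional ids for the output (default `1:n`).
#' @param alpha Significance level for category assignment (default 0.05).
#' @param n_perm Number of conditional permutations (default 999).
#' @param seed RNG seed for the permutations (reproducible p-values).
#' @param power Inverse-distance power (default 1).
#' @param row_standardize Row-standardise the weights (default `TRUE`).
#' @return Data frame `(zone_id, value, local_i, z_score, p_value,
#'   category)` with `category` in `HH, HL, LH, LL, not-significant`.
#' @export
local_moran <- function(values, coords, zone_id = NULL, alpha = 0.05,
                        n_perm = 999, seed = 1, power = 1,
                        row_standardize = TRUE) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) stop("need at least 3 zones", call. = FALSE)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n)
  if (stats::sd(x) < 1e-12 * (abs(mean(x)) + 1)) {
    stop("constant intensity values: local Moran's I undefined",
         call. = FALSE)
  }
  if (is.null(zone_id)) zone_id <- seq_len(n)
  w <- inverse_distance_weights(coords, power, row_standardize)
  z <- x - mean(x)
  s2 <- (sum(z^2) - z^2) / (n - 1)
  lag <- as.vector(w %*% z)
  obs <- z / s2 * lag

  perm_i <- matrix(NA_real_, n_perm, n)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      for (i in seq_len(n)) {
        zi <- z[-i][sample.int(n - 1)]
        perm_i[p, i] <- z[i] / s2[i] * sum(w[i, -i] * zi)
      }
    }
  })
  pm <- colMeans(perm_i)
  ps <- apply(perm_i, 2, stats::sd)
  zsc <- (obs - pm) / ps
  p_hi <- (colSums(sweep(perm_i, 2, obs, ">=")) + 1) / (n_perm + 1)
  p_lo <- (colSums(sweep(perm_i, 2, obs, "<=")) + 1) / (n_perm + 1)
  p <- pmin(1, 2 * pmin(p_hi, p_lo))

  quad <- ifelse(z >= 0,
                 ifelse(lag >= 0, "HH", "HL"),
                 ifelse(lag >= 0, "LH", "LL"))
  category <- ifelse(p <= alpha, quad, "not-significant")
  data.frame(zone_id = zone_id, value = x, local_i = obs, z_score = zsc,
             p_value = p, category = category, stringsAsFactors = FALSE)
}
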