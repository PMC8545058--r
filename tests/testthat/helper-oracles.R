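# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from first principles, sharing no code with the
# package implementation.

# type-7 quantile by the textbook interpolation formula on sorted values
oracle_quantile7 <- function(v, p) {
  x <- sort(v[is.finite(v)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_fences <- function(v) {
  q1 <- oracle_quantile7(v, 0.25)
  q3 <- oracle_quantile7(v, 0.75)
  c(lower = q1 - 1.5 * (q3 - q1), upper = q3 + 1.5 * (q3 - q1))
}

# flag and repair one series by direct comparison against its fences
oracle_repair <- function(v) {
  f <- oracle_fences(v)
  flag <- integer(length(v))
  flag[is.finite(v) & v > f["upper"]] <- 1L
  flag[is.finite(v) & v < f["lower"]] <- 2L
  rep <- v
  rep[flag == 1L] <- f["upper"]
  rep[flag == 2L] <- f["lower"]
  list(repaired = rep, flags = flag)
}

# double-loop Anselin local Moran on a precomputed weight matrix
oracle_local_moran <- function(x, w) {
  n <- length(x)
  xbar <- mean(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s2 <- 0
    for (j in seq_len(n)) if (j != i) s2 <- s2 + (x[j] - xbar)^2
    s2 <- s2 / (n - 1)
    lag <- 0
    for (j in seq_len(n)) if (j != i) lag <- lag + w[i, j] * (x[j] - xbar)
    out[i] <- (x[i] - xbar) / s2 * lag
  }
  out
}

# exhaustive natural breaks: enumerate all contiguous partitions of the
# sorted values into k classes, minimising total within-class SSD
oracle_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (c in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, c], n)
    tot <- 0
    for (m in seq_len(k)) tot <- tot + ssd(x[(b[m] + 1):b[m + 1]])
    if (tot < best) best <- tot
  }
  best
}

jenks_ssd_of <- function(values, edges) {
  x <- sort(values)
  cls <- findInterval(x, edges[2:(length(edges) - 1)] + 0, left.open = TRUE)
  sum(tapply(x, cls, function(v) sum((v - mean(v))^2)))
}

# build a quintic from 4 prescribed derivative roots; returns ascending
# coefficients and the count of strict interior maxima on [lo, hi]
oracle_quintic_from_roots <- function(droots, lead_sign, lo = -1, hi = 1) {
  dcoef <- 1
  for (r in droots) dcoef <- c(0, dcoef) + c(-r * dcoef, 0)
  dcoef <- lead_sign * dcoef
  qcoef <- c(0, dcoef / seq_along(dcoef))
  d2 <- dcoef[-1] * seq_len(length(dcoef) - 1)
  interior <- droots[droots > lo & droots < hi]
  curv <- vapply(interior, function(u)
    sum(d2 * u^(seq_along(d2) - 1)), numeric(1))
  list(coefs = qcoef, n_maxima = sum(curv < 0))
}

poly_val <- function(coefs, u) {
  drop(outer(u, seq_along(coefs) - 1, "^") %*% coefs)
}

# small default-noise scene: three cities with graded window suppression
small_scene <- function(seed = 1, levels = c(0.5, 0.7, 0.9),
                        win = c("2020-02-19", "2020-03-31"), ...) {
  zones <- list(
    zone_spec(1, c(10, 10), peak = 100, decay = 3,
              suppression = suppr_window(levels[1], win[1], win[2])),
    zone_spec(2, c(10, 30), peak = 100, decay = 3,
              suppression = suppr_window(levels[2], win[1], win[2])),
    zone_spec(3, c(30, 20), peak = 100, decay = 3,
              suppression = suppr_window(levels[3], win[1], win[2])))
  make_scene(scene_config(grid = ntl_grid(40, 40), zones = zones,
                          seed = seed, ...))
}

# noise-free identity configuration: flat dark floor, no perturbations
quiet_noise <- function() {
  list(dark_range = c(0.5, 0.5), lit_sd = 0, spike_rate = 0,
       cloud_drop_rate = 0, moon_glow = 0)
}
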