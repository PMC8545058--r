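test_that("daily difference series equal a masked-sum oracle", {
  scene <- small_scene(seed = 41)
  prep <- preprocess_stack(scene$analysis, moonless_mode = "flags")
  base <- stack_mean(scene$baseline)
  ser <- daily_difference_series(prep$stack, base, scene$zones)
  masks <- attr(ser, "masks")
  for (zid in c(1L, 3L)) {
    mk <- masks[[as.character(zid)]]
    zs <- ser[ser$zone_id == zid, ]
    for (t in c(1, 10, nrow(zs))) {
      layer <- prep$stack$values[, , t]
      d_or <- sum((layer - base$values)[mk$decrease])
      i_or <- sum((layer - base$values)[mk$increase])
      expect_equal(zs$d_value[t], d_or)
      expect_equal(zs$i_value[t], i_or)
    }
  }
})

test_that("a stack equal to its baseline yields identically zero series", {
  g <- ntl_grid(8, 8)
  vals <- matrix(runif(64, 0, 10), 8)
  st <- ntl_stack(array(rep(vals, 6), c(8, 8, 6)),
                  seq(as.Date("2020-02-16"), by = "day", length.out = 6), g)
  zones <- zone_map(matrix(1L, 8, 8), data.frame(zone_id = 1L), g)
  ser <- daily_difference_series(st, ntl_raster(vals, g), zones)
  expect_true(all(ser$d_value == 0))
  expect_true(all(ser$i_value == 0))
  expect_equal(attr(ser, "flagged"), 1L)
})

test_that("a uniform offset over a fixed mask gives a constant series", {
  g <- ntl_grid(10, 10)
  base <- matrix(10, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:10, 1:10] <- TRUE
  vals <- array(9, c(10, 10, 7))  # uniform -1 on all 100 pixels
  st <- ntl_stack(vals, seq(as.Date("2020-03-17"), by = "day",
                            length.out = 7), g)
  zones <- zone_map(matrix(1L, 10, 10), data.frame(zone_id = 1L), g)
  ser <- daily_difference_series(st, ntl_raster(base, g), zones,
                                 masks = list("1" = list(decrease = mask,
                                                         increase = !mask)))
  expect_true(all(ser$d_value == -100))
  expect_true(all(ser$i_value == 0))
})

test_that("a noiseless degree-5 polynomial is recovered exactly", {
  dates <- seq(as.Date("2020-01-20"), by = "day", length.out = 40)
  u <- seq(-1, 1, length.out = 40)
  cs <- c(2, -1, 0.5, 3, -2.5, 1.2)
  y <- poly_val(cs, u)
  fit <- fit_polyline(dates, y)
  expect_equal(fit$coef_scaled, cs, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # the day-basis coefficients describe the same curve
  t <- as.numeric(dates - min(dates))
  expect_equal(poly_val(fit$coef_days, t), y, tolerance = 1e-8)
  # constant series: zero high-order terms, intercept at the constant
  fc <- fit_polyline(dates, rep(7, 40))
  expect_equal(fc$coef_scaled[1], 7, tolerance = 1e-9)
  expect_lt(max(abs(fc$coef_scaled[-1])), 1e-9)
  expect_error(fit_polyline(dates[1:6], rnorm(6)), "at least")
})

test_that("noisy fits match the normal-equations oracle", {
  set.seed(27)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    dates <- seq(as.Date("2020-01-20"), by = "day", length.out = n)
    y <- rnorm(n, 0, 10)
    fit <- fit_polyline(dates, y)
    t <- as.numeric(dates - min(dates))
    u <- 2 * t / max(t) - 1
    X <- outer(u, 0:5, "^")
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$coef_scaled, as.vector(beta), tolerance = 1e-6)
  }
})

test_that("trajectory typing reads maxima and tail off the fitted curve", {
  dates <- seq(as.Date("2020-01-20"), by = "day", length.out = 50)
  u <- seq(-1, 1, length.out = 50)
  # single interior maximum, falling tail
  y1 <- -(u - 0)^2
  c1 <- classify_trajectory(fit_polyline(dates, y1))
  expect_equal(c1$type, "inverted-U")
  expect_equal(c1$tail, "down")
  expect_equal(c1$n_maxima, 1L)
  # two-bump quintic with an interior dip: derivative roots prescribed
  q <- oracle_quintic_from_roots(c(-0.6, -0.1, 0.5, 1.4), +1)
  expect_equal(q$n_maxima, 2L)
  c2 <- classify_trajectory(fit_polyline(dates, poly_val(q$coefs, u)))
  expect_equal(c2$type, "M")
  expect_false(c2$low_confidence)
  # monotone series: no interior maxima, low-confidence fallback
  c3 <- classify_trajectory(fit_polyline(dates, u))
  expect_equal(c3$n_maxima, 0L)
  expect_equal(c3$type, "inverted-U")
  expect_true(c3$low_confidence)
  expect_equal(c3$tail, "up")
})

test_that("type and tail are invariant to positive scaling", {
  dates <- seq(as.Date("2020-01-20"), by = "day", length.out = 44)
  u <- seq(-1, 1, length.out = 44)
  q <- oracle_quintic_from_roots(c(-0.5, 0.1, 0.6, 0.9), +1)
  y <- poly_val(q$coefs, u)
  a <- classify_trajectory(fit_polyline(dates, y))
  b <- classify_trajectory(fit_polyline(dates, 1000 * y))
  expect_equal(a$type, b$type)
  expect_equal(a$tail, b$tail)
  expect_equal(a$n_maxima, b$n_maxima)
})

test_that("maxima counting agrees with the derivative-root oracle on random quintics", {
  set.seed(55)
  n_checked <- 0
  for (rep in 1:300) {
    droots <- sort(runif(4, -1.8, 1.8))
    if (min(diff(droots)) < 0.05) next  # well-separated critical points
    if (min(abs(droots - 1)) < 0.02 || min(abs(droots + 1)) < 0.02) next
    lead <- sample(c(-1, 1), 1)
    q <- oracle_quintic_from_roots(droots, lead)
    dates <- seq(as.Date("2020-01-20"), by = "day", length.out = 48)
    u <- seq(-1, 1, length.out = 48)
    cl <- classify_trajectory(fit_polyline(dates, poly_val(q$coefs, u)))
    expect_equal(cl$n_maxima, q$n_maxima)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 200)
})

test_that("planted trajectory types are classified accurately through the full raster pathway", {
  centres <- expand.grid(r = seq(6, 54, by = 12), c = seq(6, 54, by = 12))
  types <- rep(c("M", "inverted-U"), length.out = 25)
  tails <- rep(c("up", "down"), length.out = 25)
  zones <- lapply(seq_len(25), function(k)
    zone_spec(k, c(centres$r[k], centres$c[k]), peak = 80, decay = 2,
              suppression = suppr_trajectory(types[k], tails[k])))
  scene <- make_scene(scene_config(grid = ntl_grid(60, 60), zones = zones,
                                   seed = 71))
  prep <- preprocess_stack(scene$analysis, moonless_mode = "flags")
  ser <- daily_difference_series(prep$stack, stack_mean(scene$baseline),
                                 scene$zones)
  cls <- zone_trends(ser)
  truth <- scene$truth$trajectory
  expect_identical(truth$planted_type, truth$realized_type)
  expect_gte(mean(cls$type == truth$realized_type), 0.9)
  expect_true(all(cls$r2_d > 0.8))
})

test_that("noise-free trajectory profiles classify exactly, including tails", {
  dates <- seq(as.Date("2020-01-20"), as.Date("2020-03-31"), by = "day")
  retained <- dates[dates %in% moonless_default_dates()]
  for (ty in c("M", "inverted-U")) for (tl in c("up", "down")) {
    pr <- suppr_trajectory(ty, tl)
    y <- (compile_suppression(pr, retained) - 1) * 2000
    cl <- classify_trajectory(fit_polyline(retained, y))
    expect_equal(cl$type, ty)
    expect_equal(cl$tail, tl)
  }
})
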