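make_stack <- function(series_list, start = "2020-01-20") {
  # one pixel per series, laid out on a 1 x n grid
  n <- length(series_list)
  nd <- length(series_list[[1]])
  g <- ntl_grid(1, n)
  vals <- array(NA_real_, c(1, n, nd))
  for (k in seq_len(n)) vals[1, k, ] <- series_list[[k]]
  ntl_stack(vals, seq(as.Date(start), by = "day", length.out = nd), g)
}

test_that("negative radiance clamps to zero and nonnegatives pass through", {
  st <- make_stack(list(c(-3.2, 0, 1.5, 2, -0.1)))
  out <- clamp_negatives(st)
  expect_equal(out$values[1, 1, ], c(0, 0, 1.5, 2, 0))
  st2 <- make_stack(list(c(0.3, 0.7, 1.1, 0)))
  expect_equal(clamp_negatives(st2)$values, st2$values)
})

test_that("quartile fences match hand computation and degenerate rules", {
  qb <- quartile_bounds(c(1, 2, 3, 4, 100))
  expect_equal(qb$q1, 2)
  expect_equal(qb$q3, 4)
  expect_equal(qb$upper, 7)
  expect_equal(qb$lower, -1)
  # constant series: fences collapse to the constant
  qc <- quartile_bounds(rep(3.3, 10))
  expect_equal(qc$lower, 3.3)
  expect_equal(qc$upper, 3.3)
  # bounded data keeps fences within +/- 1.5 ranges
  set.seed(1)
  qu <- quartile_bounds(runif(50))
  expect_gte(qu$lower, -1.5)
  expect_lte(qu$upper, 2.5)
  # too-short series is unprocessable
  expect_true(is.na(quartile_bounds(c(1, 2, 3))$upper))
})

test_that("fence repair replaces outliers by the fence values and nothing else", {
  st <- make_stack(list(c(1, 2, 3, 4, 100),         # one high spike
                        c(5, 5.1, 4.95, 5.02, 5.05),# clean (inside fences)
                        c(10, 11, 10.5, 0.1, 10.2)))# one low drop
  res <- smbq_repair(st)
  expect_equal(res$stack$values[1, 1, ], c(1, 2, 3, 4, 7))
  expect_equal(res$mask[1, 1, ], c(0L, 0L, 0L, 0L, 1L))
  expect_equal(res$stack$values[1, 2, ], st$values[1, 2, ])
  expect_equal(res$mask[1, 2, ], rep(0L, 5))
  expect_equal(res$mask[1, 3, 4], 2L)
  f3 <- oracle_fences(st$values[1, 3, ])
  expect_equal(res$stack$values[1, 3, 4], unname(f3["lower"]))
  expect_equal(res$summary$n_high, c(0L, 0L, 0L, 0L, 1L))
})

test_that("repair agrees exactly with the brute-force fence oracle on random series", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(30:90, 1)
    base <- runif(1, 0.5, 50)
    v <- base * rlnorm(n, 0, 0.3)
    # contaminate a few entries
    idx <- sample(n, sample(0:4, 1))
    v[idx] <- v[idx] * sample(c(10, 0.01), length(idx), replace = TRUE)
    st <- make_stack(list(v))
    res <- smbq_repair(st)
    orc <- oracle_repair(v)
    expect_equal(res$stack$values[1, 1, ], unname(orc$repaired))
    expect_equal(res$mask[1, 1, ], orc$flags)
  }
})

test_that("repair is idempotent and invariant to date permutation", {
  set.seed(3)
  v <- c(rlnorm(40, log(5), 0.2), 60, 0.01)
  st <- make_stack(list(v))
  once <- smbq_repair(st)
  twice <- smbq_repair(once$stack)
  expect_equal(twice$stack$values, once$stack$values)
  expect_true(all(twice$mask == 0L))
  # permuting the series leaves fences (order statistics) unchanged
  perm <- sample(length(v))
  stp <- make_stack(list(v[perm]))
  resp <- smbq_repair(stp)
  expect_equal(resp$stack$values[1, 1, ], once$stack$values[1, 1, perm])
  expect_equal(resp$mask[1, 1, ], once$mask[1, 1, perm])
})

test_that("nodata is excluded from fences, never flagged, and short pixels pass through", {
  v <- c(NA, 1, 2, 3, 4, 100)
  st <- make_stack(list(v))
  res <- smbq_repair(st)
  expect_equal(res$mask[1, 1, ], c(0L, 0L, 0L, 0L, 0L, 1L))
  expect_true(is.na(res$stack$values[1, 1, 1]))
  short <- make_stack(list(c(5, 500, NA, NA, NA)))
  res2 <- smbq_repair(short)
  expect_true(res2$unprocessable[1, 1])
  expect_equal(res2$stack$values[1, 1, ], c(5, 500, NA, NA, NA))
  expect_true(all(res2$mask == 0L))
})

test_that("planted spikes are recovered with high recall on a stationary scene", {
  zones <- list(zone_spec(1, c(10, 10), peak = 100, decay = 3),
                zone_spec(2, c(25, 25), peak = 60, decay = 3))
  cfg <- scene_config(grid = ntl_grid(36, 36), zones = zones,
                      noise = list(spike_rate = 0.02,
                                   spike_min_factor = 5,
                                   cloud_drop_rate = 0.005),
                      seed = 17)
  scene <- make_scene(cfg)
  prep <- preprocess_stack(scene$analysis, moonless_mode = "flags")
  keep <- !scene$analysis$moonlit
  truth_flags <- scene$truth$flags[, , keep]
  planted_high <- truth_flags == 1L
  found_high <- prep$mask == 1L
  recall <- sum(planted_high & found_high) / sum(planted_high)
  precision <- sum(planted_high & found_high) / sum(found_high)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.5)
  # asymmetry carries through detection when spikes outnumber drops
  expect_gt(sum(prep$summary$n_high), sum(prep$summary$n_low))
})

test_that("moonlight filtering keeps exactly the requested dates", {
  dates <- seq(as.Date("2020-01-20"), as.Date("2020-03-31"), by = "day")
  g <- ntl_grid(2, 2)
  st <- ntl_stack(array(1, c(2, 2, length(dates))), dates, g)
  # explicit operational windows: 13 + 16 + 15 retained days
  f <- filter_moonless(st, mode = "explicit")
  expect_equal(length(f$dates), 44L)
  expect_equal(sum(f$dates <= as.Date("2020-02-01")), 13L)
  expect_equal(sum(f$dates >= as.Date("2020-02-16") &
                     f$dates <= as.Date("2020-03-02")), 16L)
  expect_equal(sum(f$dates >= as.Date("2020-03-17")), 15L)
  # keeping every date is the identity
  all_kept <- filter_moonless(st, mode = "explicit", dates = dates)
  expect_identical(all_kept$values, st$values)
  expect_warning(filter_moonless(st, mode = "explicit",
                                 dates = as.Date("1999-01-01")),
                 "no dates retained")
})

test_that("ephemeris screening brackets the new moons", {
  # published syzygies: new moons 24 Jan / 23 Feb / 24 Mar 2020,
  # full moons 10 Jan / 9 Feb / 9 Mar 2020
  expect_gt(moon_phase_angle(as.Date("2020-01-24")),
            moon_phase_angle(as.Date("2020-02-09")))
  expect_gt(moon_phase_angle(as.Date("2020-01-24")), 160)
  expect_lt(moon_phase_angle(as.Date("2020-02-09")), 20)
  expect_lt(moon_illuminated_fraction(as.Date("2020-02-23")), 0.05)
  expect_gt(moon_illuminated_fraction(as.Date("2020-03-09")), 0.95)
  expect_true(all(moon_phase_angle(seq(as.Date("2020-01-01"),
                                       as.Date("2020-12-31"),
                                       by = "day")) >= 0))
  expect_error(moon_phase_angle(as.Date("1850-01-01")), "range")
  # phase-angle mode retains at least the 5 days around each new moon
  dates <- seq(as.Date("2020-01-20"), as.Date("2020-03-31"), by = "day")
  st <- ntl_stack(array(1, c(2, 2, length(dates))), dates, ntl_grid(2, 2))
  f <- filter_moonless(st, mode = "ephemeris")
  for (nm in as.Date(c("2020-01-24", "2020-02-23", "2020-03-24"))) {
    near <- dates[abs(as.numeric(dates - nm)) <= 5]
    expect_true(all(near %in% f$dates))
  }
})
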