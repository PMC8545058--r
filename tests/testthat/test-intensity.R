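test_that("zone intensity sums match a pixel-loop oracle on a multi-city scene", {
  scene <- small_scene(seed = 31)
  prep <- preprocess_stack(scene$analysis, moonless_mode = "flags")
  p <- period_defaults(); p <- p[p$name == "S1", ]
  keep <- prep$stack$dates >= p$start & prep$stack$dates <= p$end
  d19 <- match_lunar_dates(prep$stack$dates[keep])
  ch <- cntl(stack_mean(stack_subset(prep$stack, keep)),
             stack_mean(stack_subset(scene$baseline,
                                     scene$baseline$dates %in% d19)),
             development_index(scene$dev$pre, scene$dev$prev))
  sc <- scntl(ch, scene$zones)
  for (k in seq_len(nrow(sc))) {
    sd_or <- si_or <- 0
    for (i in seq_len(ch$grid$rows)) for (j in seq_len(ch$grid$cols)) {
      if (scene$zones$labels[i, j] == sc$zone_id[k] &&
          !is.na(ch$class[i, j])) {
        if (ch$class[i, j] == -1L) sd_or <- sd_or + ch$cntl[i, j]
        if (ch$class[i, j] == 1L) si_or <- si_or + ch$cntl[i, j]
      }
    }
    expect_equal(sc$sum_decrease[k], sd_or)
    expect_equal(sc$sum_increase[k], si_or)
    expect_equal(sc$scntl[k], sd_or + si_or)
  }
  expect_true(all(sc$sum_decrease <= 0))
  expect_true(all(sc$sum_increase >= 0))
})

test_that("an all-background zone reports zero intensity and is flagged", {
  v <- matrix(0, 6, 6)
  ch <- cntl(ntl_raster(v, ntl_grid(6, 6)), ntl_raster(v, ntl_grid(6, 6)))
  zones <- zone_map(matrix(1L, 6, 6), data.frame(zone_id = 1L),
                    ntl_grid(6, 6))
  sc <- scntl(ch, zones)
  expect_equal(sc$scntl, 0)
  expect_true(sc$flagged)
})

test_that("natural breaks equal the exhaustive optimal partition", {
  # two obvious clusters
  e <- jenks_breaks(c(1, 1, 1, 10, 10, 10), k = 2)
  expect_equal(e, c(1, 1, 10), ignore_attr = TRUE)
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, -100, 100), 1)
    if (length(unique(x)) < k) next
    edges <- jenks_breaks(x, k)
    expect_equal(jenks_ssd_of(x, edges), oracle_jenks_ssd(x, k),
                 tolerance = 1e-9)
  }
  expect_error(jenks_breaks(c(1, 1, 2), k = 3), "distinct")
  # rounding mode presents edges on a coarse unit
  x <- c(-238000, -151000, -88000, -61000, -29000, -9000, -500)
  er <- jenks_breaks(x, k = 3, round_to = 1e4)
  expect_true(all(er %% 1e4 == 0))
})

test_that("intensity levels follow the preset banding with the severe-side tie rule", {
  # a city with a -63 061 reduction total sits in the high-impact band II
  expect_equal(as.integer(classify_level(-63061)), 2L)
  expect_equal(as.integer(classify_level(-5)), 5L)
  expect_equal(as.integer(classify_level(-240000)), 1L)
  # shared edges belong to the more severe (more negative) band
  expect_equal(as.integer(classify_level(-150000)), 1L)
  expect_equal(as.integer(classify_level(-60000)), 2L)
  expect_equal(as.integer(classify_level(-10000)), 4L)
  expect_equal(attr(classify_level(c(-200000, -5)), "roman"), c("I", "V"))
  # out-of-range values clamp with a warning
  expect_warning(lv <- classify_level(-300000), "clamped")
  expect_equal(as.integer(lv), 1L)
})

test_that("local Moran matches a double-loop oracle to 1e-10 on an 8-zone fixture", {
  set.seed(14)
  coords <- cbind(runif(8, 0, 100), runif(8, 0, 100))
  x <- c(5, -3, 8, 0.5, -7, 2, 12, -1)
  for (rs in c(TRUE, FALSE)) {
    res <- local_moran(x, coords, n_perm = 99, row_standardize = rs)
    d <- as.matrix(dist(coords)); w <- 1 / d; diag(w) <- 0
    if (rs) w <- w / rowSums(w)
    expect_equal(res$local_i, oracle_local_moran(x, w), tolerance = 1e-10)
  }
})

test_that("Moran labels are translation invariant and permutation p-values reproducible", {
  set.seed(15)
  coords <- cbind(runif(9, 0, 50), runif(9, 0, 50))
  x <- rnorm(9, 10, 4)
  a <- local_moran(x, coords, seed = 3)
  b <- local_moran(x + 1000, coords, seed = 3)
  expect_equal(a$local_i, b$local_i)
  expect_equal(a$p_value, b$p_value)
  expect_identical(a$category, b$category)
  c2 <- local_moran(x, coords, seed = 3)
  expect_identical(a$p_value, c2$p_value)
  c3 <- local_moran(x, coords, seed = 4)
  expect_false(identical(a$p_value, c3$p_value))
})

test_that("a hot zone ringed by cold neighbours is a significant high-low outlier", {
  # centre very high; near ring low; far ring moderate, so the conditional
  # permutations that mix far values inward push the lag up and the observed
  # strongly negative local I is extreme
  th <- seq(0, 2 * pi - 1e-9, length.out = 8)
  coords <- rbind(c(0, 0), cbind(3 * cos(th), 3 * sin(th)),
                  cbind(15 * cos(th + 0.2), 15 * sin(th + 0.2)))
  x <- c(100, rep(0, 8) + seq(0, 0.7, length.out = 8),
         rep(20, 8) + seq(0, 3.5, length.out = 8))
  res <- local_moran(x, coords, alpha = 0.05, n_perm = 999, seed = 2)
  expect_equal(res$category[1], "HL")
  expect_lte(res$p_value[1], 0.05)
  expect_lt(res$local_i[1], 0)
})

test_that("degenerate Moran inputs error out", {
  coords <- cbind(c(0, 1, 2), c(0, 1, 0))
  expect_error(local_moran(rep(5, 3), coords), "constant")
  expect_error(local_moran(rep(5, 3) + c(0, .Machine$double.eps, 0), coords),
               "constant")
  expect_error(local_moran(c(1, 2), coords[1:2, ]), "at least 3")
  expect_error(local_moran(c(1, 2, 3), rbind(c(0, 0), c(0, 0), c(1, 1))),
               "coincident")
})

test_that("zone severity ranking is recovered from planted suppression totals", {
  scene <- make_scene(scene_config(seed = 23))
  prep <- preprocess_stack(scene$analysis, moonless_mode = "flags")
  p <- period_defaults(); p <- p[p$name == "S1", ]
  keep <- prep$stack$dates >= p$start & prep$stack$dates <= p$end
  d19 <- match_lunar_dates(prep$stack$dates[keep])
  ch <- cntl(stack_mean(stack_subset(prep$stack, keep)),
             stack_mean(stack_subset(scene$baseline,
                                     scene$baseline$dates %in% d19)),
             development_index(scene$dev$pre, scene$dev$prev))
  sc <- scntl(ch, scene$zones)
  planted <- rowSums(scene$truth$deficit[, scene$analysis$dates %in%
                                           prep$stack$dates[keep]])
  rho <- cor(planted, -sc$scntl, method = "spearman")
  expect_gte(rho, 0.9)
})
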