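#' Pipeline configuration
#'
#' One serialisable object holding every knob of the full analysis chain
#' (simulate -> preprocess -> change -> intensity -> recovery -> trends).
#' Defaults are the standard analysis settings: CNTL thresholds (-1, 3),
#' explicit moonless windows, Jenks breaks with five levels, inverse-
#' distance Moran weights with 999 conditional permutations at alpha 0.05,
#' +12-day lunar offset matching, and a degree-5 trend polynomial.
#'
#' @param seed Master RNG seed (scene, permutations).
#' @param scene Named list of overrides for [scene_config()].
#' @param thresholds CNTL class thresholds `c(low, high)`.
#' @param quartile_type Quantile estimator for the fence repair.
#' @param moonless `list(mode, dates, threshold)` for [filter_moonless()].
#' @param breaks `list(mode = "jenks"|"preset", k, round_to)`.
#' @param moran `list(power, row_standardize, alpha, n_perm)`.
#' @param lunar `list(mode, offset)` for [match_lunar_dates()].
#' @param recovery `list(edges, threshold)` for [recovery_crosstab()].
#' @param scntl_mode `"classified"` or `"raw"` (see [scntl()]).
#' @param trend_degree Trend polynomial degree.
#' @return An object of class `ntl_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, scene = list(),
                            thresholds = c(-1, 3), quartile_type = 7,
                            moonless = list(mode = "explicit", dates = NULL,
                                            threshold = 90),
                            breaks = list(mode = "jenks", k = 5,
                                          round_to = NULL),
                            moran = list(power = 1, row_standardize = TRUE,
                                         alpha = 0.05, n_perm = 999),
                            lunar = list(mode = "offset", offset = 12),
                            recovery = list(edges = c(0.3, 0.6, 0.8, 1, Inf),
                                            threshold = 0.6),
                            scntl_mode = "classified",
                            trend_degree = 5) {
  structure(list(seed = seed, scene = scene, thresholds = thresholds,
                 quartile_type = quartile_type, moonless = moonless,
                 breaks = breaks, moran = moran, lunar = lunar,
                 recovery = recovery, scntl_mode = scntl_mode,
                 trend_degree = trend_degree),
            class = "ntl_pipeline_config")
}

#' Save / load a pipeline configuration
#'
#' YAML round trip: `load_config(save_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config An `ntl_pipeline_config`.
#' @param path File path.
#' @return `load_config` returns the configuration object.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on a synthetic scene (or a
#' supplied input bundle) and optionally writes each stage's tables plus a
#' reproducibility manifest to `out_dir`. Stages only read the
#' configuration and earlier stages' outputs; a failing stage aborts with
#' its name, keeping earlier outputs.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory for CSV products and `manifest.json`;
#'   `NULL` (default) skips writing.
#' @param inputs Optional pre-built inputs: a list with `scene` (an
#'   `ntl_scene`), and optionally `cases` / `mobility` tables. Default
#'   simulates everything from the config.
#' @return Invisible list with components `scene`, `cases`, `mobility`,
#'   `preprocess`, `change`, `intensity`, `recovery`, `trends`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, inputs = NULL) {
  stopifnot(inherits(config, "ntl_pipeline_config"))

  sim <- run_stage("simulate", {
    if (is.null(inputs$scene)) {
      sc_args <- utils::modifyList(list(seed = config$seed,
                                        lunar = config$lunar),
                                   config$scene)
      scene <- do.call(scene_config, sc_args)
      scene <- make_scene(scene)
    } else scene <- inputs$scene
    cases <- inputs$cases %||% make_case_table(scene$config)
    mobility <- inputs$mobility %||% make_mobility_series(scene$config)
    list(scene = scene, cases = cases, mobility = mobility)
  })
  scene <- sim$scene
  zones <- scene$zones

  prep <- run_stage("preprocess", {
    preprocess_stack(scene$analysis, moonless_mode = config$moonless$mode,
                     moonless_dates = config$moonless$dates,
                     threshold = config$moonless$threshold %||% 90,
                     type = config$quartile_type)
  })
  clean <- prep$stack

  periods <- period_defaults()
  p_of <- function(nm) periods[periods$name == nm, ]

  # subset the analysis stack to a period's retained dates and the baseline
  # stack to their lunar matches
  period_pair <- function(p) {
    keep20 <- clean$dates >= p$start & clean$dates <= p$end
    d20 <- clean$dates[keep20]
    d19 <- match_lunar_dates(d20, mode = config$lunar$mode,
                             offset = config$lunar$offset %||% 12)
    list(a = stack_subset(clean, keep20),
         b = stack_subset(scene$baseline, scene$baseline$dates %in% d19))
  }

  change <- run_stage("change", {
    if (is.null(scene$dev)) stop("development composites missing")
    pr <- period_pair(p_of("S1"))
    if (n_layers(pr$a) == 0L) stop("no retained outbreak-period dates")
    D <- development_index(scene$dev$pre, scene$dev$prev)
    ch <- cntl(stack_mean(pr$a), stack_mean(pr$b), D,
               thresholds = config$thresholds)
    list(raster = ch, areas = affected_area(ch, zones))
  })

  intensity <- run_stage("intensity", {
    sc <- scntl(change$raster, zones, mode = config$scntl_mode)
    edges <- if (identical(config$breaks$mode, "preset")) {
      intensity_breaks_preset()
    } else {
      jenks_breaks(sc$scntl, k = config$breaks$k %||% 5,
                   round_to = config$breaks$round_to)
    }
    sc$level <- classify_level(sc$scntl, edges)
    sc$level_roman <- attr(sc$level, "roman")
    coords <- as.matrix(zones$table[, c("centroid_x", "centroid_y")])
    moran <- local_moran(sc$scntl, coords, zone_id = sc$zone_id,
                         alpha = config$moran$alpha %||% 0.05,
                         n_perm = config$moran$n_perm %||% 999,
                         seed = config$seed,
                         power = config$moran$power %||% 1,
                         row_standardize =
                           config$moran$row_standardize %||% TRUE)
    list(table = sc, edges = edges, moran = moran)
  })

  recovery <- run_stage("recovery", {
    res <- list()
    for (nm in c("feb_recovery", "mar_recovery")) {
      p <- p_of(nm)
      pr <- period_pair(p)
      r <- rntl(pr$a, pr$b, zones)
      m <- iict_period_recovery(sim$mobility, p$start, p$end,
                                lunar_mode = config$lunar$mode,
                                offset = config$lunar$offset %||% 12)
      r <- merge(r, m, by = "zone_id", all.x = TRUE)
      res[[nm]] <- r
    }
    ct <- recovery_crosstab(res$feb_recovery[, c("zone_id", "rntl")],
                            res$feb_recovery[, c("zone_id", "m")],
                            edges = config$recovery$edges,
                            threshold = config$recovery$threshold)
    dv <- d_value(res$mar_recovery, res$feb_recovery)
    list(feb = res$feb_recovery, mar = res$mar_recovery, crosstab = ct,
         d_value = dv)
  })

  trends <- run_stage("trends", {
    series <- daily_difference_series(clean, stack_mean(scene$baseline),
                                      zones)
    list(series = series,
         classification = zone_trends(series, degree = config$trend_degree))
  })

  manifest <- list(
    package = "nightshift",
    version = as.character(utils::packageVersion("nightshift")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = list(
      simulate = list(n_zones = nrow(zones$table),
                      n_dates = n_layers(scene$analysis),
                      grid = unclass(scene$analysis$grid)),
      preprocess = list(n_retained = n_layers(clean),
                        n_dropped_moonlit = prep$n_dropped_moonlit,
                        n_high = sum(prep$summary$n_high),
                        n_low = sum(prep$summary$n_low),
                        n_unprocessable = sum(prep$unprocessable)),
      change = list(n_decrease = sum(change$raster$class == CLASS_DECREASE,
                                     na.rm = TRUE),
                    n_increase = sum(change$raster$class == CLASS_INCREASE,
                                     na.rm = TRUE)),
      intensity = list(n_flagged = sum(intensity$table$flagged)),
      recovery = list(n_flagged = sum(recovery$feb$flagged)),
      trends = list(n_low_confidence =
                      sum(trends$classification$low_confidence))
    )
  )

  result <- list(scene = scene, cases = sim$cases, mobility = sim$mobility,
                 preprocess = prep, change = change, intensity = intensity,
                 recovery = recovery, trends = trends, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, nm) {
    utils::write.csv(df, file.path(out_dir, nm), row.names = FALSE)
  }
  wr(result$cases, "cases.csv")
  wr(result$mobility, "mobility.csv")
  wr(result$preprocess$summary, "outlier_summary.csv")
  wr(result$change$areas, "affected_area.csv")
  tab <- result$intensity$table
  tab$level <- as.integer(tab$level)
  wr(tab, "intensity.csv")
  wr(result$intensity$moran, "moran.csv")
  wr(result$recovery$feb, "recovery_feb.csv")
  wr(result$recovery$mar, "recovery_mar.csv")
  wr(result$recovery$d_value, "recovery_d_value.csv")
  wr(as.data.frame(result$recovery$crosstab$table), "recovery_crosstab.csv")
  wr(result$trends$series, "trend_series.csv")
  wr(result$trends$classification, "trend_classification.csv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
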