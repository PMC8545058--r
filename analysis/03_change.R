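#!/usr/bin/env Rscript
# Development-corrected change detection over the outbreak period: CNTL =
# mean outbreak radiance minus the lunar-matched baseline minus the
# year-over-year development increment, classified at thresholds (-1, 3).

library(nightshift)
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(pipeline_config(seed = 1))
ch <- res$change

write.csv(ch$areas, "results/affected_area.csv", row.names = FALSE)

tot <- colSums(ch$areas[, -1])
cat(sprintf("Affected area: %.1f km2 (%.1f%% decrease, %.1f%% increase).\n",
            tot["area_total_km2"],
            100 * tot["area_decrease_km2"] / tot["area_total_km2"],
            100 * tot["area_increase_km2"] / tot["area_total_km2"]))
cat(sprintf("Increase/decrease area ratio: %.2f.\n",
            tot["area_increase_km2"] / tot["area_decrease_km2"]))
cat(sprintf("Pixels: %d decrease, %d increase, %d background.\n",
            sum(ch$raster$class == -1L, na.rm = TRUE),
            sum(ch$raster$class == 1L, na.rm = TRUE),
            sum(ch$raster$class == 0L, na.rm = TRUE)))
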