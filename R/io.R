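#' Plain-text raster-stack I/O
#'
#' Writes a dated stack as a directory of per-date CSV matrices plus an
#' `index.csv` (date, moonlit flag, file) and a `grid.csv` with the grid
#' geometry; `read_stack_dir()` restores the stack exactly. CSV keeps the
#' artefacts text-only and diffable; conversion to GeoTIFF for GIS use is a
#' one-liner in any raster tool.
#'
#' @param stack An [ntl_stack()].
#' @param dir Target directory (created if needed).
#' @return `write_stack_dir` returns `dir` invisibly; `read_stack_dir`
#'   returns the restored [ntl_stack()].
#' @export
write_stack_dir <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- stack$grid
  utils::write.csv(data.frame(rows = g$rows, cols = g$cols,
                              pixel_size = g$pixel_size,
                              equal_area = g$equal_area),
                   file.path(dir, "grid.csv"), row.names = FALSE)
  files <- sprintf("layer_%s.csv", format(stack$dates))
  utils::write.csv(data.frame(date = format(stack$dates),
                              moonlit = stack$moonlit, file = files),
                   file.path(dir, "index.csv"), row.names = FALSE)
  for (k in seq_along(files)) {
    utils::write.table(stack$values[, , k], file.path(dir, files[k]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_stack_dir
#' @export
read_stack_dir <- function(dir) {
  g <- utils::read.csv(file.path(dir, "grid.csv"))
  grid <- ntl_grid(g$rows, g$cols, g$pixel_size, g$equal_area)
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  vals <- array(NA_real_, c(grid$rows, grid$cols, nrow(idx)))
  for (k in seq_len(nrow(idx))) {
    vals[, , k] <- as.matrix(utils::read.table(
      file.path(dir, idx$file[k]), sep = ",", header = FALSE))
  }
  ntl_stack(vals, as.Date(idx$date), grid, moonlit = idx$moonlit)
}

#' Plain-text zone-map I/O
#'
#' Writes the label raster as a CSV matrix (`labels.csv`) and the zone
#' metadata as `zones.csv`, alongside `grid.csv`.
#'
#' @param zones A [zone_map()].
#' @param dir Target directory.
#' @return `write_zone_map` returns `dir` invisibly; `read_zone_map` the
#'   restored [zone_map()].
#' @export
write_zone_map <- function(zones, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- zones$grid
  utils::write.csv(data.frame(rows = g$rows, cols = g$cols,
                              pixel_size = g$pixel_size,
                              equal_area = g$equal_area),
                   file.path(dir, "grid.csv"), row.names = FALSE)
  utils::write.table(zones$labels, file.path(dir, "labels.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(zones$table, file.path(dir, "zones.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_zone_map
#' @export
read_zone_map <- function(dir) {
  g <- utils::read.csv(file.path(dir, "grid.csv"))
  grid <- ntl_grid(g$rows, g$cols, g$pixel_size, g$equal_area)
  labels <- as.matrix(utils::read.table(file.path(dir, "labels.csv"),
                                        sep = ",", header = FALSE))
  dimnames(labels) <- NULL
  zone_map(labels, utils::read.csv(file.path(dir, "zones.csv")), grid)
}
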