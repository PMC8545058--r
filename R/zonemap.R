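#' Zone map
#'
#' Per-pixel zone labels plus zone metadata. Labels are opaque positive
#' integers; 0 marks pixels outside every zone. The metadata table carries one
#' row per zone: its display name, administrative level, parent id (for
#' aggregation to provinces / agglomerations) and centroid in grid
#' coordinates (metres).
#'
#' @param labels Integer matrix `rows x cols` of zone ids (0 = outside).
#' @param table Data frame with columns `zone_id`, `name`, `admin_level`,
#'   `parent_id`, `centroid_x`, `centroid_y`. Missing centroids are filled
#'   from the mean of member pixel centres.
#' @param grid An [ntl_grid()].
#' @return An object of class `ntl_zones`.
#' @export
zone_map <- function(labels, table, grid) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!identical(dim(labels), c(grid$rows, grid$cols))) {
    stop("label dimensions do not match grid", call. = FALSE)
  }
  present <- sort(unique(labels[labels > 0L]))
  if (!all(present %in% table$zone_id)) {
    stop("labels present in raster but missing from zone table: ",
         paste(setdiff(present, table$zone_id), collapse = ", "), call. = FALSE)
  }
  table <- as.data.frame(table)
  if (nrow(table) == 0L) {
    table <- data.frame(zone_id = integer(), name = character(),
                        admin_level = character(), parent_id = integer(),
                        centroid_x = numeric(), centroid_y = numeric())
  }
  if (is.null(table$name)) table$name <- paste0("zone_", table$zone_id)
  if (is.null(table$admin_level)) table$admin_level <- "city"
  if (is.null(table$parent_id)) table$parent_id <- NA_integer_
  if (is.null(table$centroid_x) || is.null(table$centroid_y)) {
    table$centroid_x <- NA_real_
    table$centroid_y <- NA_real_
  }
  for (k in seq_len(nrow(table))) {
    if (is.na(table$centroid_x[k]) || is.na(table$centroid_y[k])) {
      idx <- which(labels == table$zone_id[k], arr.ind = TRUE)
      if (nrow(idx) > 0L) {
        ctr <- pixel_centre(grid, idx[, 1], idx[, 2])
        table$centroid_x[k] <- mean(ctr[, "x"])
        table$centroid_y[k] <- mean(ctr[, "y"])
      }
    }
  }
  structure(list(labels = labels, table = table, grid = grid),
            class = "ntl_zones")
}

#' @export
print.ntl_zones <- function(x, ...) {
  cat(sprintf("<ntl_zones> %d zones on %d x %d grid (%d unlabelled pixels)\n",
              nrow(x$table), x$grid$rows, x$grid$cols, sum(x$labels == 0L)))
  invisible(x)
}

zone_ids <- function(zones) zones$table$zone_id

# even-odd ray casting; poly is a 2-column matrix of vertices (closed or open
# ring). On-boundary points count as inside (half-open treatment on edges is
# irrelevant at pixel centres in practice; callers requiring strictness keep
# polygons off pixel centres).
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize vector zones onto the analysis grid
#'
#' Assigns each pixel to the polygon covering its centre (pixel-centre rule:
#' exact and independent of traversal order). Overlapping polygons — two
#' polygons claiming one pixel centre — are rejected.
#'
#' @param polygons Named list of 2-column matrices/data frames of vertex
#'   coordinates (metres, grid CRS), one ring per zone. Names become zone
#'   names; ids are assigned 1..n in list order unless `ids` is given.
#' @param grid An [ntl_grid()].
#' @param ids Optional integer vector of zone ids.
#' @return An [zone_map()] object.
#' @export
rasterize_zones <- function(polygons, grid, ids = NULL) {
  n <- length(polygons)
  labels <- matrix(0L, grid$rows, grid$cols)
  if (n == 0L) {
    return(zone_map(labels, data.frame(zone_id = integer()), grid))
  }
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(length(ids) == n, all(ids > 0L))
  nm <- names(polygons)
  if (is.null(nm)) nm <- paste0("zone_", ids)
  rc <- expand.grid(row = seq_len(grid$rows), col = seq_len(grid$cols))
  ctr <- pixel_centre(grid, rc$row, rc$col)
  owner <- integer(nrow(rc))
  for (k in seq_len(n)) {
    poly <- as.matrix(polygons[[k]])
    hit <- point_in_poly(ctr[, "x"], ctr[, "y"], poly)
    clash <- hit & owner > 0L
    if (any(clash)) {
      stop(sprintf("overlapping zones: '%s' and '%s' both cover pixel centres",
                   nm[match(owner[which(clash)[1]], ids)], nm[k]),
           call. = FALSE)
    }
    owner[hit] <- ids[k]
  }
  labels[cbind(rc$row, rc$col)] <- owner
  zone_map(labels,
           data.frame(zone_id = ids, name = nm, admin_level = "city",
                      parent_id = NA_integer_, stringsAsFactors = FALSE),
           grid)
}

#' Aggregate a zone map to a parent administrative level
#'
#' Remaps every pixel label to the zone's `parent_id` and regenerates the
#' metadata table, preserving pixel coverage exactly, so any per-zone sum
#' statistic aggregates additively.
#'
#' @param zones An [zone_map()] whose table defines `parent_id` for every zone.
#' @param level Admin level string recorded on the aggregated zones
#'   (default `"province"`).
#' @param parent_names Optional named character vector `parent_id -> name`.
#' @return A new [zone_map()] at the parent level.
#' @export
aggregate_zones <- function(zones, level = "province", parent_names = NULL) {
  tab <- zones$table
  if (any(is.na(tab$parent_id))) {
    stop("missing parent_id for zones: ",
         paste(tab$zone_id[is.na(tab$parent_id)], collapse = ", "),
         call. = FALSE)
  }
  map <- tab$parent_id
  names(map) <- as.character(tab$zone_id)
  labels <- zones$labels
  nz <- labels > 0L
  labels[nz] <- as.integer(map[as.character(labels[nz])])
  parents <- sort(unique(tab$parent_id))
  nm <- if (is.null(parent_names)) paste0(level, "_", parents) else
    unname(parent_names[as.character(parents)])
  zone_map(labels,
           data.frame(zone_id = parents, name = nm, admin_level = level,
                      parent_id = NA_integer_, stringsAsFactors = FALSE),
           zones$grid)
}
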