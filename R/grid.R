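#' Analysis grid
#'
#' Defines the shared raster geometry every layer in an analysis must use:
#' a regular equal-area grid of square pixels. Pixel centres sit at
#' `((col - 0.5) * pixel_size, (row - 0.5) * pixel_size)` in a planar
#' equal-area CRS; row 1 is the top of the raster. Area statistics are only
#' defined on equal-area grids.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param pixel_size Pixel edge length in metres (default 500, the standard
#'   resampling target for daily DNB radiance).
#' @param equal_area Logical flag recording whether the grid is in an
#'   equal-area projection. Area computations refuse grids where this is
#'   `FALSE`.
#' @return An object of class `ntl_grid`.
#' @export
ntl_grid <- function(rows, cols, pixel_size = 500, equal_area = TRUE) {
  stopifnot(length(rows) == 1L, length(cols) == 1L,
            rows >= 1, cols >= 1, pixel_size > 0)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pixel_size = as.numeric(pixel_size), equal_area = isTRUE(equal_area)),
    class = "ntl_grid"
  )
}

#' @export
print.ntl_grid <- function(x, ...) {
  cat(sprintf("<ntl_grid> %d x %d pixels @ %g m%s\n", x$rows, x$cols,
              x$pixel_size, if (x$equal_area) " (equal-area)" else ""))
  invisible(x)
}

grids_identical <- function(a, b) {
  identical(a$rows, b$rows) && identical(a$cols, b$cols) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    identical(a$equal_area, b$equal_area)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!grids_identical(a, b)) {
    stop(sprintf("grid mismatch: %s must share one grid", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Single radiance raster
#'
#' A single layer (e.g. a monthly or period composite) on an [ntl_grid()].
#' Values are radiance in nW/cm\eqn{^2}/sr; `NA` marks nodata.
#'
#' @param values Numeric matrix `rows x cols`.
#' @param grid An [ntl_grid()] matching `dim(values)`.
#' @return An object of class `ntl_raster`.
#' @export
ntl_raster <- function(values, grid) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$rows, grid$cols))) {
    stop("values dimensions do not match grid", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "ntl_raster")
}

#' @export
print.ntl_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<ntl_raster> %d x %d, range [%g, %g], %d nodata\n",
              nrow(v), ncol(v), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' Dated raster stack
#'
#' An ordered collection of daily radiance layers sharing one grid, with a
#' per-date moonlit flag. This is the container for daily DNB-style data:
#' `values[ , , k]` is the layer for `dates[k]`.
#'
#' @param values Numeric array `rows x cols x n_dates`.
#' @param dates `Date` vector, strictly increasing.
#' @param grid An [ntl_grid()].
#' @param moonlit Logical vector, one flag per date (default all `FALSE`).
#' @return An object of class `ntl_stack`.
#' @export
ntl_stack <- function(values, dates, grid, moonlit = NULL) {
  dates <- as.Date(dates)
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L)
  if (!identical(dim(values)[1:2], c(grid$rows, grid$cols))) {
    stop("layer dimensions do not match grid", call. = FALSE)
  }
  if (dim(values)[3] != length(dates)) {
    stop("number of layers does not match number of dates", call. = FALSE)
  }
  if (length(dates) > 1L && any(diff(dates) <= 0)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if (is.null(moonlit)) moonlit <- rep(FALSE, length(dates))
  stopifnot(length(moonlit) == length(dates))
  storage.mode(values) <- "double"
  structure(list(values = values, dates = dates, grid = grid,
                 moonlit = as.logical(moonlit)),
            class = "ntl_stack")
}

#' @export
print.ntl_stack <- function(x, ...) {
  cat(sprintf("<ntl_stack> %d x %d pixels, %d dates (%s .. %s), %d moonlit\n",
              x$grid$rows, x$grid$cols, length(x$dates),
              format(min(x$dates)), format(max(x$dates)), sum(x$moonlit)))
  invisible(x)
}

n_layers <- function(stack) length(stack$dates)

#' Subset a stack by date
#'
#' @param stack An [ntl_stack()].
#' @param keep Logical vector over dates, or a `Date` vector of dates to keep.
#' @return The subset `ntl_stack` (date order preserved).
#' @export
stack_subset <- function(stack, keep) {
  if (inherits(keep, "Date") || is.character(keep)) {
    keep <- stack$dates %in% as.Date(keep)
  }
  stopifnot(is.logical(keep), length(keep) == n_layers(stack))
  ntl_stack(stack$values[, , keep, drop = FALSE], stack$dates[keep],
            stack$grid, stack$moonlit[keep])
}

#' Per-pixel mean over a stack's layers
#'
#' Aggregates a dated stack to a single composite layer by the per-pixel mean
#' over all its layers, ignoring nodata. A pixel with no finite observation
#' is nodata in the result.
#'
#' @param stack An [ntl_stack()].
#' @return An [ntl_raster()].
#' @export
stack_mean <- function(stack) {
  m <- apply(stack$values, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  ntl_raster(m, stack$grid)
}

#' Per-pixel sum over a stack's layers
#'
#' @param stack An [ntl_stack()].
#' @param na.rm Drop nodata values before summing (default `TRUE`).
#' @return An [ntl_raster()].
#' @export
stack_sum <- function(stack, na.rm = TRUE) {
  m <- apply(stack$values, c(1, 2), sum, na.rm = na.rm)
  ntl_raster(m, stack$grid)
}

# pixel-centre coordinates (metres) for a label/row-col pair
pixel_centre <- function(grid, row, col) {
  cbind(x = (col - 0.5) * grid$pixel_size,
        y = (row - 0.5) * grid$pixel_size)
}
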