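#' Clamp negative radiance to zero
#'
#' Raw daily DNB radiance contains small negative values from background
#' subtraction; physically radiance is nonnegative, so negatives are set to
#' 0. Nodata is preserved.
#'
#' @param stack An [ntl_stack()] (or [ntl_raster()]).
#' @return Object of the same class with `max(value, 0)` applied elementwise.
#' @export
clamp_negatives <- function(stack) {
  stack$values <- pmax(stack$values, 0)
  stack
}

#' Quartile fences of a pixel time series
#'
#' Tukey fences used by the quartile-based repair: lower fence
#' `Q1 - 1.5 (Q3 - Q1)`, upper fence `Q3 + 1.5 (Q3 - Q1)`. Quartiles use
#' linear interpolation between order statistics (the common default,
#' `stats::quantile` type 7); the estimator is configurable via `type` and
#' fixed in the tests.
#'
#' @param series Numeric vector of daily radiance for one pixel (NA = nodata,
#'   excluded).
#' @param type Quantile estimator passed to [stats::quantile()] (default 7).
#' @return List with `q1`, `q3`, `lower`, `upper`, and `n` (finite values
#'   used); all `NA` with `n < 4` finite values (pixel unprocessable).
#' @export
quartile_bounds <- function(series, type = 7) {
  v <- series[is.finite(series)]
  if (length(v) < 4L) {
    return(list(q1 = NA_real_, q3 = NA_real_, lower = NA_real_,
                upper = NA_real_, n = length(v)))
  }
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = type)
  iqr <- q[2] - q[1]
  list(q1 = q[1], q3 = q[2], lower = q[1] - 1.5 * iqr,
       upper = q[2] + 1.5 * iqr, n = length(v))
}

#' Quartile-fence outlier repair of a daily stack
#'
#' For each pixel, the daily time series over the stack's (already
#' moonless-filtered) dates is screened against its own Tukey fences:
#' values above the upper fence (scan-edge glints, fires and other ephemeral
#' lights) are replaced by the upper fence; values below the lower fence
#' (cloud-obscured nights) are replaced by the lower fence. Fences are
#' computed per pixel over the full retained date range. Pixels with fewer
#' than four finite observations are passed through unrepaired and flagged
#' unprocessable; nodata pixel-days are never flagged.
#'
#' @param stack An [ntl_stack()], moonlit dates already removed.
#' @param type Quantile estimator (see [quartile_bounds()]).
#' @return A list with components
#'   \describe{
#'     \item{stack}{the repaired [ntl_stack()]}
#'     \item{mask}{integer array of the stack's shape: 0 none, 1 high, 2 low}
#'     \item{summary}{data frame (`date`, `n_high`, `n_low`)}
#'     \item{unprocessable}{logical matrix of pass-through pixels}
#'     \item{bounds}{list of `q1`, `q3`, `lower`, `upper` matrices}
#'   }
#' @export
smbq_repair <- function(stack, type = 7) {
  dm <- dim(stack$values)
  npix <- dm[1] * dm[2]
  nd <- dm[3]
  x <- matrix(stack$values, nrow = npix, ncol = nd)  # pixels x days
  fin <- is.finite(x)
  nfin <- rowSums(fin)
  ok <- nfin >= 4L
  q1 <- q3 <- rep(NA_real_, npix)
  if (any(ok)) {
    qs <- apply(x[ok, , drop = FALSE], 1, stats::quantile,
                probs = c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                type = type)
    q1[ok] <- qs[1, ]
    q3[ok] <- qs[2, ]
  }
  iqr <- q3 - q1
  lower <- q1 - 1.5 * iqr
  upper <- q3 + 1.5 * iqr
  high <- fin & ok & (x > upper)   # recycles fences columnwise per pixel
  low  <- fin & ok & (x < lower)
  x[high] <- rep(upper, nd)[high]
  x[low]  <- rep(lower, nd)[low]
  mask <- matrix(0L, npix, nd)
  mask[high] <- 1L
  mask[low] <- 2L
  out <- stack
  out$values <- array(x, dm)
  list(
    stack = out,
    mask = array(mask, dm),
    summary = data.frame(
      date = stack$dates,
      n_high = colSums(high),
      n_low = colSums(low)
    ),
    unprocessable = matrix(!ok, dm[1], dm[2]),
    bounds = list(q1 = matrix(q1, dm[1], dm[2]),
                  q3 = matrix(q3, dm[1], dm[2]),
                  lower = matrix(lower, dm[1], dm[2]),
                  upper = matrix(upper, dm[1], dm[2]))
  )
}

#' Full daily-stack preprocessing
#'
#' Standard cleaning sequence for a daily radiance stack: clamp negatives to
#' zero, drop moonlit dates, then detect and repair per-pixel time-series
#' outliers by quartile fences.
#'
#' @param stack An [ntl_stack()].
#' @param moonless_mode,moonless_dates,threshold Passed to
#'   [filter_moonless()].
#' @param type Quantile estimator for [smbq_repair()].
#' @return The [smbq_repair()] result list (its `stack` is the cleaned
#'   stack), plus `n_dropped_moonlit`.
#' @export
preprocess_stack <- function(stack, moonless_mode = "explicit",
                             moonless_dates = NULL, threshold = 90,
                             type = 7) {
  stack <- clamp_negatives(stack)
  n0 <- n_layers(stack)
  stack <- filter_moonless(stack, mode = moonless_mode,
                           dates = moonless_dates, threshold = threshold)
  res <- smbq_repair(stack, type = type)
  res$n_dropped_moonlit <- n0 - n_layers(stack)
  res
}
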