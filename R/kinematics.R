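#' Mean signed curvature of a tracked whisker segment
#'
#' Planar signed curvature
#' \deqn{\kappa = \frac{x' y'' - x'' y'}{(x'^2 + y'^2)^{3/2}}}
#' computed by central finite differences after uniform arc-length
#' resampling (cubic-spline interpolation of x(s), y(s) against cumulative
#' chord length), averaged over a stated fraction of the whisker's length.
#' The default segment is the third of the whisker nearest the base.
#' Positive curvature is counterclockwise turning in image coordinates;
#' units are 1/pixel.
#'
#' @param x,y ordered planar coordinates along the whisker (>= 5 points).
#' @param segment length-2 fraction-of-arc-length interval from the base
#'   (default `c(0, 1/3)`).
#' @param n_resample number of uniform arc-length samples (default
#'   `max(100, 2 * length(x))`).
#' @return mean signed curvature over the segment (1/pixel).
#' @export
curvature <- function(x, y, segment = c(0, 1/3), n_resample = NULL) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 5) stop("need at least 5 points along the whisker")
  ds <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(ds == 0)) stop("degenerate path: repeated points")
  s <- c(0, cumsum(ds))
  if (is.null(n_resample)) n_resample <- max(100L, 2L * length(x))
  su <- seq(0, s[length(s)], length.out = n_resample)
  xs <- stats::spline(s, x, xout = su)$y
  ys <- stats::spline(s, y, xout = su)$y
  h <- su[2] - su[1]
  idx <- 2:(n_resample - 1)
  x1 <- (xs[idx + 1] - xs[idx - 1]) / (2 * h)
  y1 <- (ys[idx + 1] - ys[idx - 1]) / (2 * h)
  x2 <- (xs[idx + 1] - 2 * xs[idx] + xs[idx - 1]) / h^2
  y2 <- (ys[idx + 1] - 2 * ys[idx] + ys[idx - 1]) / h^2
  kappa <- (x1 * y2 - x2 * y1) / (x1^2 + y1^2)^1.5
  frac <- su[idx] / s[length(s)]
  # tolerance so grid points landing exactly on a boundary are kept
  # irrespective of floating rounding (keeps rigid-motion invariance exact)
  in_seg <- frac >= segment[1] - 1e-9 & frac <= segment[2] + 1e-9
  if (sum(in_seg) < 5) stop("fewer than 5 resampled points in segment")
  mean(kappa[in_seg])
}

#' Whisker-bend contact-force proxy
#'
#' Subtracts the free-whisking internal curvature from trial curvature
#' values; the change in bend from free whisking approximates the contact
#' force on the whisker.
#'
#' @param kappa_trial curvature time series during a trial (1/pixel).
#' @param kappa_free free-whisking baseline curvature: a scalar, or a series
#'   of non-contact-frame curvatures whose mean is used.
#' @return `kappa_trial - mean(kappa_free)`.
#' @export
bend_force_proxy <- function(kappa_trial, kappa_free) {
  kappa_trial - mean(kappa_free, na.rm = TRUE)
}

#' Read a whisker path from TSV
#'
#' Expects columns `x` and `y` (point index order preserved).
#'
#' @param file path to a TSV file.
#' @return list with `x` and `y`.
#' @export
read_whisker_path <- function(file) {
  d <- utils::read.delim(file)
  if (!all(c("x", "y") %in% names(d)))
    stop(sprintf("'%s' must have columns 'x' and 'y'", file))
  list(x = d$x, y = d$y)
}
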