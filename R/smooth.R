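#' Smooth a daily profile with a penalized cyclic B-spline
#'
#' Fits a penalized least-squares cyclic cubic (order 4) B-spline to a
#' 24-hour profile on the circular clock, optionally after a log1p
#' variance-stabilizing transform. The roughness penalty is chosen by
#' generalized cross-validation unless \code{sp} is supplied. Missing
#' cells are dropped from the fit; the curve is evaluated on the full
#' grid. Periodicity is built into the basis, so the curve and its first
#' derivative agree at minutes 0 and 1440.
#'
#' @param values numeric vector of cell values (one 24-h profile), or a
#'   single-column subset of a [DailyProfiles-class] activity matrix.
#' @param grid clock minutes at which \code{values} sit (defaults to
#'   cell midpoints of an even grid of \code{length(values)} cells).
#' @param nBasis basis dimension B (default 24); must not exceed the
#'   number of non-missing cells.
#' @param transform \code{"log1p"} (default) or \code{"none"}; the curve
#'   is returned on the transformed scale.
#' @param sp optional fixed smoothing parameter (bypasses GCV).
#' @param evalGrid clock minutes at which to evaluate the curve
#'   (defaults to \code{grid}).
#' @return A [FunctionalCurve-class] object.
#' @examples
#' y <- 10 + 3 * cos(2 * pi * ((0:143) * 10 + 5 - 840) / 1440)
#' fc <- smoothProfile(y, transform = "none")
#' max(abs(fc@fitted - y))
#' @export
smoothProfile <- function(values, grid = NULL, nBasis = 24,
                          transform = c("log1p", "none"), sp = NULL,
                          evalGrid = NULL) {
  transform <- match.arg(transform)
  values <- as.numeric(values)
  G <- length(values)
  if (is.null(grid)) grid <- (seq_len(G) - 0.5) * (1440 / G)
  if (is.null(evalGrid)) evalGrid <- grid
  ok <- is.finite(values)
  if (sum(ok) < nBasis)
    stop("basis dimension (", nBasis,
         ") exceeds the number of observed cells (", sum(ok), ")",
         call. = FALSE)
  y <- if (transform == "log1p") log1p(values[ok]) else values[ok]
  x <- grid[ok]
  fit <- fitCyclicSpline(y, x, nBasis, sp)
  fitted <- as.numeric(mgcv::predict.gam(fit,
                                         newdata = data.frame(x = evalGrid)))
  new("FunctionalCurve",
      basis = list(nBasis = as.integer(nBasis), order = 4L,
                   circular = TRUE, sp = unname(fit$sp)),
      coefficients = stats::coef(fit),
      grid = as.numeric(evalGrid), fitted = fitted,
      transform = transform)
}

## mgcv cyclic cubic regression spline on the 1440-minute clock;
## GCV-selected smoothing parameter unless sp is fixed.
fitCyclicSpline <- function(y, x, nBasis, sp = NULL) {
  dat <- data.frame(y = y, x = x)
  if (is.null(sp)) {
    mgcv::gam(y ~ s(x, bs = "cc", k = nBasis), data = dat,
              knots = list(x = c(0, 1440)))
  } else {
    mgcv::gam(y ~ s(x, bs = "cc", k = nBasis), data = dat,
              knots = list(x = c(0, 1440)), sp = sp)
  }
}

## Smooth every profile of a DailyProfiles object; returns the N x G
## matrix of curve evaluations at the cell midpoints (profiles in rows).
smoothProfileMatrix <- function(profiles, nBasis = 24,
                                transform = "log1p", sp = NULL) {
  a <- profileMatrix(profiles)
  grid <- profileGrid(profiles)
  t(apply(a, 2L, function(col)
    smoothProfile(col, grid = grid, nBasis = nBasis,
                  transform = transform, sp = sp)@fitted))
}
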