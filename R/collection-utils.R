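#' Interval-average (prune) a dataSet onto a coarser grid
#'
#' Averages rows falling into `n_bins` intervals of the `X` role column, with
#' linear or logarithmic bin edges.  All columns are averaged; the `Y`
#' uncertainty is propagated as `sqrt(sum(eY^2))/n` when the input carries an
#' `eY` column, and otherwise estimated as the standard error of the mean of
#' the member `Y` values (0 for single-member bins).  When the input has no
#' `eY` column one is appended and the role map extended.  Empty bins are
#' dropped; attributes, comments and roles are preserved.
#'
#' @param ds a [dataSet()].
#' @param n_bins number of intervals (>= 1).
#' @param scale `"linear"` or `"log"`; the latter requires positive `X` in
#'   `range`.
#' @param range optional `c(xmin, xmax)`; rows outside are dropped.  Defaults
#'   to the full `X` range.
#' @return the pruned `dataSet`.
#' @examples
#' ds <- dataSet(cbind(1:100, sin(1:100 / 10)))
#' nrow(prune(ds, 10)$data)
#' @export
prune <- function(ds, n_bins, scale = c("linear", "log"), range = NULL) {
  stopifnot(inherits(ds, "dataSet"), n_bins >= 1)
  scale <- match.arg(scale)
  x <- ds_x(ds)
  if (is.null(range)) range <- c(min(x), max(x))
  keep <- x >= range[1] & x <= range[2]
  if (!any(keep)) stop("no data in the requested range")
  if (n_bins > sum(keep))
    warning("n_bins exceeds number of rows in range; empty bins dropped")
  edges <- if (scale == "linear") seq(range[1], range[2], length.out = n_bins + 1L)
  else {
    if (any(x[keep] <= 0)) stop("log scale requires positive X in range")
    exp(seq(log(range[1]), log(range[2]), length.out = n_bins + 1L))
  }
  idx <- findInterval(x[keep], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  dat <- ds$data[keep, , drop = FALSE]
  iy <- ds$roles[["Y"]]
  ey <- ds_ey(ds)
  if (!is.null(ey)) ey <- ey[keep]
  groups <- sort(unique(idx))
  out <- matrix(NA_real_, length(groups), ncol(dat))
  newey <- numeric(length(groups))
  for (g in seq_along(groups)) {
    sel <- idx == groups[g]
    out[g, ] <- colMeans(dat[sel, , drop = FALSE])
    n <- sum(sel)
    newey[g] <- if (!is.null(ey)) sqrt(sum(ey[sel]^2)) / n
    else if (n >= 2L) stats::sd(dat[sel, iy]) / sqrt(n)
    else 0
  }
  roles <- ds$roles
  if (!is.null(ey)) {
    out[, roles[["eY"]]] <- newey
  } else {
    out <- cbind(out, newey)
    roles <- c(roles, eY = ncol(out))
  }
  dataSet(out, attributes = ds$attributes, comments = ds$comments,
          roles = roles)
}

#' Interpolate the Y role of a dataSet onto a new X grid
#'
#' Linear interpolation uses [stats::approx()]; `"polynomial"` fits one global
#' polynomial of the given degree by least squares (exact when the data lie on
#' such a polynomial); `"bspline"` uses the cubic spline of
#' [stats::splinefun()] (the `degree` argument only applies to the polynomial
#' method).
#'
#' @param ds a [dataSet()] with at least two rows.
#' @param new_x numeric vector of evaluation points, inside the observed `X`
#'   range unless `extrapolate = TRUE`.
#' @param method `"linear"`, `"polynomial"` or `"bspline"`.
#' @param degree polynomial degree (polynomial method only).
#' @param extrapolate allow `new_x` outside the data range.
#' @return a `dataSet` with columns `[new_x, Y]` and the input attributes.
#' @examples
#' ds <- dataSet(cbind(0:5, 2 * (0:5)))
#' ds_y(ds_interpolate(ds, 1.5))   # exactly 3
#' @export
ds_interpolate <- function(ds, new_x,
                           method = c("linear", "polynomial", "bspline"),
                           degree = 2L, extrapolate = FALSE) {
  stopifnot(inherits(ds, "dataSet"))
  method <- match.arg(method)
  x <- ds_x(ds); y <- ds_y(ds)
  if (length(x) < 2L) stop("need at least two rows to interpolate")
  if (!extrapolate && (any(new_x < min(x)) || any(new_x > max(x))))
    stop("new_x outside data range; set extrapolate = TRUE to allow")
  ynew <- switch(method,
    linear = stats::approx(x, y, xout = new_x, rule = 2)$y,
    polynomial = {
      degree <- min(degree, length(unique(x)) - 1L)
      fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
      unname(stats::predict(fit, newdata = data.frame(x = new_x)))
    },
    bspline = stats::splinefun(x, y)(new_x))
  dataSet(cbind(new_x, ynew), attributes = ds$attributes,
          comments = ds$comments, roles = c(X = 1L, Y = 2L))
}
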