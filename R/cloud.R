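#' Point cloud of scatterers
#'
#' A rigid arrangement of point scatterers: positions (N x 3, nm), per-point
#' scattering lengths `b` and an optional shared normalized amplitude
#' function `fa(q)` describing the subparticle form (default: point
#' scatterers, `fa = 1`; [fa_sphere()] provides the built-in sphere
#' subparticle).
#'
#' @param positions N x 3 numeric matrix of coordinates (nm), finite.
#' @param b scattering length(s); scalar or length-N vector.
#' @param fa optional function of `q` returning the normalized subparticle
#'   amplitude.
#' @return an object of class `pointCloud`.
#' @export
point_cloud <- function(positions, b = 1, fa = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  if (nrow(positions) < 1L) stop("need at least one point")
  if (!all(is.finite(positions))) stop("positions must be finite")
  b <- rep_len(b, nrow(positions))
  if (!all(is.finite(b))) stop("b must be finite")
  if (!is.null(fa) && !is.function(fa)) stop("fa must be a function of q")
  structure(list(positions = positions, b = b, fa = fa),
            class = "pointCloud")
}

#' @export
print.pointCloud <- function(x, ...) {
  cat(sprintf("pointCloud: %d points, total b = %g%s\n",
              nrow(x$positions), sum(x$b),
              if (is.null(x$fa)) "" else ", subparticle amplitude set"))
  invisible(x)
}

#' Normalized sphere subparticle amplitude
#'
#' Returns `function(q)` giving the normalized scattering amplitude
#' \eqn{3(\sin qR - qR\cos qR)/(qR)^3} of a sphere of radius `R`, for use as
#' the `fa` argument of [point_cloud()].
#'
#' @param R subparticle radius (nm).
#' @export
fa_sphere <- function(R) {
  force(R)
  function(q) .sphere_kernel(q * R)
}

#' Fibonacci orientation grid on the unit sphere
#'
#' Deterministic quasi-uniform grid of `2n + 1` unit vectors built from the
#' golden-angle spiral, used for orientational averaging.  All weights are
#' equal.
#'
#' @param n grid order (>= 1); the grid has `2n + 1` points.
#' @return matrix of `2n + 1` rows of unit vectors, of class
#'   `orientationGrid`.
#' @examples
#' g <- fibonacci_sphere(7)   # 15 points
#' range(sqrt(rowSums(g^2)))  # all exactly 1
#' @export
fibonacci_sphere <- function(n) {
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  i <- (-n):n
  m <- 2L * n + 1L
  z <- 2 * i / m                       # sin(latitude), uniform in area
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * i / golden
  rxy <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(rxy * cos(phi), rxy * sin(phi), z)
  g <- g / sqrt(rowSums(g^2))
  structure(g, class = c("orientationGrid", "matrix"))
}

#' Pseudorandom orientation grid
#'
#' `m` points drawn uniformly on the unit sphere (area-uniform), as the
#' stochastic alternative to [fibonacci_sphere()].
#'
#' @param m number of points.
#' @param seed optional random seed for reproducibility.
#' @export
random_sphere <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- stats::runif(m, -1, 1)
  phi <- stats::runif(m, 0, 2 * pi)
  rxy <- sqrt(pmax(0, 1 - z^2))
  structure(cbind(rxy * cos(phi), rxy * sin(phi), z),
            class = c("orientationGrid", "matrix"))
}

#' Build a cubic-lattice point cloud clipped to a shape
#'
#' Generates conventional-cell lattice points (simple cubic, body-centered or
#' face-centered cubic) with lattice constant `a` and keeps those inside the
#' requested shape: a cube of edge `size` (corner at the origin, boundaries
#' inclusive) or a sphere of radius `size` centered at the origin.  All
#' scattering lengths are 1.
#'
#' @param lattice `"sc"`, `"bcc"` or `"fcc"`.
#' @param a lattice constant (nm), positive.
#' @param shape `"cube"` or `"sphere"`.
#' @param size cube edge or sphere radius (nm), positive.
#' @return a [point_cloud()].
#' @examples
#' nrow(lattice_cloud("sc", 1, "cube", 3)$positions)   # 4^3 = 64
#' @export
lattice_cloud <- function(lattice = c("sc", "bcc", "fcc"), a,
                          shape = c("cube", "sphere"), size) {
  lattice <- match.arg(lattice)
  shape <- match.arg(shape)
  if (a <= 0 || size <= 0) stop("a and size must be positive")
  basis <- switch(lattice,
    sc  = matrix(c(0, 0, 0), 1, 3, byrow = TRUE),
    bcc = matrix(c(0, 0, 0, .5, .5, .5), 2, 3, byrow = TRUE),
    fcc = matrix(c(0, 0, 0, .5, .5, 0, .5, 0, .5, 0, .5, .5), 4, 3,
                 byrow = TRUE))
  nmax <- ceiling(size / a) + 1L
  rng <- if (shape == "cube") 0:nmax else (-nmax):nmax
  cells <- as.matrix(expand.grid(i = rng, j = rng, k = rng))
  pos <- do.call(rbind, lapply(seq_len(nrow(basis)), function(s)
    sweep(cells, 2L, basis[s, ], "+")))
  pos <- pos * a
  keep <- if (shape == "cube")
    apply(pos >= -1e-9 & pos <= size + 1e-9, 1L, all)
  else sqrt(rowSums(pos^2)) <= size + 1e-9
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no lattice points inside the requested shape")
  point_cloud(pos)
}

#' Orientation-averaged scattering of a point cloud
#'
#' Debye-equation-equivalent scattering of an arbitrary point cloud: for each
#' q the amplitude \eqn{A(q\mathbf u) = \sum_i b_i f_a(q) e^{iq\,\mathbf
#' u\cdot\mathbf r_i}} is averaged over the orientation grid, giving the
#' coherent intensity \eqn{\langle|A|^2\rangle}, and positional disorder of
#' r.m.s. displacement \eqn{\sigma} is included through the Debye-Waller
#' decomposition
#' \deqn{I(q) = e^{-q^2\sigma^2}\langle|A|^2\rangle +
#'       (1 - e^{-q^2\sigma^2})\sum_i b_i^2 f_a^2,}
#' i.e. the coherent term is attenuated and the complement appears as diffuse
#' (incoherent) scattering.  The asymmetry factor
#' \eqn{\beta(q) = |\langle A\rangle|^2/\langle|A|^2\rangle \in [0, 1]}
#' (computed from the coherent average) is returned for use as a
#' structure-factor correction.
#'
#' @param cloud a [point_cloud()].
#' @param q vector of momentum-transfer magnitudes (nm^-1).
#' @param grid an orientation grid ([fibonacci_sphere()] or
#'   [random_sphere()]); by default a Fibonacci grid of order
#'   `max(100, ceiling(max(q) * extent))`, where `extent` is the largest
#'   distance of a point from the cloud center.
#' @param sigma r.m.s. random displacement (nm) for the Debye-Waller factor.
#' @return a [dataSet()] with columns `[q, I, beta]` and attributes `sumb`
#'   (total scattering length) and `sumb2`.
#' @examples
#' two <- point_cloud(rbind(c(0, 0, 0), c(0, 0, 2)))
#' I <- cloud_intensity(two, seq(0.1, 5, 0.1))
#' @export
cloud_intensity <- function(cloud, q, grid = NULL, sigma = 0) {
  stopifnot(inherits(cloud, "pointCloud"))
  if (any(q < 0)) stop("q must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  pos <- cloud$positions
  b <- cloud$b
  if (is.null(grid)) {
    cen <- colMeans(pos)
    extent <- sqrt(max(rowSums(sweep(pos, 2L, cen)^2)))
    grid <- fibonacci_sphere(max(100L, ceiling(max(q) * extent)))
  }
  if (!is.matrix(grid) || ncol(grid) != 3L || nrow(grid) < 1L)
    stop("grid must be a non-empty matrix of unit vectors")
  M <- nrow(grid)
  D <- pos %*% t(grid)                   # N x M projections u . r
  fa <- if (is.null(cloud$fa)) rep(1, length(q)) else cloud$fa(q)
  sumb2 <- sum(b^2)
  I <- beta <- numeric(length(q))
  for (k in seq_along(q)) {
    E <- exp(1i * q[k] * D)
    Am <- as.vector(crossprod(E, b)) * fa[k]     # amplitude per orientation
    coh <- mean(Mod(Am)^2)
    avgA <- mean(Am)
    beta[k] <- if (coh > 0) Mod(avgA)^2 / coh else 1
    dw <- exp(-q[k]^2 * sigma^2)
    I[k] <- dw * coh + (1 - dw) * sumb2 * fa[k]^2
  }
  dataSet(cbind(q, I, beta),
          attributes = list(sumb = sum(b), sumb2 = sumb2, sigma = sigma,
                            n_orientations = M),
          roles = c(X = 1L, Y = 2L))
}

#' Export / import a point cloud as 4-column ASCII
#'
#' The cloud is written as a [dataSet()] with columns `[x y z b]` in the
#' package's ASCII dialect, so [write_dat()]/[read_dat()] round-trip it.
#'
#' @param cloud a [point_cloud()].
#' @param file path to write to / read from.
#' @export
write_cloud <- function(cloud, file) {
  ds <- dataSet(cbind(cloud$positions, cloud$b), roles = c(X = 1L, Y = 2L))
  write_dat(dataCollection(ds), file)
  invisible(file)
}

#' @rdname write_cloud
#' @export
read_cloud <- function(file) {
  dc <- read_dat(file)
  if (!length(dc)) stop("no data block in file")
  m <- dc[[1]]$data
  if (ncol(m) < 4L) stop("cloud file needs 4 columns [x y z b]")
  point_cloud(m[, 1:3, drop = FALSE], b = m[, 4])
}
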