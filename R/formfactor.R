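#' Sphere form factor
#'
#' Scattering intensity per particle of a homogeneous sphere,
#' \deqn{I(q) = (V\rho)^2 \left[\frac{3(\sin qR - qR\cos qR)}{(qR)^3}\right]^2,}
#' with volume \eqn{V = 4\pi R^3/3} and scattering-length-density contrast
#' \eqn{\rho} (particle minus solvent).  The \eqn{q = 0} limit is the forward
#' scattering \eqn{I_0 = (V\rho)^2}.
#'
#' Units: lengths in nm, `q` in 1/nm, contrast in 1/nm^2 (consistently so
#' across the package).
#'
#' @param q momentum transfer (nm^-1), `q >= 0`.
#' @param R sphere radius (nm), positive.
#' @param contrast scattering length density contrast (nm^-2).
#' @return a [dataSet()] with columns `[q, I]` and attributes `I0`, `Rg` and
#'   the model parameters.
#' @examples
#' ff <- ff_sphere(seq(0, 3, 0.01), R = 3)
#' ds_attr(ff, "I0")   # (4 pi R^3 rho / 3)^2
#' @export
ff_sphere <- function(q, R, contrast = 1) {
  if (R <= 0) stop("R must be positive")
  if (any(q < 0)) stop("q must be >= 0")
  V <- 4 * pi * R^3 / 3
  amp <- V * contrast * .sphere_kernel(q * R)
  dataSet(cbind(q, amp^2),
          attributes = list(R = R, contrast = contrast,
                            I0 = (V * contrast)^2, Rg = sqrt(3 / 5) * R),
          roles = c(X = 1L, Y = 2L))
}

# normalized sphere amplitude 3 (sin x - x cos x)/x^3 with stable small-x form
.sphere_kernel <- function(x) {
  out <- numeric(length(x))
  s <- abs(x) < 0.1
  x2 <- x[s]^2
  out[s] <- 1 - x2 / 10 + x2^2 / 280 - x2^3 / 15120
  xl <- x[!s]
  out[!s] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Multishell sphere form factor
#'
#' Concentric spherical shells with outer radii `radii` (strictly increasing)
#' and per-shell scattering-length-density contrasts.  The amplitude
#' telescopes over shells,
#' \deqn{F_a(q) = \sum_k (\rho_k - \rho_{k+1}) V_k \Phi(q r_k),}
#' with \eqn{\rho_{n+1} = 0} (solvent) and \eqn{\Phi} the sphere amplitude
#' kernel, so a single shell reduces exactly to [ff_sphere()], hollow cores
#' are obtained with a zero contrast, and density gradients can be
#' approximated by many thin shells.
#'
#' @param q momentum transfer (nm^-1).
#' @param radii outer shell radii (nm), strictly increasing.
#' @param contrasts per-shell SLD contrast (nm^-2), same length as `radii`.
#' @return a [dataSet()] with columns `[q, I]` and attribute `I0`.
#' @export
ff_multishell_sphere <- function(q, radii, contrasts) {
  if (length(radii) != length(contrasts))
    stop("radii and contrasts must have the same length")
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("radii must be positive and strictly increasing")
  rho_out <- c(contrasts[-1], 0)
  amp <- numeric(length(q)); I0 <- 0
  for (k in seq_along(radii)) {
    Vk <- 4 * pi * radii[k]^3 / 3
    dk <- contrasts[k] - rho_out[k]
    amp <- amp + dk * Vk * .sphere_kernel(q * radii[k])
    I0 <- I0 + dk * Vk
  }
  dataSet(cbind(q, amp^2),
          attributes = list(radii = radii, contrasts = contrasts, I0 = I0^2),
          roles = c(X = 1L, Y = 2L))
}

#' Gaussian-chain (Debye) form factor
#'
#' Normalized form factor of a Gaussian polymer coil,
#' \eqn{P(x) = 2(e^{-x} + x - 1)/x^2} with \eqn{x = q^2 R_g^2}; `P(0) = 1`
#' and \eqn{P \to 2/x} at large \eqn{x}.
#'
#' @param q momentum transfer (nm^-1).
#' @param Rg radius of gyration (nm), positive.
#' @return a [dataSet()] with columns `[q, P]`, attributes `Rg`, `I0 = 1`.
#' @export
ff_gaussian_chain <- function(q, Rg) {
  if (Rg <= 0) stop("Rg must be positive")
  x <- (q * Rg)^2
  P <- numeric(length(x))
  s <- x < 1e-3
  P[s] <- 1 - x[s] / 3 + x[s]^2 / 12
  P[!s] <- 2 * (exp(-x[!s]) + x[!s] - 1) / x[!s]^2
  dataSet(cbind(q, P), attributes = list(Rg = Rg, I0 = 1),
          roles = c(X = 1L, Y = 2L))
}

#' Beaucage unified Guinier/power-law form factor
#'
#' Normalized unified scattering function combining a Guinier regime with a
#' power-law tail of exponent `d`,
#' \deqn{I(q) = G e^{-q^2R_g^2/3} + B\left[\frac{(\mathrm{erf}(qR_g/\sqrt 6))^3}{q}\right]^d,}
#' with the original prefactor
#' \eqn{B = G\,d/R_g^d\,[6d^2/((2+d)(2+2d))]^{d/2}\,\Gamma(d/2)} (the variant
#' without an additional high-q cutoff in the power-law branch).
#'
#' @param q momentum transfer (nm^-1).
#' @param Rg radius of gyration (nm).
#' @param d power-law exponent in `[1, 4]` (4 = Porod).
#' @param G Guinier prefactor (forward scattering).
#' @return a [dataSet()] with columns `[q, I]`.
#' @export
ff_beaucage <- function(q, Rg, d, G = 1) {
  if (Rg <= 0) stop("Rg must be positive")
  if (d < 1 || d > 4) stop("d must be in [1, 4]")
  B <- G * d / Rg^d * (6 * d^2 / ((2 + d) * (2 + 2 * d)))^(d / 2) *
    gamma(d / 2)
  qs <- pmax(q, .Machine$double.eps)
  cut <- (pracma::erf(qs * Rg / sqrt(6)))^3 / qs
  I <- G * exp(-q^2 * Rg^2 / 3) + B * cut^d
  dataSet(cbind(q, I), attributes = list(Rg = Rg, d = d, G = G, I0 = G),
          roles = c(X = 1L, Y = 2L))
}

#' Teubner-Strey form factor for bicontinuous microemulsions
#'
#' Normalized scattering of a structure with domain repeat distance `d` and
#' correlation length `xi`,
#' \deqn{I(q) = \frac{8\pi/\xi}{a_2 + c_1 q^2 + c_2 q^4},}
#' with \eqn{k = 2\pi/d}, \eqn{a_2 = (k^2 + \xi^{-2})^2},
#' \eqn{c_1 = 2(\xi^{-2} - k^2)} and \eqn{c_2 = 1}.  For \eqn{c_1 < 0}
#' (i.e. \eqn{k\xi > 1}) the curve peaks at
#' \eqn{q^* = \sqrt{k^2 - \xi^{-2}}}; the denominator discriminant is
#' \eqn{-16k^2/\xi^2 < 0} so the intensity is positive everywhere.  The
#' \eqn{8\pi/\xi} prefactor fixes the normalization convention, which differs
#' between literature sources.
#'
#' @param q momentum transfer (nm^-1).
#' @param xi correlation length (nm), positive.
#' @param d domain repeat distance (nm), positive.
#' @return a [dataSet()] with columns `[q, I]` and attribute `qstar` (peak
#'   position, `NA` when no peak exists).
#' @export
ff_teubner_strey <- function(q, xi, d) {
  if (xi <= 0 || d <= 0) stop("xi and d must be positive")
  k <- 2 * pi / d
  a2 <- (k^2 + 1 / xi^2)^2
  c1 <- 2 * (1 / xi^2 - k^2)
  I <- (8 * pi / xi) / (a2 + c1 * q^2 + q^4)
  qstar <- if (c1 < 0) sqrt(-c1 / 2) else NA_real_
  dataSet(cbind(q, I),
          attributes = list(xi = xi, d = d, qstar = qstar),
          roles = c(X = 1L, Y = 2L))
}

#' Average a model over a distributed parameter
#'
#' Computes \eqn{\langle I(q)\rangle = \int I(q; p)\, w(p)\, dp} for a model
#' whose parameter `param` follows a statistical distribution, by fixed
#' Gauss-Legendre quadrature over the truncated support (continuous
#' distributions: +-5 widths around the mean, Lorentz +-20 widths; weights
#' renormalized to 1 on the truncation interval) or by an exact weighted sum
#' (discrete distributions).  `width` is the standard deviation for `normal`,
#' `lognorm`, `gamma` and `uniform`, the half width at half maximum for
#' `lorentz`, and the half range of integers for `duniform`; `poisson`
#' ignores it (the mean fixes the variance).
#'
#' @param model function called as `model(p, ...)` returning a numeric vector
#'   or a [dataSet()] (its `Y` column is averaged).
#' @param param name of the distributed argument of `model` (informational;
#'   the value is always passed as first argument).
#' @param distribution one of `"normal"`, `"lognorm"`, `"gamma"`,
#'   `"lorentz"`, `"uniform"`, `"poisson"`, `"duniform"`.
#' @param mean distribution mean.
#' @param width distribution width (see above); `width = 0` returns the model
#'   at the mean.
#' @param n_points number of quadrature points (continuous case).
#' @param ... further arguments passed to `model`.
#' @return numeric vector (or the averaged `Y` column if the model returns a
#'   `dataSet`).
#' @examples
#' av <- distributed_average(function(R, q) ds_y(ff_sphere(q, R)),
#'                           "R", "normal", mean = 3, width = 0.3,
#'                           q = seq(0.1, 3, 0.1))
#' @export
distributed_average <- function(model, param,
                                distribution = c("normal", "lognorm", "gamma",
                                                 "lorentz", "uniform",
                                                 "poisson", "duniform"),
                                mean, width, n_points = 30L, ...) {
  distribution <- match.arg(distribution)
  eval1 <- function(p) {
    v <- model(p, ...)
    if (inherits(v, "dataSet")) ds_y(v) else v
  }
  if (width == 0 && distribution != "poisson") return(eval1(mean))

  if (distribution %in% c("poisson", "duniform")) {
    if (distribution == "poisson") {
      lo <- max(0, floor(mean - 8 * sqrt(mean) - 5))
      hi <- ceiling(mean + 8 * sqrt(mean) + 10)
      k <- lo:hi
      w <- stats::dpois(k, lambda = mean)
    } else {
      k <- ceiling(mean - width):floor(mean + width)
      w <- rep(1, length(k))
    }
    w <- w / sum(w)
    out <- 0
    for (i in seq_along(k)) out <- out + w[i] * eval1(k[i])
    return(out)
  }

  span <- if (distribution == "lorentz") 20 else 5
  lo <- mean - span * width
  hi <- mean + span * width
  if (distribution %in% c("lognorm", "gamma")) lo <- max(lo, 1e-12)
  gl <- pracma::gaussLegendre(n_points, lo, hi)
  dens <- switch(distribution,
    normal  = stats::dnorm(gl$x, mean, width),
    lognorm = {
      s2 <- log(1 + width^2 / mean^2)
      stats::dlnorm(gl$x, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    gamma   = stats::dgamma(gl$x, shape = (mean / width)^2,
                            scale = width^2 / mean),
    lorentz = stats::dcauchy(gl$x, location = mean, scale = width),
    uniform = stats::dunif(gl$x, mean - sqrt(3) * width,
                           mean + sqrt(3) * width))
  w <- gl$w * dens
  w <- w / sum(w)
  out <- 0
  for (i in seq_along(gl$x)) out <- out + w[i] * eval1(gl$x[i])
  out
}
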