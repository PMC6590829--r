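#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic structure factor of monodisperse hard spheres in the Percus-Yevick
#' approximation (Wertheim's closed-form direct correlation function).  The
#' zero-angle limit is the PY compressibility value
#' \eqn{S(0) = (1-\phi)^4/(1+2\phi)^2}.
#'
#' @param q momentum transfer (nm^-1), `q >= 0`.
#' @param R sphere radius (nm).
#' @param phi volume fraction, `0 <= phi < 0.74`.
#' @return a [dataSet()] with columns `[q, S]` and model parameters as
#'   attributes.
#' @examples
#' S <- sf_py(seq(0, 3, 0.01), R = 3, phi = 0.3)
#' @export
sf_py <- function(q, R, phi) {
  if (phi < 0 || phi >= 0.74) stop("phi must be in [0, 0.74)")
  if (R <= 0) stop("R must be positive")
  S <- .py_sq(q * 2 * R, phi)
  dataSet(cbind(q, S), attributes = list(R = R, phi = phi),
          roles = c(X = 1L, Y = 2L))
}

# PY S as a function of A = q*sigma (sigma = diameter), Ashcroft-Lekner form.
.py_sq <- function(A, phi) {
  if (phi == 0) return(rep(1, length(A)))
  al <- (1 + 2 * phi)^2 / (1 - phi)^4
  be <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  ga <- phi * al / 2
  f1 <- f2 <- f3 <- numeric(length(A))
  s <- A < 0.7
  if (any(s)) {          # small-argument series (catastrophic cancellation)
    x2 <- A[s]^2
    f1[s] <- 1/3 - x2/30 + x2^2/840 - x2^3/45360 + x2^4/3991680
    f2[s] <- 1/4 - x2/36 + x2^2/960 - x2^3/50400 + x2^4/4354560
    f3[s] <- 1/6 - x2/48 + x2^2/1200 - x2^3/60480 + x2^4/5080320
  }
  if (any(!s)) {
    x <- A[!s]
    f1[!s] <- (sin(x) - x * cos(x)) / x^3
    f2[!s] <- (2 * x * sin(x) + (2 - x^2) * cos(x) - 2) / x^4
    f3[!s] <- (-x^4 * cos(x) +
               4 * ((3 * x^2 - 6) * cos(x) + (x^3 - 6 * x) * sin(x) + 6)) / x^6
  }
  1 / (1 + 24 * phi * (al * f1 + be * f2 + ga * f3))
}

#' Sticky (adhesive) hard-sphere structure factor
#'
#' Baxter's adhesive hard-sphere solution: a hard core decorated with a
#' surface adhesion whose strength is the stickiness parameter `tau` (large
#' `tau` = weak attraction).  The adhesion parameter \eqn{\lambda} solves
#' \eqn{(\phi/12)\lambda^2 - (\tau + \phi/(1-\phi))\lambda +
#' (1+\phi/2)/(1-\phi)^2 = 0}; the physical (smaller) root is used.  Inside
#' the one-phase region the discriminant is positive; parameters beyond the
#' critical stickiness raise an error naming the boundary.  The well width
#' enters the Baxter model only through the sticky limit and is stored as
#' metadata.
#'
#' @inheritParams sf_py
#' @param tau stickiness parameter (> critical value for the given `phi`).
#' @param width relative well width, kept as an attribute.
#' @return a [dataSet()] with columns `[q, S]`.
#' @export
sf_sticky <- function(q, R, phi, tau, width = 0) {
  if (phi <= 0 || phi >= 0.6) stop("phi must be in (0, 0.6)")
  if (R <= 0) stop("R must be positive")
  qa <- phi / 12
  qb <- -(tau + phi / (1 - phi))
  qc <- (1 + phi / 2) / (1 - phi)^2
  disc <- qb^2 - 4 * qa * qc
  if (disc < 0) {
    tau_c <- sqrt(4 * qa * qc) - phi / (1 - phi)
    stop(sprintf(paste0("parameters inside the two-phase region: ",
                        "tau = %.4g below critical stickiness %.4g ",
                        "at phi = %.3g"), tau, tau_c, phi))
  }
  lam <- (-qb - sqrt(disc)) / (2 * qa)    # smaller root is physical
  ab <- .sticky_ab(phi, lam)
  S <- .baxter_sq(q * 2 * R, ab[1], ab[2], lam / 12, 12 * phi)
  dataSet(cbind(q, S),
          attributes = list(R = R, phi = phi, tau = tau, width = width,
                            lambda = lam),
          roles = c(X = 1L, Y = 2L))
}

# Baxter factor-function coefficients for the adhesive sphere, with
# mu = lambda phi (1 - phi); lambda = 0 recovers the Percus-Yevick values.
# (The contact delta contributes at the edge of the factor-function support,
# which the published solution accounts for; verified here via the
# g(r < sigma) = 0 criterion.)
.sticky_ab <- function(phi, lam) {
  mu <- lam * phi * (1 - phi)
  c((1 + 2 * phi - mu) / (1 - phi)^2,
    (-3 * phi + mu) / (2 * (1 - phi)^2))
}

# S(A) = 1/|Qhat(A)|^2 for factor function
# q(r) = (a/2)(r^2-1) + b(r-1) + c0 on (0,1); A = q*sigma.
.baxter_sq <- function(A, a, b, c0, T) {
  Qh <- .qhat_poly(A, a, b, c0, T)
  1 / (Re(Qh)^2 + Im(Qh)^2)
}

.qhat_poly <- function(A, a, b, c0, T) {
  out <- complex(length(A))
  s <- A < 0.5
  if (any(s)) {
    gl <- .gl64()
    qin <- a / 2 * (gl$x^2 - 1) + b * (gl$x - 1) + c0
    E <- exp(1i * outer(A[s], gl$x))
    out[s] <- 1 - T * as.vector(E %*% (gl$w * qin))
  }
  if (any(!s)) {
    iq <- 1i * A[!s]
    E1 <- exp(iq)
    I0 <- (E1 - 1) / iq
    I1 <- (E1 * (iq - 1) + 1) / iq^2
    I2 <- (E1 * (iq * iq - 2 * iq + 2) - 2) / iq^3
    out[!s] <- 1 - T * (a / 2 * (I2 - I0) + b * (I1 - I0) + c0 * I0)
  }
  out
}

# cached 64-point Gauss-Legendre rule on (0, 1)
.gl_env <- new.env(parent = emptyenv())
.gl64 <- function() {
  if (is.null(.gl_env$rule)) {
    gl <- pracma::gaussLegendre(64, 0, 1)
    .gl_env$rule <- list(x = gl$x, w = gl$w)
  }
  .gl_env$rule
}

#' Radial distribution function from a structure factor
#'
#' Inverse sine transform
#' \deqn{g(r) = 1 + \frac{1}{2\pi^2 n r}\int_0^{q_{max}} q\,(S(q)-1)\sin(qr)\,dq}
#' by the trapezoid rule on the stored `q` grid.  An optional Lanczos sigma
#' window damps the truncation (Gibbs) ringing caused by the finite `q` range.
#' If `|S-1|` at the end of the grid exceeds 0.01 a warning is raised and the
#' value is attached as the `truncation` attribute.
#'
#' @param S a [dataSet()] with columns `[q, S]` (roles X/Y).
#' @param n number density (nm^-3).
#' @param r radial grid (nm), positive.
#' @param window `"none"` (plain trapezoid, the textbook transform) or
#'   `"lanczos"`.
#' @return a [dataSet()] with columns `[r, g]` and attributes `n` and any
#'   truncation estimate.
#' @export
sq_to_gr <- function(S, n, r, window = c("none", "lanczos")) {
  stopifnot(inherits(S, "dataSet"))
  window <- match.arg(window)
  qv <- ds_x(S); Sv <- ds_y(S)
  if (any(r <= 0)) stop("r must be positive")
  tail_dev <- abs(Sv[length(Sv)] - 1)
  attrs <- list(n = n)
  if (tail_dev > 0.01) {
    warning(sprintf("S(q) deviates from 1 by %.3g at qmax; transform truncated",
                    tail_dev))
    attrs$truncation <- tail_dev
  }
  w <- if (window == "lanczos") .sinc(qv / qv[length(qv)]) else rep(1, length(qv))
  f <- w * qv * (Sv - 1)
  g <- 1 + .sine_transform(qv, f, r) / (2 * pi^2 * n * r)
  dataSet(cbind(r, g), attributes = attrs, roles = c(X = 1L, Y = 2L))
}

.sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# trapezoid-rule int f(q) sin(q r) dq for each r, chunked to limit memory
.sine_transform <- function(qv, f, r) {
  nq <- length(qv)
  wq <- diff(qv)
  wq <- c(wq[1] / 2, (wq[-1] + wq[-(nq - 1)]) / 2, wq[nq - 1] / 2)
  fw <- f * wq
  out <- numeric(length(r))
  chunk <- max(1L, floor(2e6 / nq))
  for (i0 in seq(1L, length(r), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(r))
    out[ii] <- sin(outer(r[ii], qv)) %*% fw
  }
  out
}
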