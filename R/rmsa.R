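#' Rescaled MSA structure factor for screened-Coulomb spheres
#'
#' Structure factor of charged hard spheres interacting through a repulsive
#' screened Coulomb (Yukawa) potential
#' \deqn{\beta u(x) = \Gamma\, e^{-ak\,(x-1)}/x, \quad x = r/\sigma > 1,}
#' with contact potential `gamma` (\eqn{\Gamma}, in units of kT), hard-core
#' diameter \eqn{\sigma = 2R} and dimensionless screening constant `ak`
#' (\eqn{\kappa\sigma}).  The mean spherical approximation is solved
#' analytically through the Baxter factorization; the closure reduces to a
#' quartic whose four roots are all computed as eigenvalues of the companion
#' matrix.  For every real root the structure factor and, via the sine
#' transform, the radial distribution function are evaluated, and the root
#' with the smallest mean |g| in the middle of the forbidden hard-core region
#' (r between 0.4 and 0.6 diameters) is selected — the physical solution has
#' g(r) = 0 inside the core.  If the contact value g(sigma+) of the selected
#' solution is negative beyond tolerance, the Hansen-Hayter rescaling is
#' applied: the effective hard-core diameter is inflated (bisection on the
#' scale factor, at most 50 iterations) until the contact condition holds,
#' and the structure factor of the rescaled system is returned.
#'
#' @param q momentum transfer (nm^-1).
#' @param R particle radius (nm); the hard-core diameter is `2 * R`.
#' @param phi volume fraction, in (0, 0.5].
#' @param gamma contact potential in units of kT (>= 0).
#' @param ak dimensionless screening constant \eqn{\kappa\sigma} (> 0).
#' @param rescale apply the Hansen-Hayter rescaling when the contact value is
#'   negative (default `TRUE`).
#' @param contact_tol tolerated negative contact value before rescaling.
#' @return a [dataSet()] with columns `[q, S]` and attributes including
#'   `root_index` (selected quartic root), `rescaled` (0/1), `phi_eff`
#'   (effective volume fraction after rescaling), `contact` (analytic
#'   g at the effective core boundary) and `core_score` (mean |g| in the
#'   selection window).
#' @examples
#' S <- sf_rmsa(seq(0.01, 2, 0.01), R = 3.1, phi = 0.2, gamma = 3, ak = 2)
#' @export
sf_rmsa <- function(q, R, phi, gamma, ak, rescale = TRUE,
                    contact_tol = 1e-3) {
  if (phi <= 0 || phi > 0.5) stop("phi must be in (0, 0.5]")
  if (gamma < 0) stop("gamma must be >= 0")
  if (ak <= 0) stop("ak must be positive")
  if (R <= 0) stop("R must be positive")

  scale <- 1
  sol <- .msa_select(phi, gamma, ak)
  rescaled <- FALSE
  if (rescale && sol$contact < -contact_tol) {
    smax <- min((0.68 / phi)^(1/3), 2.5)
    fc <- function(s) {
      p <- .msa_rescaled_params(phi, gamma, ak, s)
      .msa_select(p$phi, p$gamma, p$ak, quick = TRUE)$contact
    }
    lo <- 1; hi <- smax
    if (fc(hi) < -contact_tol)
      stop("rescaling failed: contact value still negative at maximum ",
           "effective packing (phi_eff = ", signif(phi * smax^3, 3), ")")
    for (it in seq_len(50)) {
      mid <- (lo + hi) / 2
      v <- fc(mid)
      if (abs(v) < contact_tol / 2) { lo <- hi <- mid; break }
      if (v < 0) lo <- mid else hi <- mid
    }
    scale <- hi
    p <- .msa_rescaled_params(phi, gamma, ak, scale)
    sol <- .msa_select(p$phi, p$gamma, p$ak)
    rescaled <- TRUE
  }

  phi_eff <- phi * scale^3
  A <- q * 2 * R * scale                  # dimensionless Q sigma_eff
  S <- .msa_sq(A, sol)
  dataSet(cbind(q, S),
          attributes = list(R = R, phi = phi, gamma = gamma, ak = ak,
                            root_index = sol$root_index,
                            rescaled = as.numeric(rescaled),
                            phi_eff = phi_eff,
                            contact = sol$contact,
                            core_score = sol$score),
          roles = c(X = 1L, Y = 2L))
}

.msa_rescaled_params <- function(phi, gamma, ak, s) {
  # enlarge the hard core at fixed physical potential: sigma' = s sigma
  list(phi = phi * s^3, ak = ak * s,
       gamma = gamma * exp(-ak * (s - 1)) / s)
}

# ---- analytic MSA machinery (sigma = 1 units) ------------------------------

# All real roots of the closure quartic with their factor-function
# coefficients.  gek is the contact potential Gamma; the closure tail is
# c(r) = -gek e^{-z(r-1)}/r.
.msa_roots <- function(eta, gek, z) {
  T <- 12 * eta
  if (gek == 0) {                        # uncharged: pure PY hard spheres
    ab <- .msa_ab_stable(0, 0, T, z)
    return(list(list(A = 0, C = 0, a = ab[1], b = ab[2])))
  }
  m <- .msa_coef_matrices(T, gek, z)  # G in the derivation equals gek
  N <- -m$c1[1, ]; D <- m$c1[2, ]
  poly <- .polymul(.polymul(D, D), m$c5[1, ])
  p2 <- .polymul(.polymul(N, D), m$c5[2, ])
  p3 <- .polymul(.polymul(N, N), m$c5[3, ])
  poly[seq_along(p2)] <- poly[seq_along(p2)] + p2
  poly[seq_along(p3)] <- poly[seq_along(p3)] + p3
  poly <- poly[1:5]                       # quartic; higher orders vanish
  roots <- .polyroots_companion(poly)
  re <- Re(roots[abs(Im(roots)) < 1e-9 * pmax(abs(Re(roots)), 1)])
  if (!length(re)) stop("no real root of the MSA quartic")
  lapply(sort(re), function(A) {
    C <- (N[1] + N[2] * A + N[3] * A^2) / (D[1] + D[2] * A)
    ab <- .msa_ab_stable(C, A, T, z)
    list(A = A, C = C, a = ab[1], b = ab[2])
  })
}

.polymul <- function(x, y) {
  out <- numeric(length(x) + length(y) - 1L)
  for (i in seq_along(x))
    out[i:(i + length(y) - 1L)] <- out[i:(i + length(y) - 1L)] + x[i] * y
  out
}

# roots of p[1] + p[2] x + ... + p[n+1] x^n as companion-matrix eigenvalues
.polyroots_companion <- function(p) {
  p <- p / max(abs(p))
  n <- length(p) - 1L
  pn <- p / p[n + 1L]
  comp <- matrix(0, n, n)
  comp[1, ] <- -rev(pn[1:n])
  if (n > 1L) comp[cbind(2:n, 1:(n - 1L))] <- 1
  eigen(comp, only.values = TRUE)$values
}

# a, b from the core condition h(r<1) = -1, solved as a well-conditioned
# 2x2 linear system (stable down to z -> 0 via expm1/series moments).
.msa_ab_stable <- function(C, A, T, z) {
  emz <- exp(-z)
  J0 <- -expm1(-z) / z
  J1 <- if (z < 0.1)
    1/2 - z/3 + z^2/8 - z^3/30 + z^4/144 - z^5/840
  else (1 - (1 + z) * emz) / z^2
  S0 <- C * J0 + (A - C) * emz + A * emz / z
  S1 <- C * J1 + (A - C) * emz / 2 + A * (1 + z) * emz / z^2
  M <- matrix(c(1 - T / 3, -T / 2,
                T / 8, 1 + T / 6), 2, 2, byrow = TRUE)
  solve(M, c(1 - T * S0, T * S1))
}

# analytic contact value g(1+) of one solution
.msa_contact <- function(sol, T, z) {
  A <- sol$A; C <- sol$C; a <- sol$a; b <- sol$b
  emz <- exp(-z)
  J0 <- -expm1(-z) / z
  J1 <- if (z < 0.1)
    1/2 - z/3 + z^2/8 - z^3/30 + z^4/144 - z^5/840
  else (1 - (1 + z) * emz) / z^2
  M0 <- -a/3 - b/2 + C * J0 + (A - C) * emz + A * emz / z
  M1 <- -a/8 - b/6 + C * J1 + (A - C) * emz / 2 + A * (1 + z) * emz / z^2
  1 + z * A * emz - T * (M0 - M1) - z * C * emz
}

# S(A) for one solution; A = q sigma (dimensionless)
.msa_sq <- function(A, sol) {
  T <- sol$T; z <- sol$z
  Qh <- .msa_qhat(A, sol$coef$a, sol$coef$b, sol$coef$C, sol$coef$A, T, z)
  1 / (Re(Qh)^2 + Im(Qh)^2)
}

.msa_qhat <- function(A, a, b, C, Ayuk, T, z) {
  out <- complex(length(A))
  s <- A < 2
  if (any(s)) {
    gl <- .gl64()
    qin <- a / 2 * (gl$x^2 - 1) + b * (gl$x - 1) +
      C * exp(-z * gl$x) + (Ayuk - C) * exp(-z)
    E <- exp(1i * outer(A[s], gl$x))
    tail <- Ayuk * exp(1i * A[s] - z) / (z - 1i * A[s])
    out[s] <- 1 - T * (as.vector(E %*% (gl$w * qin)) + tail)
  }
  if (any(!s)) {
    iq <- 1i * A[!s]
    E1 <- exp(iq)
    I0 <- (E1 - 1) / iq
    I1 <- (E1 * (iq - 1) + 1) / iq^2
    I2 <- (E1 * (iq * iq - 2 * iq + 2) - 2) / iq^3
    Iz <- (exp(iq - z) - 1) / (iq - z)
    Iin <- a / 2 * (I2 - I0) + b * (I1 - I0) + C * Iz +
      (Ayuk - C) * exp(-z) * I0
    Itail <- -Ayuk * exp(iq - z) / (iq - z)
    out[!s] <- 1 - T * (Iin + Itail)
  }
  out
}

# Solve the MSA at (eta, gek, z), score every real root by the mean |g| in
# the core window r/sigma in [0.4, 0.6] (sine transform of S), and return the
# best solution together with its score and analytic contact value.
.msa_select <- function(eta, gek, z, quick = FALSE) {
  T <- 12 * eta
  rho <- 6 * eta / pi
  roots <- .msa_roots(eta, gek, z)
  nq <- if (quick) 4096L else 8192L
  qmax <- 800
  qg <- seq(qmax / nq, qmax, length.out = nq)
  rwin <- seq(0.4, 0.6, length.out = 33L)
  win <- .sinc(qg / qmax)
  best <- NULL
  for (i in seq_along(roots)) {
    cf <- roots[[i]]
    S <- 1 / Mod(.msa_qhat(qg, cf$a, cf$b, cf$C, cf$A, T, z))^2
    if (any(!is.finite(S)) || any(S <= 0)) next
    f <- win * qg * (S - 1)
    g <- 1 + .sine_transform(qg, f, rwin) / (2 * pi^2 * rho * rwin)
    score <- mean(abs(g))
    if (is.null(best) || score < best$score)
      best <- list(coef = cf, score = score, root_index = i,
                   T = T, z = z, eta = eta, rho = rho)
  }
  if (is.null(best)) stop("no physical MSA solution found")
  best$contact <- .msa_contact(best$coef, T, z)
  best
}
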