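#' Intermediate scattering functions I(q, t)
#'
#' Time-domain correlation functions of common diffusive processes at a
#' single momentum transfer `q`:
#' * `diffusion`: \eqn{e^{-q^2 D t}},
#' * `stretched`: \eqn{e^{-(\Gamma t)^\beta}} (KWW; `beta = 1` is a simple
#'   exponential),
#' * `jumpdiffusion`: \eqn{e^{-\Gamma_j t}} with
#'   \eqn{\Gamma_j = Dq^2/(1 + Dq^2\tau)} (free diffusion as `tau -> 0`,
#'   saturating at \eqn{1/\tau} for large q).
#'
#' Units: time in ns, rates in 1/ns, `D` in nm^2/ns, `q` in 1/nm.
#'
#' @param model `"diffusion"`, `"stretched"` or `"jumpdiffusion"`.
#' @param t times (ns), `t >= 0`.
#' @param q momentum transfer (nm^-1), scalar.
#' @param D diffusion coefficient (nm^2/ns).
#' @param beta stretching exponent in (0, 2] (stretched model).
#' @param tau residence time (ns; jump diffusion).
#' @param Gamma relaxation rate (1/ns; stretched model, default `D*q^2`).
#' @return a [dataSet()] `[t, I]` of class `timeCurve` with `q` and the model
#'   parameters as attributes.
#' @examples
#' I <- intermediate_scattering("diffusion", t = 0:10, q = 1, D = 0.1)
#' @export
intermediate_scattering <- function(model = c("diffusion", "stretched",
                                              "jumpdiffusion"),
                                    t, q, D = NULL, beta = 1, tau = NULL,
                                    Gamma = NULL) {
  model <- match.arg(model)
  if (any(t < 0)) stop("t must be >= 0")
  I <- switch(model,
    diffusion = {
      if (is.null(D)) stop("D required")
      exp(-q^2 * D * t)
    },
    stretched = {
      if (beta <= 0 || beta > 2) stop("beta must be in (0, 2]")
      if (is.null(Gamma)) {
        if (is.null(D)) stop("Gamma (or D) required")
        Gamma <- D * q^2
      }
      exp(-(Gamma * t)^beta)
    },
    jumpdiffusion = {
      if (is.null(D) || is.null(tau)) stop("D and tau required")
      Gj <- D * q^2 / (1 + D * q^2 * tau)
      exp(-Gj * t)
    })
  ds <- dataSet(cbind(t, I),
                attributes = c(list(q = q, model_name = model),
                               Filter(Negate(is.null),
                                      list(D = D, beta = beta, tau = tau,
                                           Gamma = Gamma))),
                roles = c(X = 1L, Y = 2L))
  class(ds) <- c("timeCurve", class(ds))
  ds
}

.spectrum <- function(w, S, q, extra = list()) {
  ds <- dataSet(cbind(w, S),
                attributes = c(list(q = q, dw = w[2] - w[1]), extra),
                roles = c(X = 1L, Y = 2L))
  class(ds) <- c("spectrum", class(ds))
  ds
}

.check_wgrid <- function(w) {
  dw <- diff(w)
  if (max(abs(dw - dw[1])) > 1e-8 * dw[1])
    stop("omega grid must be uniform")
  if (abs(w[1] + w[length(w)]) > 1e-8 * max(abs(w)))
    stop("omega grid must be symmetric about 0")
  invisible(dw[1])
}

# analytic Lorentzian, rescaled (by at most ~1%) so that its weight on the
# represented frequency window equals the full-line unit area
.lorentz_w <- function(w, Gam) {
  v <- (1 / pi) * Gam / (Gam^2 + w^2)
  v / ((atan(max(w) / Gam) - atan(min(w) / Gam)) / pi)
}

#' Lorentzian quasielastic spectra S(q, omega)
#'
#' Frequency-domain spectra of unit area,
#' \eqn{S(\omega) = (1/\pi)\,\Gamma/(\Gamma^2+\omega^2)}, with half width at
#' half maximum \eqn{\Gamma = Dq^2} for translational diffusion
#' (`"transdiff"`) or \eqn{\Gamma = Dq^2/(1+Dq^2\tau)} for jump diffusion
#' (`"jumpdiff"`).
#'
#' @param model `"transdiff"` or `"jumpdiff"`.
#' @param w symmetric uniform frequency grid (1/ns).
#' @param q momentum transfer (nm^-1).
#' @param D diffusion coefficient (nm^2/ns), positive.
#' @param tau residence time (ns; jump diffusion).
#' @return a `spectrum` [dataSet()] `[omega, S]` with attribute `hwhm`.
#' @export
lorentzian_w <- function(model = c("transdiff", "jumpdiff"), w, q, D,
                         tau = NULL) {
  model <- match.arg(model)
  .check_wgrid(w)
  if (D <= 0) stop("D must be positive")
  Gam <- if (model == "transdiff") D * q^2
         else {
           if (is.null(tau)) stop("tau required for jump diffusion")
           D * q^2 / (1 + D * q^2 * tau)
         }
  .spectrum(w, .lorentz_w(w, Gam), q,
            list(model_name = model, D = D, hwhm = Gam))
}

#' Spectra of spatially confined diffusion
#'
#' Frequency-domain models whose spatial restriction produces an elastic line
#' (EISF) plus a quasielastic Lorentzian hierarchy:
#'
#' * `"sphere"`: diffusion inside an impermeable sphere of radius `R`
#'   (Volino-Dianoux).  The eigenvalues \eqn{x_{nl}} are the roots of
#'   \eqn{j_l'(x) = 0}; the elastic fraction is
#'   \eqn{A_0^0 = [3 j_1(qR)/(qR)]^2} and each mode contributes a Lorentzian
#'   of width \eqn{x_{nl}^2 D/R^2}.  As \eqn{qR \to 0} the quasielastic
#'   width plateaus at \eqn{x_{01}^2 D/R^2 = 4.3325\,D/R^2} (first l = 1
#'   root 2.0816), the hallmark of confinement.
#' * `"harmonic"`: diffusion in a 3D harmonic potential with mean-square
#'   displacement `u2` and relaxation time `tau`:
#'   \eqn{S = e^{-q^2 u_2}[\delta(\omega) + \sum_n \frac{(q^2u_2)^n}{n!}
#'   L(\omega; n/\tau)]}; the EISF is \eqn{e^{-q^2 u_2}}.
#'
#' The elastic line is represented as an area-preserving single-bin spike in
#' the central bin (consistently so in convolution, binning and HWHM
#' extraction).  If the truncated amplitude sum misses more than 1% a
#' `truncation` attribute is attached with a warning.
#'
#' @param model `"sphere"` or `"harmonic"`.
#' @param w symmetric uniform frequency grid (1/ns).
#' @param q momentum transfer (nm^-1).
#' @param D diffusion coefficient inside the sphere (nm^2/ns).
#' @param R confinement radius (nm).
#' @param u2 mean-square displacement (nm^2; harmonic model).
#' @param tau relaxation time (ns; harmonic model).
#' @param l_max,n_max cutoffs of the mode sums (>= 3).
#' @return a `spectrum` [dataSet()] with attributes `eisf` and
#'   `elastic_weight`.
#' @examples
#' w <- seq(-40, 40, 0.02)
#' s <- confined_w("sphere", w, q = 0.1, D = 1, R = 1)
#' @export
confined_w <- function(model = c("sphere", "harmonic"), w, q, D = NULL,
                       R = NULL, u2 = NULL, tau = NULL,
                       l_max = 12L, n_max = 12L) {
  model <- match.arg(model)
  dw <- .check_wgrid(w)
  if (l_max < 3 || n_max < 3) stop("cutoffs must be >= 3")
  ic <- which.min(abs(w))
  if (model == "sphere") {
    if (is.null(D) || is.null(R) || D <= 0 || R <= 0)
      stop("sphere model needs positive D and R")
    x <- q * R
    eisf <- .sphere_kernel(x)^2
    S <- numeric(length(w))
    total <- eisf
    for (l in 0:l_max) {
      xr <- .vd_roots(l, n_max)
      jlp <- .sph_bessel_deriv(l, x)
      for (n in seq_len(n_max)) {
        xnl <- xr[n]
        Anl <- if (abs(x - xnl) < 1e-6) {
          (2 * l + 1) * 1.5 * .sph_bessel(l, xnl)^2 *
            (xnl^2 - l * (l + 1)) / xnl^2
        } else {
          (2 * l + 1) * 6 * xnl^2 / (xnl^2 - l * (l + 1)) *
            (x * jlp / (x^2 - xnl^2))^2
        }
        total <- total + Anl
        S <- S + Anl * .lorentz_w(w, xnl^2 * D / R^2)
      }
    }
    extra <- list(model_name = "sphere", eisf = eisf, elastic_weight = eisf,
                  D = D, R = R)
    if (1 - total > 0.01) {
      warning(sprintf("mode sum truncated: amplitudes add to %.3f", total))
      extra$truncation <- 1 - total
    }
  } else {
    if (is.null(u2) || is.null(tau) || u2 < 0 || tau <= 0)
      stop("harmonic model needs u2 >= 0 and tau > 0")
    y <- q^2 * u2
    eisf <- exp(-y)
    S <- numeric(length(w))
    total <- eisf
    for (n in seq_len(n_max)) {
      An <- eisf * y^n / factorial(n)
      total <- total + An
      S <- S + An * .lorentz_w(w, n / tau)
    }
    extra <- list(model_name = "harmonic", eisf = eisf,
                  elastic_weight = eisf, u2 = u2, tau = tau)
    if (1 - total > 0.01) {
      warning(sprintf("mode sum truncated: amplitudes add to %.3f", total))
      extra$truncation <- 1 - total
    }
  }
  S[ic] <- S[ic] + eisf / dw              # elastic line as single-bin spike
  .spectrum(w, S, q, extra)
}

#' Rotational diffusion spectrum (Sears expansion)
#'
#' Incoherent scattering of a scatterer at radius `R` rotating with
#' rotational diffusion coefficient `Dr`:
#' \deqn{S(\omega) = j_0^2(qR)\,\delta(\omega) + \sum_{l\ge1} (2l+1)
#'       j_l^2(qR)\, L(\omega;\, l(l+1)D_r).}
#' A warning `truncation` attribute is attached when the truncated sum rule
#' \eqn{\sum_l (2l+1) j_l^2} falls below 0.99.
#'
#' @param w symmetric uniform frequency grid (1/ns).
#' @param q momentum transfer (nm^-1).
#' @param R radius of the rotating scatterer (nm).
#' @param Dr rotational diffusion coefficient (1/ns).
#' @param l_max expansion cutoff (>= 3).
#' @return a `spectrum` [dataSet()] with attributes `eisf`, `elastic_weight`.
#' @export
rotational_diffusion_w <- function(w, q, R, Dr, l_max = 10L) {
  dw <- .check_wgrid(w)
  if (l_max < 3) stop("l_max must be >= 3")
  x <- q * R
  eisf <- .sph_bessel(0, x)^2
  S <- numeric(length(w))
  total <- eisf
  for (l in seq_len(l_max)) {
    Al <- (2 * l + 1) * .sph_bessel(l, x)^2
    total <- total + Al
    S <- S + Al * .lorentz_w(w, l * (l + 1) * Dr)
  }
  ic <- which.min(abs(w))
  S[ic] <- S[ic] + eisf / dw
  extra <- list(model_name = "rotdiff", eisf = eisf, elastic_weight = eisf,
                R = R, Dr = Dr, sumrule = total)
  if (total < 0.99) {
    warning(sprintf("Sears expansion truncated: sum rule %.3f < 0.99", total))
    extra$truncation <- 1 - total
  }
  .spectrum(w, S, q, extra)
}

# spherical Bessel functions and derivative via half-integer Bessel J
.sph_bessel <- function(l, x) {
  out <- numeric(length(x))
  s <- abs(x) < 1e-8
  out[s] <- if (l == 0) 1 else 0
  xs <- x[!s]
  if (length(xs))
    out[!s] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  out
}

.sph_bessel_deriv <- function(l, x) {
  if (abs(x) < 1e-8) return(if (l == 1) 1 / 3 else 0)
  if (l == 0) return(-.sph_bessel(1, x))
  .sph_bessel(l - 1, x) - (l + 1) / x * .sph_bessel(l, x)
}

# cached roots of j_l'(x) = 0 (n = 1 .. n_max), bracketed bisection
.vd_env <- new.env(parent = emptyenv())
.vd_roots <- function(l, n_max) {
  key <- as.character(l)
  have <- .vd_env[[key]]
  if (!is.null(have) && length(have) >= n_max) return(have[seq_len(n_max)])
  f <- function(x) .sph_bessel_deriv(l, x)
  roots <- numeric(0)
  x0 <- if (l == 0) 0.5 else 1e-3       # skip trivial root at 0
  step <- 0.05
  x <- max(x0, l / 2)                    # first root of j_l' lies beyond ~l
  fprev <- f(x)
  while (length(roots) < n_max) {
    xn <- x + step
    fn <- f(xn)
    if (is.finite(fprev) && is.finite(fn) && fprev * fn < 0) {
      r <- stats::uniroot(f, c(x, xn), tol = 1e-12)$root
      if (r > 1e-6) roots <- c(roots, r)
    }
    x <- xn; fprev <- fn
  }
  .vd_env[[key]] <- roots
  roots[seq_len(n_max)]
}

#' Fourier bridge from time to frequency domain
#'
#' Computes \eqn{S(q,\omega)} from an intermediate scattering function by the
#' cosine transform
#' \deqn{S(\omega) = \frac{1}{\pi}\int_0^{t_{max}} I(q,t)\,R(t)\cos\omega t\,dt,}
#' where \eqn{R(t) = e^{-\sigma_\omega^2 t^2/2}} is the time-domain
#' representation of a Gaussian instrument resolution of width
#' \eqn{\sigma_\omega} (the resolution doubles as the window controlling
#' leakage; `resolution = 0` transforms the bare model).  The time grid uses
#' \eqn{2^{14}} points with \eqn{t_{max}} set by the slower of the signal
#' decay and the resolution.  A warning is raised (and a `leak` attribute
#' attached) when the windowed signal has not decayed below 1% of I(0) at
#' \eqn{t_{max}}.
#'
#' @param model function of `t` returning I(q, t) (e.g. a closure over
#'   [intermediate_scattering()]), or a `timeCurve` dataSet to be
#'   interpolated.
#' @param w symmetric uniform frequency grid (1/ns).
#' @param resolution Gaussian resolution width in omega units (1/ns).
#' @param q momentum transfer, stored as attribute.
#' @param nt number of time points.
#' @return a `spectrum` [dataSet()] `[omega, S]`.
#' @examples
#' w <- seq(-20, 20, 0.02)
#' s <- time_to_frequency(function(t) exp(-0.5 * t), w)
#' abs(hwhm(s) - 0.5) < 0.02
#' @export
time_to_frequency <- function(model, w, resolution = 0, q = NA_real_,
                              nt = 2^14) {
  .check_wgrid(w)
  if (inherits(model, "dataSet")) {
    ds <- model
    q <- ds_attr(ds, "q", q)
    model <- function(t) stats::approx(ds_x(ds), ds_y(ds), xout = t,
                                       rule = 2)$y
  }
  wmax <- max(w)
  # t_max: long enough for the slowest feature we can resolve on this grid
  dw <- w[2] - w[1]
  tmax <- if (resolution > 0) max(20 / dw, 5 / resolution) else 20 / dw
  tmax <- min(tmax, 50 / dw)
  tt <- seq(0, tmax, length.out = nt)
  It <- model(tt)
  win <- if (resolution > 0) exp(-resolution^2 * tt^2 / 2) else rep(1, nt)
  f <- It * win
  if (abs(f[nt]) > 0.01 * abs(f[1]))
    warning(sprintf("signal not decayed at t_max: I(t_max)/I(0) = %.3g; %s",
                    f[nt] / f[1], "spectrum may leak"))
  dt <- tt[2] - tt[1]
  wt <- rep(dt, nt); wt[c(1, nt)] <- dt / 2
  fw <- f * wt
  S <- numeric(length(w))
  chunk <- max(1L, floor(4e6 / nt))
  for (i0 in seq(1L, length(w), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(w))
    S[ii] <- cos(outer(w[ii], tt)) %*% fw
  }
  S <- S / pi
  S[S < 0 & S > -1e-9] <- 0
  .spectrum(w, S, q, list(resolution = resolution,
                          leak = abs(f[nt] / f[1])))
}

#' Convolution of two spectra
#'
#' Discrete convolution on the common uniform grid, scaled by the grid step
#' so that `area(a %*% b) = area(a) * area(b)`.  A spectrum whose elastic
#' line is a single-bin spike of unit area acts exactly as the identity.
#'
#' @param a,b `spectrum` dataSets on identical omega grids.
#' @return a `spectrum` [dataSet()] on the same grid.
#' @export
convolve_w <- function(a, b) {
  wa <- ds_x(a); wb <- ds_x(b)
  if (length(wa) != length(wb) || max(abs(wa - wb)) > 1e-8 * max(abs(wa)))
    stop("spectra must share one omega grid")
  dw <- .check_wgrid(wa)
  Sa <- ds_y(a); Sb <- ds_y(b)
  n <- length(Sa)
  full <- stats::convolve(Sa, rev(Sb), type = "open") * dw
  ic <- which.min(abs(wa))
  S <- full[(ic):(ic + n - 1L)]
  .spectrum(wa, S, ds_attr(a, "q", NA_real_),
            list(model_name = paste0(ds_attr(a, "model_name", "a"), "*",
                                     ds_attr(b, "model_name", "b"))))
}

#' Average a spectrum over frequency channels
#'
#' Each channel value is the mean of the spectrum over the grid points inside
#' `[edges[i], edges[i+1])`; the new omega is the mean of the member
#' frequencies.  Empty channels are dropped with a warning.  Binning a
#' constant spectrum returns the same constant and the integral is conserved
#' to discretization accuracy.
#'
#' @param s a `spectrum` [dataSet()].
#' @param edges increasing channel edges (1/ns).
#' @return a [dataSet()] `[omega, S]` (class `spectrum` when the resulting
#'   grid is uniform).
#' @export
bin_channels <- function(s, edges) {
  if (any(diff(edges) <= 0)) stop("edges must be increasing")
  w <- ds_x(s); S <- ds_y(s)
  idx <- findInterval(w, edges)
  inside <- idx >= 1L & idx < length(edges)
  wnew <- Snew <- numeric(0)
  empty <- 0L
  for (ch in seq_len(length(edges) - 1L)) {
    sel <- inside & idx == ch
    if (!any(sel)) { empty <- empty + 1L; next }
    wnew <- c(wnew, mean(w[sel]))
    Snew <- c(Snew, mean(S[sel]))
  }
  if (empty > 0L) warning(empty, " empty channel(s) dropped")
  ds <- dataSet(cbind(wnew, Snew),
                attributes = c(s$attributes[setdiff(names(s$attributes), "dw")],
                               list(binned = 1)),
                roles = c(X = 1L, Y = 2L))
  ds
}

#' Half width at half maximum of a spectrum
#'
#' Linear interpolation of the half-maximum crossing on the positive-omega
#' side of a spectrum peaked at omega = 0.  With `exclude_elastic = TRUE` the
#' single-bin elastic spike is removed (central bin replaced by the
#' interpolation of its neighbours) before the extraction, so the quasielastic
#' width of a confined model is measured.
#'
#' @param s a `spectrum` [dataSet()].
#' @param exclude_elastic drop the central-bin elastic spike first.
#' @return the HWHM (1/ns).
#' @examples
#' w <- seq(-30, 30, 0.005)
#' hwhm(lorentzian_w("transdiff", w, q = 1, D = 1))  # 1 to grid accuracy
#' @export
hwhm <- function(s, exclude_elastic = FALSE) {
  w <- ds_x(s); S <- ds_y(s)
  ic <- which.min(abs(w))
  if (exclude_elastic)
    S[ic] <- (S[ic - 1L] + S[ic + 1L]) / 2
  if (max(S) > S[ic] * (1 + 1e-9) + 1e-300)
    stop("spectrum maximum is not at omega = 0")
  half <- S[ic] / 2
  pos <- which(w >= 0)
  wp <- w[pos]; Sp <- S[pos]
  below <- which(Sp < half)
  if (!length(below))
    stop("no half-maximum crossing inside the grid; widen the omega range")
  i2 <- below[1]
  if (i2 == 1L) stop("grid too coarse at omega = 0 for HWHM")
  i1 <- i2 - 1L
  wp[i1] + (half - Sp[i1]) * (wp[i2] - wp[i1]) / (Sp[i2] - Sp[i1])
}
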