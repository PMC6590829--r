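#' Analytic structure factor of cubic lattices
#'
#' Powder structure factor of sc/bcc/fcc crystals with finite domain size,
#' Debye-Waller attenuation and an optional particle asymmetry correction.
#' Reciprocal-lattice points (hkl) are enumerated up to the largest requested
#' q, folded into multiplicities with their unit-cell structure factors
#' \eqn{|F_{hkl}|^2} (the extinction rules of bcc/fcc emerge from
#' \eqn{F_{hkl}}), and assembled into the lattice part
#' \deqn{Z(q) = \sum_{hkl} m_{hkl}\,\frac{|F_{hkl}|^2}{N_c}\,
#'       \frac{q_{hkl}^2}{q^2}\, P(q - q_{hkl};\,\delta),}
#' with a normalized peak shape `P` (Lorentzian by default, Gaussian
#' selectable) of width \eqn{\delta = 2\pi/L} set by the domain size `L`
#' (Scherrer constant 1).  The \eqn{q_{hkl}^2/q^2} factor is the powder
#' (Lorentz) factor, written so that integrating `Z` across one isolated
#' peak recovers its multiplicity-weighted \eqn{|F_{hkl}|^2/N_c} exactly.
#' The full structure factor follows the Foerster composition
#' \deqn{S(q) = 1 + \beta(q)\,[Z(q)\,e^{-q^2\langle u^2\rangle/3} - 1],}
#' in which the Debye-Waller factor attenuates the Bragg part and the
#' complement appears as diffuse scattering.
#'
#' @param q momentum transfer (nm^-1), positive.
#' @param lattice `"sc"`, `"bcc"` or `"fcc"` (conventional cubic cell).
#' @param a lattice constant (nm).
#' @param domainsize crystal domain size L (nm); sets the peak width
#'   `2*pi/L`.
#' @param u2 mean-square displacement (nm^2) for the Debye-Waller factor.
#' @param beta optional asymmetry factor: function of `q` or a constant
#'   (default 1, isotropic particles).
#' @param peak `"lorentz"` or `"gauss"` peak shape.
#' @return a [dataSet()] with columns `[q, S]` and an attribute `peaks`
#'   holding the distinct `q_hkl` positions.
#' @examples
#' S <- sf_lattice(seq(0.5, 4, 0.005), "sc", a = 5, domainsize = 50)
#' ds_attr(S, "peaks")[1]   # 2*pi/5
#' @export
sf_lattice <- function(q, lattice = c("sc", "bcc", "fcc"), a, domainsize,
                       u2 = 0, beta = NULL, peak = c("lorentz", "gauss")) {
  lattice <- match.arg(lattice)
  peak <- match.arg(peak)
  if (a <= 0 || domainsize <= 0) stop("a and domainsize must be positive")
  if (u2 < 0) stop("u2 must be >= 0")
  qmax <- max(q)
  hkl <- .enumerate_hkl(lattice, a, qmax)
  delta <- 2 * pi / domainsize
  Z <- numeric(length(q))
  q2 <- pmax(q, 1e-12)^2
  for (i in seq_len(nrow(hkl))) {
    qh <- hkl$q[i]
    P <- if (peak == "lorentz") {
      (delta / (2 * pi)) / ((q - qh)^2 + (delta / 2)^2)
    } else {
      s <- delta / (2 * sqrt(2 * log(2)))
      stats::dnorm(q, qh, s)
    }
    Z <- Z + hkl$weight[i] * qh^2 / q2 * P
  }
  bq <- if (is.null(beta)) rep(1, length(q))
        else if (is.function(beta)) beta(q) else rep(beta, length(q))
  S <- 1 + bq * (Z * exp(-q^2 * u2 / 3) - 1)
  dataSet(cbind(q, S),
          attributes = list(lattice = lattice, a = a,
                            domainsize = domainsize, u2 = u2,
                            peaks = hkl$q),
          roles = c(X = 1L, Y = 2L))
}

# distinct reciprocal-lattice shells up to qmax with multiplicity-weighted
# normalized cell structure factors; weight = m_hkl |F|^2 / N_cell
.enumerate_hkl <- function(lattice, a, qmax) {
  L <- ceiling(qmax * a / (2 * pi)) + 1L
  if ((2 * L + 1)^3 > 1e5 * 8)
    stop("qmax enumerates too many hkl points; reduce qmax")
  rng <- (-L):L
  hkl <- as.matrix(expand.grid(h = rng, k = rng, l = rng))
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  F2 <- switch(lattice,
    sc  = rep(1, nrow(hkl)),
    bcc = ifelse((rowSums(hkl) %% 2) == 0, 4, 0) / 2,
    fcc = {
      par <- hkl %% 2
      same <- (par[, 1] == par[, 2]) & (par[, 2] == par[, 3])
      ifelse(same, 16, 0) / 4
    })
  qh <- 2 * pi / a * sqrt(rowSums(hkl^2))
  keep <- F2 > 0 & qh <= qmax * 1.05
  qh <- qh[keep]; F2 <- F2[keep]
  key <- round(qh, 9)
  agg <- stats::aggregate(F2, by = list(q = key), FUN = sum)
  data.frame(q = agg$q, weight = agg$x)
}
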