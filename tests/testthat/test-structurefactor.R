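test_that("PY hard spheres: ideal-gas limit, compressibility, peak", {
  q <- seq(0.01, 4, 0.01)
  expect_true(all(ds_y(sf_py(q, 3, 0)) == 1))
  for (phi in c(0.1, 0.2, 0.3, 0.4)) {
    S0 <- ds_y(sf_py(1e-6, 3, phi))[1]
    expect_lt(abs(S0 - (1 - phi)^4 / (1 + 2 * phi)^2), 1e-4)
  }
  S <- sf_py(q, 3, 0.4)
  ipk <- which.max(ds_y(S))
  expect_gt(ds_y(S)[ipk], 1)
  expect_gt(ds_x(S)[ipk] * 6, 2 * pi * 0.8)   # peak near q sigma ~ 2 pi
  # S -> 1 at large q
  expect_lt(abs(ds_y(sf_py(30, 3, 0.4))[1] - 1), 1e-3)
  expect_error(sf_py(q, 3, 0.8), "phi")
})

test_that("sticky spheres: PY limit, stickiness trend, phase boundary", {
  q <- seq(0.01, 6, 0.01)
  s_inf <- sf_sticky(q, 3, 0.3, tau = 1e8)
  expect_close(ds_y(s_inf), ds_y(sf_py(q, 3, 0.3)), 1e-6)
  # stronger adhesion (smaller tau) raises the compressibility S(0)
  S0 <- vapply(c(5, 1, 0.5, 0.2), function(tau)
    ds_y(sf_sticky(1e-6, 3, 0.2, tau))[1], numeric(1))
  expect_true(all(diff(S0) > 0))
  expect_lt(abs(ds_y(sf_sticky(300, 3, 0.2, 0.5))[1] - 1), 1e-3)
  expect_error(sf_sticky(q, 3, 0.3, tau = 0.01), "two-phase")
  # adhesive solution keeps the hard core empty
  Ss <- sf_sticky(seq(0.005, 130, 0.005), R = 0.5, phi = 0.25, tau = 0.4)
  n <- 6 * 0.25 / pi
  g <- suppressWarnings(sq_to_gr(Ss, n, seq(0.1, 0.85, 0.05), window = "lanczos"))
  expect_lt(max(abs(ds_y(g))), 0.03)
})

test_that("RMSA reduces to PY for an uncharged system", {
  q <- seq(0.01, 5, 0.01)
  for (phi in c(0.2, 0.4)) {
    s <- sf_rmsa(q, 3.1, phi, gamma = 0, ak = 2)
    expect_close(ds_y(s), ds_y(sf_py(q, 3.1, phi)), 1e-4)
  }
})

test_that("RMSA approaches PY in the fully screened weak limit", {
  q <- seq(0.05, 5, 0.05)
  s <- sf_rmsa(q, 3.1, 0.4, gamma = 0.05, ak = 50, rescale = FALSE)
  expect_lt(max(abs(ds_y(s) / ds_y(sf_py(q, 3.1, 0.4)) - 1)), 0.01)
})

test_that("RMSA selected root beats every rejected root on the core test", {
  set.seed(21)
  for (k in 1:6) {
    eta <- stats::runif(1, 0.1, 0.45)
    gek <- stats::runif(1, 0.5, 5)
    z <- stats::runif(1, 0.3, 20)
    roots <- scatterfit:::.msa_roots(eta, gek, z)
    if (length(roots) < 2) next
    qg <- seq(0.1, 600, length.out = 6000)
    rwin <- seq(0.4, 0.6, length.out = 21)
    rho <- 6 * eta / pi
    win <- scatterfit:::.sinc(qg / 600)
    scores <- vapply(roots, function(cf) {
      S <- 1 / Mod(scatterfit:::.msa_qhat(qg, cf$a, cf$b, cf$C, cf$A,
                                          12 * eta, z))^2
      if (any(!is.finite(S)) || any(S <= 0)) return(Inf)
      f <- win * qg * (S - 1)
      g <- 1 + scatterfit:::.sine_transform(qg, f, rwin) /
        (2 * pi^2 * rho * rwin)
      mean(abs(g))
    }, numeric(1))
    sel <- scatterfit:::.msa_select(eta, gek, z)
    expect_equal(which.min(scores), sel$root_index)
    expect_lt(min(scores), 0.05)
  }
})

test_that("RMSA monotonicity: stronger repulsion suppresses S(0)", {
  S0 <- vapply(c(0.5, 1, 2, 4, 8), function(g)
    ds_y(sf_rmsa(1e-4, 3.1, 0.3, gamma = g, ak = 2, rescale = FALSE))[1],
    numeric(1))
  expect_true(all(diff(S0) < 0))
})

test_that("RMSA rescaling engages at low volume fraction", {
  q <- seq(0.01, 3, 0.01)
  s <- sf_rmsa(q, 3.1, phi = 0.05, gamma = 3, ak = 1)
  expect_identical(ds_attr(s, "rescaled"), 1)
  expect_gt(ds_attr(s, "phi_eff"), 0.05)
  expect_gt(ds_attr(s, "contact"), -1e-3)
  expect_true(all(ds_y(s) > 0))
})

test_that("sine transform: ideal gas, PY hard core, qmax convergence", {
  q <- seq(0.01, 100, 0.01)
  ideal <- dataSet(cbind(q, rep(1, length(q))), roles = c(X = 1L, Y = 2L))
  g <- sq_to_gr(ideal, n = 0.1, r = seq(0.5, 5, 0.5))
  expect_close(ds_y(g), rep(1, 10), 1e-10)
  # PY at phi = 0.3: empty core, g -> 1 far away
  R <- 1
  n <- 0.3 / (4 * pi * R^3 / 3)
  Sq <- sf_py(seq(0.005, 120, 0.005), R, 0.3)
  r <- c(seq(0.2, 1.8 * R, 0.1), 10 * R)
  gg <- ds_y(sq_to_gr(Sq, n, r, window = "lanczos"))
  expect_lt(max(abs(gg[r < 1.8 * R])), 0.05)
  expect_lt(abs(gg[length(gg)] - 1), 0.02)
  # doubling qmax changes g by < 0.01
  S1 <- sf_py(seq(0.005, 60, 0.005), R, 0.3)
  g1 <- ds_y(sq_to_gr(S1, n, r, window = "lanczos"))
  expect_lt(max(abs(g1 - gg)), 0.01)
  # truncation warning for short q range
  Sshort <- sf_py(seq(0.01, 3, 0.01), R, 0.3)
  expect_warning(sq_to_gr(Sshort, n, r), "truncated")
})

test_that("lattice peaks sit on the reciprocal lattice with extinctions", {
  a <- 5
  q <- seq(0.5, 4.5, 0.002)
  base <- 2 * pi / a
  Ssc <- sf_lattice(q, "sc", a, domainsize = 200)
  psc <- ds_attr(Ssc, "peaks")
  expect_close(psc[1:3] / base, sqrt(c(1, 2, 3)), 1e-9)
  Sbcc <- sf_lattice(q, "bcc", a, domainsize = 200)
  pbcc <- ds_attr(Sbcc, "peaks")
  expect_close(pbcc[1:3] / base, sqrt(c(2, 4, 6)), 1e-9)  # (100) absent
  Sfcc <- sf_lattice(q, "fcc", a, domainsize = 200)
  pfcc <- ds_attr(Sfcc, "peaks")
  expect_close(pfcc[1:3] / base, sqrt(c(3, 4, 8)), 1e-9)  # mixed parity out
})

test_that("isolated lattice peak integrates to its weighted |F|^2", {
  a <- 5
  base <- 2 * pi / a
  # fine grid around the isolated sc (100) peak, u2 = 0, huge domain
  q <- seq(base - 0.25, base + 0.25, 5e-5)
  S <- sf_lattice(q, "sc", a, domainsize = 5e3, u2 = 0)
  # S = Z here (u2 = 0, beta = 1), so the peak integral of Z is the
  # integral of (S - 1) plus the window width
  integral <- sum(ds_y(S) - 1) * 5e-5 + 0.5
  # m(100) = 6, |F|^2/Ncell = 1
  expect_equal(integral, 6, tolerance = 0.01)
})

test_that("explicit bcc cluster shows the analytic peaks plus finite-size",
{
  a <- 1
  cl <- lattice_cloud("bcc", a, "cube", 6 * a)
  q <- seq(5, 12, 0.02)
  I <- cloud_intensity(cl, q, grid = fibonacci_sphere(140))
  y <- ds_y(I) / nrow(cl$positions)
  # strongest explicit peak within grid resolution of the (110) position
  expect_lt(abs(q[which.max(y)] - 2 * pi * sqrt(2) / a), 0.1)
  # forbidden sc (100) position only carries finite-size intensity:
  i100 <- y[which.min(abs(q - 2 * pi / a))]
  expect_gt(i100, 0)
  expect_lt(i100, max(y) / 10)
})
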