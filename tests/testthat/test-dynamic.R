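test_that("intermediate scattering functions: normalization and limits", {
  t <- seq(0, 20, 0.1)
  I <- intermediate_scattering("diffusion", t, q = 1, D = 0.1)
  expect_equal(ds_y(I)[1], 1)
  expect_true(all(diff(ds_y(I)) < 0))
  # stretched with beta = 1 is the simple exponential
  Is <- intermediate_scattering("stretched", t, q = 1, D = 0.1, beta = 1)
  expect_close(ds_y(Is), ds_y(I), 1e-12)
  # jump diffusion -> free diffusion as tau -> 0
  Ij <- intermediate_scattering("jumpdiffusion", t, q = 1, D = 0.1,
                                tau = 1e-12)
  expect_close(ds_y(Ij), ds_y(I), 1e-10)
  expect_error(intermediate_scattering("stretched", t, 1, D = 1, beta = 3),
               "beta")
})

test_that("Lorentzian spectra: HWHM, saturation, unit area", {
  w <- seq(-200, 200, 0.01)
  s <- lorentzian_w("transdiff", w, q = 1.3, D = 1)
  expect_equal(hwhm(s), 1.3^2, tolerance = 0.01 / 1.69)
  expect_equal(sum(ds_y(s)) * 0.01, 1, tolerance = 1e-3)
  # jump diffusion saturates at 1/tau: D q^2 tau = 100
  tau <- 0.5
  qbig <- sqrt(100 / tau)       # with D = 1
  sj <- lorentzian_w("jumpdiff", seq(-30, 30, 0.002), q = qbig, D = 1,
                     tau = tau)
  expect_equal(hwhm(sj), 1 / tau, tolerance = 0.011)
  expect_error(lorentzian_w("transdiff", w, 1, D = -1), "positive")
})

test_that("diffusion in a sphere: EISF, completeness, confinement plateau", {
  w <- seq(-60, 60, 0.02)
  # EISF -> 1 as q -> 0 for both confined models
  s0 <- confined_w("sphere", w, q = 1e-4, D = 1, R = 1)
  expect_equal(ds_attr(s0, "eisf"), 1, tolerance = 1e-6)
  h0 <- confined_w("harmonic", w, q = 1e-4, u2 = 0.5, tau = 1)
  expect_equal(ds_attr(h0, "eisf"), 1, tolerance = 1e-6)
  # amplitude completeness at qR = 3 with cutoffs 7/7
  s3 <- confined_w("sphere", w, q = 3, D = 1, R = 1, l_max = 7, n_max = 7)
  dw <- 0.02
  area <- sum(ds_y(s3)) * dw
  expect_equal(area, 1, tolerance = 2e-3)
  # quasielastic width plateaus at 4.333 D/R^2 as qR -> 0 (within 2%)
  hw <- hwhm(confined_w("sphere", w, q = 0.1, D = 1, R = 1),
             exclude_elastic = TRUE)
  expect_equal(hw, 2.0816^2, tolerance = 0.02)
  # harmonic EISF = exp(-q^2 u2)
  h <- confined_w("harmonic", w, q = 1.2, u2 = 0.5, tau = 1)
  expect_equal(ds_attr(h, "eisf"), exp(-1.2^2 * 0.5), tolerance = 1e-10)
})

test_that("rotational diffusion: sum rule, elastic limit, leading width", {
  w <- seq(-40, 40, 0.01)
  s <- rotational_diffusion_w(w, q = 2, R = 1, Dr = 1, l_max = 10)
  expect_gte(ds_attr(s, "sumrule"), 0.999)
  # q -> 0 spectrum is purely elastic
  s0 <- rotational_diffusion_w(w, q = 1e-5, R = 1, Dr = 1)
  expect_equal(ds_attr(s0, "eisf"), 1, tolerance = 1e-8)
  # small qR: quasielastic part dominated by l = 1, HWHM -> 2 Dr
  sq <- rotational_diffusion_w(seq(-20, 20, 0.005), q = 0.3, R = 1, Dr = 1)
  expect_equal(hwhm(sq, exclude_elastic = TRUE), 2, tolerance = 0.05)
})

test_that("Fourier bridge reproduces frequency-domain widths", {
  w <- seq(-25, 25, 0.01)
  # exact Lorentzian pair
  s <- time_to_frequency(function(t) exp(-0.7 * t), w)
  expect_equal(hwhm(s), 0.7, tolerance = 0.01 / 0.7)
  # constant I(t) = 1 gives back the resolution function
  sres <- time_to_frequency(function(t) rep(1, length(t)), w,
                            resolution = 0.5)
  expect_equal(hwhm(sres), sqrt(2 * log(2)) * 0.5, tolerance = 0.01)
  expect_equal(sum(ds_y(sres)) * 0.01, 1, tolerance = 1e-3)
  # time-domain vs frequency-domain HWHM over a q scan, within 2%
  D <- 0.5; tau <- 0.3
  for (q in c(0.2, 0.7, 1.4, 2)) {
    wq <- seq(-40, 40, 0.005)
    ht <- hwhm(time_to_frequency(function(t)
      ds_y(intermediate_scattering("diffusion", t, q, D = D)), wq))
    expect_equal(ht, D * q^2, tolerance = 0.02 * D * q^2 + 1e-4)
    hj <- hwhm(time_to_frequency(function(t)
      ds_y(intermediate_scattering("jumpdiffusion", t, q, D = D,
                                   tau = tau)), wq))
    hjw <- hwhm(lorentzian_w("jumpdiff", wq, q, D = D, tau = tau))
    expect_equal(hj, hjw, tolerance = 0.02 * hjw + 1e-4)
  }
})

test_that("convolution: delta identity, width addition, associativity", {
  w <- seq(-50, 50, 0.01)
  dwstep <- 0.01
  l1 <- lorentzian_w("transdiff", w, q = 1, D = 0.8)
  # unit-area central spike is the identity
  spike <- scatterfit:::.spectrum(w, {
    s <- numeric(length(w)); s[which.min(abs(w))] <- 1 / dwstep; s
  }, q = 1)
  cid <- convolve_w(l1, spike)
  expect_close(ds_y(cid), ds_y(l1), 1e-10)
  # two Lorentzians add their widths within 1%
  l2 <- lorentzian_w("transdiff", w, q = 1, D = 1.4)
  cc <- convolve_w(l1, l2)
  expect_equal(hwhm(cc), 2.2, tolerance = 0.01)
  # area multiplies
  expect_equal(sum(ds_y(cc)) * dwstep,
               sum(ds_y(l1)) * dwstep * sum(ds_y(l2)) * dwstep,
               tolerance = 1e-3)
  # associativity (window wide enough that edge truncation is negligible)
  wb <- seq(-400, 400, 0.05)
  b1 <- lorentzian_w("transdiff", wb, q = 1, D = 0.8)
  b2 <- lorentzian_w("transdiff", wb, q = 1, D = 1.4)
  b3 <- lorentzian_w("transdiff", wb, q = 1, D = 0.5)
  c1 <- convolve_w(convolve_w(b1, b2), b3)
  c2 <- convolve_w(b1, convolve_w(b2, b3))
  expect_close(ds_y(c1), ds_y(c2), 1e-6)
  # composite with zero harmonic fraction reduces to trans x rot
  rot <- rotational_diffusion_w(w, q = 1, R = 1, Dr = 0.5, l_max = 8)
  harm <- confined_w("harmonic", w, q = 1, u2 = 0.4, tau = 1)
  f <- 0
  mix <- scatterfit:::.spectrum(w, (1 - f) * ds_y(spike) + f * ds_y(harm),
                                q = 1)
  full <- convolve_w(convolve_w(l1, rot), mix)
  plain <- convolve_w(l1, rot)
  expect_close(ds_y(full), ds_y(plain), 1e-8)
  expect_error(convolve_w(l1, lorentzian_w("transdiff",
                                           seq(-10, 10, 0.01), 1, 1)),
               "grid")
})

test_that("channel binning preserves constants and integrals", {
  w <- seq(-10, 10, 0.01)
  s <- lorentzian_w("transdiff", w, q = 1, D = 1)
  # edges aligned with the grid leave the spectrum unchanged
  edges <- seq(-10.005, 10.005, 0.01)
  sb <- bin_channels(s, edges)
  expect_close(ds_y(sb), ds_y(s), 1e-12)
  # constant spectrum stays constant
  cst <- scatterfit:::.spectrum(w, rep(2, length(w)), q = 1)
  cb <- bin_channels(cst, seq(-10, 10, 0.5))
  expect_true(all(abs(ds_y(cb) - 2) < 1e-12))
  # 2:1 downbinning halves the points and conserves the covered integral
  e2 <- seq(-10.005, 10.005, 0.02)
  s2 <- bin_channels(s, e2)
  expect_equal(length(ds_y(s2)), 1000)
  covered <- w >= e2[1] & w < e2[length(e2)]
  expect_equal(sum(ds_y(s2)) * 0.02, sum(ds_y(s)[covered]) * 0.01,
               tolerance = 1e-6)
  expect_warning(bin_channels(s, c(-20, -15, 0, 15)), "empty")
})

test_that("HWHM extraction: Gaussian factor and grid convergence", {
  # Gaussian of width sigma: HWHM = sqrt(2 ln 2) sigma within 0.5%
  sig <- 2
  for (dw in c(0.02, 0.01)) {
    w <- seq(-15, 15, dw)
    g <- scatterfit:::.spectrum(w, stats::dnorm(w, 0, sig), q = 1)
    expect_equal(hwhm(g), sqrt(2 * log(2)) * sig, tolerance = 0.005)
  }
  # error when no crossing exists
  w <- seq(-0.5, 0.5, 0.01)
  broad <- scatterfit:::.spectrum(w, stats::dnorm(w, 0, 50), q = 1)
  expect_error(hwhm(broad), "widen")
})
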