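test_that("parameter resolution follows the priority order", {
  dc <- decay_collection()
  model <- function(t, q, D) exp(-q^2 * D * t)
  b <- resolve_parameters(model, dc, free = list(D = 0.1))
  src <- stats::setNames(vapply(b, `[[`, "", "source"),
                         vapply(b, `[[`, "", "name"))
  expect_identical(src[["q"]], "fixed-attribute")
  expect_identical(src[["D"]], "free-common")
  # attribute values bound per dataset
  expect_equal(b[[which(names(src) == "q")]]$value, c(0.5, 1))
  # user-fixed beats the attribute
  b2 <- resolve_parameters(model, dc, free = list(D = 0.1),
                           fixed = list(q = 2))
  expect_identical(b2[[1]]$source, "fixed-user")
  # list start -> independent with one value per dataset
  b3 <- resolve_parameters(model, dc, free = list(D = c(0.1, 0.2)))
  expect_identical(b3[[2]]$source, "free-independent")
  # length mismatch and unresolved parameters raise
  expect_error(resolve_parameters(model, dc, free = list(D = c(1, 2, 3))),
               "length")
  expect_error(resolve_parameters(function(t, q, D, missing_par) 0, dc,
                                  free = list(D = 1)), "missing_par")
  # model default used when nothing else resolves
  b4 <- resolve_parameters(function(t, q, D, bg = 0) 0, dc,
                           free = list(D = 1))
  expect_identical(b4[[3]]$source, "model-default")
})

test_that("noise-free linear data is fit exactly with chi2 ~ 0", {
  x <- seq(0, 10, 0.5)
  dc <- dataCollection(dataSet(cbind(x, 2 * x + 1)))
  fit <- fit_collection(dc, function(x, a, b) a * x + b,
                        free = list(a = 0.5, b = 0))
  expect_close(coef(fit), c(a = 2, b = 1), 1e-8)
  expect_lt(fit$chi2_reduced, 1e-12)
})

test_that("common D is recovered within 3 sigma from noisy two-q decays", {
  dc <- decay_collection(qs = c(0.5, 1), D = 0.1, noise = 0.01, seed = 42)
  fit <- fit_collection(dc, function(t, q, D) exp(-q^2 * D * t),
                        free = list(D = 0.05))
  D <- coef(fit)[["D"]]
  sD <- fit$errors$D
  expect_true(is.finite(sD) && sD > 0)
  expect_lt(abs(D - 0.1), 3 * sD)
})

test_that("independent fits on identical datasets equal the common fit", {
  x <- seq(0, 10, 0.5)
  mk <- function() dataSet(cbind(x, 3 * exp(-0.4 * x)))
  dc <- dataCollection(list(mk(), mk()))
  model <- function(x, a, k) a * exp(-k * x)
  fc <- fit_collection(dc, model, free = list(a = 1, k = 0.2))
  fi <- fit_collection(dc, model, free = list(a = c(1, 1), k = 0.2))
  expect_close(fi$parameters$a, rep(fc$parameters$a, 2), 1e-6)
})

test_that("reported chi2 equals recomputation from model curves", {
  dc <- decay_collection(seed = 7)
  fit <- fit_collection(dc, function(t, q, D) exp(-q^2 * D * t),
                        free = list(D = 0.05))
  chi2 <- 0
  for (i in seq_along(dc)) {
    r <- (ds_y(dc[[i]]) - ds_y(fit$model_curves[[i]])) / ds_ey(dc[[i]])
    chi2 <- chi2 + sum(r^2)
  }
  expect_lt(abs(chi2 - fit$chi2), 1e-10 * max(1, chi2))
})

test_that("all algorithms recover generating parameters on noise-free data", {
  x <- seq(0, 10, 0.25)
  dc <- dataCollection(dataSet(cbind(x, 2.5 * exp(-0.3 * x))))
  model <- function(x, a, k) a * exp(-k * x)
  for (alg in c("leastsquare", "neldermead", "bfgs")) {
    fit <- fit_collection(dc, model, free = list(a = 1, k = 0.1),
                          algorithm = alg)
    expect_close(coef(fit) / c(2.5, 0.3), c(1, 1), 1e-6)
  }
  fit_de <- fit_collection(dc, model, free = list(a = 1, k = 0.1),
                           bounds = list(a = c(0.1, 10), k = c(0.01, 2)),
                           algorithm = "diffev", seed = 11)
  expect_close(coef(fit_de) / c(2.5, 0.3), c(1, 1), 1e-4)
})

test_that("diffev is bit-identical for a fixed seed", {
  dc <- decay_collection(seed = 3)
  model <- function(t, q, D) exp(-q^2 * D * t)
  f1 <- fit_collection(dc, model, free = list(D = 0.05),
                       bounds = list(D = c(0.001, 1)),
                       algorithm = "diffev", seed = 99,
                       control = list(maxgen = 40))
  f2 <- fit_collection(dc, model, free = list(D = 0.05),
                       bounds = list(D = c(0.001, 1)),
                       algorithm = "diffev", seed = 99,
                       control = list(maxgen = 40))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$chi2, f2$chi2)
})

test_that("bounds are respected via the logistic transform", {
  x <- seq(0, 10, 0.5)
  dc <- dataCollection(dataSet(cbind(x, 3 * exp(-0.4 * x))))
  fit <- fit_collection(dc, function(x, a, k) a * exp(-k * x),
                        free = list(a = 1, k = 0.55),
                        bounds = list(k = c(0.5, 1)))
  expect_gte(coef(fit)[["k"]], 0.5)
  expect_lte(coef(fit)[["k"]], 1)
  expect_error(fit_collection(dc, function(x, a, k) a * exp(-k * x),
                              free = list(a = 1, k = 0.1),
                              bounds = list(k = c(0.5, 1))), "bounds")
})

test_that("non-finite model output raises naming the parameters", {
  dc <- dataCollection(dataSet(cbind(1:5, 1:5)))
  expect_error(fit_collection(dc, function(x, a) rep(NaN, length(x)),
                              free = list(a = 1)), "non-finite")
})

test_that("model-returned dataSets propagate extra attributes", {
  x <- seq(0, 5, 0.5)
  dc <- dataCollection(dataSet(cbind(x, 2 * x)))
  model <- function(x, a) {
    dataSet(cbind(x, a * x), attributes = list(half_a = a / 2))
  }
  fit <- fit_collection(dc, model, free = list(a = 1))
  expect_equal(ds_attr(fit$model_curves[[1]], "half_a"),
               coef(fit)[["a"]] / 2, tolerance = 1e-6)
})

test_that("fit results serialize through the ASCII dialect", {
  dc <- decay_collection(seed = 5)
  fit <- fit_collection(dc, function(t, q, D) exp(-q^2 * D * t),
                        free = list(D = 0.05))
  back <- read_dat(text = write_dat(fit$model_curves))
  expect_length(back, length(dc))
  expect_identical(back[[1]]$data, unname(fit$model_curves[[1]]$data))
  expect_equal(ds_attr(back[[1]], "D"), fit$parameters$D)
})

test_that("fitting a singleton collection equals fitting the dataSet alone", {
  dc <- decay_collection(qs = 0.7, seed = 8)
  model <- function(t, q, D) exp(-q^2 * D * t)
  f1 <- fit_collection(dc, model, free = list(D = 0.05))
  f2 <- fit_collection(dc[[1]], model, free = list(D = 0.05))
  expect_identical(coef(f1), coef(f2))
})

test_that("simulate evaluates the model with overridden parameters", {
  dc <- decay_collection(qs = c(0.5, 1), D = 0.1, noise = 0, seed = 1)
  fit <- fit_collection(dc, function(t, q, D) exp(-q^2 * D * t),
                        free = list(D = 0.05))
  same <- simulate(fit)
  expect_close(ds_y(same[[1]]), ds_y(fit$model_curves[[1]]), 1e-12)
  # doubling D halves the 1/e time at fixed q
  tg <- seq(0, 50, 0.01)
  s1 <- simulate(fit, x_grid = tg)
  s2 <- simulate(fit, overrides = list(D = 2 * coef(fit)[["D"]]),
                 x_grid = tg)
  te <- function(ds) tg[which.min(abs(ds_y(ds) - exp(-1)))]
  expect_equal(te(s2[[1]]) / te(s1[[1]]), 0.5, tolerance = 0.01)
  # overriding a fixed-attribute parameter changes the output accordingly
  s3 <- simulate(fit, overrides = list(q = 2), x_grid = tg)
  expect_close(ds_y(s3[[1]]), exp(-4 * coef(fit)[["D"]] * tg), 1e-10)
  expect_error(simulate(fit, overrides = list(nope = 1)), "unknown")
})
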