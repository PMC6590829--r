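#' Resolve model parameters against a data collection
#'
#' Determines, for every parameter of a model, where its value comes from
#' when fitting a [dataCollection()].  The priority order is: user-fixed
#' value > free start value > dataset attribute of the same name > model
#' default (the formal's default).  A scalar start makes a parameter
#' free-common (one value shared by all datasets); a list/vector start of
#' length equal to the collection makes it free-independent (one value per
#' dataset).
#'
#' @param model a model function: first formal receives the `X` column,
#'   remaining formals are parameters; or a character vector of parameter
#'   names.
#' @param collection a [dataCollection()].
#' @param free named list of start values (scalar = common, vector of
#'   collection length = independent).
#' @param fixed named list of user-fixed values.
#' @return a list of bindings, each with elements `name`, `source` (one of
#'   `free-common`, `free-independent`, `fixed-user`, `fixed-attribute`,
#'   `model-default`) and `value` (per-dataset vector for attribute and
#'   independent bindings).
#' @examples
#' dc <- dataCollection(lapply(c(.5, 1), function(qv)
#'   dataSet(cbind(1:5, exp(-qv^2 * .1 * (1:5))),
#'           attributes = list(q = qv))))
#' b <- resolve_parameters(function(t, q, D) exp(-q^2 * D * t),
#'                         dc, free = list(D = 0.05))
#' vapply(b, `[[`, "", "source")
#' @export
resolve_parameters <- function(model, collection, free = list(),
                               fixed = list()) {
  stopifnot(inherits(collection, "dataCollection"))
  if (is.function(model)) {
    fl <- formals(model)
    pnames <- names(fl)[-1L]
    defaults <- fl[-1L]
  } else {
    pnames <- model
    defaults <- stats::setNames(vector("list", length(pnames)), pnames)
  }
  nd <- length(collection)
  bad <- setdiff(c(names(free), names(fixed)), pnames)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  both <- intersect(names(free), names(fixed))
  if (length(both))
    stop("parameter(s) both free and fixed: ", paste(both, collapse = ", "))

  lapply(pnames, function(nm) {
    if (nm %in% names(fixed))
      return(list(name = nm, source = "fixed-user", value = fixed[[nm]]))
    if (nm %in% names(free)) {
      v <- unlist(free[[nm]])
      if (length(v) == 1L)
        return(list(name = nm, source = "free-common", value = v))
      if (length(v) != nd)
        stop(sprintf(
          "start values for '%s' have length %d but collection has %d items",
          nm, length(v), nd))
      return(list(name = nm, source = "free-independent", value = v))
    }
    av <- dc_attr(collection, nm, simplify = FALSE)
    if (!any(vapply(av, function(x) length(x) == 1L && is.na(x), logical(1)))) {
      vals <- vapply(av, function(x) as.numeric(x)[1], numeric(1))
      return(list(name = nm, source = "fixed-attribute", value = vals))
    }
    has_default <- !identical(defaults[[nm]], quote(expr = )) &&
      !is.null(defaults[[nm]]) && is.numeric(defaults[[nm]])
    if (has_default)
      return(list(name = nm, source = "model-default",
                  value = defaults[[nm]]))
    stop(sprintf(paste0("parameter '%s' is unresolved: not fixed, not free, ",
                        "no matching attribute on every dataset, ",
                        "no model default"), nm))
  })
}

#' Simultaneous chi-square fit of a data collection
#'
#' Minimizes
#' \deqn{\chi^2 = \sum_{datasets}\sum_{rows}
#'       \left(\frac{Y - \mathrm{model}(X)}{e_Y}\right)^2}
#' (unit weights where no `eY` column exists) over all free parameters, with
#' free-common parameters shared across datasets and free-independent
#' parameters carrying one value per dataset (packed contiguously per name).
#' Parameters named like dataset attributes are bound per dataset
#' automatically; see [resolve_parameters()].
#'
#' Algorithms: `"leastsquare"` (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]; the default), `"neldermead"` and `"bfgs"`
#' ([stats::optim()]), and `"diffev"` (a seeded differential-evolution
#' search, reproducible for a given `seed`, refined by a final
#' Levenberg-Marquardt polish).  Box bounds are imposed through a logistic
#' transform of the parameters for the gradient-based algorithms and
#' natively for `diffev`; `diffev` requires bounds (defaulting to start
#' +- 10 |start| + 1).  Inequality constraints can be supplied as functions
#' of the named parameter values returning >= 0 when satisfied; they are
#' added to the objective as quadratic penalties of weight `penalty`.
#'
#' @param collection a [dataCollection()] (or single [dataSet()]).
#' @param model function `(x, par1, par2, ...)` returning the model `Y` for
#'   one dataset (a numeric vector or a [dataSet()] whose `Y` is used and
#'   whose extra attributes are propagated into the fit result).
#' @param free named list of start values (scalar = common, vector = one per
#'   dataset).
#' @param fixed named list of fixed parameter values.
#' @param bounds named list of `c(lower, upper)` per parameter.
#' @param algorithm one of `"leastsquare"`, `"neldermead"`, `"bfgs"`,
#'   `"diffev"`.
#' @param seed integer random seed used by `"diffev"`.
#' @param constraints optional list of inequality functions.
#' @param penalty weight of the constraint penalty term.
#' @param control list passed to the underlying optimizer.
#' @return an object of class `scatterFit` with methods [print()],
#'   [summary()], [coef()], [vcov()], [predict()], [residuals()] and
#'   [simulate()].  Elements include `parameters`, `errors`, `covariance`,
#'   `chi2`, `chi2_reduced`, `model_curves` (a `dataCollection`, writable
#'   with [write_dat()]).
#' @examples
#' dc <- dataCollection(dataSet(cbind(0:10, 2 * (0:10) + 1)))
#' fit <- fit_collection(dc, function(x, a, b) a * x + b,
#'                       free = list(a = 1, b = 0))
#' coef(fit)
#' @export
fit_collection <- function(collection, model, free, fixed = list(),
                           bounds = NULL,
                           algorithm = c("leastsquare", "neldermead",
                                         "bfgs", "diffev"),
                           seed = 12345L, constraints = NULL,
                           penalty = 1e6, control = list()) {
  if (inherits(collection, "dataSet")) collection <- dataCollection(collection)
  algorithm <- match.arg(algorithm)
  bindings <- resolve_parameters(model, collection, free, fixed)
  nd <- length(collection)

  frees <- Filter(function(b) startsWith(b$source, "free"), bindings)
  if (!length(frees)) stop("no free parameters")
  # pack free parameters into one vector, contiguously per name
  slots <- list(); start <- numeric(0)
  for (b in frees) {
    k <- length(start)
    nv <- length(b$value)
    slots[[b$name]] <- k + seq_len(nv)
    start <- c(start, as.numeric(b$value))
  }
  pnames_packed <- unlist(lapply(frees, function(b)
    if (length(b$value) == 1L) b$name
    else paste0(b$name, "[", seq_along(b$value), "]")))

  lower <- rep(-Inf, length(start)); upper <- rep(Inf, length(start))
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      if (!nm %in% names(slots)) next
      lower[slots[[nm]]] <- bounds[[nm]][1]
      upper[slots[[nm]]] <- bounds[[nm]][2]
    }
    if (any(start < lower | start > upper))
      stop("start values violate bounds")
  }

  pars_for <- function(p, i) {
    out <- list()
    for (b in bindings) {
      out[[b$name]] <- switch(b$source,
        "free-common" = p[slots[[b$name]]],
        "free-independent" = p[slots[[b$name]]][i],
        "fixed-user" = b$value,
        "fixed-attribute" = b$value[i],
        "model-default" = b$value)
    }
    out
  }

  extra_attrs <- list()
  eval_model <- function(p, i, x = NULL) {
    ds <- collection[[i]]
    if (is.null(x)) x <- ds_x(ds)
    v <- do.call(model, c(list(x), pars_for(p, i)))
    if (inherits(v, "dataSet")) {
      if (length(v$attributes)) extra_attrs[[i]] <<- v$attributes
      v <- ds_y(v)
    }
    v
  }

  residuals_fun <- function(p) {
    unlist(lapply(seq_len(nd), function(i) {
      ds <- collection[[i]]
      m <- eval_model(p, i)
      if (any(!is.finite(m)))
        stop("model returned non-finite values at parameters: ",
             paste(sprintf("%s=%.6g", pnames_packed, p), collapse = ", "))
      ey <- ds_ey(ds)
      r <- ds_y(ds) - m
      if (!is.null(ey) && all(ey > 0)) r <- r / ey
      r
    }))
  }
  pen_fun <- function(p) {
    if (is.null(constraints)) return(0)
    v <- vapply(constraints, function(g) {
      gv <- g(stats::setNames(as.list(p[vapply(names(slots), function(nm)
        slots[[nm]][1], numeric(1))]), names(slots)))
      min(gv, 0)
    }, numeric(1))
    penalty * sum(v^2)
  }
  chi2_fun <- function(p) sum(residuals_fun(p)^2) + pen_fun(p)

  bounded <- any(is.finite(lower)) || any(is.finite(upper))
  to_nat <- function(t) .logistic_map(t, lower, upper)
  to_t <- function(p) .logistic_unmap(p, lower, upper)

  if (algorithm == "leastsquare") {
    if (bounded) {
      out <- minpack.lm::nls.lm(par = to_t(start),
                                fn = function(t) residuals_fun(to_nat(t)),
                                control = do.call(minpack.lm::nls.lm.control,
                                                  control))
      phat <- to_nat(out$par)
    } else {
      out <- minpack.lm::nls.lm(par = start, fn = residuals_fun,
                                control = do.call(minpack.lm::nls.lm.control,
                                                  control))
      phat <- out$par
    }
  } else if (algorithm %in% c("neldermead", "bfgs")) {
    meth <- if (algorithm == "neldermead") "Nelder-Mead" else "BFGS"
    obj <- if (bounded) function(t) chi2_fun(to_nat(t)) else chi2_fun
    st <- if (bounded) to_t(start) else start
    if (length(st) == 1L && meth == "Nelder-Mead") meth <- "BFGS"
    ctl <- utils::modifyList(list(maxit = 10000, reltol = 1e-15,
                                  abstol = 1e-15,
                                  ndeps = rep(1e-7, length(st))),
                             control)
    if (meth == "Nelder-Mead") ctl$ndeps <- NULL
    out <- stats::optim(st, obj, method = meth, control = ctl)
    phat <- if (bounded) to_nat(out$par) else out$par
  } else {                               # diffev
    lo <- ifelse(is.finite(lower), lower, start - 10 * abs(start) - 1)
    hi <- ifelse(is.finite(upper), upper, start + 10 * abs(start) + 1)
    de <- .diffev(chi2_fun, lo, hi, seed = seed, control = control)
    pol <- try(minpack.lm::nls.lm(par = de$par, fn = residuals_fun),
               silent = TRUE)
    phat <- if (!inherits(pol, "try-error") &&
                sum(pol$fvec^2) <= de$value) pol$par else de$par
    phat <- pmin(pmax(phat, lo), hi)
  }

  res <- residuals_fun(phat)
  chi2 <- sum(res^2)
  npts <- length(res)
  dof <- max(1L, npts - length(phat))
  chi2_red <- chi2 / dof

  # covariance from the finite-difference jacobian on the natural scale
  J <- .num_jacobian(residuals_fun, phat)
  JtJ <- crossprod(J)
  cov <- try(solve(JtJ) * chi2_red, silent = TRUE)
  if (inherits(cov, "try-error") || any(!is.finite(cov))) {
    warning("singular covariance; parameter errors unavailable")
    cov <- matrix(NA_real_, length(phat), length(phat))
  }
  errs <- sqrt(pmax(diag(cov), 0))
  dimnames(cov) <- list(pnames_packed, pnames_packed)

  parameters <- list(); errors <- list()
  for (b in bindings) {
    if (startsWith(b$source, "free")) {
      parameters[[b$name]] <- phat[slots[[b$name]]]
      errors[[b$name]] <- errs[slots[[b$name]]]
    } else parameters[[b$name]] <- b$value
  }

  curves <- dataCollection(lapply(seq_len(nd), function(i) {
    ds <- collection[[i]]
    x <- ds_x(ds)
    y <- eval_model(phat, i)
    at <- pars_for(phat, i)
    at <- at[vapply(at, is.numeric, logical(1))]
    if (length(extra_attrs) >= i && !is.null(extra_attrs[[i]]))
      at <- utils::modifyList(at, extra_attrs[[i]])
    dataSet(cbind(x, y), attributes = at, roles = c(X = 1L, Y = 2L))
  }))

  structure(list(parameters = parameters, errors = errors,
                 covariance = cov, chi2 = chi2, chi2_reduced = chi2_red,
                 dof = dof, n_points = npts,
                 model_curves = curves, bindings = bindings,
                 model = model, data = collection,
                 model_name = deparse(substitute(model))[1],
                 algorithm = algorithm, seed = seed,
                 slots = slots, packed = phat, packed_names = pnames_packed),
            class = "scatterFit")
}

.logistic_map <- function(t, lower, upper) {
  p <- t
  b <- is.finite(lower) & is.finite(upper)
  p[b] <- lower[b] + (upper[b] - lower[b]) / (1 + exp(-t[b]))
  lo <- is.finite(lower) & !is.finite(upper)
  p[lo] <- lower[lo] + exp(t[lo])
  hi <- !is.finite(lower) & is.finite(upper)
  p[hi] <- upper[hi] - exp(t[hi])
  p
}

.logistic_unmap <- function(p, lower, upper) {
  t <- p
  b <- is.finite(lower) & is.finite(upper)
  f <- pmin(pmax((p[b] - lower[b]) / (upper[b] - lower[b]), 1e-10), 1 - 1e-10)
  t[b] <- log(f / (1 - f))
  lo <- is.finite(lower) & !is.finite(upper)
  t[lo] <- log(pmax(p[lo] - lower[lo], 1e-10))
  hi <- !is.finite(lower) & is.finite(upper)
  t[hi] <- log(pmax(upper[hi] - p[hi], 1e-10))
  t
}

.num_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    J[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}

# seeded differential evolution (rand/1/bin)
.diffev <- function(fn, lower, upper, seed = 12345L, control = list()) {
  ctl <- utils::modifyList(list(np = max(20L, 10L * length(lower)),
                                F = 0.8, CR = 0.9, maxgen = 200L,
                                tol = 1e-10), control)
  set.seed(seed)
  d <- length(lower)
  pop <- matrix(stats::runif(ctl$np * d, lower, upper), ctl$np, d,
                byrow = TRUE)
  cost <- apply(pop, 1L, function(p) tryCatch(fn(p), error = function(e) Inf))
  for (gen in seq_len(ctl$maxgen)) {
    for (i in seq_len(ctl$np)) {
      idx <- sample(setdiff(seq_len(ctl$np), i), 3L)
      trial <- pop[idx[1], ] + ctl$F * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(d) < ctl$CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tc <- tryCatch(fn(trial), error = function(e) Inf)
      if (tc <= cost[i]) { pop[i, ] <- trial; cost[i] <- tc }
    }
    if (max(cost) - min(cost) < ctl$tol * (1 + abs(min(cost)))) break
  }
  ib <- which.min(cost)
  list(par = pop[ib, ], value = cost[ib], generations = gen)
}

#' @export
print.scatterFit <- function(x, ...) {
  cat(sprintf("scatterFit (%s): %d dataset(s), chi2_red = %.4g\n",
              x$algorithm, length(x$data), x$chi2_reduced))
  for (nm in names(x$parameters)) {
    v <- x$parameters[[nm]]
    e <- x$errors[[nm]]
    src <- x$bindings[[which(vapply(x$bindings, `[[`, "", "name") == nm)]]$source
    if (!is.null(e))
      cat(sprintf("  %s = %s +- %s  (%s)\n", nm,
                  paste(signif(v, 6), collapse = ", "),
                  paste(signif(e, 3), collapse = ", "), src))
    else
      cat(sprintf("  %s = %s  (%s)\n", nm,
                  paste(signif(unique(v), 6), collapse = ", "), src))
  }
  invisible(x)
}

#' @export
summary.scatterFit <- function(object, ...) {
  print(object)
  cat(sprintf("  chi2 = %.6g on %d points, %d d.o.f.\n",
              object$chi2, object$n_points, object$dof))
  invisible(object)
}

#' @export
coef.scatterFit <- function(object, ...) {
  stats::setNames(object$packed, object$packed_names)
}

#' @export
vcov.scatterFit <- function(object, ...) object$covariance

#' @export
residuals.scatterFit <- function(object, ...) {
  unlist(lapply(seq_along(object$data), function(i) {
    ds_y(object$data[[i]]) - ds_y(object$model_curves[[i]])
  }))
}

#' @export
predict.scatterFit <- function(object, newdata = NULL, item = 1L, ...) {
  if (is.null(newdata)) return(ds_y(object$model_curves[[item]]))
  sim <- simulate(object, x_grid = newdata)
  ds_y(sim[[item]])
}

#' Simulate a fitted model with modified parameters
#'
#' Evaluates the fitted model with the best-fit parameter values, optionally
#' replacing any of them (free or bound) through `overrides`, on the original
#' or a new `X` grid.  The returned curves carry all parameter values as
#' attributes, so the effect of a parameter variation can be compared
#' directly against `object$model_curves`.
#'
#' @param object a `scatterFit`.
#' @param nsim,seed unused (S3 signature compatibility).
#' @param overrides named list of parameter values replacing the fitted ones.
#' @param x_grid optional replacement `X` grid for all curves.
#' @param ... unused.
#' @return a [dataCollection()] of simulated curves.
#' @export
simulate.scatterFit <- function(object, nsim = 1L, seed = NULL,
                                overrides = list(), x_grid = NULL, ...) {
  bn <- vapply(object$bindings, `[[`, "", "name")
  bad <- setdiff(names(overrides), bn)
  if (length(bad))
    stop("unknown override parameter(s): ", paste(bad, collapse = ", "))
  nd <- length(object$data)
  dataCollection(lapply(seq_len(nd), function(i) {
    pars <- list()
    for (b in object$bindings) {
      v <- object$parameters[[b$name]]
      v <- switch(b$source,
        "free-independent" = v[i],
        "fixed-attribute" = v[i],
        v[1])
      if (b$name %in% names(overrides)) v <- overrides[[b$name]]
      pars[[b$name]] <- v
    }
    x <- if (is.null(x_grid)) ds_x(object$data[[i]]) else x_grid
    y <- do.call(object$model, c(list(x), pars))
    if (inherits(y, "dataSet")) y <- ds_y(y)
    dataSet(cbind(x, y), attributes = pars[vapply(pars, is.numeric,
                                                  logical(1))],
            roles = c(X = 1L, Y = 2L))
  }))
}
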