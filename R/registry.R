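#' Model registry
#'
#' Named registry of intensity models `I(q; ...)` so that scripts and the
#' command-line tool can refer to models by name.  A registered model is a
#' function whose first argument is `q`; its remaining formals are the
#' parameters visible to [fit_collection()].
#'
#' @param name registry key.
#' @param fun model function `(q, ...)` returning a numeric vector or a
#'   [dataSet()].
#' @param description one-line description.
#' @export
register_model <- function(name, fun, description = "") {
  stopifnot(is.character(name), is.function(fun))
  .registry[[name]] <- list(fun = fun, description = description,
                            parameters = names(formals(fun))[-1L])
  invisible(name)
}

#' @rdname register_model
#' @export
get_model <- function(name) {
  m <- .registry[[name]]
  if (is.null(m)) stop("unknown model '", name, "'; see list_models()")
  m
}

#' @rdname register_model
#' @return `list_models` returns a data frame of names, parameters and
#'   descriptions.
#' @export
list_models <- function() {
  nm <- ls(.registry)
  data.frame(name = nm,
             parameters = vapply(nm, function(n)
               paste(.registry[[n]]$parameters, collapse = ", "), ""),
             description = vapply(nm, function(n)
               .registry[[n]]$description, ""),
             row.names = NULL)
}

.registry <- new.env(parent = emptyenv())

.register_builtins <- function() {
  register_model("sphere",
    function(q, R = 3, contrast = 1) ds_y(ff_sphere(q, R, contrast)),
    "homogeneous sphere form factor")
  register_model("gaussian_chain",
    function(q, Rg = 3) ds_y(ff_gaussian_chain(q, Rg)),
    "Debye Gaussian-chain form factor")
  register_model("beaucage",
    function(q, Rg = 3, d = 2, G = 1) ds_y(ff_beaucage(q, Rg, d, G)),
    "unified Guinier/power-law model")
  register_model("teubner_strey",
    function(q, xi = 5, d = 20) ds_y(ff_teubner_strey(q, xi, d)),
    "Teubner-Strey microemulsion model")
  register_model("py_hard_sphere",
    function(q, R = 3, phi = 0.2) ds_y(sf_py(q, R, phi)),
    "Percus-Yevick hard-sphere structure factor")
  register_model("sticky_hard_sphere",
    function(q, R = 3, phi = 0.2, tau = 0.5) ds_y(sf_sticky(q, R, phi, tau)),
    "Baxter adhesive hard-sphere structure factor")
  register_model("rmsa",
    function(q, R = 3, phi = 0.2, gamma = 2, ak = 2)
      ds_y(sf_rmsa(q, R, phi, gamma, ak)),
    "rescaled MSA screened-Coulomb structure factor")
  register_model("sphere_py",
    function(q, R = 3, phi = 0.2, contrast = 1, n = 1)
      n * ds_y(ff_sphere(q, R, contrast)) * ds_y(sf_py(q, R, phi)),
    "product model n * F(q) * S(q) for interacting spheres")
}

.onLoad <- function(libname, pkgname) {
  .register_builtins()
}
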