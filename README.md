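# scatterfit

An R toolkit for evaluating small-angle scattering (SAXS/SANS) and
quasielastic neutron scattering data.  It couples a metadata-attributed data
container with simultaneous multi-dataset fitting and a model library:
analytic form factors, fluid and crystalline structure factors (including a
rescaled-MSA solver for charged spheres that examines *all* roots of the
closure quartic), Debye-equation point-cloud scattering with Fibonacci
orientational averaging, time- and frequency-domain dynamic models with an
FFT bridge, and instrument smearing / iterative Lake desmearing.

Who it is for: scattering practitioners who want scripted, reproducible
analyses in R — reading column-oriented ASCII data with experimental
metadata, fitting many curves at once with parameters shared or bound to
per-curve attributes, and comparing against standard physical models.

## The core ideas

**Data with metadata.** A `dataSet` is a numeric matrix plus named
attributes (temperature, wavevector, ...), comments, and a column-role map
`X`/`Y`/`eY`.  The ASCII dialect (`read_dat`/`write_dat`) round-trips all of
it losslessly: numeric rows are data, `name value` lines are attributes,
everything else is a comment.  A `dataCollection` holds many such sets and
is the unit of filtering (`filter_collection`) and fitting.

**Attribute-aware fitting.** `fit_collection()` minimizes
χ² = Σ ((Y − model)/eY)² over all datasets at once.  A model parameter
named like a dataset attribute (say `q`) is bound per dataset
automatically; a scalar start value makes a parameter common to all
datasets, a vector start makes it independent per dataset.  Levenberg-
Marquardt, Nelder-Mead, BFGS and a seeded differential evolution are
available; the result is a classed object with `coef`, `vcov`, `summary`,
`predict`, `residuals` and `simulate` methods.

**The RMSA solver.** For charged spheres in a screening electrolyte the
structure factor follows from the mean spherical approximation for the
screened-Coulomb (Yukawa) potential βu(x) = Γ e^{−ak(x−1)}/x, x = r/σ.
The analytic solution reduces to a quartic; `sf_rmsa()` computes **all
four roots** as eigenvalues of the companion matrix, evaluates g(r) for
each by sine transform, selects the root with the smallest |g| inside the
forbidden hard core, and applies the Hansen-Hayter rescaling when the
contact value is negative.  This removes the failures of the classic
single-root Newton iteration, which can land on an unphysical root.

## A worked example

Simultaneous fit of two neutron spin-echo-style decay curves sharing one
diffusion coefficient, with `q` bound from the attributes:

```r
library(scatterfit)

t  <- seq(0, 30, 0.5)
dc <- dataCollection(lapply(c(0.5, 1.0), function(qv) {
  y  <- exp(-qv^2 * 0.1 * t)
  ey <- pmax(0.01 * y, 1e-6)
  set.seed(round(100 * qv))
  dataSet(cbind(t, y + rnorm(length(t), 0, ey), ey),
          attributes = list(q = qv))
}))

fit <- fit_collection(dc, function(t, q, D) exp(-q^2 * D * t),
                      free = list(D = 0.05))
fit
#> scatterFit (leastsquare): 2 dataset(s), chi2_red = 0.9723
#>   q = 0.5, 1  (fixed-attribute)
#>   D = 0.100009 +- 7.04e-05  (free-common)
```

`D` is recovered within one standard error of the generating value 0.1;
`chi2_red` near 1 says the 1% error bars describe the residuals.  Changed
parameters can be explored with
`simulate(fit, overrides = list(D = 0.2))`, and `write_dat(fit$model_curves,
"fit.dat")` stores the curves with every bound parameter as attributes.

A structure-factor example at the charged-sphere parameter set Γ = 3 kT,
Φ = 0.4, R = 3.1 nm:

```r
S <- sf_rmsa(seq(0.01, 2, 0.01), R = 3.1, phi = 0.4, gamma = 3, ak = 2)
ds_attr(S, "root_index")   # which quartic root is physical (here 2)
ds_attr(S, "contact")      # g at the core boundary: 3.034 (no rescaling)
```

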