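---
title: "Models and numerical methods in scatterfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in scatterfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatterfit)
```

This vignette explains the science implemented in the package: the data
model, the fitting machinery, each scattering and dynamics model with its
assumptions, and the numerical choices made where several defensible
options existed.  Units are nm for lengths, nm^-1 for momentum transfer
`q`, nm^-2 for scattering-length-density (SLD) contrast, ns for time and
ns^-1 for frequency, consistently across all modules.

## Data containers and the ASCII dialect

A `dataSet` is a numeric matrix with named metadata attributes, free-text
comments and a role map assigning columns to `X`, `Y` and optionally `eY`
(the 1-sigma uncertainty of `Y`).  On parsing, a line whose tokens are all
numbers is a data row; an identifier followed by at least one further token
is an attribute (numeric scalar, numeric vector, or — beyond the numeric
case — a raw string); anything else is a comment.  Blocks are split by
blank lines, by attribute/comment lines appearing after data rows, or by a
user keyword.  On writing, comments get a `#` prefix so they can never be
re-read as attributes, numbers are printed with 17 significant digits
(lossless for doubles), and the reserved `.roles` line records the role
map.  The `.roles` convention also settles an ambiguity of the plain
dialect: a written one-row vector attribute keeps its name and therefore
never collides with a one-row data block.  This is a deliberate dialect
extension; files without `.roles` default to `X` = column 1, `Y` = column
2, `eY` = column 3 when present, which matches typical reduced SAS files.

`prune()` bin-averages a curve on a linear or logarithmic grid.  Error
propagation had to be chosen: with an input `eY` column the bin uncertainty
is `sqrt(sum(eY^2))/n` (error of the mean of independent points); without
one it is the standard error of the member `Y` values, 0 for single-member
bins.  When no `eY` column exists a new one is appended and the role map
extended, so pruning always yields a weightable curve.

## Simultaneous fitting

`fit_collection()` minimizes the weighted sum of squares over all datasets
of a collection.  The binding rules (user-fixed beats free beats dataset
attribute beats model default) mean a model can be written naturally in
terms of experimental metadata; when both a user-fixed value and an
attribute exist the user wins, a choice this package makes explicitly.
Free parameters with a scalar start are shared across datasets; vector
starts make one value per dataset, packed contiguously per name in the
optimizer vector.

Bounds are enforced by a logistic reparametrization for the
Levenberg-Marquardt, Nelder-Mead and BFGS paths (these algorithms are
intrinsically unbounded) and natively by the differential-evolution search,
which is seeded (default 12345) and therefore reproducible; a final
Levenberg-Marquardt polish refines the DE solution when it improves the
objective.  Inequality constraints are quadratic penalty terms of weight
1e6 added to the objective.

Parameter uncertainties come from the finite-difference Jacobian `J` of the
weighted residuals at the optimum: `cov = (J'J)^-1 * chi2_red`.  Scaling by
the reduced chi-square is the common convention when error bars may be
misestimated; it is exact when `chi2_red = 1`.  A singular `J'J` yields a
warning and missing errors, but the fit is still returned.

## Form factors

All form factors return intensity-per-particle curves with the forward
scattering `I0` attached; `q = 0` is handled by analytic limits (series
expansions of the kernels), never by offsetting `q`.

* **Sphere**: `I(q) = (V rho)^2 [3(sin x - x cos x)/x^3]^2`, `x = qR`.
  Guinier radius `Rg^2 = (3/5) R^2`; first intensity zero at
  `qR = 4.4934` (root of `tan x = x`).
* **Multishell sphere**: the amplitude telescopes over shells with the
  contrast steps `(rho_k - rho_{k+1}) V_k Phi(q r_k)`, so a single shell
  reduces exactly to the sphere, a zero-contrast core gives hollow shells,
  and smooth SLD profiles can be approximated by thin shells (midpoint
  sampling of the profile converges quadratically in the shell width).
* **Gaussian chain**: the Debye function `P(x) = 2(e^-x + x - 1)/x^2`,
  `x = (q Rg)^2`.
* **Beaucage**: the unified Guinier + power-law expression in its original
  form (no extra high-q cutoff term in the power-law branch), prefactor
  `B = G d/Rg^d [6d^2/((2+d)(2+2d))]^{d/2} Gamma(d/2)`.
* **Teubner-Strey**: `I = (8 pi / xi)/(a2 + c1 q^2 + q^4)` with
  `a2 = (k^2 + xi^-2)^2`, `c1 = 2(xi^-2 - k^2)`, `k = 2 pi / d`.  The
  `8 pi/xi` prefactor is a convention (normalizations differ across the
  literature) and is stated in the documentation; the denominator
  discriminant is `-16 k^2/xi^2 < 0`, so the curve is positive everywhere
  and peaks at `q* = sqrt(k^2 - xi^-2)` when `k xi > 1`.

`distributed_average()` integrates a model over a distributed parameter by
fixed Gauss-Legendre quadrature on a truncated support: +-5 widths for
normal/lognorm/gamma/uniform and +-20 widths for the heavy-tailed Lorentz
line, renormalized on the interval (truncation is unavoidable for Lorentz,
whose moments diverge).  Poisson and discrete-uniform parameters are summed
exactly over a +-8-sigma integer range.

## Point-cloud scattering

`cloud_intensity()` evaluates the coherent orientation average of
`A(q u) = sum_i b_i f_a(q) exp(i q u . r_i)` on a Fibonacci grid of `2n+1`
golden-angle points (deterministic; a pseudorandom grid is available).
The default grid order grows with `q_max` times the cloud extent, a
heuristic matching the number of fringes that must be resolved.  The
orientational average is a direct sum — exact up to grid discretization on
the small clouds (up to ~10^4 points) this is intended for, and it keeps
the asymmetry factor `beta(q) = |<A>|^2 / <|A|^2>` available for use as a
structure-factor correction.

Positional disorder uses the standard displacement-disorder decomposition:
the coherent term is attenuated by the Debye-Waller factor
`exp(-q^2 sigma^2)` and the complementary weight appears as a flat diffuse
term `sum b_i^2 f_a^2`.  Its limits are exact: the full coherent pattern
at `sigma = 0` and the incoherent sum at large `sigma`.

Lattice clouds (sc/bcc/fcc, clipped to cubes or spheres) let one compare
explicit finite clusters against the analytic lattice structure factor;
incomplete lattice planes at the cluster surface produce weak intensity at
positions forbidden for the infinite lattice, which the analytic model
cannot show.

## Fluid structure factors

**Percus-Yevick hard spheres** use Wertheim's closed form in the
Ashcroft-Lekner arrangement, with series expansions of the three
trigonometric kernels below `q sigma = 0.7` where the closed forms cancel
catastrophically.  `S(0) = (1-phi)^4/(1+2phi)^2` follows to 1e-12.

**Sticky hard spheres** implement Baxter's adhesive-sphere solution: the
adhesion parameter `lambda` solves
`(phi/12) lambda^2 - (tau + phi/(1-phi)) lambda + (1+phi/2)/(1-phi)^2 = 0`
(the smaller root is the physical branch; a negative discriminant marks the
two-phase region and raises an error naming the critical stickiness), and
the Baxter factor function gains a contact term `lambda/12` with the
published mu-form coefficients.  The implementation is verified against the
hard-core criterion `g(r < sigma) = 0` via the sine transform, against the
`tau -> infinity` Percus-Yevick limit, and against the monotone growth of
`S(0)` with adhesion.  The `width` argument is retained as metadata: in the
Baxter sticky limit the well width has been collapsed into `tau` and does
not enter `S(q)` separately.

**Screened-Coulomb (RMSA)** solves the mean spherical approximation for
the hard-core Yukawa fluid through the Baxter factorization of the
Ornstein-Zernike equation.  The factor function is a quadratic polynomial
inside the core plus an exponential tail; the closure conditions reduce to
a bilinear 2x2 system whose elimination is a quartic.  Key numerical
choices:

* All four roots are computed as eigenvalues of the companion matrix of
  the quartic — no Newton iteration from an initial estimate, so no risk
  of converging to an unphysical root.
* For each real root (imaginary parts below 1e-9 relative are discarded)
  the structure factor is evaluated in closed form (a Gauss-Legendre
  quadrature is used below `q sigma = 2` where the closed form loses
  precision), and `g(r)` follows from a Lanczos-windowed sine transform on
  a wide grid (`q sigma` up to 800).  The root minimizing the mean `|g|`
  over `r/sigma` in `[0.4, 0.6]` — the middle of the forbidden core —
  is selected.
* The quartic coefficients cancel catastrophically as the screening
  constant `ak -> 0` (eleven significant digits are lost at `ak = 0.1`,
  enough to displace the root and visibly violate the core condition), so
  below `ak = 0.75` exact series expansions in `ak`, generated
  symbolically, replace the closed forms.
* The analytic contact value `g(sigma+)` follows from the factor-function
  moments.  When it is negative beyond 1e-3 — the known failure of the
  bare MSA at low volume fraction — the Hansen-Hayter rescaling inflates
  the effective hard-core diameter (volume fraction `phi' = phi s^3`,
  screening `ak' = ak s`, contact potential re-evaluated on the fixed
  physical potential) by bisection on `s` until the contact condition
  holds, in at most 50 iterations.  The selected root index, rescaling
  flag, effective volume fraction and contact value are attached as
  attributes.
* The uncharged case `gamma = 0` takes the same factorization with a
  vanishing tail and reproduces the independent Percus-Yevick closed form
  to 1e-11 — a strong cross-check of both derivations.

The solver was additionally validated against a numerical
Ornstein-Zernike/MSA iteration during development; within the package the
tests assert the Percus-Yevick limits, the empty-core criterion across the
screening sweep `ak = 0.1-58` at `Gamma = 3 kT`, `phi = 0.4`, and that the
selected root always beats every rejected root on the core criterion.

`sq_to_gr()` exposes the trapezoid sine transform
`g(r) = 1 + (2 pi^2 n r)^-1 Int q (S-1) sin(qr) dq`; the optional Lanczos
sigma window suppresses the Gibbs ringing of the truncated transform at the
cost of slightly smoothing the contact discontinuity.  A warning (with a
`truncation` attribute) is raised when `|S-1| > 0.01` at the end of the
grid.

## Lattice structure factors

`sf_lattice()` enumerates reciprocal-lattice points to the largest
requested `q`, folds them into multiplicities with their unit-cell
structure factors (bcc and fcc extinction rules emerge from `F_hkl`, they
are not hard-coded), and builds
`Z(q) = sum m_hkl (|F_hkl|^2/N_c) (q_hkl^2/q^2) P(q - q_hkl; delta)` with a
normalized Lorentzian (or Gaussian) peak of width `delta = 2 pi / L`
(Scherrer constant 1) set by the domain size.  The normalization constant
was fixed by the requirement that integrating `Z` across one isolated peak
recovers `m_hkl |F_hkl|^2 / N_c` exactly; the `q_hkl^2/q^2` factor is the
powder (Lorentz) correction.  The full structure factor is the Förster-type
composition `S(q) = 1 + beta(q) [Z(q) e^{-q^2 u2 / 3} - 1]`, in which the
Debye-Waller factor attenuates the Bragg part and the complement appears as
diffuse scattering; `beta(q)` accepts the asymmetry factor computed by
`cloud_intensity()`.

## Quasielastic dynamics

Time-domain models (`intermediate_scattering`) are simple diffusion
`exp(-q^2 D t)`, the stretched exponential, and jump diffusion with rate
`Gamma_j = D q^2/(1 + D q^2 tau)` (free diffusion at small `q`, saturating
at `1/tau`).  Frequency-domain models are classical (symmetric in omega; no
detailed-balance factor): Lorentzians for translational and jump diffusion,
the Volino-Dianoux expansion for diffusion inside a sphere, the Gaussian
expansion for diffusion in a 3D harmonic potential, and the Sears expansion
for rotational diffusion.  A frequency-domain model for strictly
one-dimensional diffusion is intentionally not provided.

Numerical conventions shared by all spectra:

* The elastic line is an area-preserving single-bin spike at `omega = 0`.
  This representation is exact under the discrete convolution (a unit-area
  spike is the identity), is preserved by channel binning, and can be
  removed before HWHM extraction (`exclude_elastic = TRUE` replaces the
  central bin by its neighbours' interpolation).
* Every Lorentzian line is rescaled by the analytic weight of the
  represented window (`(atan(w_max/Gamma) - atan(w_min/Gamma))/pi`, a
  correction of at most about 1%), so the spectrum carries the line's full
  weight and areas compose exactly under convolution; the half-width is
  untouched.
* The sphere-model eigenvalues (roots of `j_l'(x) = 0`) are found by
  bracketed bisection on first use and cached per `l`; amplitudes use the
  analytic limit at `x = x_nl` where the generic expression is 0/0.  The
  small-`qR` quasielastic width plateaus at `x_01^2 D/R^2 = 4.33 D/R^2`,
  the confinement signature.

`time_to_frequency()` bridges the domains: `I(q,t)` is multiplied by the
Gaussian time-domain factor corresponding to an omega-resolution of width
`sigma` (the resolution doubles as the window controlling spectral
leakage — the package's resolution-as-window choice) and cosine-transformed
on a 2^14-point grid whose extent is set by the slower of the signal decay
and the resolution.  A warning with a leak estimate is raised when the
windowed signal has not decayed at the end of the grid.  The tests verify
that half-widths from transformed time-domain models match the
frequency-domain models within 2% over a `q` scan for both free and jump
diffusion.

## Smearing and desmearing

`smear()` applies a per-point Gaussian resolution (pinhole geometry) or a
slit integral (Kratky geometry) on an oversampled grid, with discrete
kernel rows renormalized to unit sum; outside the measured range the curve
is continued flat below and by a power law fitted to the high-q tail
(Porod-like) above.  Zero width is the exact identity.

`desmear_lake()` inverts the smearing by the multiplicative Lake update
`I <- I * I_meas / K[I]` (chosen over the additive variant because it
preserves positivity), followed by Vad-style stabilization implemented as a
**quadratic Savitzky-Golay filter** of odd width (default 7).  A centered
moving average — the more obvious smoother — was measured on the
package's own synthetic round trip and cannot satisfy both quality metrics
at once: it either biases the sharp minima (large chi-square of
`K[I]` against the data) or, disabled, lets the deconvolution amplify
noise.  The quadratic filter preserves local curvature and achieves
reduced chi-square well below 1.5 together with a 1-2% r.m.s.
reconstruction at 1% noise.  The automatic stop is chi-square based
(against the measurement, not between iterates — a documented choice):
iteration ends when chi-square stops improving by 0.1%, or drops below the
number of points, or after `max_iter`; three consecutive increases declare
divergence and the best iterate is returned with a warning.

## What the synthetic tests do and do not show

The test fixtures are generated by the package itself: exponential decays
with Gaussian noise and exact 1-sigma error columns, noiseless analytic
curves, ideal lattice clusters, and smeared model curves re-noised at 1%.
They exercise correctness of the mathematics — limits, sum rules,
round-trip identities, independence of algorithm — under exactly known
conditions.  They do not emulate features of real measurements such as
background and incoherent contributions, resolution functions varying
nonstandardly with `q`, correlated or non-Gaussian noise, multiple
scattering, or calibration errors; passing them shows the estimators and
models are implemented correctly, not that any particular experiment is
described by them.  Problem sizes (for example 2^13-point transform grids,
point clouds of a few thousand sites, a ten-point screening sweep) were
chosen as the smallest at which the quoted tolerances are comfortably
discretization-dominated.

## Known limitations

* Fluid structure factors are monodisperse; polydispersity must be added
  through `distributed_average()` at the form-factor level, and the decoupling
  approximation (`beta(q)`) is the only anisotropy correction.
* The RMSA solver accepts `phi <= 0.5` and repulsive potentials
  (`gamma >= 0`); attractive Yukawa tails and multi-Yukawa potentials are
  out of scope.
* Spectra are classical and symmetric; no detailed-balance asymmetry.
* The desmearing quality degrades with noise roughly linearly; above ~5%
  noise the smoothing window should be widened at the cost of resolution.
* 2D (oriented) scattering, image data and hydrodynamic-function
  corrections are not implemented.
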