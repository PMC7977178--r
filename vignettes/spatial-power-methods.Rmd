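---
title: "Local power analysis for the spatial relative risk function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local power analysis for the spatial relative risk function: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srrpower)
```

## The problem

Point-pattern studies in environmental epidemiology ask where the incidence
of a disease is elevated relative to the population at risk — for instance,
whether cancer cases cluster around an industrial point source of emissions.
The standard nonparametric tool is the spatial relative risk (SRR) function:
given the residential locations of cases and of controls inside a study
window $W$, it compares their spatial densities,

$$ r(z) = \frac{f(z)}{g(z)}, \qquad \rho(z) = \log r(z), $$

where $f$ is the bivariate probability density of case locations, $g$ the
density of control locations, and $z$ ranges over a lattice of knots (grid
cells) covering $W$. Under the null hypothesis of no spatial clustering of
one group relative to the other, $\rho(z) = 0$ everywhere; a local excess of
cases appears as $\rho(z) > 0$.

Designing such a study requires knowing *where* in the window a real cluster
could actually be detected with the planned sample sizes. Conventional
power formulas do not apply: the statistic is a smoothed density ratio with
spatially varying variance, and its null behaviour depends on the window
geometry, the sampling design of both groups and the kernel bandwidth.
`srrpower` answers the design question by simulation: it generates point
patterns under the investigator's expected sampling models, runs the full
SRR estimation and test on each replicate, and reports, at every knot, the
proportion of replicates in which the local null hypothesis was rejected —
the *local power* — together with the region where that proportion reaches
a design threshold (0.8 by default), the *sufficiently powered region*.

## Estimation pipeline

### Kernel density estimation with edge correction

Each group's density is estimated with a fixed-bandwidth isotropic bivariate
Gaussian kernel, evaluated at the knot lattice:

$$ \hat f(z) \;=\; \frac{1}{n\, e_h(z)} \sum_{i=1}^{n} K_h(z - p_i),
   \qquad e_h(z) = \int_W K_h(z - u)\, du , $$

where $K_h$ is the Gaussian density with standard deviation $h$ per axis.
The uniform edge-correction factor $e_h(z)$ — the kernel mass falling inside
the window — removes the downward bias near the boundary; it equals 1 deep
in the interior and drops to about 0.5 along a straight edge. The kernel sum
is computed exactly as a separable matrix product (no binning), so the
estimate agrees with a direct double loop to machine precision. The
correction integral is evaluated by midpoint quadrature on a subgrid four
times finer than the knot lattice, with each fine cell weighted by the
fraction of its area inside the window (a 4 × 4 sub-sample per fine cell);
because the quadrature covers the entire bounding box, no truncation of the
kernel support is introduced. Residual quadrature error enters only through
the antialiased window indicator and is well below the 1% tolerance used for
the integrate-to-one check. Agreement between corrected and uncorrected
values in the interior is limited by the Gaussian tail itself: at distance
$4h$ from the boundary the kernel places mass $\Phi(-4) \approx 3\times10^{-5}$
beyond a straight edge, so exact agreement is only reached several further
bandwidths in.

### Bandwidth

The default bandwidth is the maximal smoothing (oversmoothing) principle for
a bivariate Gaussian kernel,

$$ h \;=\; \hat\sigma \left[ \frac{8\,(d+4)\,(2\sqrt{\pi})^d}{(d+2)\,n}
   \right]^{1/(d+4)}, \qquad d = 2, $$

with $\hat\sigma = \sqrt{(s_x^2 + s_y^2)/2}$, the root-mean marginal sample
variance. The root-mean form (rather than, say, the minimum of the marginal
standard deviations) keeps the kernel isotropic, matching the isotropic
$R(K)$ constant used by the test below. One *common* bandwidth is computed
from the pooled case + control pattern and used for both densities: a shared
$h$ makes $\hat\rho$ exactly antisymmetric under a group swap, the symmetric
convention of density-ratio estimation. The pooled count enters the $n$ in
the formula. A user-fixed $h$ is accepted everywhere the selector is the
default.

### The asymptotic knot test

At each evaluable knot the null $\rho(z)=0$ is tested with the asymptotic
normal approximation to the kernel log-risk estimator. The plug-in standard
error is

$$ \widehat{se}(z) = \sqrt{ \frac{R(K)}{h^{2}} \left(
   \frac{1}{n_1 \hat f(z)} + \frac{1}{n_2 \hat g(z)} \right) },
   \qquad R(K) = \frac{1}{4\pi}, $$

giving $z$-score $\hat\rho/\widehat{se}$ and a two-tailed normal p-value
(one-sided variants are available for case-excess-only or deficit-only
designs). Rejection uses strict inequality $p < \alpha$. The observed,
edge-corrected $\hat f$ and $\hat g$ enter the variance as-is; no additional
boundary variance inflation is applied.

A knot is *evaluable* when both density estimates exceed a floor of
$10^{-12}$ times their window-mean value; where either group has essentially
no estimated density the log-ratio and its variance diverge, and such knots
are excluded from testing and from the power denominator. With Gaussian
kernels on the bundled scenarios virtually every inside knot is evaluable;
the floor matters for compactly supported configurations and extreme
bandwidths.

### The power procedure

A power run with `spatial_power()` executes:

1. Simulate the case pattern once from the case model.
2. For each of `n_iter` iterations: re-simulate the controls, recompute the
   pooled oversmoothing bandwidth (the pooled pattern changes with the
   controls), both densities, $\hat\rho$, and the knot test; retain the
   per-knot rejection indicator at level $\alpha$.
3. Report per knot: `power` = rejections / `n_eval`, where `n_eval` counts
   the iterations in which the knot was evaluable, plus the powered mask
   `power >= threshold`.

Defaults are 10,000 iterations, a 128 × 128 grid, $\alpha = 0.05$
two-tailed, and threshold 0.8 — all overridable in code, config files, and
on the command line.

**Conditioning on the case pattern.** Fixing the cases after the first draw
is deliberate: in a surveillance setting the case locations are what the
study will observe, and the design question is whether *that* configuration
is detectable against re-sampled controls. The reported power is therefore
conditional on the realised case pattern. Two consequences are worth
understanding at design time. First, with few cases the conditional power
surface varies a great deal from one case draw to the next — with 8 cases a
small sufficiently powered zone appears for some draws and not for others,
so single runs at small case counts should be read as one realisation, not
an expectation. Second, under a *null* configuration (both groups sampled
from the same distribution) the conditional rejection rate at a knot is not
the test's size: wherever the single case draw happens to clump, the test
rejects persistently across iterations. For size/calibration questions the
package provides `resim_cases = TRUE`, which re-draws the cases every
iteration and so estimates unconditional rejection probabilities.

**Reproducibility.** One top-level seed expands into independent
L'Ecuyer-CMRG substreams: one for the case draw and one per iteration for
the controls (when cases are re-simulated they share the iteration's
substream). Identical seeds give bit-identical surfaces, extending the
iteration count leaves earlier iterations unchanged, and iterations are
order-independent by construction.

### Calibration of the asymptotic test

The asymptotic p-values are *conservative* under maximal smoothing, and
users should expect that. The variance formula above is the leading-order
asymptotic, valid when the density is approximately constant at the scale of
$h$. The oversmoothing selector intentionally violates that premise: at the
bundled surveillance scenario ($n = 8 + 428$, $\sigma = 1.67$ km controls,
pooled $h \approx 1.4$ km) the plug-in standard error exceeds the true
sampling standard deviation of $\hat\rho$ by roughly 40% near the window
center and by an order of magnitude in the low-density tail, where
$1/\hat f$ blows up faster than the actual variance. In a null calibration
run (`resim_cases = TRUE`, 1,000 iterations, 64 × 64 grid) the mean
rejection proportion over interior knots is about 0.015 at nominal
$\alpha = 0.05$ — a conservative test, never anticonservative in any
configuration we simulate. Power estimates inherit this conservatism: they
understate what a better-calibrated (e.g. resampling-based) test could
achieve, which is the safe direction for sample-size planning. The test
suite asserts conservatism (rejection rate below $\alpha$) and documents the
nominal-calibration check as aspirational.

## The simulation models

Three group models cover the sampling designs the tool targets:

* **Gaussian cluster(s)** (`mvn_model`): each point is a cluster center
  plus independent $N(0, \sigma)$ offsets per axis — the canonical model
  both for disease clusters around a point source and for a town's
  population density. Multiple clusters split the group size by
  largest-remainder allocation of user weights (equal by default).
* **Complete spatial randomness** (`csr_model`): uniform over the window.
* **Uniform disc** (`uniform_model`): uniform inside a disc around a
  center — a flat-topped cluster.

Draws landing outside the window are rejected and redrawn. Rejection (as
opposed to clipping to the boundary or reflecting) preserves the shape of
the density *inside* the window, which is the only thing the density ratio
sees; the expected number of redraws is capped at 1,000 per requested point,
beyond which the scenario is reported as infeasible. Points exactly on the
boundary count as inside, so nothing is lost on a circular rim.

The bundled study emulates a cancer-surveillance design: a 10 km disc window
around an exposure point source, 8 cases clustered at the source
($\sigma = 0.83$ km) and 428 controls representing the town's population
($\sigma = 1.67$ km), an incidence of 1,834.9 per 100,000. The original
analysis centers the controls on the town and the cases on the source
without stating the distance between the two; the bundled configurations
place both at the window center, the neutral choice absent that offset. The
incidence helpers use half-up rounding so that a total of 1,000 at the same
incidence yields exactly 18 cases and 982 controls.

What the generator does *not* emulate: population density read from census
tracts (the Gaussian control model is the stated approximation), spatially
varying case ascertainment, household clustering, or exposure along linear
networks. Passing tests on these models therefore demonstrate the
correctness of the machinery and the qualitative design trade-offs, not the
detectability of clusters against any particular real population surface.

## Numerical and design choices

* **Containment** is boundary-inclusive for every window type; discs and
  rectangles use analytic containment, polygons (with holes) an even-odd
  ray cast with an explicit on-edge snap at $10^{-9}$.
* **Knots are cell centers** of the bounding-box lattice, so an
  $n_x \times n_y$ grid has exactly $n_x n_y$ knots; knots outside the
  window are masked from every statistic.
* **Ties**: rejection requires $p$ strictly below $\alpha$.
* **Degenerate inputs** fail fast with named errors: zero-area windows,
  patterns of fewer than two points (bandwidth undefined), zero coordinate
  variance, empty groups in a power run, infeasible rejection sampling.
* **Coordinates are abstract planar units** (kilometers in the bundled
  configurations); the package performs no geodetic projection.
* **Sweep rows with zero expected cases** (incidence × total rounding to 0)
  are reported with zero powered area without simulation: a study that
  expects no cases has no power to detect a case cluster, and the row is
  kept so the trend table stays complete.
* **Raster export** uses the ESRI ASCII grid dialect (square cells, values
  at 10 significant digits, nodata outside the window) plus a JSON metadata
  sidecar from which the identical run can be reproduced.

## Problem sizes used in the checks

The original analysis ran 10,000 iterations on a 128 × 128 grid. The
package's own checks keep the study parameters (window, $\sigma$'s, sample
sizes, $\alpha$, threshold) and scale the Monte-Carlo effort to what the
statistical claim needs: oracle comparisons run on lattices up to 32 × 32
with up to 50 points; the null-calibration and surveillance-comparison runs
use a 64 × 64 grid with 1,000 and 500 iterations; the incidence/sample-size
sweep uses 300 iterations per condition. At these sizes a rejection
proportion is estimated to within about ±0.01 and the powered-region
orderings replicate stably.

## Known limitations

* The asymptotic test is conservative under oversmoothing (measured above);
  resampling-based tolerance contours, which would calibrate better, are
  out of scope precisely because the asymptotic test is what makes
  10,000-iteration power runs feasible.
* No multiple-testing correction across knots is applied; the power surface
  is a field of local tests, and the powered region should be read
  per-knot.
* Conditional power at small case counts is a realisation-level quantity;
  report it together with the case draw (the `power_surface` object stores
  the fixed case pattern for exactly this reason).
* Only fixed bandwidths are supported; adaptive smoothing changes both the
  estimator and the variance formula.
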