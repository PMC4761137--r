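---
title: "Small-area disease risk mapping with riskmap: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease risk mapping with riskmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskmap)
```

# The problem

Cancer registries record where people lived when they were diagnosed, but
for confidentiality and historical reasons the spatial reference is often
imprecise: a full civic address geocodes to a point, a postal code only
says "somewhere within the census regions that contain this postal code",
and older records may carry nothing finer than an administrative division.
At the same time, the administrative geography itself changes between
censuses. riskmap implements two complementary estimators of spatial (and
spatio-temporal) variation in disease risk for exactly this kind of data,
modelled on the registry structure of a small Canadian province
(~311 stable "communities", ~100 coarse census units in the early 1980s
growing to ~1400 fine units later, populations of a few hundred per fine
unit):

1. **A community-level Besag–York–Mollié (BYM) model.** Case counts per
   community are Poisson, and the log relative risk decomposes into an
   intercept, covariate effects, a spatially structured intrinsic-CAR
   effect and an unstructured effect.
2. **A spatially continuous local-EM kernel smoother.** Each case with a
   censored geocode is averaged over all locations it could have occupied,
   against a population offset surface, producing a risk surface on a
   regular grid — with bandwidths chosen by cross-validation, significance
   assessed by a parametric-bootstrap score test, and uncertainty reported
   as exceedance probabilities at a relative-risk threshold of 1.1.

Because registry microdata are confidential, the package ships a
first-class synthetic registry generator; every estimator is exercised and
tested against data whose true risk surface is known.

# The community-level model

For community $i$ with observed count $Y_i$ and expected count $E_i$,

$$Y_i \sim \text{Poisson}(E_i\lambda_i), \qquad
  \log \lambda_i = \mu + X_i\beta + S_i + V_i,$$

with $S$ an intrinsic conditional autoregression
($S_i \mid S_{-i} \sim N(\bar S_{\partial i}, \sigma_S^2/d_i)$) and
$V_i \sim N(0, \sigma_V^2)$. $E_i$ comes from indirect standardization:
person-years per region and sex–age stratum (each calendar year assigned
to the census window, census year ± 2, that contains it) times pooled
reference rates. The quantities reported per community are the posterior
mean relative risk $E[\exp(S_i+V_i)\mid\text{data}]$ and the exceedance
probability $P_i(10\%) = \Pr[\exp(S_i+V_i) > 1.1 \mid \text{data}]$, with
0.8 and 0.95 as the conventional mapping bands.

**Priors.** $\mu,\beta \sim N(0, 10^2)$ and
$\sigma_S, \sigma_V \sim$ half-Normal(0, 1): proper and weakly informative
on the log-risk scale, where residual standard deviations of 0.1–0.4 are
typical for registry data of this size.

**Inference.** Metropolis-within-Gibbs in compiled code: random-walk
updates for $\mu$, $\beta$, the $S_i$ (against their ICAR full
conditionals) and the conditionally independent $V_i$; slice sampling on
$\log\sigma$; proposal scales adapted toward 0.44 acceptance during
burn-in only. The ICAR is kept identified by recentring $S$ to mean zero
within each connected component after every sweep — the standard
constraint-by-centring device for intrinsic fields; islands (communities
with no neighbour) have $S_i$ pinned at 0 and rely on $V_i$. A Laplace
approximation would also fit this model; MCMC was chosen because the
posterior summaries, not the algorithm, are the contract, and a sampler
makes the exceedance probabilities exact functionals of the draws.
Defaults are 20 000 iterations, 5 000 burn-in, thinning 5, all
configurable; an effective sample size below 100 on either variance
parameter triggers a warning rather than a failure. Recovery experiments
in the test suite simulate from the model at $\sigma_S = 0.23$,
$\sigma_V = 0.12$ — the scale reported for male bladder cancer in the
motivating study — on the full 311-community geography.

**Queen contiguity** defines neighbourhood: two communities are
neighbours when their boundaries come within a snap tolerance (1 mm) of
each other, so shared edges and shared corners both count.

# The local-EM estimator

Work on a regular grid (default cell 1 km; the smallest bandwidth the
method typically selects is ~3 km, and three cells per kernel standard
deviation keeps discretization error negligible). The offset surface
$\rho(s,t)$ spreads each fine region's expected cases (person-years ×
reference rates) uniformly over the inhabited portion of its cells —
"inhabited" because census agencies flag partially uninhabited regions; a
region with inhabited fraction 0.5 concentrates twice the density on the
inhabited half.

Each case $j$ has a candidate cell set $A_j$: its own cell if the geocode
is exact, the cells of the census regions containing its postal code if
postal-censored, or the cells of its census division if only that is
known — the two censoring types run through one mechanism. The fixed
point iterated to convergence is:

- **E-step:** $w_{jg} \propto \lambda(g)\,\rho(g)\,|g|$ over
  $g \in A_j$ (the case's own census period's offset), normalized to 1
  per case.
- **M-step:** $\lambda(s) = \mathcal{S}[\sum_j w_{j\cdot}](s) \,/\,
  \mathcal{S}[\rho\,|g|](s)$, where $\mathcal{S}$ is the smoothing
  operator below, followed by a global rescale so that
  $\sum_g \lambda(g)\rho(g)|g|$ equals the case total — the constraint
  the unsmoothed maximum-likelihood estimator satisfies exactly and
  kernel smoothing would otherwise perturb.

Convergence is declared when the sup-norm relative change drops below
`tol` (default 1e-4, maximum 200 iterations); a likelihood-based stopping
rule was rejected because the smoothed iteration need not be
likelihood-monotone. The iteration starts from $\lambda \equiv 1$.
With exact-only data the estimator reduces, in one iteration and to
machine precision, to the familiar ratio of smoothed case counts over
smoothed expecteds; with everything censored to one region covering the
study area it reduces to the flat standardized incidence ratio.

**The smoothing operator.** A truncated Gaussian kernel (sd $h$,
truncation 4 sd per axis) is renormalized *symmetrically* over the study
region's cells (iterative proportional fitting to a doubly stochastic
operator). This edge correction was chosen over the usual one-sided
renormalizations because it gives both identities the estimator's tests
rely on *exactly*: smoothing preserves the total of any field, and
constant fields pass through unchanged. In the interior the operator is
indistinguishable from an ordinary normalized Gaussian. The
spatio-temporal variant uses a separable product with a Gaussian in time
(sd $\tau$), itself renormalized over the observed year range; as
$\tau \to \infty$ the spatio-temporal fit collapses onto the pooled
spatial fit, a limit verified to 1e-6 in the tests.

**Bandwidth selection.** Half-split cross-validation: fit on a random
half of the cases with the offset halved, score the held-out half's cell
counts by Poisson log-likelihood, average both fold orientations over
`n_splits` splits (default 10), pick the bandwidth with the best mean
score, break exact ties toward more smoothing. Held-out censored cases
are allocated over their candidate cells proportionally to the offset — a
fixed, risk-independent allocation, so no information leaks from the
fitted surface into the score.

**Score test.** The test statistic is the offset-weighted variance of the
fitted surface (for the temporal test, of the surface after removing each
location's offset-weighted time mean). Its null distribution comes from
parametric-bootstrap datasets at constant risk 1 with the data's
censoring pattern re-imposed — each simulated case drawing a precision
class from the data's per-period empirical mix and a candidate-set size
from the data's empirical sizes. The p-value uses the $(1+\#)/(B+1)$
correction, so it is finite-sample conservative; B below 19 is refused
because the p-value lattice becomes useless. The statistic is defined
here by its calibration (type-I error within [0.01, 0.12] at nominal
0.05 in the acceptance suite) and power (a twofold bump at ~2000 cases is
detected in ≥8/10 replicates), not by a closed-form formula.

**Exceedance surfaces.** $B$ datasets (default 100) are simulated at
constant relative risk $\lambda_0 = 1.1$, re-censored, and refitted with
the same bandwidths; $P(s;10\%)$ is one minus the proportion of bootstrap
surfaces exceeding the data's surface at $s$. Non-convergent replicates
are dropped and logged; more than 10% dropped is an error. The division
uses $B$ (a proportion), not $B+1$: here the quantity is a map layer, not
a test.

# The synthetic registry

The generator emulates the study conditions end to end: nested
Voronoi-style tessellations (coarse divisions → communities → per-census
fine regions, re-tessellated each census to emulate boundary changes; the
geometry layer guarantees each fine region lies in exactly one community);
fine-region populations drawn uniformly in 400–700 per census year and
split over sex and fourteen 5-year adult age bands; log-linear-in-age
baseline rates scaled so the two cancer sites yield roughly 3 200 and
2 100 cases over a recent 13-year era at full population, with
male-to-female rate ratios of 2.9 and 1.5; Poisson cell counts under a
configurable latent risk field (constant, one or two Gaussian bumps, or a
gradient, with optional temporal drift); and era-specific geocoding
precision — 86.6 / 2.3 / 11.1 percent exact / postal-censored /
division-censored in the recent era, 43.6 / 52.9 / 3.4 in the early era,
the mixes observed in long-run registry data. Postal censoring sets
contain the truly containing fine region plus up to three adjacent ones
(uniform 1–4; registries only say a postal code may span "several"
units). The "town name" class of historical geocoding is treated as
division-level censoring. Everything is a pure function of the scenario
seed; the same seed reproduces every byte.

Two deliberate simplifications. First, fine-region totals are 400–700 in
*every* era, so the early censuses (with ~10× fewer regions) carry ~10×
less population than the late ones; downstream code never assumes a
constant provincial total, and keeping the per-region rule uniform makes
generator properties easy to state and test. Second, the geography is a
tessellated rectangle: no coastline, no migration, no age-period-cohort
rate dynamics. Passing tests therefore demonstrate correctness of the
estimators under the stated sampling model — censoring, boundary change,
heterogeneous offsets — not robustness to real-data pathologies such as
geocoding bias or population displacement.

# Numerical and design notes

- **Geometry** is planar, in a projected metre-unit CRS; bandwidths are
  specified in km and converted internally. Any equal-area metric
  projection is acceptable for synthetic work; geodetic computation is
  out of scope.
- **Rasterization** is by cell-centre containment; a point exactly on a
  cell boundary belongs to the cell with the smaller linear index, and a
  populated region smaller than a cell is assigned the cell holding its
  centroid.
- **Surfaces on disk**: ESRI ASCII grids (text, lossless at %.17g, read
  back bit-exact) with a JSON sidecar for CRS/band metadata, or 32-bit
  float TIFF with an ESRI world file. The pipeline's `mask_risk` flag
  (on by default) withholds fitted risk rasters from report bundles while
  always writing exceedance rasters — the disclosure practice for
  confidential registry analyses.
- **Temporal gate**: the pipeline proceeds from the spatial to the
  spatio-temporal model when the spatial test's p-value is below 0.1
  (practice in this literature maps spatio-temporal surfaces at p-values
  as large as 0.07, so 0.05 would be too strict a codification), and maps
  exceedance from the pooled spatial model otherwise.
- **Problem sizes in the test-suite experiments** were chosen as the
  smallest that leave the checked property comfortably identified: e.g.
  type-I calibration uses 200 replicates of ~250 cases on a 12×12 grid at
  B=99; bootstrap calibration pools six replicates of ~3 300 cases on a
  40×40 grid at B=50 (pooling is needed because each replicate's
  exceedance field shares a single global level shift — its realized case
  total — so the one-replicate distribution over cells is not an estimate
  of the marginal distribution); BYM recovery uses ten replicates on the
  full 311-community geography at 9 000 iterations.

# Known limitations

- The local-EM track accommodates no covariates; risk is relative to the
  demographic standard only.
- The kernel is isotropic and stationary; no adaptive bandwidths.
- Exceedance probabilities are pointwise; no familywise control across
  cells is attempted (nor is it in the practice this package codifies).
- The grid approximation *is* the estimator: continuous-space integrals
  are never computed exactly, and results at bandwidths below ~1.5 cells
  carry discretization artifacts (the smoother warns below half a cell).
- Single-site random-walk updates mix slowly for $\sigma_S$ on weakly
  informative data; the effective-sample-size warning is the guard, and
  long chains are cheap (the 311-community default fit takes seconds).
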