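# riskmap

Small-area spatial and spatio-temporal disease risk mapping for
cancer-registry-style data, for epidemiologists and biostatisticians who
need to answer "where, and when, is incidence elevated?" from case records
whose geocodes range from exact street addresses down to "somewhere in
this census division", referenced to administrative boundaries that change
between censuses.

The package implements two complementary tracks and everything needed to
run them end to end without confidential data:

**Community-level track — the Besag–York–Mollié (BYM) model.** Counts per
community are Poisson with indirectly standardized expecteds,

    Y_i ~ Poisson(E_i λ_i),   log λ_i = μ + X_i β + S_i + V_i,

where S is an intrinsic CAR (ICAR) spatial effect with standard deviation
σ_S (sum-to-zero per connected component), V is unstructured noise with
standard deviation σ_V, and X holds community covariates (well-water use,
material and social deprivation indices from correlation-matrix PCA).
Inference is Metropolis-within-Gibbs in compiled code; outputs are the
posterior parameter table, posterior relative risks
E[exp(S_i + V_i) | data], and exceedance probabilities
P_i(10%) = Pr[exp(S_i + V_i) > 1.1 | data].

**Spatially continuous track — the local-EM kernel smoother.** On a
regular grid with a population offset ρ(s,t), each censored case is
averaged over its candidate locations (E-step: weights ∝ λ·ρ over the
cells of its candidate region set) and the risk surface is re-estimated as
a ratio of identically smoothed fields (M-step), iterated to a fixed
point. The Gaussian kernel (sd h km; optionally × sd τ years in time) is
edge-corrected by symmetric renormalization over the study region, so
smoothing preserves totals and flat fields exactly. Bandwidths are chosen
by half-split cross-validation; spatial and temporal structure is tested
with a parametric-bootstrap score test; uncertainty is mapped as bootstrap
exceedance probabilities P(s;10%) against a constant-risk null of
λ0 = 1.1.

A first-class synthetic registry generator (`scenario()`,
`simulate_registry()`) reproduces the study conditions — nested Voronoi
geographies with per-census boundary changes, census populations by sex
and 5-year age band, era-specific geocode censoring mixes, and a known
latent risk field — so every estimator is testable against ground truth.

## Worked example

A compact synthetic study: 16 communities on a 60 × 60 km rectangle, a
twofold Gaussian risk bump (15 km scale) in the west, and both analysis
tracks.

```r
library(riskmap)
sc <- scenario(seed = 7, n_communities = 16, n_coarse = 4,
               width_km = 60, height_km = 60, cell_km = 3,
               fine_targets = c("1981" = 20, "1986" = 20, "1991" = 60,
                                "1996" = 60, "2001" = 60, "2006" = 60,
                                "2011" = 60),
               target_cases = c(bladder = 1200, kidney = 250),
               risk_field = list(type = "one_bump", amplitude = 2,
                                 scale_km = 15))
reg <- simulate_registry(sc)
table(reg$cases$precision)
#>     coarse      exact region_set
#>        295       2712       1122

res <- run_community_analysis(reg, sites = "bladder", sexes = "M",
                              mcmc = list(n_iter = 8000, burn_in = 2000,
                                          thin = 3, seed = 1))
print(res$bladder_M$params, digits = 2)
#>                         parameter    mean    q2.5 q97.5
#> 1                       Intercept -0.1045 -0.7314 0.517
#> 2              % using well water  0.0022 -0.0138 0.017
#> 3            Material deprivation  0.0439 -0.0997 0.171
#> 4              Social deprivation -0.1016 -0.2353 0.031
#> 5      Spatial standard deviation  0.2929  0.0075 0.768
#> 6 Unstructured standard deviation  0.2464  0.0537 0.506
res$bladder_M$n_over_80
#> [1] 3

lem <- run_localem_analysis(reg, site = "bladder",
                            h_grid = c(3, 6, 11, 17), tau_grid = c(8, 13),
                            B = 50, n_splits = 5, seed = 2, grid_km = 3)
lem$h_km                      # cross-validated spatial bandwidth (km)
#> [1] 6
lem$spatial_test$p_value      # bootstrap score test for spatial structure
#> [1] 0.0196
mean(lem$exceedance$values[, 1] > 0.8)   # cells with P(s;10%) > 0.8
#> [1] 0.188
```

Reading: none of the covariates matters (their intervals straddle zero —
the bump was simulated independently of them), the residual spatial
standard deviation is large, three communities exceed the 10%-above-typical
risk threshold with probability > 0.8, and the continuous track localizes
the same excess at finer resolution: the spatial score test rejects
constant risk (p ≈ 0.02) and 19% of grid cells — the bump region — carry
exceedance probability above 0.8. Fitted risk rasters are withheld from
report bundles by default (`mask_risk`), mirroring disclosure practice;
exceedance rasters are always written.

A YAML-driven command-line front end for the whole pipeline (simulate /
summary / bym / localem / run-all) ships in `inst/cli/riskmap`.

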