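Package: riskmap
Title: Small-Area Spatial and Spatio-Temporal Disease Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two complementary approaches to small-area disease risk mapping for
    cancer-registry style data: a Besag-York-Mollie (BYM) Poisson spatial
    autoregression at the community level with MCMC inference, posterior relative
    risks and exceedance probabilities; and a spatially continuous local-EM kernel
    smoother that handles case geocodes censored to sets of census regions, with
    cross-validated bandwidth selection, bootstrap score tests for spatial and
    spatio-temporal effects, and parametric-bootstrap exceedance surfaces.
    Includes a synthetic registry generator (nested Voronoi geographies,
    census-style populations, deprivation covariates and mixed-precision
    geocoding) so the full pipeline runs without confidential data, plus
    indirect standardization and PCA deprivation indices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    tiff,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
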