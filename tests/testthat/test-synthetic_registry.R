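# Generator properties: nesting, populations, Poisson case counts,
# censoring shares, covariates, determinism.

test_that("geography is nested, complete and sized as configured", {
  reg <- tiny_registry()
  geo <- reg$geography
  expect_equal(n_regions(geo$communities), 16)
  expect_equal(n_regions(geo$coarse), 4)

  # communities tile the study rectangle
  area_tot <- sum(vapply(geo$communities$polygons, poly_area, 0))
  expect_equal(area_tot, 60000 * 60000, tolerance = 1e-9)

  # every fine centroid lies in exactly one community, and in the community
  # the table claims as parent
  cen <- t(vapply(geo$fine$polygons, poly_centroid, numeric(2)))
  inside <- vapply(geo$communities$polygons,
                   function(p) point_in_poly(p, cen), logical(nrow(cen)))
  expect_true(all(rowSums(inside) == 1))
  claimed <- geo$communities$table$region_id[apply(inside, 1, which.max)]
  expect_equal(claimed, geo$fine$table$community_id)

  # community -> coarse nesting
  ccen <- t(vapply(geo$communities$polygons, poly_centroid, numeric(2)))
  cin <- vapply(geo$coarse$polygons,
                function(p) point_in_poly(p, ccen), logical(nrow(ccen)))
  expect_equal(geo$coarse$table$region_id[apply(cin, 1, which.max)],
               geo$communities$table$coarse_id)

  # boundary change: early and late censuses have different region counts
  counts <- table(geo$fine$table$census_year)
  expect_lt(counts[["1981"]], counts[["2001"]])
})

test_that("too few communities is rejected", {
  expect_error(scenario(n_communities = 3), "at least 4")
})

test_that("populations are integer, in range, capped and reproducible", {
  reg <- tiny_registry()
  pop <- reg$population
  expect_true(all(pop$count >= 0))
  expect_true(all(pop$count == round(pop$count)))
  totals <- tapply(pop$count, list(pop$region_id, pop$census_year), sum)
  expect_true(all(is.na(totals) | (totals >= 200 & totals <= 1400)))
  # community cap
  ft <- reg$geography$fine$table
  cmap <- stats::setNames(ft$community_id, ft$region_id)
  ctot <- tapply(pop$count, list(cmap[pop$region_id], pop$census_year), sum)
  expect_true(all(is.na(ctot) | ctot <= reg$scenario$community_pop_cap))
  pop2 <- make_population(reg$scenario, reg$geography)
  expect_identical(pop, pop2)
})

test_that("case totals are Poisson-consistent with the expected count", {
  # lambda = 1 everywhere; the realized total must sit in the Poisson bulk
  sc <- tiny_scenario(seed = 21, risk_field = list(type = "constant",
                                                   amplitude = 1))
  geo <- make_geography(sc)
  pop <- make_population(sc, geo)
  rates <- sc$rates
  # expected total over the study, computed independently of the simulator
  exp_tot <- 0
  for (cy in sc$census_years) {
    win <- length(intersect((cy - 2):(cy + 2), sc$study_years))
    p <- pop[pop$census_year == cy, ]
    rmap <- stats::setNames(rates$rate[rates$site == "bladder"],
                            paste(rates$sex[rates$site == "bladder"],
                                  rates$age_group[rates$site == "bladder"]))
    exp_tot <- exp_tot + sum(p$count * rmap[paste(p$sex, p$age_group)] * win)
  }
  n <- vapply(1:5, function(s) {
    nrow(simulate_cases(sc, geo, pop, seed = s, sites = "bladder"))
  }, 0)
  expect_true(all(abs(n - exp_tot) < 4 * sqrt(exp_tot)))
})

test_that("zero risk yields zero cases", {
  sc <- tiny_scenario(seed = 3, risk_field = list(type = "constant",
                                                  amplitude = 0))
  geo <- make_geography(sc)
  pop <- make_population(sc, geo)
  expect_equal(nrow(simulate_cases(sc, geo, pop, seed = 1)), 0)
})

test_that("a risk bump doubles the local case density", {
  sc <- tiny_scenario(seed = 5,
                      risk_field = list(type = "one_bump", amplitude = 2,
                                        scale_km = 12),
                      target_cases = c(bladder = 2500, kidney = 0))
  geo <- make_geography(sc)
  pop <- make_population(sc, geo)
  cs <- simulate_cases(sc, geo, pop, seed = 2, sites = "bladder")
  expect_gt(nrow(cs), 3000)  # 31 years at NS-like rates
  # compare observed / expected-under-flat-risk between the bump core and
  # the far field; the ratio of these SIRs estimates the risk ratio
  rates <- sc$rates[sc$rates$site == "bladder", ]
  off <- build_offset(pop, rates[, c("sex", "age_group", "rate")],
                      geo$fine, scenario_grid(sc), sc$study_years)
  centers <- grid_centers(off$grid)
  centre <- c(0.35 * 60000, 0.5 * 60000)
  d_cell <- sqrt((centers[, 1] - centre[1])^2 + (centers[, 2] - centre[2])^2)
  e_cell <- rowSums(off$values) * cell_area(off$grid)
  # count cases by cell so both sides use the same spatial partition
  case_cell <- cell_index(off$grid, cs$x, cs$y)
  n_by_cell <- tabulate(case_cell, nrow(centers))
  sir_in <- sum(n_by_cell[d_cell < 8000]) / sum(e_cell[d_cell < 8000])
  sir_out <- sum(n_by_cell[d_cell > 24000]) / sum(e_cell[d_cell > 24000])
  lam_in <- sum((true_risk(sc, centers) * e_cell)[d_cell < 8000]) /
    sum(e_cell[d_cell < 8000])
  lam_out <- sum((true_risk(sc, centers) * e_cell)[d_cell > 24000]) /
    sum(e_cell[d_cell > 24000])
  ratio <- (sir_in / sir_out) / (lam_in / lam_out)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
  # and the headline contrast: empirical risk ratio of about 2 at amplitude 2
  expect_gt(sir_in / sir_out, (lam_in / lam_out) - 0.2)
  expect_lt(sir_in / sir_out, (lam_in / lam_out) + 0.2)
})

test_that("censoring matches the era mixes and keeps cases intact", {
  sc <- tiny_scenario(seed = 9, target_cases = c(bladder = 3000, kidney = 0))
  geo <- make_geography(sc)
  pop <- make_population(sc, geo)
  cs <- simulate_cases(sc, geo, pop, seed = 4, sites = "bladder")
  cen <- censor_geocodes(cs, sc, geo, seed = 5)

  # censoring preserves identity columns exactly
  for (col in c("case_id", "site", "sex", "age_group", "year", "behaviour")) {
    expect_identical(cen[[col]], cs[[col]])
  }
  expect_identical(cen$true_x, cs$x)

  # empirical shares near the configured mixes (binomial tolerance)
  for (era in c("recent", "early")) {
    sel <- if (era == "recent") cen$year >= 1998 else cen$year < 1998
    expect_gt(sum(sel), 800)
    sh <- table(factor(cen$precision[sel], c("exact", "region_set", "coarse")))
    sh <- as.numeric(sh) / sum(sel)
    expect_lt(max(abs(sh - sc$geocode_mix[[era]])), 0.025)
  }

  # every region-set case's candidate list contains the truly containing
  # region, and candidate sets are never empty
  rsel <- which(cen$precision == "region_set")
  cand <- split_candidates(cen$candidate_regions[rsel])
  expect_true(all(lengths(cand) >= 1))
  cyr <- riskmap:::census_for_year(sc, cen$year[rsel])
  ok <- vapply(seq_along(rsel), function(k) {
    rs <- regions_for_census(geo$fine, cyr[k])
    rid <- riskmap:::locate_regions(
      rs, cbind(cen$true_x[rsel[k]], cen$true_y[rsel[k]]))
    rs$table$region_id[rid] %in% cand[[k]]
  }, TRUE)
  expect_true(all(ok))

  # degenerate mix: everything stays exact
  sc2 <- tiny_scenario(seed = 9,
                       geocode_mix = list(recent = c(1, 0, 0),
                                          early = c(1, 0, 0)))
  cen2 <- censor_geocodes(cs, sc2, geo, seed = 5)
  expect_identical(cen2$precision, rep("exact", nrow(cs)))
  expect_identical(cen2$x, cs$x)
})

test_that("covariates have the designed factor structure", {
  reg <- tiny_registry()
  cov <- make_covariates(reg$scenario, reg$geography$communities, seed = 99)
  expect_true(all(cov$well_water_pct >= 0 & cov$well_water_pct <= 100))
  mat <- cbind(cov$no_highschool_pct, -cov$avg_income, -cov$employment_rate)
  cors <- stats::cor(mat)
  expect_true(all(cors[upper.tri(cors)] > 0.3))
  soc <- cbind(cov$sep_div_wid_pct, cov$single_parent_pct,
               cov$living_alone_pct)
  expect_true(all(stats::cor(soc)[upper.tri(diag(3))] > 0.3))
  # zero noise makes indicators collinear with the latent factor
  cov0 <- make_covariates(reg$scenario, reg$geography$communities,
                          seed = 99, noise_sd = 0)
  tr <- attr(cov0, "truth")
  expect_equal(abs(stats::cor(cov0$no_highschool_pct, tr$material_latent)), 1)
  expect_equal(abs(stats::cor(cov0$living_alone_pct, tr$social_latent)), 1)
})

test_that("the full registry is deterministic in the scenario seed", {
  r1 <- simulate_registry(tiny_scenario(seed = 31))
  r2 <- simulate_registry(tiny_scenario(seed = 31))
  expect_identical(r1$cases, r2$cases)
  expect_identical(r1$population, r2$population)
  expect_identical(r1$covariates, r2$covariates)
  expect_identical(r1$geography$fine$polygons, r2$geography$fine$polygons)
  r3 <- simulate_registry(tiny_scenario(seed = 32))
  expect_false(identical(r1$cases, r3$cases))
})

test_that("community case aggregation is consistent with the truth", {
  # aggregated cases / self-standardized expecteds track mean community risk
  reg <- tiny_registry(seed = 13,
                       risk_field = list(type = "one_bump", amplitude = 2,
                                         scale_km = 20),
                       target_cases = c(bladder = 4000, kidney = 0))
  sc <- reg$scenario
  cs <- reg$cases_exact[reg$cases_exact$site == "bladder", ]
  rates <- sc$rates[sc$rates$site == "bladder", ]
  pop <- reg$population
  py <- person_years(pop, sc$study_years)
  ec <- suppressWarnings(expected_counts(
    py, rates, stats::setNames(reg$geography$fine$table$community_id,
                               reg$geography$fine$table$region_id)))
  rid <- riskmap:::locate_regions(reg$geography$communities,
                                  cbind(cs$x, cs$y))
  y <- table(reg$geography$communities$table$region_id[rid])
  big <- ec$community_id[ec$E >= 150]
  expect_gt(length(big), 2)
  for (cid in big) {
    poly <- reg$geography$communities$polygons[[
      match(cid, reg$geography$communities$table$region_id)]]
    lam_bar <- mean(true_risk(sc, runif_in_poly(400, poly)))
    sir <- as.numeric(y[cid]) / ec$E[ec$community_id == cid]
    expect_lt(abs(sir / lam_bar - 1), 0.25)
  }
})
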