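# Kernel smoothing operator, offset construction, and the local-EM fixed
# point with its exact reductions and conservation identities.

test_that("smoothing preserves mass and constants, and matches closed form", {
  g <- grid_spec(0, 0, 1000, 30, 30)
  sm <- make_smoother(g, kernel_spec(2))
  set.seed(1)
  f <- runif(900)
  out <- apply_smoother(sm, f)
  expect_equal(sum(out), sum(f), tolerance = 1e-10)
  expect_lt(max(abs(apply_smoother(sm, rep(3.3, 900)) - 3.3)), 1e-9)

  # delta on a large domain reproduces the truncated discrete Gaussian
  g2 <- grid_spec(0, 0, 1000, 41, 41)
  sm2 <- make_smoother(g2, kernel_spec(2))
  delta <- numeric(41 * 41)
  ctr <- cell_index(g2, 20500, 20500)
  delta[ctr] <- 1
  out2 <- apply_smoother(sm2, delta)
  cen <- grid_centers(g2)
  k <- exp(-((cen[, 1] - 20500)^2 + (cen[, 2] - 20500)^2) / (2 * 2000^2))
  k[pmax(abs(cen[, 1] - 20500), abs(cen[, 2] - 20500)) > 8000] <- 0
  expect_lt(max(abs(out2 - k / sum(k))), 1e-6)
})

test_that("smoothing equals a brute-force dense-kernel application", {
  g <- grid_spec(0, 0, 500, 12, 9)
  set.seed(2)
  mask <- runif(108) > 0.2     # ragged study region
  sm <- make_smoother(g, kernel_spec(1.2), mask)
  f <- runif(108) * mask
  ours <- apply_smoother(sm, f)
  oracle <- brute_smoother(brute_kernel_matrix(g, 1200), mask)(f)
  expect_lt(max(abs(ours - oracle)), 1e-10)
})

test_that("sub-cell bandwidths warn about undersmoothing", {
  g <- grid_spec(0, 0, 1000, 5, 5)
  expect_warning(make_smoother(g, kernel_spec(0.3)), "undersmoothing")
})

test_that("offset construction conserves expected totals and handles the
           ecumene", {
  reg <- tiny_registry()
  off <- registry_offset(reg, "bladder")
  sc <- reg$scenario
  cs <- reg$cases[reg$cases$site == "bladder", ]
  # self-standardized: per-period integrals sum to the case total
  expect_equal(sum(off$values) * cell_area(off$grid), nrow(cs),
               tolerance = 1e-9)
  # each period's integral matches its expected count to 0.5%
  py <- person_years(reg$population, sc$study_years)
  rates <- provincial_rates(cs, py)
  rmap <- stats::setNames(rates$rate, paste(rates$sex, rates$age_group))
  for (k in seq_len(nrow(off$periods))) {
    cy <- sort(unique(reg$geography$fine$table$census_year))[k]
    pk <- py[py$census_year == cy, ]
    want <- sum(pk$person_years * rmap[paste(pk$sex, pk$age_group)])
    got <- sum(off$values[, k]) * cell_area(off$grid)
    expect_lt(abs(got - want) / want, 0.005)
  }
})

test_that("a half-inhabited region doubles density on its inhabited half", {
  g <- grid_spec(0, 0, 1000, 4, 2)
  tab <- data.frame(region_id = "r1", period_start = 1999L,
                    period_end = 2003L, inhabited_fraction = 0.5,
                    census_year = 2001L)
  rs <- region_set("fine_census", tab, list(rect_poly(0, 0, 4000, 2000)))
  pop <- data.frame(region_id = "r1", census_year = 2001L, sex = "M",
                    age_group = "70-74", count = 1000L)
  rates <- data.frame(sex = "M", age_group = "70-74", rate = 0.001)
  off <- build_offset(pop, rates, rs, g, study_years = 1999:2003)
  e <- off$values[, 1] * cell_area(g)
  expect_equal(sum(e), 1000 * 0.001 * 5)           # mass preserved
  expect_equal(sum(e > 0), 4)                      # half the 8 cells
  expect_equal(max(e), 5 / 4)                      # doubled density
  # one region, one cell: all mass in that cell
  g1 <- grid_spec(0, 0, 4000, 2, 2)
  off1 <- build_offset(pop, rates, rs, g1, study_years = 1999:2003)
  expect_equal(sort(off1$values[, 1] * cell_area(g1), decreasing = TRUE)[1], 5)
  expect_equal(sum(off1$values > 0), 1)
})

test_that("exact-only data reduces to the smoothed ratio in one iteration", {
  off <- toy_offset(nx = 6, ny = 3, e_cells = runif(18, 0.5, 2))
  cs <- toy_cases_on_grid(off, list(list(cell = 2), list(cell = 9),
                                    list(cell = 9), list(cell = 15)))
  sm <- make_smoother(off$grid, kernel_spec(1.5), off$mask)
  fit <- localem_fit(cs, off, kernel_spec(1.5), smoother = sm)
  expect_equal(fit$iterations, 1L)
  # the single-smooth ratio estimator, computed directly
  e <- off$values[, 1] * cell_area(off$grid)
  w <- numeric(18); w[2] <- 1; w[9] <- 2; w[15] <- 1
  lam <- apply_smoother(sm, w) / apply_smoother(sm, e)
  lam <- lam * 4 / sum(lam * e)
  expect_lt(max(abs(fit$values[, 1] - lam)), 1e-12)
  # further iterations change nothing
  fit2 <- localem_fit(cs, off, kernel_spec(1.5), smoother = sm,
                      control = list(tol = 0, max_iter = 5))
  expect_lt(max(abs(fit2$values - fit$values)), 1e-12)
})

test_that("fully censored single-region data reduces to the flat SIR", {
  set.seed(3)
  off <- toy_offset(nx = 5, ny = 2, e_cells = runif(10, 0.5, 2),
                    split = 1:10)   # region A covers the whole grid
  cs <- toy_cases_on_grid(off, rep(list(list(region = "A")), 7))
  fit <- localem_fit(cs, off, kernel_spec(2))
  e_tot <- sum(off$values[, 1]) * cell_area(off$grid)
  expect_lt(max(abs(fit$values[, 1] - 7 / e_tot)), 1e-6)
})

test_that("local-EM matches the brute-force oracle on all small instances", {
  # every 1-D-style instance with <= 10 cells, 2 regions and <= 5 cases
  set.seed(42)
  worst <- 0
  for (nx in c(3L, 5L)) {
    for (rep in 1:6) {
      ncell <- nx * 2L
      e_cells <- runif(ncell, 0.3, 2)
      split <- sample(ncell, sample(2:(ncell - 2), 1))
      off <- toy_offset(nx = nx, ny = 2, e_cells = e_cells, split = split)
      n_cases <- sample(1:5, 1)
      spec <- lapply(seq_len(n_cases), function(i) {
        kind <- sample(3, 1)
        if (kind == 1) list(cell = sample(ncell, 1))
        else if (kind == 2) list(region = "A") else list(region = "B")
      })
      cs <- toy_cases_on_grid(off, spec)
      fit <- localem_fit(cs, off, kernel_spec(1),
                         control = list(tol = 1e-12, max_iter = 2000))
      case_cells <- lapply(spec, function(s) {
        if (!is.null(s$cell)) s$cell else off$region_cells[[s$region]]
      })
      oracle <- brute_localem(off$grid, 1000,
                              off$values[, 1] * cell_area(off$grid),
                              case_cells, tol = 1e-12)
      worst <- max(worst, max(abs(fit$values[, 1] - oracle)))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("mass is conserved and the fit is invariant to case order and
           to splitting duplicate censored cases", {
  reg <- tiny_registry()
  off <- registry_offset(reg, "bladder")
  cs <- reg$cases[reg$cases$site == "bladder", ]
  fit <- localem_fit(cs, off, kernel_spec(8))
  e_pool <- rowSums(off$values) * cell_area(off$grid)
  expect_lt(abs(sum(fit$values[, 1] * e_pool) / nrow(cs) - 1), 1e-4)
  expect_equal(fit$mass_balance, 1, tolerance = 1e-12)
  expect_true(all(is.finite(fit$values)) && all(fit$values >= 0))
  # permuted case order: identical surface
  set.seed(5)
  fit2 <- localem_fit(cs[sample(nrow(cs)), ], off, kernel_spec(8))
  expect_equal(fit2$values, fit$values, tolerance = 1e-12)
  # sup-norm change is below tol at termination and tail-monotone
  h <- fit$change_history
  expect_lt(h[length(h)], 1e-4)
  tail10 <- utils::tail(h, 10)
  expect_true(all(diff(tail10) <= 1e-12))
})

test_that("duplicating a censored case's region set leaves the fit alone", {
  off <- toy_offset(nx = 5, ny = 2, e_cells = runif(10, 0.5, 2))
  cs <- toy_cases_on_grid(off, list(list(region = "A"), list(region = "A"),
                                    list(cell = 7)))
  # same censored mass expressed as one duplicated record set vs two
  fit_a <- localem_fit(cs, off, kernel_spec(1.5),
                       control = list(tol = 1e-10))
  cs_b <- cs
  cs_b$candidate_regions[2] <- "A"   # identical set, distinct string order
  fit_b <- localem_fit(cs_b, off, kernel_spec(1.5),
                       control = list(tol = 1e-10))
  expect_equal(fit_a$values, fit_b$values, tolerance = 1e-12)
})

test_that("zero-offset candidate sets and off-grid cases are rejected", {
  e <- c(rep(1, 5), rep(0, 5))            # region B has zero offset
  off <- toy_offset(nx = 5, ny = 2, e_cells = e, split = 1:5)
  cs <- toy_cases_on_grid(off, list(list(region = "B")))
  expect_error(localem_fit(cs, off, kernel_spec(1.5)), "zero offset")
  cs2 <- toy_cases_on_grid(off, list(list(cell = 1)))
  cs2$x <- 1e7
  expect_error(localem_fit(cs2, off, kernel_spec(1.5)), "outside the grid")
})

test_that("spatio-temporal fit collapses to the pooled fit as tau grows", {
  reg <- tiny_registry()
  off <- registry_offset(reg, "bladder")
  cs <- reg$cases[reg$cases$site == "bladder", ]
  pooled <- localem_fit(cs, off, kernel_spec(11))
  st <- localem_fit_st(cs, off, kernel_spec(11, tau_years = 1e6),
                       index_years = c(1985L, 2005L))
  expect_lt(max(abs(st$values - pooled$values[, 1])), 1e-6)
  expect_equal(st$years, c(1985L, 2005L))
})

test_that("a time-constant truth gives a stable surface across index years", {
  reg <- tiny_registry(seed = 17,
                       risk_field = list(type = "one_bump", amplitude = 2,
                                         scale_km = 15),
                       target_cases = c(bladder = 1500, kidney = 0))
  off <- registry_offset(reg, "bladder")
  cs <- reg$cases[reg$cases$site == "bladder", ]
  st <- localem_fit_st(cs, off, kernel_spec(11, tau_years = 13),
                       index_years = c(1980L, 2010L))
  use <- rowSums(off$values) > 0
  rel <- abs(st$values[use, 1] - st$values[use, 2]) /
    pmax(st$values[use, 1], 0.2)
  expect_lt(max(rel), 0.35)
  expect_lt(stats::median(rel), 0.1)
  expect_equal(st$mass_balance, 1, tolerance = 1e-10)
})

test_that("local-EM recovers a risk bump and improves with sample size", {
  reg <- tiny_registry(seed = 23,
                       risk_field = list(type = "one_bump", amplitude = 2,
                                         scale_km = 15),
                       target_cases = c(bladder = 1300, kidney = 0))
  off <- registry_offset(reg, "bladder", external = TRUE)
  cs <- reg$cases[reg$cases$site == "bladder", ]
  fit <- localem_fit(cs, off, kernel_spec(8))
  lam_true <- true_risk(reg$scenario, grid_centers(off$grid))
  use <- rowSums(off$values) > 0
  expect_gt(stats::cor(fit$values[use, 1], lam_true[use]), 0.8)
  # a 10% subsample fits worse
  set.seed(7)
  small <- cs[sample(nrow(cs), round(nrow(cs) / 10)), ]
  fit_s <- localem_fit(small, off, kernel_spec(8))
  rmse <- function(f) sqrt(mean((f$values[use, 1] - lam_true[use])^2))
  expect_lt(rmse(fit), rmse(fit_s))
})
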