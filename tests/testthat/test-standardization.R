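# Person-years, reference rates, expected counts, deprivation indices.

test_that("person-years multiply counts by the window's study years", {
  pop <- data.frame(region_id = "r1", census_year = 2001L, sex = "M",
                    age_group = "70-74", count = 100L)
  py <- person_years(pop, 1999:2003)
  expect_equal(py$person_years, 500)
  # a study year two years past the last census is still covered
  pop2 <- data.frame(region_id = "r1", census_year = 2011L, sex = "M",
                     age_group = "70-74", count = 10L)
  expect_equal(person_years(pop2, 2012)$person_years, 10)
  expect_error(person_years(pop, 1999:2005), "not covered.*2004")
})

test_that("multi-census person-years equal the year-by-year sum", {
  set.seed(4)
  grid <- expand.grid(region_id = c("a", "b"),
                      census_year = seq(1981L, 2011L, 5L),
                      sex = c("M", "F"), age_group = c("20-24", "50-54"),
                      stringsAsFactors = FALSE)
  grid$count <- rpois(nrow(grid), 60)
  years <- 1980:2010
  py <- person_years(grid, years)
  # brute force: walk each calendar year, find its census, add the count
  brute <- 0
  for (yr in years) {
    cy <- grid$census_year[abs(grid$census_year - yr) <= 2][1]
    sel <- grid$census_year == cy
    brute <- brute + sum(grid$count[sel])
  }
  expect_equal(sum(py$person_years), brute)
  # per-stratum check on one cell
  one <- py[py$region_id == "a" & py$sex == "F" & py$age_group == "50-54", ]
  ref <- vapply(seq_len(nrow(one)), function(i) {
    cy <- one$census_year[i]
    n_years <- sum(abs(years - cy) <= 2)
    grid$count[grid$region_id == "a" & grid$sex == "F" &
                 grid$age_group == "50-54" & grid$census_year == cy] * n_years
  }, 0)
  expect_equal(one$person_years, ref)
})

test_that("provincial rates divide stratum cases by person-years", {
  py <- data.frame(region_id = "r", census_year = 2001L,
                   sex = c("M", "M", "F"),
                   age_group = c("70-74", "50-54", "70-74"),
                   person_years = c(1000, 2000, 1500))
  cs <- empty_cases(3)
  cs$case_id <- c("a", "b", "c")
  cs$site <- "kidney"; cs$behaviour <- "invasive"
  cs$sex <- c("M", "M", "M")
  cs$age_group <- c("70-74", "70-74", "50-54")
  cs$year <- 2001L; cs$precision <- "coarse"; cs$coarse_region <- "d"
  rates <- provincial_rates(cs, py)
  expect_equal(rates$rate[rates$sex == "M" & rates$age_group == "70-74"],
               2 / 1000)
  expect_equal(rates$rate[rates$sex == "M" & rates$age_group == "50-54"],
               1 / 2000)
  expect_equal(rates$rate[rates$sex == "F" & rates$age_group == "70-74"], 0)
  # cases in a stratum without denominator is an error
  cs$sex[3] <- "F"; cs$age_group[3] <- "20-24"
  expect_error(provincial_rates(cs, py), "zero person-years")
})

test_that("self-standardization closes: sum(E) equals observed total", {
  reg <- tiny_registry()
  sc <- reg$scenario
  cs <- reg$cases[reg$cases$site == "bladder", ]
  py <- person_years(reg$population, sc$study_years)
  rates <- provincial_rates(cs, py)
  cmap <- stats::setNames(reg$geography$fine$table$community_id,
                          reg$geography$fine$table$region_id)
  ec <- expected_counts(py, rates, cmap)
  expect_true(all(ec$E > 0))
  expect_equal(sum(ec$E), nrow(cs), tolerance = 1e-9)
})

test_that("expected counts match a brute-force double loop", {
  py <- expand.grid(region_id = c("r1", "r2", "r3", "r4", "r5"),
                    sex = c("M", "F"), age_group = c("60-64", "70-74"),
                    stringsAsFactors = FALSE)
  py$census_year <- 2001L
  set.seed(8)
  py$person_years <- runif(nrow(py), 100, 5000)
  rates <- expand.grid(sex = c("M", "F"), age_group = c("60-64", "70-74"),
                       stringsAsFactors = FALSE)
  rates$rate <- runif(4) / 1000
  cmap <- c(r1 = "c1", r2 = "c1", r3 = "c2", r4 = "c2", r5 = "c2")
  ec <- expected_counts(py, rates, cmap)
  brute <- c(c1 = 0, c2 = 0)
  for (i in seq_len(nrow(py))) {
    for (j in seq_len(nrow(rates))) {
      if (py$sex[i] == rates$sex[j] && py$age_group[i] == rates$age_group[j]) {
        brute[cmap[py$region_id[i]]] <- brute[cmap[py$region_id[i]]] +
          py$person_years[i] * rates$rate[j]
      }
    }
  }
  expect_equal(stats::setNames(ec$E, ec$community_id), brute)
  # single community holding everything: E equals the total
  ec1 <- expected_counts(py, rates, stats::setNames(rep("c0", 5), names(cmap)))
  expect_equal(ec1$E, sum(brute))
  # a community with zero population is dropped with a warning
  cmap2 <- c(cmap, r9 = "ghost")
  expect_warning(expected_counts(py, rates, cmap2), "ghost")
})

test_that("deprivation indices equal an eigen-decomposition oracle", {
  set.seed(12)
  n <- 20
  z <- rnorm(n)
  ind <- data.frame(
    community_id = sprintf("c%02d", 1:n),
    no_highschool_pct = 20 + 6 * z + rnorm(n, 0, 2),
    avg_income = 40000 - 5000 * z + rnorm(n, 0, 2000),
    employment_rate = 55 - 5 * z + rnorm(n, 0, 3),
    sep_div_wid_pct = 10 + 3 * z + rnorm(n, 0, 2),
    single_parent_pct = 14 + 3 * z + rnorm(n, 0, 2),
    living_alone_pct = 9 + 2 * z + rnorm(n, 0, 2))
  dep <- deprivation_indices(ind)
  expect_equal(mean(dep$material), 0, tolerance = 1e-10)
  expect_equal(mean(dep$social), 0, tolerance = 1e-10)
  # oracle: explicit eigen decomposition of the correlation matrix of the
  # sign-aligned standardized indicators
  zmat <- scale(cbind(ind$no_highschool_pct, -ind$avg_income,
                      -ind$employment_rate))
  ev <- eigen(cor(zmat))
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  expect_equal(dep$material, as.numeric(zmat %*% v), tolerance = 1e-10)
  # higher = more deprived: positive correlation with the latent factor
  expect_gt(cor(dep$material, z), 0.8)
  expect_gt(cor(dep$social, z), 0.6)
})

test_that("indices are invariant to affine indicator rescaling", {
  set.seed(13)
  n <- 15
  base <- data.frame(
    community_id = sprintf("c%02d", 1:n),
    no_highschool_pct = rnorm(n, 20, 5), avg_income = rnorm(n, 4e4, 5e3),
    employment_rate = rnorm(n, 55, 5), sep_div_wid_pct = rnorm(n, 10, 2),
    single_parent_pct = rnorm(n, 15, 4), living_alone_pct = rnorm(n, 9, 2))
  resc <- base
  resc$avg_income <- base$avg_income / 1000 + 7     # different units
  resc$single_parent_pct <- base$single_parent_pct * 10
  expect_equal(deprivation_indices(base), deprivation_indices(resc),
               tolerance = 1e-10)
})

test_that("degenerate indicator sets are handled", {
  flat <- data.frame(community_id = c("a", "b", "c"),
                     no_highschool_pct = 1, avg_income = 1,
                     employment_rate = 1, sep_div_wid_pct = 1,
                     single_parent_pct = 1, living_alone_pct = 1)
  # one warning per index dimension
  expect_warning(expect_warning(dep <- deprivation_indices(flat),
                                "zero variance"), "zero variance")
  expect_equal(dep$material, c(0, 0, 0))
  # two communities: symmetric scores
  two <- data.frame(community_id = c("a", "b"),
                    no_highschool_pct = c(10, 30), avg_income = c(5e4, 3e4),
                    employment_rate = c(60, 50), sep_div_wid_pct = c(8, 12),
                    single_parent_pct = c(10, 20), living_alone_pct = c(7, 12))
  expect_error(deprivation_indices(two), "at least 3")
})
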