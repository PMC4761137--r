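# Shared fixtures: all synthetic, built in code at test time.

# A small but complete scenario: 16 communities, 60 x 60 km, 3 km cells,
# seven censuses with a 20 -> 60 fine-region boundary change.
tiny_scenario <- function(seed = 7, ...) {
  args <- utils::modifyList(list(
    seed = seed, n_communities = 16L, n_coarse = 4L,
    width_km = 60, height_km = 60, cell_km = 3,
    fine_targets = c("1981" = 20L, "1986" = 20L, "1991" = 60L, "1996" = 60L,
                     "2001" = 60L, "2006" = 60L, "2011" = 60L),
    target_cases = c(bladder = 1200, kidney = 250)), list(...))
  do.call(scenario, args)
}

# registry cached per option set (generation is the slow part)
.reg_cache <- new.env(parent = emptyenv())
tiny_registry <- function(seed = 7, ...) {
  key <- paste(seed, deparse(list(...)), collapse = "")
  if (is.null(.reg_cache[[key]])) {
    .reg_cache[[key]] <- simulate_registry(tiny_scenario(seed, ...))
  }
  .reg_cache[[key]]
}

# offset for one site of a registry; external = TRUE standardizes against
# the scenario's true baseline rates instead of the observed cases
registry_offset <- function(reg, site = "bladder", external = FALSE,
                            sex = NULL) {
  sc <- reg$scenario
  cs <- reg$cases[reg$cases$site == site, , drop = FALSE]
  if (!is.null(sex)) cs <- cs[cs$sex == sex, , drop = FALSE]
  pop <- reg$population
  if (!is.null(sex)) pop <- pop[pop$sex == sex, , drop = FALSE]
  if (external) {
    rates <- sc$rates[sc$rates$site == site, c("sex", "age_group", "rate")]
    return(build_offset(pop, rates, reg$geography$fine, reg$grid,
                        sc$study_years))
  }
  py <- person_years(pop, sc$study_years)
  rates <- provincial_rates(cs, py)
  pyc <- py
  names(pyc)[names(pyc) == "person_years"] <- "count"
  pyc$count <- pyc$count / vapply(pyc$census_year, function(cy) {
    length(intersect((cy - 2):(cy + 2), sc$study_years))
  }, 0)
  build_offset(pyc, rates, reg$geography$fine, reg$grid, sc$study_years)
}

# a valid hand-built case table
toy_cases <- function() {
  df <- data.frame(
    case_id = c("a1", "a2", "a3"),
    site = c("bladder", "kidney", "bladder"),
    behaviour = c("in_situ", "invasive", "invasive"),
    sex = c("M", "F", "M"),
    age_group = c("70-74", "55-59", "85+"),
    year = c(2001L, 1985L, 1999L),
    precision = c("exact", "region_set", "coarse"),
    x = c(1500, NA, NA), y = c(2500, NA, NA),
    candidate_regions = c(NA, "F1986-0001;F1986-0002", NA),
    coarse_region = c(NA, NA, "D01"),
    stringsAsFactors = FALSE)
  df
}

# single-period offset on a tiny grid with two regions splitting the cells;
# everything constructed by hand for oracle work
toy_offset <- function(nx = 4, ny = 2, cell_m = 1000, e_cells = NULL,
                       split = NULL, years = 2000:2002) {
  g <- grid_spec(0, 0, cell_m, nx, ny)
  ncell <- nx * ny
  if (is.null(e_cells)) e_cells <- rep(1, ncell)
  if (is.null(split)) split <- seq_len(ceiling(ncell / 2))
  cells_a <- split
  cells_b <- setdiff(seq_len(ncell), split)
  vals <- e_cells / cell_area(g)
  off <- offset_surface(g, matrix(vals, ncol = 1),
                        data.frame(start = min(years), end = max(years)))
  off$mask <- rep(TRUE, ncell)
  off$region_cells <- list(A = cells_a, B = cells_b)
  off$region_meta <- data.frame(region_id = c("A", "B"), period = 1L,
                                coarse_id = c("D1", "D1"),
                                stringsAsFactors = FALSE)
  off$study_years <- years
  off
}

# case table living on a toy offset: `spec` is a list of entries either
# list(cell = i) for exact cases or list(region = "A") for censored ones
toy_cases_on_grid <- function(off, spec, year = 2000L) {
  g <- off$grid
  centers <- grid_centers(g)
  n <- length(spec)
  df <- empty_cases(n)
  df$case_id <- sprintf("c%02d", seq_len(n))
  df$site <- "bladder"; df$behaviour <- "invasive"
  df$sex <- "M"; df$age_group <- "70-74"
  df$year <- rep_len(as.integer(year), n)
  for (i in seq_len(n)) {
    s <- spec[[i]]
    if (!is.null(s$cell)) {
      df$precision[i] <- "exact"
      df$x[i] <- centers[s$cell, 1]
      df$y[i] <- centers[s$cell, 2]
    } else {
      df$precision[i] <- "region_set"
      df$candidate_regions[i] <- paste(s$region, collapse = ";")
    }
  }
  df
}
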