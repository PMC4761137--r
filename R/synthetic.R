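# Synthetic cancer-registry generator. Emulates the structure of a
# provincial registry: ~311 stable communities nested in coarse divisions,
# fine census regions that change between censuses (~115 units in the two
# early censuses, ~1400 later), populations uniform within fine regions,
# Poisson case counts drawn from a known relative-risk surface, and
# mixed-precision geocoding (exact point / censored to a set of fine
# regions / censored to a coarse division) with era-specific proportions.

#' Define a synthetic-registry scenario
#'
#' The scenario fixes every study condition: geography sizes, census years,
#' population ranges, baseline incidence rates per sex and age band (scaled
#' so the two sites yield roughly 3200 and 2100 cases over the recent
#' 13-year era at full population), the latent relative-risk field, and the
#' geocode-precision mix per era (recent era: 86.6 / 2.3 / 11.1 percent
#' exact / region-set / coarse; early era: 43.6 / 52.9 / 3.4, the shares
#' observed in long-run registry data).
#'
#' @param seed Integer master seed.
#' @param n_communities Number of communities (default 311, >= 4).
#' @param n_coarse Number of coarse divisions.
#' @param width_km,height_km Study-rectangle dimensions.
#' @param cell_km Analysis-grid cell size in km.
#' @param census_years Census years (window = year +/- 2).
#' @param study_years Calendar years of the full case series.
#' @param era_break First year of the "recent" geocoding era.
#' @param fine_targets Named integer vector: fine-region count per census year.
#' @param region_pop_range Range for fine-region population totals.
#' @param community_pop_cap Upper cap on any community's population.
#' @param uninhabited_prob Probability a fine region is partially uninhabited.
#' @param risk_field List: \code{type} in \code{"constant"}, \code{"one_bump"},
#'   \code{"two_bump"}, \code{"gradient"}; \code{amplitude} (peak relative
#'   risk); \code{scale_km} (Gaussian bump sd); \code{centers} (matrix of km
#'   coordinates, one row per bump; default central); \code{drift_per_year}
#'   (additive amplitude drift per year, 0 = time-constant).
#' @param geocode_mix List with elements \code{recent} and \code{early}, each
#'   a length-3 probability vector (exact, region_set, coarse).
#' @param censor_set_sizes Integer vector sampled uniformly for the number of
#'   fine regions in a postal-censoring set.
#' @param target_cases Named vector: expected case totals per site over the
#'   recent era at nominal full population.
#' @param male_rate_ratio Named vector: male/female rate ratio per site.
#' @param in_situ_share Named list per site: \code{recent} and \code{early}
#'   in-situ fractions.
#' @return A \code{scenario} object.
#' @export
scenario <- function(seed = 1L,
                     n_communities = 311L,
                     n_coarse = 18L,
                     width_km = 400, height_km = 220, cell_km = 2,
                     census_years = seq(1981L, 2011L, 5L),
                     study_years = 1980:2010,
                     era_break = 1998L,
                     fine_targets = c("1981" = 113L, "1986" = 118L,
                                      "1991" = 1379L, "1996" = 1450L,
                                      "2001" = 1550L, "2006" = 1600L,
                                      "2011" = 1645L),
                     region_pop_range = c(400, 700),
                     community_pop_cap = 30900,
                     uninhabited_prob = 0.2,
                     risk_field = list(type = "constant", amplitude = 1,
                                       scale_km = 30, centers = NULL,
                                       drift_per_year = 0),
                     geocode_mix = list(
                       recent = c(exact = 0.866, region_set = 0.023, coarse = 0.111),
                       early = c(exact = 0.436, region_set = 0.529, coarse = 0.034)),
                     censor_set_sizes = 1:4,
                     target_cases = c(bladder = 3232, kidney = 2143),
                     male_rate_ratio = c(bladder = 2.9, kidney = 1.5),
                     in_situ_share = list(bladder = c(recent = 0.36, early = 0.21),
                                          kidney = c(recent = 0, early = 0))) {
  if (n_communities < 4) stop("n_communities must be at least 4")
  for (m in geocode_mix) {
    if (any(m < 0) || abs(sum(m) - 1) > 0.02) {
      stop("geocode mix must be non-negative and sum to 1")
    }
  }
  stopifnot(all(as.character(census_years) %in% names(fine_targets)))
  if (is.null(risk_field$amplitude)) risk_field$amplitude <- 1
  if (is.null(risk_field$scale_km)) risk_field$scale_km <- 30
  if (is.null(risk_field$drift_per_year)) risk_field$drift_per_year <- 0
  if (risk_field$amplitude < 0) stop("risk-field amplitude must be >= 0")
  sc <- structure(list(
    seed = as.integer(seed), n_communities = as.integer(n_communities),
    n_coarse = as.integer(n_coarse),
    width_km = width_km, height_km = height_km, cell_km = cell_km,
    census_years = as.integer(census_years),
    study_years = as.integer(study_years),
    era_break = as.integer(era_break),
    fine_targets = fine_targets,
    region_pop_range = region_pop_range,
    community_pop_cap = community_pop_cap,
    uninhabited_prob = uninhabited_prob,
    risk_field = risk_field,
    geocode_mix = lapply(geocode_mix, function(m) m / sum(m)),
    censor_set_sizes = as.integer(censor_set_sizes),
    target_cases = target_cases,
    male_rate_ratio = male_rate_ratio,
    in_situ_share = in_situ_share), class = "scenario")
  sc$rates <- baseline_rates(sc)
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0("scenario: seed %d, %d communities, %.0f x %.0f km, ",
                     "risk field '%s'\n"),
              x$seed, x$n_communities, x$width_km, x$height_km,
              x$risk_field$type))
  invisible(x)
}

# Age distribution of the adult population over the 14 five-year bands.
default_age_weights <- function() {
  w <- c(9, 9, 9, 9, 8, 8, 7, 7, 6, 5, 4, 3, 2, 2)
  names(w) <- age_groups()
  w / sum(w)
}

# Annual incidence per person by (site, sex, age band). Log-linear in age
# midpoint; male/female ratio and overall level set so the recent 13-year
# era yields the target case totals at nominal full population.
baseline_rates <- function(sc) {
  mids <- age_group_midpoints()
  curve <- exp(0.085 * (mids - 70))
  w <- default_age_weights()
  nominal_pop <- mean(sc$fine_targets[as.character(max(sc$census_years))]) *
    mean(sc$region_pop_range)
  recent_years <- sum(sc$study_years >= sc$era_break)
  out <- NULL
  for (site in names(sc$target_cases)) {
    rr <- sc$male_rate_ratio[[site]]
    msex <- c(M = 2 * rr / (1 + rr), F = 2 / (1 + rr))
    # expected cases per unit K: pop/2 per sex, age weights w
    per_k <- nominal_pop / 2 * recent_years *
      sum(w * curve) * sum(msex)
    k <- sc$target_cases[[site]] / per_k
    for (sex in c("M", "F")) {
      out <- rbind(out, data.frame(site = site, sex = sex,
                                   age_group = age_groups(),
                                   rate = k * msex[[sex]] * curve,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# inclusive window of years a census covers, intersected with the study span
census_window <- function(sc, census_year) {
  intersect((census_year - 2L):(census_year + 2L), sc$study_years)
}

# census year whose window contains each year (error if uncovered)
census_for_year <- function(sc, years) {
  out <- rep(NA_integer_, length(years))
  for (cy in sc$census_years) {
    out[years >= cy - 2L & years <= cy + 2L] <- cy
  }
  if (anyNA(out)) {
    stop("study year(s) not covered by any census window: ",
         paste(unique(years[is.na(out)]), collapse = ", "))
  }
  out
}

#' Evaluate the scenario's true relative-risk field
#'
#' @param sc A \code{scenario}.
#' @param pts Two-column matrix of point coordinates in metres.
#' @param year Calendar year (matters only with temporal drift).
#' @return Numeric vector of relative risks (> 0).
#' @export
true_risk <- function(sc, pts, year = stats::median(sc$study_years)) {
  rf <- sc$risk_field
  w <- sc$width_km * 1000; h <- sc$height_km * 1000
  if (is.null(rf$centers)) {
    centers <- switch(rf$type,
                      two_bump = rbind(c(0.3 * w, 0.5 * h), c(0.75 * w, 0.45 * h)),
                      rbind(c(0.35 * w, 0.5 * h)))
  } else {
    centers <- rf$centers * 1000
  }
  amp <- rf$amplitude + rf$drift_per_year * (year - stats::median(sc$study_years))
  amp <- max(amp, 0.05)
  s2 <- (rf$scale_km * 1000)^2
  lam <- switch(rf$type,
                constant = rep(rf$amplitude, nrow(pts)),
                gradient = rf$amplitude^((pts[, 1] - 0) / w - 0.5),
                one_bump = , two_bump = {
                  l <- rep(1, nrow(pts))
                  for (b in seq_len(nrow(centers))) {
                    d2 <- (pts[, 1] - centers[b, 1])^2 + (pts[, 2] - centers[b, 2])^2
                    l <- l + (amp - 1) * exp(-d2 / (2 * s2))
                  }
                  l
                },
                stop("unknown risk-field type: ", rf$type))
  pmax(lam, 1e-8)
}

#' Analysis grid implied by a scenario
#' @param sc A \code{scenario}.
#' @return A \code{grid_spec} covering the study rectangle.
#' @export
scenario_grid <- function(sc) {
  cm <- sc$cell_km * 1000
  grid_spec(0, 0, cm, ceiling(sc$width_km / sc$cell_km),
            ceiling(sc$height_km / sc$cell_km))
}

#' Generate the nested synthetic geography
#'
#' Voronoi-style tessellations of the study rectangle, nested on three
#' levels: coarse divisions, communities (stable over time), and per-census
#' fine regions (re-tessellated each census to emulate boundary changes).
#' Every fine region lies inside exactly one community; every community
#' inside exactly one coarse division.
#'
#' @param sc A \code{scenario}.
#' @return List with \code{region_set} elements \code{communities},
#'   \code{fine} (all census years stacked; subset with
#'   \code{\link{regions_for_census}}) and \code{coarse}.
#' @export
make_geography <- function(sc) {
  if (sc$n_communities < 4) stop("n_communities must be at least 4")
  set.seed(sc$seed + 101L)
  w <- sc$width_km * 1000; h <- sc$height_km * 1000
  rect <- rect_poly(0, 0, w, h)
  span <- range(c(sc$study_years, sc$census_years - 2L, sc$census_years + 2L))

  coarse_seeds <- cbind(runif(sc$n_coarse, 0, w), runif(sc$n_coarse, 0, h))
  for (it in 1:2) {  # Lloyd relaxation for evenly sized divisions
    cells <- voronoi_tessellation(coarse_seeds, rect)
    coarse_seeds <- t(vapply(cells, poly_centroid, numeric(2)))
  }
  coarse_polys <- voronoi_tessellation(coarse_seeds, rect)
  coarse_ids <- sprintf("D%02d", seq_len(sc$n_coarse))

  comm_seeds <- cbind(runif(sc$n_communities, 0, w),
                      runif(sc$n_communities, 0, h))
  comm_coarse <- nearest_seed(comm_seeds, coarse_seeds)
  # guarantee every coarse division holds at least one community
  for (d in which(!(seq_len(sc$n_coarse) %in% comm_coarse))) {
    mv <- which.max(tabulate(comm_coarse, sc$n_coarse)[comm_coarse])
    comm_seeds[mv, ] <- poly_centroid(coarse_polys[[d]])
    comm_coarse[mv] <- d
  }
  comm_polys <- vector("list", sc$n_communities)
  for (i in seq_len(sc$n_communities)) {
    sib <- setdiff(which(comm_coarse == comm_coarse[i]), i)
    comm_polys[[i]] <- voronoi_cell(comm_seeds[i, ],
                                    comm_seeds[sib, , drop = FALSE],
                                    coarse_polys[[comm_coarse[i]]])
  }
  comm_ids <- sprintf("C%03d", seq_len(sc$n_communities))
  communities <- region_set("community", data.frame(
    region_id = comm_ids, period_start = span[1], period_end = span[2],
    inhabited_fraction = 1, coarse_id = coarse_ids[comm_coarse],
    stringsAsFactors = FALSE), comm_polys)

  fine_tab <- NULL; fine_polys <- list()
  for (cy in sc$census_years) {
    nf <- sc$fine_targets[[as.character(cy)]]
    seeds <- cbind(runif(nf, 0, w), runif(nf, 0, h))
    f_comm <- nearest_nested(seeds, coarse_seeds, comm_seeds, comm_coarse)
    # communities without a fine seed get one at their own seed point
    missing <- which(!(seq_len(sc$n_communities) %in% f_comm))
    if (length(missing)) {
      seeds <- rbind(seeds, comm_seeds[missing, , drop = FALSE])
      f_comm <- c(f_comm, missing)
      nf <- nrow(seeds)
    }
    polys <- vector("list", nf)
    for (i in seq_len(nf)) {
      sib <- setdiff(which(f_comm == f_comm[i]), i)
      polys[[i]] <- voronoi_cell(seeds[i, ], seeds[sib, , drop = FALSE],
                                 comm_polys[[f_comm[i]]])
    }
    inhf <- ifelse(runif(nf) < sc$uninhabited_prob, runif(nf, 0.3, 0.95), 1)
    tab <- data.frame(
      region_id = sprintf("F%d-%04d", cy, seq_len(nf)),
      period_start = min(census_window(sc, cy)),
      period_end = max(census_window(sc, cy)),
      inhabited_fraction = inhf,
      community_id = comm_ids[f_comm],
      coarse_id = coarse_ids[comm_coarse[f_comm]],
      census_year = cy, stringsAsFactors = FALSE)
    fine_tab <- rbind(fine_tab, tab)
    fine_polys <- c(fine_polys, polys)
  }
  fine <- region_set("fine_census", fine_tab, fine_polys)
  coarse <- region_set("coarse_division", data.frame(
    region_id = coarse_ids, period_start = span[1], period_end = span[2],
    inhabited_fraction = 1, stringsAsFactors = FALSE), coarse_polys)
  list(communities = communities, fine = fine, coarse = coarse)
}

nearest_seed <- function(pts, seeds) {
  out <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    out[i] <- which.min((seeds[, 1] - pts[i, 1])^2 + (seeds[, 2] - pts[i, 2])^2)
  }
  out
}

# nested nearest: first the coarse seed, then the nearest community seed
# belonging to that coarse division
nearest_nested <- function(pts, coarse_seeds, comm_seeds, comm_coarse) {
  cz <- nearest_seed(pts, coarse_seeds)
  out <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    members <- which(comm_coarse == cz[i])
    out[i] <- members[which.min((comm_seeds[members, 1] - pts[i, 1])^2 +
                                  (comm_seeds[members, 2] - pts[i, 2])^2)]
  }
  out
}

#' Subset the stacked fine-region set to one census year
#' @param fine The \code{fine} element of \code{\link{make_geography}}.
#' @param census_year A census year present in the set.
#' @return A \code{region_set} for that census only.
#' @export
regions_for_census <- function(fine, census_year) {
  keep <- fine$table$census_year == census_year
  if (!any(keep)) stop("no fine regions for census year ", census_year)
  region_set("fine_census", fine$table[keep, , drop = FALSE],
             fine$polygons[keep], fine$crs_label)
}

#' Generate census population tables
#'
#' Per fine region and census year, counts by sex and five-year age band.
#' Region totals are drawn uniformly from the scenario's
#' \code{region_pop_range}; community totals are capped at
#' \code{community_pop_cap} by proportional scaling.
#'
#' @param sc A \code{scenario}.
#' @param geography Output of \code{\link{make_geography}}.
#' @return data.frame (region_id, census_year, sex, age_group, count).
#' @export
make_population <- function(sc, geography) {
  set.seed(sc$seed + 202L)
  wts <- default_age_weights()
  strata <- expand.grid(sex = c("M", "F"), age_group = age_groups(),
                        stringsAsFactors = FALSE)
  p_strata <- 0.5 * wts[strata$age_group]
  out <- vector("list", length(sc$census_years))
  ft <- geography$fine$table
  for (k in seq_along(sc$census_years)) {
    cy <- sc$census_years[k]
    rows <- which(ft$census_year == cy)
    totals <- round(runif(length(rows), sc$region_pop_range[1],
                          sc$region_pop_range[2]))
    # cap community totals
    ctot <- tapply(totals, ft$community_id[rows], sum)
    over <- ctot[ctot > sc$community_pop_cap]
    for (cid in names(over)) {
      sel <- ft$community_id[rows] == cid
      totals[sel] <- floor(totals[sel] * sc$community_pop_cap / over[[cid]])
    }
    counts <- vapply(totals, function(tt) {
      as.vector(stats::rmultinom(1, tt, p_strata))
    }, numeric(nrow(strata)))
    out[[k]] <- data.frame(
      region_id = rep(ft$region_id[rows], each = nrow(strata)),
      census_year = cy,
      sex = rep(strata$sex, length(rows)),
      age_group = rep(strata$age_group, length(rows)),
      count = as.integer(counts),
      stringsAsFactors = FALSE)
  }
  pop <- do.call(rbind, out)
  rownames(pop) <- NULL
  pop
}

# Cells of each fine region of one census, restricted to the inhabited
# portion (the ceil(f * n) cells nearest the region centroid). Returns a
# list of integer cell-index vectors named by region_id.
inhabited_cells <- function(rs, grid) {
  assign <- rasterize_regions(rs, grid)
  centers <- grid_centers(grid)
  out <- rep(list(integer(0)), nrow(rs$table))
  names(out) <- rs$table$region_id
  for (r in seq_len(nrow(rs$table))) {
    cells <- which(assign == r)
    if (!length(cells)) {
      # sliver smaller than a cell: use the cell holding its centroid
      cen <- poly_centroid(rs$polygons[[r]])
      cells <- cell_index(grid, cen[1], cen[2])
      cells <- cells[!is.na(cells)]
    }
    f <- rs$table$inhabited_fraction[r]
    if (f < 1 && length(cells) > 1) {
      cen <- poly_centroid(rs$polygons[[r]])
      d2 <- (centers[cells, 1] - cen[1])^2 + (centers[cells, 2] - cen[2])^2
      cells <- cells[order(d2)][seq_len(ceiling(f * length(cells)))]
    }
    out[[r]] <- cells
  }
  out
}

#' Simulate case records from the true risk surface
#'
#' Cell-level counts are Poisson with mean (stratum rate x population density
#' x cell area x exposure years x relative risk at the cell), populations
#' being uniform over each fine region's inhabited cells. Each case is
#' placed uniformly within its cell with an exact geocode (censoring is a
#' separate step, \code{\link{censor_geocodes}}).
#'
#' @param sc A \code{scenario}.
#' @param geography Output of \code{\link{make_geography}}.
#' @param population Output of \code{\link{make_population}}.
#' @param seed Integer seed for this draw.
#' @param sites Sites to simulate (default both).
#' @param grid Analysis grid (default \code{scenario_grid(sc)}).
#' @return Case data.frame, all rows with \code{precision = "exact"}.
#' @export
simulate_cases <- function(sc, geography, population, seed,
                           sites = names(sc$target_cases),
                           grid = scenario_grid(sc)) {
  set.seed(seed)
  centers <- grid_centers(grid)
  rates <- sc$rates
  out <- list()
  n_id <- 0L
  for (cy in sc$census_years) {
    window <- census_window(sc, cy)
    if (!length(window)) next
    rs <- regions_for_census(geography$fine, cy)
    cells <- inhabited_cells(rs, grid)
    ncell <- vapply(cells, length, 0L)
    if (any(ncell == 0)) {
      pop_r <- tapply(population$count[population$census_year == cy],
                      population$region_id[population$census_year == cy], sum)
      bad <- names(cells)[ncell == 0 & pop_r[names(cells)] > 0]
      if (length(bad)) {
        stop("grid too coarse: no cells for populated region ", bad[1])
      }
    }
    mid_year <- stats::median(window)
    lam_cell <- true_risk(sc, centers, mid_year)
    if (any(!is.finite(lam_cell))) stop("risk field non-finite")
    pop_cy <- population[population$census_year == cy, , drop = FALSE]
    for (site in sites) {
      rt <- rates[rates$site == site, ]
      key <- paste(pop_cy$sex, pop_cy$age_group)
      rmap <- stats::setNames(rt$rate, paste(rt$sex, rt$age_group))
      exp_rs <- pop_cy$count * rmap[key] * length(window)
      base_r <- tapply(exp_rs, pop_cy$region_id, sum)
      for (rid in names(cells)) {
        cl <- cells[[rid]]
        if (!length(cl)) next
        b <- base_r[[rid]]
        if (is.na(b) || b <= 0) next
        lw <- lam_cell[cl]
        n_cases <- stats::rpois(1, b * mean(lw))
        if (n_cases == 0) next
        pick <- if (length(cl) == 1) rep(1L, n_cases) else {
          sample.int(length(cl), n_cases, replace = TRUE, prob = lw)
        }
        sel <- which(pop_cy$region_id == rid & exp_rs > 0)
        strat <- sel[sample.int(length(sel), n_cases, replace = TRUE,
                                prob = exp_rs[sel])]
        cm <- grid$cell_m
        px <- centers[cl[pick], 1] + runif(n_cases, -cm / 2, cm / 2)
        py <- centers[cl[pick], 2] + runif(n_cases, -cm / 2, cm / 2)
        yr <- window[sample.int(length(window), n_cases, replace = TRUE)]
        era <- ifelse(yr >= sc$era_break, "recent", "early")
        p_insitu <- sc$in_situ_share[[site]][era]
        beh <- ifelse(runif(n_cases) < p_insitu, "in_situ", "invasive")
        df <- empty_cases(n_cases)
        df$case_id <- sprintf("%s-%07d", site, n_id + seq_len(n_cases))
        n_id <- n_id + n_cases
        df$site <- site
        df$behaviour <- beh
        df$sex <- pop_cy$sex[strat]
        df$age_group <- pop_cy$age_group[strat]
        df$year <- as.integer(yr)
        df$precision <- "exact"
        df$x <- px; df$y <- py
        out[[length(out) + 1L]] <- df
      }
    }
  }
  cases <- if (length(out)) do.call(rbind, out) else empty_cases(0)
  rownames(cases) <- NULL
  validate_cases(cases)
}

#' Censor case geocodes to emulate mixed-precision spatial referencing
#'
#' Each case keeps its exact point with probability given by its era's mix,
#' is censored to a set of fine census regions (the truly containing region
#' plus adjacent ones), or is censored to its coarse division. The original
#' point is retained in \code{true_x}/\code{true_y} for evaluation only.
#'
#' @param cases Case data.frame with exact geocodes.
#' @param sc A \code{scenario}.
#' @param geography Output of \code{\link{make_geography}}.
#' @param seed Integer seed.
#' @return Censored case data.frame.
#' @export
censor_geocodes <- function(cases, sc, geography, seed) {
  stopifnot(all(cases$precision == "exact"))
  for (m in sc$geocode_mix) {
    if (any(m < 0) || abs(sum(m) - 1) > 1e-8) stop("invalid geocode mix")
  }
  set.seed(seed)
  cases$true_x <- cases$x
  cases$true_y <- cases$y
  if (!nrow(cases)) return(cases)
  era <- ifelse(cases$year >= sc$era_break, "recent", "early")
  u <- runif(nrow(cases))
  prec <- character(nrow(cases))
  for (e in c("recent", "early")) {
    m <- sc$geocode_mix[[e]]
    sel <- era == e
    prec[sel] <- c("exact", "region_set", "coarse")[
      1L + (u[sel] >= m[1]) + (u[sel] >= m[1] + m[2])]
  }
  cy <- census_for_year(sc, cases$year)
  for (census in unique(cy[prec != "exact"])) {
    rs <- regions_for_census(geography$fine, census)
    sel <- which(cy == census & prec != "exact")
    rid <- locate_regions(rs, cbind(cases$x[sel], cases$y[sel]))
    if (anyNA(rid)) {
      stop("case outside all fine regions: ", cases$case_id[sel[is.na(rid)][1]])
    }
    adj <- build_adjacency_quiet(rs)
    for (k in seq_along(sel)) {
      i <- sel[k]
      if (prec[i] == "coarse") {
        cases$coarse_region[i] <- rs$table$coarse_id[rid[k]]
      } else {
        size <- sample(sc$censor_set_sizes, 1)
        set <- rs$table$region_id[rid[k]]
        nbrs <- adj[[rid[k]]]
        if (size > 1 && length(nbrs)) {
          set <- c(set, sample(nbrs, min(size - 1, length(nbrs))))
        }
        cases$candidate_regions[i] <- paste(set, collapse = ";")
      }
      cases$x[i] <- NA_real_; cases$y[i] <- NA_real_
    }
  }
  cases$precision <- prec
  validate_cases(cases)
}

build_adjacency_quiet <- function(rs) {
  suppressWarnings(build_adjacency(rs))
}

# region row index containing each point (polygon containment with bbox
# prefilter); NA when outside every region
locate_regions <- function(rs, pts) {
  out <- rep(NA_integer_, nrow(pts))
  bbs <- t(vapply(rs$polygons, poly_bbox, numeric(4)))
  for (r in seq_len(nrow(rs$table))) {
    cand <- which(is.na(out) &
                    pts[, 1] >= bbs[r, 1] & pts[, 1] <= bbs[r, 3] &
                    pts[, 2] >= bbs[r, 2] & pts[, 2] <= bbs[r, 4])
    if (!length(cand)) next
    inside <- point_in_poly(rs$polygons[[r]], pts[cand, , drop = FALSE])
    out[cand[inside]] <- r
  }
  # points that sit exactly on shared boundaries can be claimed by no
  # polygon under even-odd counting; fall back to the nearest region
  for (i in which(is.na(out))) {
    d <- vapply(rs$polygons, function(p) {
      points_to_segments_dist(pts[i, , drop = FALSE], p)
    }, 0)
    if (min(d) < 1) out[i] <- which.min(d)
  }
  out
}

#' Generate community covariates
#'
#' Six census-style socioeconomic indicators driven by two correlated latent
#' deprivation factors (material and social) plus noise, and a well-water
#' usage percentage with a smooth west-east trend. The latent factors are
#' attached as \code{attr(, "truth")} for recovery tests.
#'
#' @param sc A \code{scenario}.
#' @param communities Community \code{region_set}.
#' @param seed Integer seed.
#' @param loading Loading of each indicator on its latent factor.
#' @param noise_sd Residual sd of each indicator.
#' @return data.frame of indicators plus \code{well_water_pct}.
#' @export
make_covariates <- function(sc, communities, seed, loading = 0.8,
                            noise_sd = 0.6) {
  set.seed(seed)
  n <- n_regions(communities)
  zm <- rnorm(n)
  zs <- 0.4 * zm + sqrt(1 - 0.4^2) * rnorm(n)
  ind <- function(latent, sign = 1) {
    sign * loading * latent + noise_sd * rnorm(n)
  }
  cen <- t(vapply(communities$polygons, poly_centroid, numeric(2)))
  xrel <- cen[, 1] / (sc$width_km * 1000)
  df <- data.frame(
    community_id = communities$table$region_id,
    no_highschool_pct = 25 + 8 * ind(zm),
    avg_income = 35000 + 6000 * ind(zm, -1),
    employment_rate = 60 + 7 * ind(zm, -1),
    sep_div_wid_pct = 12 + 4 * ind(zs),
    single_parent_pct = 15 + 5 * ind(zs),
    living_alone_pct = 10 + 4 * ind(zs),
    well_water_pct = 100 * stats::plogis(
      stats::qlogis(0.45) + 1.2 * (0.5 - xrel) + 0.5 * rnorm(n)),
    stringsAsFactors = FALSE)
  attr(df, "truth") <- list(material_latent = zm, social_latent = zs)
  df
}

#' Simulate a complete synthetic registry
#'
#' Convenience wrapper running geography, population, covariates, case
#' simulation (both sites) and geocode censoring under one scenario seed.
#'
#' @param sc A \code{scenario}.
#' @return List: \code{scenario}, \code{geography}, \code{population},
#'   \code{covariates}, \code{cases} (censored), \code{cases_exact}
#'   (pre-censoring), \code{grid}, \code{truth} (true risk per grid cell at
#'   the study mid-year and the scenario parameters).
#' @export
simulate_registry <- function(sc) {
  geography <- make_geography(sc)
  population <- make_population(sc, geography)
  covariates <- make_covariates(sc, geography$communities, sc$seed + 303L)
  cases_exact <- simulate_cases(sc, geography, population, sc$seed + 404L)
  cases <- censor_geocodes(cases_exact, sc, geography, sc$seed + 505L)
  grid <- scenario_grid(sc)
  truth <- list(
    lambda = true_risk(sc, grid_centers(grid)),
    risk_field = sc$risk_field, rates = sc$rates)
  list(scenario = sc, geography = geography, population = population,
       covariates = covariates, cases = cases, cases_exact = cases_exact,
       grid = grid, truth = truth)
}

#' Write a synthetic registry to a directory
#'
#' Emits the standard file set: region GeoJSONs, population / case /
#' covariate CSVs and a JSON manifest of every scenario parameter and seed.
#'
#' @param reg Output of \code{\link{simulate_registry}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_registry <- function(reg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_regions(reg$geography$communities, file.path(dir, "communities.geojson"))
  write_regions(reg$geography$fine, file.path(dir, "fine_regions.geojson"))
  write_regions(reg$geography$coarse, file.path(dir, "coarse_divisions.geojson"))
  utils::write.csv(reg$population, file.path(dir, "population.csv"),
                   row.names = FALSE)
  write_cases(reg$cases, file.path(dir, "cases.csv"))
  utils::write.csv(reg$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  sc <- reg$scenario
  manifest <- sc[setdiff(names(sc), "rates")]
  manifest$risk_field$centers <- if (is.null(sc$risk_field$centers)) NULL else
    as.data.frame(sc$risk_field$centers)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"), file.path(dir, "manifest.json"))
  invisible(dir)
}
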