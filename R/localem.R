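# Local-EM intensity estimation for spatially censored case locations.
#
# The E-step spreads each censored case over the cells of its candidate
# region set proportionally to (current risk) x (expected cases); exact
# cases put unit mass on their own cell. The M-step is a locally weighted
# Poisson maximizer: the redistributed case field and the offset are
# smoothed with the same edge-corrected Gaussian kernel and the risk is
# their ratio, rescaled so that risk x offset integrates to the case total.
# Iteration continues to a sup-norm fixed point.

#' Build the gridded expected-case (offset) surface
#'
#' For each census period, each fine region's expected count (person-years
#' within the window times the reference stratum rates) is spread uniformly
#' over the inhabited portion of the region's grid cells, giving an
#' expected-case density per period. Partially uninhabited regions
#' concentrate their population on the inhabited cells (the density doubles
#' when half the region is inhabited).
#'
#' @param population Population table (region_id, census_year, sex,
#'   age_group, count).
#' @param rates Stratum rates (sex, age_group, rate), e.g. from
#'   \code{\link{provincial_rates}}.
#' @param regions Fine-census \code{region_set} (all periods stacked, with
#'   \code{census_year} and optionally \code{coarse_id} columns).
#' @param grid A \code{grid_spec}.
#' @param study_years Years the offset must cover (defines each census
#'   window's year count).
#' @return An \code{offset_surface} with density values (expected cases per
#'   square metre per period), plus the region-to-cell map, study-region
#'   mask and per-region metadata used by the local-EM fit.
#' @export
build_offset <- function(population, rates, regions, grid,
                         study_years = NULL) {
  census_years <- sort(unique(regions$table$census_year))
  if (!length(census_years) || anyNA(census_years)) {
    stop("regions must carry a census_year column")
  }
  if (is.null(study_years)) {
    study_years <- min(census_years - 2L):max(census_years + 2L)
  }
  rmap <- stats::setNames(rates$rate, paste(rates$sex, rates$age_group))
  n_cells <- grid$nx * grid$ny
  values <- matrix(0, n_cells, length(census_years))
  mask <- rep(FALSE, n_cells)
  region_cells <- list()
  meta <- NULL
  periods <- data.frame(start = integer(0), end = integer(0))
  area <- cell_area(grid)
  for (k in seq_along(census_years)) {
    cy <- census_years[k]
    window <- intersect((cy - 2L):(cy + 2L), study_years)
    periods <- rbind(periods, data.frame(start = min(window), end = max(window)))
    rs <- region_set("fine_census",
                     regions$table[regions$table$census_year == cy, ,
                                   drop = FALSE],
                     regions$polygons[regions$table$census_year == cy],
                     regions$crs_label)
    assign <- rasterize_regions(rs, grid)
    mask <- mask | !is.na(assign)
    cells <- inhabited_cells(rs, grid)
    pop <- population[population$census_year == cy, , drop = FALSE]
    exp_r <- tapply(pop$count * rmap[paste(pop$sex, pop$age_group)] *
                      length(window), pop$region_id, sum)
    for (r in seq_len(nrow(rs$table))) {
      rid <- rs$table$region_id[r]
      e <- exp_r[rid]
      if (is.na(e)) e <- 0
      cl <- cells[[rid]]
      if (!length(cl)) {
        if (e > 0) stop("grid too coarse: populated region ", rid,
                        " covers no grid cell")
        next
      }
      values[cl, k] <- values[cl, k] + e / (length(cl) * area)
      region_cells[[rid]] <- cl
    }
    meta <- rbind(meta, data.frame(
      region_id = rs$table$region_id, period = k,
      coarse_id = if ("coarse_id" %in% names(rs$table)) rs$table$coarse_id
      else NA_character_,
      stringsAsFactors = FALSE))
  }
  off <- offset_surface(grid, values, periods)
  off$mask <- mask
  off$region_cells <- region_cells
  off$region_meta <- meta
  off$study_years <- study_years
  off
}

# period index of each case year; error outside all periods
period_of_year <- function(offset, years) {
  p <- rep(NA_integer_, length(years))
  for (k in seq_len(nrow(offset$periods))) {
    p[years >= offset$periods$start[k] & years <= offset$periods$end[k]] <- k
  }
  if (anyNA(p)) {
    stop("case year(s) outside the offset's periods: ",
         paste(unique(years[is.na(p)]), collapse = ", "))
  }
  p
}

# Resolve every case to candidate cells + period. Returns list:
#   exact: data.frame(cell, period)
#   groups: list of list(cells, period, count) for censored cases
prep_case_alloc <- function(cases, offset) {
  grid <- offset$grid
  period <- period_of_year(offset, cases$year)
  ex <- cases$precision == "exact"
  exact <- NULL
  if (any(ex)) {
    cell <- cell_index(grid, cases$x[ex], cases$y[ex])
    if (anyNA(cell)) {
      stop("exact case outside the grid: ", cases$case_id[ex][is.na(cell)][1])
    }
    exact <- data.frame(cell = cell, period = period[ex])
  }
  groups <- list()
  cen <- which(!ex)
  if (length(cen)) {
    key <- character(length(cen))
    cellsets <- vector("list", length(cen))
    meta <- offset$region_meta
    for (m in seq_along(cen)) {
      i <- cen[m]
      if (cases$precision[i] == "region_set") {
        rids <- split_candidates(cases$candidate_regions[i])[[1]]
      } else {
        rids <- meta$region_id[meta$period == period[i] &
                                 !is.na(meta$coarse_id) &
                                 meta$coarse_id == cases$coarse_region[i]]
        if (!length(rids)) {
          stop("coarse region ", cases$coarse_region[i],
               " has no fine regions in period ", period[i],
               " (case ", cases$case_id[i], ")")
        }
      }
      cl <- sort(unique(unlist(offset$region_cells[rids], use.names = FALSE)))
      if (!length(cl)) {
        stop("case ", cases$case_id[i], ": candidate regions cover no cells")
      }
      cellsets[[m]] <- cl
      key[m] <- paste0(period[i], "|", paste(rids, collapse = ";"))
    }
    uk <- !duplicated(key)
    counts <- table(key)
    groups <- lapply(which(uk), function(m) {
      list(cells = cellsets[[m]], period = period[cen[m]],
           count = as.numeric(counts[[key[m]]]))
    })
    for (m in seq_along(groups)) {
      g <- groups[[m]]
      if (sum(offset$values[g$cells, g$period]) <= 0) {
        first <- cases$case_id[cen[match(key[uk][m], key)]]
        stop("case ", first, ": candidate set has zero offset in its period")
      }
    }
  }
  list(exact = exact, groups = groups, n = nrow(cases))
}

#' Fit the spatial local-EM risk surface
#'
#' Fixed-point iteration for the relative-risk surface lambda(s) given
#' case records with mixed geocode precision and a gridded offset. Periods
#' are pooled spatially; censored cases are spread within their own
#' period's candidate regions using their period's offset.
#'
#' @param cases Case data.frame (see \code{\link{validate_cases}}).
#' @param offset An \code{offset_surface} from \code{\link{build_offset}}.
#' @param kernel A \code{kernel_spec} (spatial bandwidth; any temporal
#'   component is ignored here).
#' @param control List: \code{tol} (sup-norm relative change, default 1e-4),
#'   \code{max_iter} (200).
#' @param smoother Optional precomputed \code{\link{make_smoother}} result
#'   (reused across bootstrap replicates).
#' @return A \code{risk_surface} with fields \code{iterations},
#'   \code{converged}, \code{sup_change}, \code{n_cases} and
#'   \code{mass_balance} (sum of risk x expected over cells divided by the
#'   case count; 1 up to numerical tolerance).
#' @export
localem_fit <- function(cases, offset, kernel, control = list(),
                        smoother = NULL) {
  ctl <- utils::modifyList(list(tol = 1e-4, max_iter = 200), control)
  if (is.null(smoother)) smoother <- make_smoother(offset$grid, kernel,
                                                   offset$mask)
  alloc <- prep_case_alloc(cases, offset)
  area <- cell_area(offset$grid)
  e_mat <- offset$values * area            # expected counts per cell/period
  e_pool <- rowSums(e_mat)
  den <- apply_smoother(smoother, e_pool)
  pos <- den > 0
  n <- alloc$n
  w0 <- numeric(length(e_pool))
  if (!is.null(alloc$exact)) {
    tab <- table(alloc$exact$cell)
    w0[as.integer(names(tab))] <- as.numeric(tab)
  }
  lam <- as.numeric(offset$mask)           # lambda^0 = 1 on the region
  iters <- 0L; sup <- Inf
  history <- numeric(0)
  repeat {
    w <- w0
    for (g in alloc$groups) {
      wt <- lam[g$cells] * e_mat[g$cells, g$period]
      tot <- sum(wt)
      if (tot <= 0) {  # risk vanished on the candidate set; fall back to offset
        wt <- e_mat[g$cells, g$period]
        tot <- sum(wt)
      }
      w[g$cells] <- w[g$cells] + g$count * wt / tot
    }
    num <- apply_smoother(smoother, w)
    lam_new <- numeric(length(lam))
    lam_new[pos] <- num[pos] / den[pos]
    if (n > 0) {
      tot <- sum(lam_new * e_pool)
      if (tot > 0) lam_new <- lam_new * n / tot
    }
    iters <- iters + 1L
    sup <- max(abs(lam_new - lam) / pmax(lam, 1e-8))
    history <- c(history, sup)
    lam <- lam_new
    if (sup < ctl$tol || iters >= ctl$max_iter || length(alloc$groups) == 0) {
      break
    }
  }
  converged <- sup < ctl$tol || length(alloc$groups) == 0
  if (!converged) {
    warning(sprintf("local-EM did not converge in %d iterations (sup change %.2e)",
                    iters, sup))
  }
  lam[lam < 0] <- 0
  risk_surface(offset$grid, lam, h_km = kernel$h_km,
               iterations = iters, converged = converged, sup_change = sup,
               change_history = history, n_cases = n,
               mass_balance = if (n > 0) sum(lam * e_pool) / n else NA_real_,
               mask = offset$mask)
}

#' Fit the spatio-temporal local-EM risk surface
#'
#' Separable space-time Gaussian kernel: spatial smoothing as in
#' \code{\link{localem_fit}} and a temporal Gaussian (sd \code{tau_years})
#' renormalized over the observed year range. The E-step spreads censored
#' cases only within their own period's candidate cells at their (known)
#' diagnosis year. The returned surface is evaluated at \code{index_years}.
#'
#' @inheritParams localem_fit
#' @param kernel A \code{kernel_spec} with both \code{h_km} and
#'   \code{tau_years}.
#' @param index_years Years at which to report the surface (default
#'   1980, 1990, 2000, 2010 clipped to the offset's span).
#' @return A \code{risk_surface} with one band per index year.
#' @export
localem_fit_st <- function(cases, offset, kernel, control = list(),
                           index_years = c(1980L, 1990L, 2000L, 2010L),
                           smoother = NULL) {
  if (is.null(kernel$tau_years)) stop("kernel must carry tau_years")
  ctl <- utils::modifyList(list(tol = 1e-4, max_iter = 200), control)
  if (is.null(smoother)) smoother <- make_smoother(offset$grid, kernel,
                                                   offset$mask)
  years <- offset$study_years
  index_years <- intersect(as.integer(index_years), years)
  if (!length(index_years)) stop("no index year falls within the study span")
  kt <- time_smoother_matrix(years, kernel$tau_years, kernel$truncation)
  yper <- period_of_year(offset, years)
  ylen <- tabulate(yper, nrow(offset$periods))
  area <- cell_area(offset$grid)
  # expected counts per cell per single year
  e_year <- offset$values[, yper, drop = FALSE] * area /
    rep(ylen[yper], each = nrow(offset$values))
  alloc <- prep_case_alloc(cases, offset)
  case_year_idx <- match(cases$year, years)
  den <- apply_smoother(smoother, e_year) %*% t(kt)
  pos <- den > 0
  n <- alloc$n
  w0 <- matrix(0, nrow(e_year), ncol(e_year))
  ex <- which(cases$precision == "exact")
  if (length(ex)) {
    cell <- cell_index(offset$grid, cases$x[ex], cases$y[ex])
    for (m in seq_along(ex)) {
      w0[cell[m], case_year_idx[ex[m]]] <- w0[cell[m], case_year_idx[ex[m]]] + 1
    }
  }
  # censored cases grouped by (candidate set, year)
  cen <- which(cases$precision != "exact")
  groups <- list()
  if (length(cen)) {
    # group censored cases by (candidate cell set, diagnosis year)
    for (i in cen) {
      one <- prep_case_alloc(cases[i, , drop = FALSE], offset)$groups[[1]]
      key <- paste0(paste(one$cells, collapse = ","), "@",
                    case_year_idx[i])
      if (is.null(groups[[key]])) {
        groups[[key]] <- list(cells = one$cells, yi = case_year_idx[i],
                              count = 1)
      } else {
        groups[[key]]$count <- groups[[key]]$count + 1
      }
    }
  }
  lam <- matrix(as.numeric(offset$mask), nrow(e_year), length(years))
  iters <- 0L; sup <- Inf
  repeat {
    w <- w0
    for (g in groups) {
      wt <- lam[g$cells, g$yi] * e_year[g$cells, g$yi]
      tot <- sum(wt)
      if (tot <= 0) {
        wt <- e_year[g$cells, g$yi]
        tot <- sum(wt)
      }
      w[g$cells, g$yi] <- w[g$cells, g$yi] + g$count * wt / tot
    }
    num <- apply_smoother(smoother, w) %*% t(kt)
    lam_new <- matrix(0, nrow(lam), ncol(lam))
    lam_new[pos] <- num[pos] / den[pos]
    if (n > 0) {
      tot <- sum(lam_new * e_year)
      if (tot > 0) lam_new <- lam_new * n / tot
    }
    iters <- iters + 1L
    sup <- max(abs(lam_new - lam) / pmax(lam, 1e-8))
    lam <- lam_new
    if (sup < ctl$tol || iters >= ctl$max_iter || length(groups) == 0) break
  }
  converged <- sup < ctl$tol || length(groups) == 0
  if (!converged) {
    warning(sprintf("local-EM (spatio-temporal) did not converge in %d iterations",
                    iters))
  }
  lam[lam < 0] <- 0
  risk_surface(offset$grid, lam[, match(index_years, years), drop = FALSE],
               years = index_years, h_km = kernel$h_km,
               tau_years = kernel$tau_years,
               iterations = iters, converged = converged, sup_change = sup,
               n_cases = n,
               mass_balance = if (n > 0) sum(lam * e_year) / n else NA_real_,
               mask = offset$mask)
}
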