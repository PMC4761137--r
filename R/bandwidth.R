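# Bandwidth selection by half-split cross-validation, bootstrap score
# tests for spatial and spatio-temporal effects, and parametric-bootstrap
# exceedance surfaces at a relative-risk threshold (default 1.1).

#' Cross-validation scores over a bandwidth grid
#'
#' For each of \code{n_splits} random half-splits of the cases, the model
#' is fitted to one half (with the offset halved to keep expectations
#' consistent) and scored on the other half's cell counts by Poisson
#' log-likelihood; both fold orientations are scored. Held-out censored
#' cases are allocated to cells proportionally to the offset within their
#' candidate set (a fixed, risk-independent allocation). Higher scores are
#' better.
#'
#' @param cases Case data.frame (>= 20 cases).
#' @param offset \code{offset_surface} from \code{\link{build_offset}}.
#' @param bandwidths Numeric vector of spatial bandwidths (km), or a
#'   data.frame with columns \code{h_km} and optionally \code{tau_years}
#'   for spatio-temporal candidates.
#' @param n_splits Number of random half-splits (default 10).
#' @param seed Integer seed for the splits.
#' @param control Passed to \code{\link{localem_fit}}.
#' @return A \code{cv_table}: one row per candidate with mean score and
#'   score sd over the 2 x n_splits folds.
#' @export
cv_score <- function(cases, offset, bandwidths, n_splits = 10, seed = 1,
                     control = list()) {
  if (!is.data.frame(bandwidths)) {
    bandwidths <- data.frame(h_km = as.numeric(bandwidths))
  }
  if (nrow(bandwidths) < 2) stop("need at least 2 candidate bandwidths")
  if (nrow(cases) < 20) stop("need at least 20 cases for cross-validation")
  st <- "tau_years" %in% names(bandwidths) &&
    any(!is.na(bandwidths$tau_years))
  half <- offset
  half$values <- offset$values / 2
  n <- nrow(cases)
  set.seed(seed)
  splits <- list()
  attempt <- 0L
  while (length(splits) < n_splits) {
    inA <- sample(c(rep(TRUE, floor(n / 2)), rep(FALSE, ceiling(n / 2))))
    if (!any(inA) || all(inA)) {  # degenerate fold: resplit
      attempt <- attempt + 1L
      message("empty fold; resplitting with incremented seed")
      set.seed(seed + attempt)
      next
    }
    splits[[length(splits) + 1L]] <- inA
  }
  smoothers <- lapply(seq_len(nrow(bandwidths)), function(b) {
    make_smoother(offset$grid, kernel_spec(bandwidths$h_km[b]), offset$mask)
  })
  scores <- matrix(NA_real_, nrow(bandwidths), 2 * n_splits)
  for (s in seq_len(n_splits)) {
    for (orient in 1:2) {
      inA <- if (orient == 1) splits[[s]] else !splits[[s]]
      trn <- cases[inA, , drop = FALSE]
      tst <- cases[!inA, , drop = FALSE]
      for (b in seq_len(nrow(bandwidths))) {
        kb <- kernel_spec(bandwidths$h_km[b],
                          tau_years = if (st) bandwidths$tau_years[b])
        scores[b, 2 * (s - 1) + orient] <-
          heldout_score(trn, tst, half, kb, control, smoothers[[b]])
      }
    }
  }
  out <- bandwidths
  out$mean_score <- rowMeans(scores)
  out$score_sd <- apply(scores, 1, stats::sd)
  attr(out, "n_splits") <- n_splits
  attr(out, "seed") <- seed
  class(out) <- c("cv_table", class(out))
  out
}

# Poisson log-likelihood (up to the y! term) of the held-out fold's cell
# counts under the fitted risk times the held-out half offset
heldout_score <- function(trn, tst, half_offset, kernel, control, smoother) {
  st <- !is.null(kernel$tau_years) && !is.na(kernel$tau_years)
  if (st) {
    years <- half_offset$study_years
    fit <- localem_fit_st(trn, half_offset, kernel, control,
                          index_years = years, smoother = smoother)
    yper <- period_of_year(half_offset, years)
    ylen <- tabulate(yper, nrow(half_offset$periods))
    e_y <- half_offset$values[, yper, drop = FALSE] * cell_area(half_offset$grid) /
      rep(ylen[yper], each = nrow(half_offset$values))
    ycnt <- heldout_counts_st(tst, half_offset, years)
    mu <- pmax(fit$values * e_y, 1e-300)
    use <- e_y > 0
    sum(ycnt[use] * log(mu[use]) - mu[use])
  } else {
    fit <- localem_fit(trn, half_offset, kernel, control, smoother = smoother)
    e_pool <- rowSums(half_offset$values) * cell_area(half_offset$grid)
    ycnt <- heldout_counts(tst, half_offset)
    mu <- pmax(fit$values[, 1] * e_pool, 1e-300)
    use <- e_pool > 0
    sum(ycnt[use] * log(mu[use]) - mu[use])
  }
}

# held-out cell counts: exact cases at their cell, censored cases spread
# proportionally to the offset over their candidate cells
heldout_counts <- function(tst, offset) {
  y <- numeric(nrow(offset$values))
  if (!nrow(tst)) return(y)
  alloc <- prep_case_alloc(tst, offset)
  if (!is.null(alloc$exact)) {
    tab <- table(alloc$exact$cell)
    y[as.integer(names(tab))] <- y[as.integer(names(tab))] + as.numeric(tab)
  }
  for (g in alloc$groups) {
    wt <- offset$values[g$cells, g$period]
    y[g$cells] <- y[g$cells] + g$count * wt / sum(wt)
  }
  y
}

heldout_counts_st <- function(tst, offset, years) {
  y <- matrix(0, nrow(offset$values), length(years))
  if (!nrow(tst)) return(y)
  yi <- match(tst$year, years)
  ex <- which(tst$precision == "exact")
  if (length(ex)) {
    cell <- cell_index(offset$grid, tst$x[ex], tst$y[ex])
    for (m in seq_along(ex)) y[cell[m], yi[ex[m]]] <- y[cell[m], yi[ex[m]]] + 1
  }
  cen <- which(tst$precision != "exact")
  for (i in cen) {
    g <- prep_case_alloc(tst[i, , drop = FALSE], offset)$groups[[1]]
    wt <- offset$values[g$cells, g$period]
    y[g$cells, yi[i]] <- y[g$cells, yi[i]] + wt / sum(wt)
  }
  y
}

#' Select the bandwidth from a CV table
#'
#' Argmax of the mean CV score; exact ties go to the larger bandwidth
#' (more smoothing, fewer spurious structures).
#'
#' @param cv A \code{cv_table} from \code{\link{cv_score}}.
#' @return One-row data.frame (\code{h_km} and, if present,
#'   \code{tau_years}).
#' @export
select_bandwidth <- function(cv) {
  stopifnot(nrow(cv) >= 1)
  best <- which(cv$mean_score == max(cv$mean_score))
  if (length(best) > 1) {
    tau <- if ("tau_years" %in% names(cv)) cv$tau_years[best] else
      rep(0, length(best))
    best <- best[order(cv$h_km[best], tau, decreasing = TRUE)[1]]
  }
  cols <- intersect(c("h_km", "tau_years"), names(cv))
  out <- as.data.frame(cv)[best, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- parametric-bootstrap machinery ------------------------------------

# Censoring template: per-period precision mix and candidate-set-size
# distribution estimated from the observed cases, plus the raster adjacency
# of fine regions needed to rebuild candidate sets on simulated data.
censor_template <- function(cases, offset) {
  period <- period_of_year(offset, cases$year)
  nper <- nrow(offset$periods)
  mix <- matrix(0, nper, 3, dimnames = list(NULL, .precisions))
  overall <- table(factor(cases$precision, .precisions)) / max(1, nrow(cases))
  for (k in seq_len(nper)) {
    sel <- period == k
    mix[k, ] <- if (any(sel)) {
      table(factor(cases$precision[sel], .precisions)) / sum(sel)
    } else as.numeric(overall)
  }
  sizes <- sort(vapply(split_candidates(
    cases$candidate_regions[cases$precision == "region_set"]), length, 0L))
  if (!length(sizes)) sizes <- 1L
  list(mix = mix, sizes = sizes, adjacency = raster_adjacency(offset))
}

# fine-region adjacency per period from the gridded region map (two regions
# are adjacent when they own 4-neighbouring cells)
raster_adjacency <- function(offset) {
  grid <- offset$grid
  meta <- offset$region_meta
  out <- vector("list", nrow(offset$periods))
  for (k in seq_len(nrow(offset$periods))) {
    rids <- meta$region_id[meta$period == k]
    cellmap <- rep(NA_integer_, grid$nx * grid$ny)
    for (r in seq_along(rids)) {
      cellmap[offset$region_cells[[rids[r]]]] <- r
    }
    m <- field_matrix(grid, cellmap)
    pairs <- rbind(
      cbind(as.vector(m[-nrow(m), ]), as.vector(m[-1, ])),
      cbind(as.vector(m[, -ncol(m)]), as.vector(m[, -1])))
    pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]) &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    adj <- rep(list(integer(0)), length(rids))
    if (nrow(pairs)) {
      pairs <- unique(rbind(pairs, pairs[, 2:1]))
      sp <- split(pairs[, 2], pairs[, 1])
      adj[as.integer(names(sp))] <- lapply(sp, unique)
    }
    names(adj) <- rids
    out[[k]] <- lapply(adj, function(ix) rids[ix])
  }
  out
}

# Simulate one dataset with constant relative risk lambda0 against the
# offset, then censor it with the template's precision mix.
simulate_null_cases <- function(offset, lambda0, template) {
  grid <- offset$grid
  area <- cell_area(grid)
  meta <- offset$region_meta
  out <- list()
  id <- 0L
  for (k in seq_len(nrow(offset$periods))) {
    e_cell <- offset$values[, k] * area
    cells <- which(e_cell > 0)
    if (!length(cells)) next
    counts <- stats::rpois(length(cells), lambda0 * e_cell[cells])
    tot <- sum(counts)
    if (tot == 0) next
    cell_of <- rep(cells[counts > 0], counts[counts > 0])
    # cell -> containing fine region
    rids <- meta$region_id[meta$period == k]
    cellmap <- rep(NA_character_, grid$nx * grid$ny)
    for (rid in rids) cellmap[offset$region_cells[[rid]]] <- rid
    region_of <- cellmap[cell_of]
    years <- offset$periods$start[k]:offset$periods$end[k]
    yr <- years[sample.int(length(years), tot, replace = TRUE)]
    u <- runif(tot)
    mx <- template$mix[k, ]
    prec <- c("exact", "region_set", "coarse")[
      1L + (u >= mx[1]) + (u >= mx[1] + mx[2])]
    centers <- grid_centers(grid)
    df <- empty_cases(tot)
    df$case_id <- sprintf("sim-%07d", id + seq_len(tot)); id <- id + tot
    df$site <- "bladder"; df$behaviour <- "invasive"
    df$sex <- "M"; df$age_group <- "70-74"
    df$year <- as.integer(yr)
    df$precision <- prec
    ex <- prec == "exact"
    df$x[ex] <- centers[cell_of[ex], 1]
    df$y[ex] <- centers[cell_of[ex], 2]
    coarse_of <- stats::setNames(meta$coarse_id[meta$period == k], rids)
    adj <- template$adjacency[[k]]
    for (i in which(prec == "region_set")) {
      size <- template$sizes[sample.int(length(template$sizes), 1)]
      set <- region_of[i]
      nbrs <- adj[[region_of[i]]]
      if (size > 1 && length(nbrs)) {
        set <- c(set, sample(nbrs, min(size - 1, length(nbrs))))
      }
      df$candidate_regions[i] <- paste(set, collapse = ";")
    }
    co <- prec == "coarse"
    if (any(co)) {
      cr <- coarse_of[region_of[co]]
      if (anyNA(cr)) {  # no coarse lineage: censor to the fine region instead
        df$precision[co][is.na(cr)] <- "region_set"
        df$candidate_regions[co][is.na(cr)] <- region_of[co][is.na(cr)]
        co <- df$precision == "coarse"
        cr <- cr[!is.na(cr)]
      }
      df$coarse_region[df$precision == "coarse"] <- cr
    }
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) return(empty_cases(0))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# offset-weighted variance of the risk surface (the score-test statistic);
# for the temporal variant each location's offset-weighted time mean is
# removed first
surface_variance <- function(fit, offset, temporal = FALSE) {
  if (!temporal) {
    e <- rowSums(offset$values) * cell_area(offset$grid)
    lam <- if (ncol(fit$values) > 1) {
      rowSums(fit$values * ncol(fit$values)^-1)
    } else fit$values[, 1]
    lbar <- sum(e * lam) / sum(e)
    sum(e * (lam - lbar)^2) / sum(e)
  } else {
    stopifnot(ncol(fit$values) > 1)
    yrs <- fit$years
    per <- period_of_year(offset, yrs)
    e <- offset$values[, per, drop = FALSE] * cell_area(offset$grid)
    lam <- fit$values
    rs <- rowSums(e)
    use <- rs > 0
    tmean <- rowSums(e * lam)[use] / rs[use]
    resid <- lam[use, , drop = FALSE] - tmean
    sum(e[use, , drop = FALSE] * resid^2) / sum(e)
  }
}

#' Bootstrap score test for spatial or spatio-temporal risk variation
#'
#' The statistic is the offset-weighted variance of the fitted risk surface
#' (for the spatio-temporal test, of the surface after removing each
#' location's time mean -- a pure temporal-variation statistic). Its null
#' distribution is built from \code{B} parametric-bootstrap datasets
#' simulated at constant risk 1 with the data's censoring pattern, and
#' p = (1 + #\{T* >= T\}) / (B + 1).
#'
#' @param cases Case data.frame.
#' @param offset \code{offset_surface}.
#' @param h_km Spatial bandwidth (km), typically from
#'   \code{\link{select_bandwidth}}.
#' @param tau_years Optional temporal bandwidth; when given the test
#'   targets spatio-temporal (time-varying) structure.
#' @param B Bootstrap replicates (>= 19).
#' @param seed Integer seed.
#' @param control Passed to the local-EM fits.
#' @return List: \code{p_value}, \code{statistic}, \code{null_stats},
#'   \code{h_km}, \code{tau_years}, \code{B}.
#' @export
score_test <- function(cases, offset, h_km, tau_years = NULL, B = 100,
                       seed = 1, control = list()) {
  if (B < 19) stop("B must be at least 19 for usable p-value resolution")
  st <- !is.null(tau_years)
  kern <- kernel_spec(h_km, tau_years)
  smoother <- make_smoother(offset$grid, kern, offset$mask)
  fit <- if (st) {
    localem_fit_st(cases, offset, kern, control,
                   index_years = offset$study_years, smoother = smoother)
  } else localem_fit(cases, offset, kern, control, smoother = smoother)
  t_obs <- surface_variance(fit, offset, temporal = st)
  template <- censor_template(cases, offset)
  set.seed(seed)
  t_null <- numeric(B)
  for (b in seq_len(B)) {
    sim <- simulate_null_cases(offset, 1, template)
    fb <- if (st) {
      localem_fit_st(sim, offset, kern, control,
                     index_years = offset$study_years, smoother = smoother)
    } else localem_fit(sim, offset, kern, control, smoother = smoother)
    t_null[b] <- surface_variance(fb, offset, temporal = st)
  }
  list(p_value = (1 + sum(t_null >= t_obs)) / (B + 1),
       statistic = t_obs, null_stats = t_null,
       h_km = h_km, tau_years = tau_years, B = B)
}

#' Parametric-bootstrap exceedance surface P(s; 10\%)
#'
#' Simulates \code{B} datasets at constant relative risk \code{lambda0}
#' (default 1.1) with the data's censoring pattern, refits the local-EM
#' surface for each, and reports at every location one minus the proportion
#' of bootstrap surfaces exceeding the data's surface: large values mean
#' the data's risk is unlikely to be below \code{lambda0}.
#'
#' @param cases Case data.frame.
#' @param offset \code{offset_surface}.
#' @param h_km Spatial bandwidth (km).
#' @param tau_years Optional temporal bandwidth: when given, surfaces are
#'   spatio-temporal and exceedance is computed per index year.
#' @param cfg List: \code{B} (default 100), \code{lambda0} (1.1),
#'   \code{seed}, \code{index_years} (spatio-temporal only).
#' @param control Passed to the local-EM fits.
#' @return An \code{exceedance_surface}; the fitted data surface is
#'   attached as attribute \code{"fit"}.
#' @export
bootstrap_exceedance <- function(cases, offset, h_km, tau_years = NULL,
                                 cfg = list(), control = list()) {
  cfg <- utils::modifyList(list(B = 100L, lambda0 = 1.1, seed = 1L,
                                index_years = c(1980L, 1990L, 2000L, 2010L)),
                           cfg)
  if (cfg$B < 1) stop("B must be >= 1")
  if (cfg$lambda0 <= 0) stop("lambda0 must be positive")
  st <- !is.null(tau_years)
  kern <- kernel_spec(h_km, tau_years)
  smoother <- make_smoother(offset$grid, kern, offset$mask)
  fit_one <- function(cs) {
    if (st) {
      localem_fit_st(cs, offset, kern, control,
                     index_years = cfg$index_years, smoother = smoother)
    } else localem_fit(cs, offset, kern, control, smoother = smoother)
  }
  fit <- fit_one(cases)
  template <- censor_template(cases, offset)
  set.seed(cfg$seed)
  exceed <- matrix(0, nrow(fit$values), ncol(fit$values))
  used <- 0L
  dropped <- 0L
  for (b in seq_len(cfg$B)) {
    sim <- simulate_null_cases(offset, cfg$lambda0, template)
    fb <- withCallingHandlers(
      fit_one(sim),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    if (!isTRUE(fb$converged)) {
      dropped <- dropped + 1L
      message("bootstrap replicate ", b, " non-convergent; dropped")
      next
    }
    exceed <- exceed + (fb$values > fit$values)
    used <- used + 1L
  }
  if (dropped > 0.1 * cfg$B) {
    stop("more than 10% of bootstrap replicates failed to converge")
  }
  p <- exceed / used
  out <- exceedance_surface(offset$grid, 1 - p,
                            years = if (st) fit$years else NULL,
                            threshold = cfg$lambda0, B = used)
  attr(out, "fit") <- fit
  out
}
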