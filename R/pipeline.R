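# Study orchestration: cohort summary tables, the four community-level BYM
# fits, the local-EM analysis chain (CV -> score tests -> exceedance), and
# a YAML-configured end-to-end run.

#' Cohort characteristics summary
#'
#' Tabulates, per era, site and sex group (plus the sex total): cases
#' diagnosed and analyzed, in-situ and invasive splits, mean age at
#' diagnosis (age-band midpoints), geocode-precision percentages and
#' exclusions. An optional logical column \code{excluded} in \code{cases}
#' marks diagnosed-but-not-analyzed records.
#'
#' @param cases Case data.frame (possibly with an \code{excluded} column).
#' @param eras Named list of year vectors.
#' @return data.frame, one row per era x site x group.
#' @export
cohort_summary <- function(cases,
                           eras = list("1998-2010" = 1998:2010,
                                       "1980-2010" = 1980:2010)) {
  if (!"excluded" %in% names(cases)) {
    cases$excluded <- rep(FALSE, nrow(cases))
  }
  mids <- age_group_midpoints()
  rows <- list()
  for (era in names(eras)) {
    for (site in .sites) {
      for (grp in c("Total", "F", "M")) {
        sel <- cases$year %in% eras[[era]] & cases$site == site &
          (grp == "Total" | cases$sex == grp)
        cc <- cases[sel, , drop = FALSE]
        an <- cc[!cc$excluded, , drop = FALSE]
        n_an <- nrow(an)
        pr <- if (n_an) {
          100 * table(factor(an$precision, .precisions)) / n_an
        } else stats::setNames(rep(0, 3), .precisions)
        rows[[length(rows) + 1L]] <- data.frame(
          era = era, site = site, group = grp,
          diagnosed = nrow(cc), analyzed = n_an,
          in_situ = sum(an$behaviour == "in_situ"),
          invasive = sum(an$behaviour == "invasive"),
          mean_age = if (n_an) mean(mids[an$age_group]) else NA_real_,
          pct_exact = as.numeric(pr[["exact"]]),
          pct_region_set = as.numeric(pr[["region_set"]]),
          pct_coarse = as.numeric(pr[["coarse"]]),
          excluded = sum(cc$excluded),
          excluded_pct = if (nrow(cc)) 100 * sum(cc$excluded) / nrow(cc) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic case listing with the published Nova Scotia cohort structure
#'
#' Builds a registry-shaped case table whose marginal counts reproduce the
#' published characteristics of the Nova Scotia bladder and kidney cancer
#' cohorts: the 1998-2010 provincial cohort (3,292 / 2,199 diagnosed;
#' 3,232 / 2,143 analyzed after community-population exclusions; 1,164
#' in-situ bladder cases; sex-specific geocode-precision mixes around
#' 86 / 2 / 12 percent exact / postal-censored / town-censored) and the
#' 1980-2010 south-western cohort with its roughly 44 / 53 / 3 mix. Ages
#' are assigned as a two-band mixture matching each stratum's published
#' mean age at the band-midpoint level. Geometry fields hold placeholders:
#' the listing exercises cohort arithmetic, not mapping.
#'
#' @param period \code{"recent"} (1998-2010, province-wide) or
#'   \code{"early_sw"} (1980-2010, south-western subregion).
#' @return Case data.frame with an \code{excluded} column.
#' @export
synthetic_ns_cohort <- function(period = c("recent", "early_sw")) {
  period <- match.arg(period)
  spec <- if (period == "recent") list(
    years = 1998:2010,
    strata = list(
      list(site = "bladder", sex = "F", diagnosed = 834, analyzed = 820,
           in_situ = 298, mean_age = 71.2, mix = c(85.5, 2.07, 12.4)),
      list(site = "bladder", sex = "M", diagnosed = 2458, analyzed = 2412,
           in_situ = 866, mean_age = 70.5, mix = c(86.9, 2.36, 10.7)),
      list(site = "kidney", sex = "F", diagnosed = 863, analyzed = 848,
           in_situ = 0, mean_age = 66, mix = c(86.4, 1.65, 11.9)),
      list(site = "kidney", sex = "M", diagnosed = 1336, analyzed = 1295,
           in_situ = 0, mean_age = 63.7, mix = c(85.5, 2.39, 12.1))))
  else list(
    years = 1980:2010,
    strata = list(
      list(site = "bladder", sex = "F", diagnosed = 423, analyzed = 423,
           in_situ = 86, mean_age = 70.5, mix = c(40.4, 56.3, 3.3)),
      list(site = "bladder", sex = "M", diagnosed = 1387, analyzed = 1387,
           in_situ = 300, mean_age = 69.9, mix = c(44.6, 51.9, 3.5)),
      list(site = "kidney", sex = "F", diagnosed = 358, analyzed = 358,
           in_situ = 0, mean_age = 65.9, mix = c(50.6, 46.1, 3.3)),
      list(site = "kidney", sex = "M", diagnosed = 599, analyzed = 599,
           in_situ = 0, mean_age = 63.8, mix = c(45.2, 52.1, 2.7))))
  mids <- age_group_midpoints()
  out <- list()
  id <- 0L
  for (st in spec$strata) {
    n <- st$diagnosed
    df <- empty_cases(n)
    df$case_id <- sprintf("%s-%s-%05d", st$site, st$sex, id + seq_len(n))
    id <- id + n
    df$site <- st$site
    df$sex <- st$sex
    df$year <- as.integer(rep_len(spec$years, n))
    df$excluded <- c(rep(FALSE, st$analyzed), rep(TRUE, n - st$analyzed))
    # behaviour: published in-situ count among analyzed cases
    df$behaviour <- "invasive"
    df$behaviour[seq_len(st$in_situ)] <- "in_situ"
    # ages: two bands 10 years apart mixed to hit the published mean
    lo <- names(mids)[max(which(mids <= st$mean_age))]
    hi <- names(mids)[match(lo, names(mids)) + 2L]
    w <- (mids[[hi]] - st$mean_age) / (mids[[hi]] - mids[[lo]])
    n_lo <- round(w * n)
    df$age_group <- c(rep(lo, n_lo), rep(hi, n - n_lo))
    # geocode precision with placeholder geometry fields
    mix <- st$mix / sum(st$mix)
    n_ex <- round(mix[1] * st$analyzed)
    n_rs <- round(mix[2] * st$analyzed)
    prec <- rep("coarse", n)
    prec[seq_len(n_ex)] <- "exact"
    if (n_rs > 0) prec[n_ex + seq_len(n_rs)] <- "region_set"
    df$precision <- prec
    df$x[prec == "exact"] <- 0
    df$y[prec == "exact"] <- 0
    df$candidate_regions[prec == "region_set"] <- "R1"
    df$coarse_region[prec == "coarse"] <- "D1"
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Table-2-style labels for the BYM parameter table
.bym_row_labels <- c(mu = "Intercept",
                     well_water_pct = "% using well water",
                     material = "Material deprivation",
                     social = "Social deprivation",
                     sigma_S = "Spatial standard deviation",
                     sigma_V = "Unstructured standard deviation")

#' Run the community-level analysis for every site and sex
#'
#' For each site x sex data set: indirect standardization against that
#' stratum's own provincial rates, a BYM fit with the well-water and
#' deprivation covariates, the posterior parameter table, per-community
#' relative risks and exceedance probabilities, counts of communities in
#' the 0.8 / 0.95 exceedance bands, and the excess-case total (observed
#' minus expected in high-probability communities).
#'
#' @param registry Output of \code{\link{simulate_registry}} (or a list
#'   with the same components).
#' @param era Years of the analysis cohort (default 1998:2010).
#' @param sites,sexes Subsets to fit.
#' @param mcmc,priors Passed to \code{\link{fit_bym}}.
#' @param threshold Exceedance threshold (default 1.1).
#' @return Named list (one element per site_sex) of lists: \code{params}
#'   (labelled summary table), \code{communities} (RR and P_i),
#'   \code{n_over_80}, \code{n_over_95}, \code{excess_cases}. Failed cells
#'   carry the error message instead.
#' @export
run_community_analysis <- function(registry, era = 1998:2010,
                                   sites = .sites, sexes = .sexes,
                                   mcmc = list(), priors = list(),
                                   threshold = 1.1) {
  geo <- registry$geography
  cmap <- stats::setNames(geo$fine$table$community_id,
                          geo$fine$table$region_id)
  out <- list()
  for (site in sites) {
    for (sex in sexes) {
      key <- paste(site, sex, sep = "_")
      out[[key]] <- tryCatch({
        cs <- registry$cases
        cs <- cs[cs$site == site & cs$sex == sex & cs$year %in% era, ,
                 drop = FALSE]
        pop <- registry$population[registry$population$sex == sex, ,
                                   drop = FALSE]
        py <- person_years(pop, era)
        rates <- provincial_rates(cs, py)
        ec <- suppressWarnings(expected_counts(py, rates, cmap))
        dat <- community_data(cs, ec, registry$covariates, geo)
        post <- fit_bym(dat, mcmc = mcmc, priors = priors)
        params <- as.data.frame(post$summary)
        params <- cbind(parameter = .bym_row_labels[rownames(post$summary)],
                        params, row.names = NULL)
        rr <- posterior_relative_risk(post)
        ep <- exceedance_prob(post, threshold)
        comm <- data.frame(community_id = dat$community_id, Y = dat$Y,
                           E = dat$E, relative_risk = unname(rr),
                           exceedance_prob = ep$prob,
                           stringsAsFactors = FALSE)
        high <- comm$exceedance_prob > 0.8
        list(params = params, communities = comm,
             n_over_80 = sum(comm$exceedance_prob > 0.8),
             n_over_95 = sum(comm$exceedance_prob > 0.95),
             excess_cases = sum(comm$Y[high] - comm$E[high]),
             posterior = post)
      }, error = function(e) list(error = conditionMessage(e)))
    }
  }
  out
}

#' Run the spatially continuous local-EM analysis chain
#'
#' Mirrors the study design: cross-validate the spatial bandwidth, test for
#' spatial variation; when the spatial test passes the gate (default 0.1),
#' cross-validate the temporal bandwidth and test for spatio-temporal
#' variation; map exceedance probabilities from the spatio-temporal model
#' when time matters, from the pooled spatial model otherwise. Risk
#' surfaces themselves are withheld from the report when
#' \code{mask_risk = TRUE} (the disclosure rule); exceedance surfaces are
#' always reported.
#'
#' @param registry Registry bundle.
#' @param site,sex Data set selector.
#' @param era Analysis years (default the full span).
#' @param window Optional bbox \code{c(xmin, ymin, xmax, ymax)} in km
#'   selecting a subregion.
#' @param h_grid Candidate spatial bandwidths, km.
#' @param tau_grid Candidate temporal bandwidths, years.
#' @param gate p-value gate for proceeding to the temporal model.
#' @param B Bootstrap replicates for tests and exceedance.
#' @param index_years Index years for spatio-temporal surfaces.
#' @param n_splits CV splits.
#' @param seed Seed for CV splits and bootstraps.
#' @param grid_km Cell size of the analysis grid, km (default 1, the
#'   package default for kernel work).
#' @param mask_risk Withhold fitted risk surfaces from the report.
#' @param control Local-EM control list.
#' @return List: \code{cv}, \code{h_km}, \code{spatial_test}, and when
#'   gated through, \code{cv_tau}, \code{tau_years}, \code{temporal_test};
#'   \code{exceedance} (an \code{exceedance_surface}) when any test passed;
#'   \code{risk} unless masked.
#' @export
run_localem_analysis <- function(registry, site, sex = NULL,
                                 era = NULL, window = NULL,
                                 h_grid = c(3, 6, 11, 17, 22),
                                 tau_grid = c(5, 9, 13),
                                 gate = 0.1, B = 100L,
                                 index_years = c(1980L, 1990L, 2000L, 2010L),
                                 n_splits = 10L, seed = 1L, grid_km = 1,
                                 mask_risk = TRUE, control = list()) {
  sc <- registry$scenario
  if (is.null(era)) era <- sc$study_years
  cs <- registry$cases[registry$cases$site == site &
                         registry$cases$year %in% era, , drop = FALSE]
  if (!is.null(sex)) cs <- cs[cs$sex == sex, , drop = FALSE]
  cs_all <- cs   # province-wide case set: defines the reference rates
  fine <- registry$geography$fine
  if (!is.null(window)) {
    wm <- window * 1000
    cen <- t(vapply(fine$polygons, poly_centroid, numeric(2)))
    keep <- cen[, 1] >= wm[1] & cen[, 1] <= wm[3] &
      cen[, 2] >= wm[2] & cen[, 2] <= wm[4]
    fine <- region_set("fine_census", fine$table[keep, , drop = FALSE],
                       fine$polygons[keep], fine$crs_label)
    grid <- grid_spec(wm[1], wm[2], grid_km * 1000,
                      ceiling((wm[3] - wm[1]) / (grid_km * 1000)),
                      ceiling((wm[4] - wm[2]) / (grid_km * 1000)))
  } else {
    cm <- grid_km * 1000
    grid <- grid_spec(0, 0, cm, ceiling(sc$width_km / grid_km),
                      ceiling(sc$height_km / grid_km))
  }
  keep_rids <- fine$table$region_id
  keep_case <- (cs$precision == "exact" &
                  !is.na(cell_in_window(cs, grid))) |
    (cs$precision == "region_set" &
       vapply(split_candidates(ifelse(is.na(cs$candidate_regions), "",
                                      cs$candidate_regions)),
              function(v) length(v) > 0 && v[1] %in% keep_rids, TRUE)) |
    (cs$precision == "coarse" & cs$coarse_region %in% fine$table$coarse_id)
  cs <- cs[keep_case, , drop = FALSE]
  sexes_in <- if (is.null(sex)) .sexes else sex
  pop <- registry$population[registry$population$sex %in% sexes_in, ,
                             drop = FALSE]
  py <- person_years(pop, era)
  rates <- provincial_rates(cs_all, py)
  pyc <- py
  names(pyc)[names(pyc) == "person_years"] <- "count"
  pyc$count <- pyc$count / vapply(pyc$census_year, function(cy) {
    length(intersect((cy - 2):(cy + 2), era))
  }, 0)
  off <- build_offset(pyc, rates, fine, grid, study_years = era)

  res <- list(site = site, sex = sex, n_cases = nrow(cs))
  cv <- cv_score(cs, off, h_grid, n_splits = n_splits, seed = seed,
                 control = control)
  res$cv <- as.data.frame(cv)
  res$h_km <- select_bandwidth(cv)$h_km
  res$spatial_test <- score_test(cs, off, res$h_km, B = B, seed = seed + 1,
                                 control = control)
  use_st <- FALSE
  if (res$spatial_test$p_value < gate) {
    cvt <- cv_score(cs, off, data.frame(h_km = res$h_km, tau_years = tau_grid),
                    n_splits = n_splits, seed = seed + 2, control = control)
    res$cv_tau <- as.data.frame(cvt)
    res$tau_years <- select_bandwidth(cvt)$tau_years
    res$temporal_test <- score_test(cs, off, res$h_km, res$tau_years, B = B,
                                    seed = seed + 3, control = control)
    use_st <- res$temporal_test$p_value < gate
    ex <- bootstrap_exceedance(cs, off, res$h_km,
                               tau_years = if (use_st) res$tau_years,
                               cfg = list(B = B, lambda0 = 1.1,
                                          seed = seed + 4,
                                          index_years = index_years),
                               control = control)
    res$exceedance <- ex
    if (!mask_risk) res$risk <- attr(ex, "fit")
    attr(res$exceedance, "fit") <- NULL
  }
  res
}

cell_in_window <- function(cs, grid) {
  out <- rep(NA_integer_, nrow(cs))
  ex <- !is.na(cs$x)
  out[ex] <- cell_index(grid, cs$x[ex], cs$y[ex])
  out
}

#' Load a study configuration from YAML
#'
#' @param path YAML file; top-level keys \code{scenario} (arguments to
#'   \code{\link{scenario}}), \code{community} and \code{localem}
#'   (argument lists for the two analysis drivers), \code{out_dir},
#'   \code{mask_risk}.
#' @return Configuration list with defaults filled in.
#' @export
study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(list(scenario = list(), community = list(),
                         localem = list(), out_dir = NULL,
                         mask_risk = TRUE), cfg)
}

#' Run the full synthetic study end to end
#'
#' simulate -> cohort summary -> community BYM fits -> local-EM chain,
#' writing tables (CSV), surfaces (.asc) and a JSON manifest when
#' \code{out_dir} is set.
#'
#' @param cfg Configuration list from \code{\link{study_config}} (or built
#'   directly).
#' @return List: \code{registry}, \code{cohort}, \code{community},
#'   \code{localem}.
#' @export
run_study <- function(cfg) {
  sc <- do.call(scenario, cfg$scenario)
  registry <- simulate_registry(sc)
  cohort <- cohort_summary(registry$cases,
                           eras = stats::setNames(
                             list(sc$era_break:max(sc$study_years),
                                  sc$study_years),
                             c(paste0(sc$era_break, "-", max(sc$study_years)),
                               paste0(min(sc$study_years), "-",
                                      max(sc$study_years)))))
  community <- do.call(run_community_analysis,
                       c(list(registry = registry), cfg$community))
  localem <- lapply(cfg$localem, function(args) {
    do.call(run_localem_analysis,
            c(list(registry = registry, mask_risk = cfg$mask_risk), args))
  })
  out <- list(registry = registry, cohort = cohort, community = community,
              localem = localem)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_registry(registry, file.path(cfg$out_dir, "registry"))
    utils::write.csv(cohort, file.path(cfg$out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    for (key in names(community)) {
      cell <- community[[key]]
      if (!is.null(cell$error)) next
      utils::write.csv(cell$params,
                       file.path(cfg$out_dir, paste0("bym_params_", key, ".csv")),
                       row.names = FALSE)
      utils::write.csv(cell$communities,
                       file.path(cfg$out_dir, paste0("bym_communities_", key, ".csv")),
                       row.names = FALSE)
    }
    for (i in seq_along(localem)) {
      lm <- localem[[i]]
      tag <- paste0("localem_", i, "_", lm$site,
                    if (!is.null(lm$sex)) paste0("_", lm$sex))
      utils::write.csv(lm$cv, file.path(cfg$out_dir, paste0(tag, "_cv.csv")),
                       row.names = FALSE)
      if (!is.null(lm$exceedance)) {
        write_surface(lm$exceedance,
                      file.path(cfg$out_dir, paste0(tag, "_exceedance.asc")))
      }
      if (!is.null(lm$risk) && !isTRUE(cfg$mask_risk)) {
        write_surface(lm$risk, file.path(cfg$out_dir, paste0(tag, "_risk.asc")))
      }
    }
  }
  out
}
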