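# Indirect standardization: person-years from census windows, provincial
# stratum rates, expected counts per community, and PCA deprivation indices.

#' Person-years of exposure per region and stratum
#'
#' Each study year is assigned to the census whose window (census year +/- 2)
#' contains it; person-years are the census count times the number of study
#' years the window contributes.
#'
#' @param population Population table (region_id, census_year, sex,
#'   age_group, count).
#' @param study_years Integer vector of study years; every year must fall in
#'   exactly one census window.
#' @return data.frame (region_id, census_year, sex, age_group, person_years).
#' @export
person_years <- function(population, study_years) {
  census_years <- sort(unique(population$census_year))
  nyears <- integer(length(census_years))
  covered <- rep(FALSE, length(study_years))
  for (k in seq_along(census_years)) {
    inwin <- study_years >= census_years[k] - 2L &
      study_years <= census_years[k] + 2L
    nyears[k] <- sum(inwin)
    covered <- covered | inwin
  }
  if (!all(covered)) {
    stop("study year(s) not covered by any census window: ",
         paste(study_years[!covered], collapse = ", "))
  }
  ny <- stats::setNames(nyears, census_years)
  out <- population
  out$person_years <- out$count * ny[as.character(out$census_year)]
  out$count <- NULL
  out[out$person_years > 0, , drop = FALSE]
}

#' Provincial (whole-study-area) stratum rates
#'
#' Indirect-standardization reference rates: cases per person-year by sex
#' and age band, pooled over the study area and period.
#'
#' @param cases Case data.frame.
#' @param py Person-years table from \code{\link{person_years}}.
#' @return data.frame (sex, age_group, rate).
#' @export
provincial_rates <- function(cases, py) {
  key_py <- paste(py$sex, py$age_group)
  denom <- tapply(py$person_years, key_py, sum)
  strata <- expand.grid(sex = c("M", "F"), age_group = age_groups(),
                        stringsAsFactors = FALSE)
  key_s <- paste(strata$sex, strata$age_group)
  num <- rep(0, nrow(strata))
  if (nrow(cases)) {
    tab <- table(paste(cases$sex, cases$age_group))
    num[match(names(tab), key_s)] <- as.numeric(tab)
  }
  den <- as.numeric(denom[key_s])
  den[is.na(den)] <- 0
  if (any(num > 0 & den == 0)) {
    bad <- which(num > 0 & den == 0)[1]
    stop("stratum with cases but zero person-years: ", key_s[bad])
  }
  strata$rate <- ifelse(den > 0, num / den, 0)
  strata
}

#' Expected case counts per community
#'
#' E_i = sum over the community's fine regions and strata of person-years
#' times the reference stratum rate. When the rates come from the same data
#' (self-standardization), sum(E_i) equals the observed total exactly.
#'
#' @param py Person-years table.
#' @param rates Stratum rates from \code{\link{provincial_rates}}.
#' @param community_map Named character vector mapping fine region_id to
#'   community_id (e.g. built from the geography's fine-region table).
#' @return data.frame (community_id, E); communities with zero population
#'   are dropped with a warning.
#' @export
expected_counts <- function(py, rates, community_map) {
  unmapped <- setdiff(unique(py$region_id), names(community_map))
  if (length(unmapped)) {
    stop("fine region(s) not mapped to a community: ",
         paste(utils::head(unmapped, 3), collapse = ", "))
  }
  rmap <- stats::setNames(rates$rate, paste(rates$sex, rates$age_group))
  contrib <- py$person_years * rmap[paste(py$sex, py$age_group)]
  comm <- community_map[py$region_id]
  e <- tapply(contrib, comm, sum)
  all_comms <- unique(unname(community_map))
  zero <- setdiff(all_comms, names(e)[e > 0])
  if (length(zero)) {
    warning(length(zero), " community(ies) excluded for unavailable ",
            "population: ", paste(utils::head(zero, 3), collapse = ", "))
  }
  out <- data.frame(community_id = names(e), E = as.numeric(e),
                    stringsAsFactors = FALSE)
  out[out$E > 0, , drop = FALSE]
}

#' Assemble the community-level data set for the BYM model
#'
#' Joins observed counts (cases located by community), expected counts and
#' covariates into one table, and attaches the neighbour structure.
#'
#' @param cases Case data.frame (exact geocodes are located by polygon
#'   containment; censored cases are assigned by their first candidate
#'   region's community or coarse division majority community).
#' @param expected Output of \code{\link{expected_counts}}.
#' @param covariates Covariate data.frame with \code{community_id},
#'   \code{well_water_pct} and six indicator columns (see
#'   \code{\link{deprivation_indices}}).
#' @param geography Output of \code{\link{make_geography}}.
#' @return data.frame (community_id, Y, E, well_water_pct, material, social)
#'   with a \code{neighbours} attribute (named list of community ids).
#' @export
community_data <- function(cases, expected, covariates, geography) {
  comms <- geography$communities
  ids <- comms$table$region_id
  y <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(cases)) {
    cid <- assign_cases_to_communities(cases, geography)
    tab <- table(cid)
    y[names(tab)] <- as.integer(tab)
  }
  dep <- deprivation_indices(covariates)
  df <- merge(expected, dep, by = "community_id")
  df <- merge(df, covariates[, c("community_id", "well_water_pct")],
              by = "community_id")
  df$Y <- as.integer(y[df$community_id])
  df <- df[, c("community_id", "Y", "E", "well_water_pct",
               "material", "social")]
  df <- df[order(match(df$community_id, ids)), , drop = FALSE]
  rownames(df) <- NULL
  nb <- build_adjacency_quiet(comms)
  attr(df, "neighbours") <- nb[df$community_id]
  df
}

# community of each case: exact points by containment; region-set cases via
# their first (truly containing, by construction) candidate region; coarse
# cases are spread to the coarse division's most populous community
assign_cases_to_communities <- function(cases, geography) {
  ft <- geography$fine$table
  comm_of_fine <- stats::setNames(ft$community_id, ft$region_id)
  out <- rep(NA_character_, nrow(cases))
  ex <- which(cases$precision == "exact")
  if (length(ex)) {
    rid <- locate_regions(geography$communities,
                          cbind(cases$x[ex], cases$y[ex]))
    out[ex] <- geography$communities$table$region_id[rid]
  }
  rsel <- which(cases$precision == "region_set")
  if (length(rsel)) {
    first <- vapply(split_candidates(cases$candidate_regions[rsel]),
                    `[`, "", 1)
    out[rsel] <- comm_of_fine[first]
  }
  co <- which(cases$precision == "coarse")
  if (length(co)) {
    ct <- geography$communities$table
    for (i in co) {
      members <- ct$region_id[ct$coarse_id == cases$coarse_region[i]]
      out[i] <- members[1]
    }
  }
  out
}

#' Material and social deprivation indices
#'
#' First principal component (correlation-matrix PCA) of three standardized
#' indicators per dimension. Income and employment are sign-flipped before
#' scoring so that higher always means more deprived; each component is
#' oriented so its loading sum is positive, and scores have mean zero.
#'
#' @param indicators data.frame with \code{community_id} and the six columns
#'   \code{no_highschool_pct}, \code{avg_income}, \code{employment_rate}
#'   (material) and \code{sep_div_wid_pct}, \code{single_parent_pct},
#'   \code{living_alone_pct} (social).
#' @return data.frame (community_id, material, social).
#' @export
deprivation_indices <- function(indicators) {
  if (nrow(indicators) < 3) stop("need at least 3 communities for PCA")
  mat <- cbind(indicators$no_highschool_pct, -indicators$avg_income,
               -indicators$employment_rate)
  soc <- cbind(indicators$sep_div_wid_pct, indicators$single_parent_pct,
               indicators$living_alone_pct)
  data.frame(community_id = indicators$community_id,
             material = first_pc_scores(mat),
             social = first_pc_scores(soc),
             stringsAsFactors = FALSE)
}

first_pc_scores <- function(x) {
  sds <- apply(x, 2, stats::sd)
  keep <- which(sds > 0)
  if (!length(keep)) {
    warning("all indicators have zero variance; scores set to 0")
    return(rep(0, nrow(x)))
  }
  if (length(keep) < ncol(x)) {
    warning("dropping zero-variance indicator(s) from index")
  }
  z <- scale(x[, keep, drop = FALSE])
  ev <- eigen(stats::cor(z), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  as.numeric(z %*% v)
}
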