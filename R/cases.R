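# Case records live in a plain data.frame with one row per diagnosis:
#   case_id, site (bladder|kidney), behaviour (in_situ|invasive), sex (M|F),
#   age_group ("20-24", ..., "85+"), year, precision (exact|region_set|coarse),
#   x, y (metres, exact cases), candidate_regions (semicolon-joined fine
#   region ids, region_set cases), coarse_region (coarse division id).
# Optional columns true_x, true_y retain the pre-censoring location of
# synthetic cases for evaluation only.

.sites <- c("bladder", "kidney")
.behaviours <- c("in_situ", "invasive")
.sexes <- c("M", "F")
.precisions <- c("exact", "region_set", "coarse")

#' Age-band labels used throughout the package
#'
#' Five-year bands from 20-24 up to 85+, adults only.
#' @return Character vector of band labels.
#' @export
age_groups <- function() {
  c(paste(seq(20, 80, 5), seq(24, 84, 5), sep = "-"), "85+")
}

#' Midpoints of the age bands (85+ assigned 87.5)
#' @return Named numeric vector.
#' @export
age_group_midpoints <- function() {
  mids <- c(seq(22.5, 82.5, 5), 87.5)
  names(mids) <- age_groups()
  mids
}

#' Validate a case table
#'
#' Checks every row against the case-record invariants: legal factor levels,
#' age 20+, and exactly one geocode representation matching \code{precision}
#' (a point for \code{exact}, a non-empty candidate fine-region set for
#' \code{region_set}, a coarse division id for \code{coarse}).
#'
#' @param cases data.frame of case records.
#' @return The validated data.frame (character columns normalized), invisibly
#'   usable; errors name the first offending case.
#' @export
validate_cases <- function(cases) {
  req <- c("case_id", "site", "behaviour", "sex", "age_group", "year",
           "precision", "x", "y", "candidate_regions", "coarse_region")
  miss <- setdiff(req, names(cases))
  if (length(miss)) stop("case table lacks column(s): ", paste(miss, collapse = ", "))
  chk <- function(col, levels) {
    bad <- !(cases[[col]] %in% levels)
    if (any(bad)) {
      stop(sprintf("case %s: invalid %s '%s'", cases$case_id[which(bad)[1]],
                   col, cases[[col]][which(bad)[1]]))
    }
  }
  chk("site", .sites); chk("behaviour", .behaviours)
  chk("sex", .sexes); chk("precision", .precisions)
  chk("age_group", age_groups())
  if (anyDuplicated(cases$case_id)) {
    stop("duplicate case_id: ", cases$case_id[duplicated(cases$case_id)][1])
  }
  has_pt <- !is.na(cases$x) & !is.na(cases$y)
  any_pt <- !is.na(cases$x) | !is.na(cases$y)
  has_cand <- !is.na(cases$candidate_regions) & nzchar(cases$candidate_regions)
  has_coarse <- !is.na(cases$coarse_region) & nzchar(cases$coarse_region)
  ok <- (cases$precision == "exact" & has_pt & !has_cand & !has_coarse) |
    (cases$precision == "region_set" & !any_pt & has_cand & !has_coarse) |
    (cases$precision == "coarse" & !any_pt & !has_cand & has_coarse)
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop(sprintf("case %s: geocode fields inconsistent with precision '%s'",
                 cases$case_id[i], cases$precision[i]))
  }
  cases
}

#' Read case records from CSV
#'
#' Validates every row and logs the share of each geocode-precision class.
#'
#' @param path CSV file with a header row.
#' @return Validated case data.frame.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cases <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(case_id = "character",
                                          site = "character",
                                          behaviour = "character",
                                          sex = "character",  # "F" != FALSE
                                          age_group = "character",
                                          precision = "character",
                                          candidate_regions = "character",
                                          coarse_region = "character"))
  for (col in c("candidate_regions", "coarse_region")) {
    if (!col %in% names(cases)) cases[[col]] <- NA_character_
    cases[[col]][!is.na(cases[[col]]) & !nzchar(cases[[col]])] <- NA_character_
  }
  for (col in c("x", "y")) if (!col %in% names(cases)) cases[[col]] <- NA_real_
  cases <- validate_cases(cases)
  sh <- table(factor(cases$precision, .precisions)) / max(1L, nrow(cases))
  message(sprintf("read %d cases: %.1f%% exact, %.1f%% region_set, %.1f%% coarse",
                  nrow(cases), 100 * sh[["exact"]], 100 * sh[["region_set"]],
                  100 * sh[["coarse"]]))
  cases
}

#' Write case records to CSV
#' @param cases Validated case data.frame.
#' @param path Output path.
#' @export
write_cases <- function(cases, path) {
  utils::write.csv(validate_cases(cases), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Split semicolon-joined candidate-region strings
#' @param s Character vector as stored in \code{candidate_regions}.
#' @return List of character vectors.
#' @export
split_candidates <- function(s) strsplit(s, ";", fixed = TRUE)

empty_cases <- function(n = 0) {
  data.frame(case_id = character(n), site = character(n),
             behaviour = character(n), sex = character(n),
             age_group = character(n), year = integer(n),
             precision = character(n),
             x = rep(NA_real_, n), y = rep(NA_real_, n),
             candidate_regions = NA_character_[rep(1, n)],
             coarse_region = NA_character_[rep(1, n)],
             stringsAsFactors = FALSE)
}
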