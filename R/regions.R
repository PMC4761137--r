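#' Construct a region set
#'
#' A \code{region_set} holds one level of the nested study geography:
#' communities, fine census regions (which may change between census periods),
#' or coarse divisions. Geometry is planar, in a projected CRS with metre
#' units.
#'
#' @param level One of \code{"community"}, \code{"fine_census"},
#'   \code{"coarse_division"}.
#' @param table data.frame with columns \code{region_id}, \code{period_start},
#'   \code{period_end} (inclusive years), \code{inhabited_fraction} in (0, 1],
#'   and optionally parent ids (\code{community_id}, \code{coarse_id}).
#' @param polygons List of two-column vertex matrices, one per table row.
#' @param crs_label Free-text label of the projected CRS (metre units).
#' @return An object of class \code{region_set}.
#' @export
region_set <- function(level, table, polygons, crs_label = "local-metric") {
  level <- match.arg(level, c("community", "fine_census", "coarse_division"))
  stopifnot(is.data.frame(table), length(polygons) == nrow(table))
  req <- c("region_id", "period_start", "period_end", "inhabited_fraction")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("region table lacks column(s): ", paste(miss, collapse = ", "))
  }
  table$region_id <- as.character(table$region_id)
  key <- paste(table$region_id, table$period_start, table$period_end)
  if (anyDuplicated(key)) {
    stop("duplicate region_id within a period: ",
         table$region_id[duplicated(key)][1])
  }
  if (any(table$inhabited_fraction <= 0 | table$inhabited_fraction > 1)) {
    bad <- which(table$inhabited_fraction <= 0 | table$inhabited_fraction > 1)[1]
    stop("inhabited_fraction outside (0,1] for region ", table$region_id[bad])
  }
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 || anyNA(p)) {
      stop("invalid polygon for region ", table$region_id[i])
    }
    storage.mode(p) <- "double"
    if (!poly_is_simple(p)) {
      stop("self-intersecting polygon for region ", table$region_id[i])
    }
    polygons[[i]] <- poly_ccw(unname(p))
  }
  structure(list(level = level, table = table, polygons = polygons,
                 crs_label = crs_label),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set (%s): %d regions, CRS '%s'\n",
              x$level, nrow(x$table), x$crs_label))
  invisible(x)
}

#' Number of regions in a region set
#' @param rs A \code{region_set}.
#' @export
n_regions <- function(rs) nrow(rs$table)

#' Read a region set from GeoJSON
#'
#' Features must be Polygon geometries carrying \code{region_id},
#' \code{period_start}, \code{period_end} and \code{inhabited_fraction}
#' properties. Coordinates are taken to be already in the projected metric
#' CRS named by the file's \code{crs_label} member (geodetic input is out of
#' scope).
#'
#' @param path GeoJSON file path.
#' @param level Region level, see \code{\link{region_set}}.
#' @return A \code{region_set}.
#' @export
read_regions <- function(path, level) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  rows <- vector("list", length(feats))
  polys <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    pr <- f$properties
    for (nm in c("region_id", "period_start", "period_end", "inhabited_fraction")) {
      if (is.null(pr[[nm]])) {
        stop(sprintf("feature %d is missing property '%s'", i, nm))
      }
    }
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon")) {
      stop("feature ", i, " (", pr$region_id, "): geometry must be Polygon")
    }
    ring <- f$geometry$coordinates[[1]]
    p <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    # drop the closing vertex GeoJSON requires
    if (nrow(p) > 1 && all(abs(p[1, ] - p[nrow(p), ]) < 1e-9)) {
      p <- p[-nrow(p), , drop = FALSE]
    }
    polys[[i]] <- p
    keep <- pr[setdiff(names(pr), character(0))]
    rows[[i]] <- as.data.frame(keep, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  region_set(level, tab, polys,
             crs_label = if (!is.null(gj$crs_label)) gj$crs_label else "local-metric")
}

#' Write a region set to GeoJSON
#'
#' Inverse of \code{\link{read_regions}}: properties and vertices round-trip
#' (vertices to better than 1e-6 m).
#'
#' @param rs A \code{region_set}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_regions <- function(rs, path) {
  feats <- lapply(seq_len(nrow(rs$table)), function(i) {
    p <- rs$polygons[[i]]
    ring <- lapply(seq_len(nrow(p) + 1), function(k) {
      v <- p[if (k > nrow(p)) 1 else k, ]
      c(round(v[1], 7), round(v[2], 7))
    })
    props <- as.list(rs$table[i, , drop = FALSE])
    props <- lapply(props, function(z) if (is.factor(z)) as.character(z) else z)
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection", crs_label = rs$crs_label,
              features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Queen-contiguity adjacency between regions
#'
#' Two regions are neighbours when their boundaries come within \code{tol}
#' metres of one another (shared edges and shared corner points both count,
#' i.e. queen contiguity). Islands -- regions with no neighbour -- trigger a
#' warning.
#'
#' @param rs A \code{region_set} (one period's tessellation).
#' @param tol Snap tolerance in metres.
#' @return Named list: for each region_id, a character vector of neighbouring
#'   region_ids. Symmetric, no self-neighbours.
#' @export
build_adjacency <- function(rs, tol = 1e-3) {
  n <- nrow(rs$table)
  ids <- rs$table$region_id
  bbs <- t(vapply(rs$polygons, poly_bbox, numeric(4)))
  nb <- rep(list(character(0)), n)
  names(nb) <- ids
  for (i in seq_len(n - 1)) {
    # bbox prefilter with tolerance
    cand <- which(bbs[(i + 1):n, 1] <= bbs[i, 3] + tol &
                    bbs[(i + 1):n, 3] >= bbs[i, 1] - tol &
                    bbs[(i + 1):n, 2] <= bbs[i, 4] + tol &
                    bbs[(i + 1):n, 4] >= bbs[i, 2] - tol) + i
    for (j in cand) {
      if (poly_boundary_dist(rs$polygons[[i]], rs$polygons[[j]]) <= tol) {
        nb[[i]] <- c(nb[[i]], ids[j])
        nb[[j]] <- c(nb[[j]], ids[i])
      }
    }
  }
  deg0 <- ids[vapply(nb, length, 0L) == 0]
  if (length(deg0)) {
    warning("region(s) with no neighbours (islands): ",
            paste(deg0, collapse = ", "))
  }
  nb
}
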