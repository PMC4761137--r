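# Gridded surfaces. `values` is a matrix with one row per grid cell
# (row-major linear index) and one column per band (census period for
# offsets, index year for spatio-temporal fits, single column otherwise).

new_surface <- function(class, grid, values, bands = NULL, ...) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  stopifnot(nrow(values) == grid$nx * grid$ny)
  if (is.null(bands)) bands <- paste0("band", seq_len(ncol(values)))
  colnames(values) <- as.character(bands)
  structure(c(list(grid = grid, values = values, bands = bands), list(...)),
            class = c(class, "riskmap_surface"))
}

#' Construct an expected-case (offset) surface
#'
#' Holds the gridded expected-case density rho(s, t): expected cases per
#' square metre per band under the reference rates.
#'
#' @param grid A \code{grid_spec}.
#' @param values Matrix, cells x periods, non-negative density.
#' @param periods data.frame with columns \code{start}, \code{end}
#'   (inclusive years), one row per column of \code{values}.
#' @return An \code{offset_surface}.
#' @export
offset_surface <- function(grid, values, periods) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  stopifnot(nrow(periods) == ncol(values))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("offset density must be finite and non-negative")
  }
  new_surface("offset_surface", grid, values,
              bands = paste(periods$start, periods$end, sep = "-"),
              periods = periods)
}

#' Construct a relative-risk surface
#'
#' @param grid A \code{grid_spec}.
#' @param values Matrix, cells x bands; finite and >= 0.
#' @param years Optional integer vector of index years (one per band).
#' @param h_km Spatial kernel sd used, km.
#' @param tau_years Optional temporal kernel sd, years.
#' @param ... Further fields (iterations, converged, ...).
#' @return A \code{risk_surface}.
#' @export
risk_surface <- function(grid, values, years = NULL, h_km = NA_real_,
                         tau_years = NULL, ...) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("risk values must be finite and non-negative")
  }
  new_surface("risk_surface", grid, values,
              bands = if (is.null(years)) NULL else years,
              years = years, h_km = h_km, tau_years = tau_years, ...)
}

#' Construct an exceedance-probability surface
#'
#' @param grid A \code{grid_spec}.
#' @param values Matrix, cells x bands, probabilities in [0, 1].
#' @param years Optional index years.
#' @param threshold Relative-risk threshold (default 1.1).
#' @param B Bootstrap replicates used.
#' @return An \code{exceedance_surface}.
#' @export
exceedance_surface <- function(grid, values, years = NULL, threshold = 1.1,
                               B = NA_integer_) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  vals <- values[is.finite(values)]
  if (any(vals < 0 | vals > 1)) {
    stop("exceedance probabilities must lie in [0, 1]")
  }
  new_surface("exceedance_surface", grid, values,
              bands = if (is.null(years)) NULL else years,
              years = years, threshold = threshold, B = B)
}

#' @export
print.riskmap_surface <- function(x, ...) {
  cat(sprintf("%s: %d x %d grid, %d band(s)\n", class(x)[1],
              x$grid$nx, x$grid$ny, ncol(x$values)))
  invisible(x)
}

#' Write a surface to disk
#'
#' Two formats, chosen by extension. \code{.asc} writes one ESRI ASCII grid
#' per band (band tag inserted before the extension when there are several)
#' at full double precision, plus a JSON sidecar with CRS, band labels and
#' surface metadata -- this path round-trips losslessly. \code{.tif} writes a
#' (multi-page) 32-bit float TIFF via the tiff package with an ESRI world
#' file; values are stored in single precision.
#'
#' @param surface A \code{risk_surface}, \code{exceedance_surface} or
#'   \code{offset_surface}.
#' @param path Output path ending in \code{.asc} or \code{.tif}.
#' @return Character vector of files written, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "riskmap_surface"))
  if (inherits(surface, "exceedance_surface")) {
    vals <- surface$values[is.finite(surface$values)]
    if (any(vals < 0 | vals > 1)) stop("exceedance probabilities must lie in [0, 1]")
  }
  ext <- tolower(tools::file_ext(path))
  g <- surface$grid
  nb <- ncol(surface$values)
  meta <- list(class = class(surface)[1],
               crs_label = if (!is.null(surface$crs_label)) surface$crs_label else "local-metric",
               bands = as.character(surface$bands),
               grid = list(x0 = g$x0, y0 = g$y0, cell_m = g$cell_m,
                           nx = g$nx, ny = g$ny),
               h_km = surface$h_km, tau_years = surface$tau_years,
               threshold = surface$threshold, B = surface$B)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null",
                              digits = NA), sidecar)
  if (ext == "asc") {
    files <- character(nb)
    for (b in seq_len(nb)) {
      f <- if (nb == 1) path else {
        paste0(tools::file_path_sans_ext(path), "_",
               gsub("[^A-Za-z0-9-]", "", surface$bands[b]), ".asc")
      }
      m <- field_matrix(g, surface$values[, b])
      con <- file(f, "w")
      writeLines(c(paste("ncols", g$nx), paste("nrows", g$ny),
                   sprintf("xllcorner %.10f", g$x0),
                   sprintf("yllcorner %.10f", g$y0),
                   sprintf("cellsize %.10f", g$cell_m),
                   "NODATA_value -9999"), con)
      # ASCII grids run top row first
      for (j in rev(seq_len(g$ny))) {
        v <- m[, j]
        v[!is.finite(v)] <- -9999
        writeLines(paste(sprintf("%.17g", v), collapse = " "), con)
      }
      close(con)
      files[b] <- f
    }
    invisible(c(files, sidecar))
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("writing .tif requires the 'tiff' package; use .asc instead")
    }
    pages <- lapply(seq_len(nb), function(b) {
      m <- t(field_matrix(g, surface$values[, b]))  # rows = y, top first
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    })
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 32),
                   error = function(e) stop("I/O error writing ", path, ": ",
                                            conditionMessage(e)))
    tfw <- paste0(tools::file_path_sans_ext(path), ".tfw")
    writeLines(sprintf("%.10f", c(g$cell_m, 0, 0, -g$cell_m,
                                  g$x0 + g$cell_m / 2,
                                  g$y0 + (g$ny - 0.5) * g$cell_m)), tfw)
    invisible(c(path, tfw, sidecar))
  } else {
    stop("unsupported surface format: .", ext)
  }
}

#' Read a surface written by \code{\link{write_surface}}
#'
#' @param path Path passed to \code{write_surface} (the \code{.asc}/\code{.tif}
#'   path; multi-band ASCII sets are located through the JSON sidecar).
#' @return Surface object of the class recorded in the sidecar.
#' @export
read_surface <- function(path) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) stop("missing surface sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  g <- grid_spec(meta$grid$x0, meta$grid$y0, meta$grid$cell_m,
                 meta$grid$nx, meta$grid$ny)
  nb <- length(meta$bands)
  ext <- tolower(tools::file_ext(path))
  vals <- matrix(NA_real_, g$nx * g$ny, nb)
  if (ext == "asc") {
    for (b in seq_len(nb)) {
      f <- if (nb == 1) path else {
        paste0(tools::file_path_sans_ext(path), "_",
               gsub("[^A-Za-z0-9-]", "", meta$bands[b]), ".asc")
      }
      lines <- readLines(f)
      rows <- lapply(lines[-(1:6)], function(l) scan(text = l, quiet = TRUE))
      m <- matrix(0, g$nx, g$ny)
      for (j in seq_len(g$ny)) m[, g$ny - j + 1] <- rows[[j]]
      m[m == -9999] <- NA_real_
      vals[, b] <- field_vector(m)
    }
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    for (b in seq_len(nb)) {
      m <- pages[[b]][rev(seq_len(nrow(pages[[b]]))), , drop = FALSE]
      vals[, b] <- field_vector(t(m))
    }
  } else stop("unsupported surface format: .", ext)
  years <- suppressWarnings(as.integer(meta$bands))
  if (anyNA(years)) years <- NULL
  switch(meta$class,
         risk_surface = risk_surface(g, vals, years = years, h_km = meta$h_km,
                                     tau_years = meta$tau_years),
         exceedance_surface = exceedance_surface(g, vals, years = years,
                                                 threshold = meta$threshold,
                                                 B = meta$B),
         offset_surface = {
           pr <- do.call(rbind, strsplit(as.character(meta$bands), "-"))
           offset_surface(g, vals, data.frame(start = as.integer(pr[, 1]),
                                              end = as.integer(pr[, 2])))
         },
         stop("unknown surface class in sidecar: ", meta$class))
}
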