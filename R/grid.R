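#' Define a regular analysis grid
#'
#' A grid of square cells in a projected coordinate system with metre units.
#' Cell \code{(i, j)} (column \code{i} in x, row \code{j} in y, both 1-based)
#' has its center at \code{(x0 + (i - 1/2) * cell_m, y0 + (j - 1/2) * cell_m)}.
#' The row-major linear index is \code{(j - 1) * nx + i}.
#'
#' @param x0,y0 Coordinates of the lower-left corner of the grid, in metres.
#' @param cell_m Cell side length in metres (> 0).
#' @param nx,ny Number of cells along x and y (both >= 2).
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(x0, y0, cell_m, nx, ny) {
  stopifnot(is.numeric(cell_m), cell_m > 0, nx >= 2, ny >= 2)
  structure(list(x0 = x0, y0 = y0, cell_m = cell_m,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.0f m, origin (%.0f, %.0f)\n",
              x$nx, x$ny, x$cell_m, x$x0, x$y0))
  invisible(x)
}

#' Cell-center coordinates of every grid cell
#'
#' @param grid A \code{grid_spec}.
#' @return A two-column matrix (x, y), rows in row-major linear-index order.
#' @export
grid_centers <- function(grid) {
  cx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell_m
  cy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell_m
  cbind(x = rep(cx, times = grid$ny), y = rep(cy, each = grid$nx))
}

#' Map points to grid cells
#'
#' Points exactly on a cell boundary belong to the cell with the smaller
#' linear index; points outside the grid get NA.
#'
#' @param grid A \code{grid_spec}.
#' @param x,y Point coordinates in metres.
#' @return Integer vector of row-major linear cell indices.
#' @export
cell_index <- function(grid, x, y) {
  ix <- ceiling((x - grid$x0) / grid$cell_m)
  iy <- ceiling((y - grid$y0) / grid$cell_m)
  # left/bottom edge of the grid itself still belongs to the first cell
  ix[x == grid$x0] <- 1L
  iy[y == grid$y0] <- 1L
  bad <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
  idx <- (iy - 1L) * grid$nx + ix
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Area of one grid cell in square metres
#' @param grid A \code{grid_spec}.
#' @export
cell_area <- function(grid) grid$cell_m^2

# field vector (linear index order) <-> nx x ny matrix (x runs along rows)
field_matrix <- function(grid, v) matrix(v, nrow = grid$nx, ncol = grid$ny)
field_vector <- function(m) as.vector(m)

#' Rasterize a region set onto a grid by cell-center containment
#'
#' Each grid cell is assigned to the first region (in table order) whose
#' polygon contains the cell center. Cells contained in no region get NA.
#'
#' @param regions A \code{region_set}.
#' @param grid A \code{grid_spec}.
#' @return Integer vector over cells: row number (in \code{regions$table}) of
#'   the containing region, NA outside.
#' @export
rasterize_regions <- function(regions, grid) {
  centers <- grid_centers(grid)
  n_cells <- nrow(centers)
  assign <- rep(NA_integer_, n_cells)
  tab <- regions$table
  for (r in seq_len(nrow(tab))) {
    poly <- regions$polygons[[r]]
    bb <- poly_bbox(poly)
    cand <- which(is.na(assign) &
                    centers[, 1] >= bb[1] & centers[, 1] <= bb[3] &
                    centers[, 2] >= bb[2] & centers[, 2] <= bb[4])
    if (!length(cand)) next
    inside <- point_in_poly(poly, centers[cand, , drop = FALSE])
    assign[cand[inside]] <- r
  }
  assign
}
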