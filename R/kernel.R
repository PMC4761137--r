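# Gaussian kernel smoothing on the analysis grid, with a symmetric
# renormalization (Sinkhorn balancing) edge correction inside the study
# region. The resulting operator is symmetric and doubly stochastic over
# the region's cells, so smoothing preserves both the total mass of any
# field (sum out = sum in, to the balancing tolerance) and constant fields
# exactly -- the two properties the local-EM estimator relies on.

#' Specify a smoothing kernel
#'
#' @param h_km Spatial standard deviation of the Gaussian kernel, km.
#' @param tau_years Optional temporal standard deviation, years.
#' @param truncation Truncation radius in standard deviations (default 4).
#' @return A \code{kernel_spec}.
#' @export
kernel_spec <- function(h_km, tau_years = NULL, truncation = 4) {
  stopifnot(h_km > 0, is.null(tau_years) || tau_years > 0, truncation > 0)
  structure(list(h_km = h_km, tau_years = tau_years, truncation = truncation),
            class = "kernel_spec")
}

# 1-D Gaussian kernel matrix over coordinates, truncated at `trunc` sds
gauss_kernel_matrix <- function(coords, sd, trunc) {
  d <- abs(outer(coords, coords, "-"))
  k <- exp(-d^2 / (2 * sd^2))
  k[d > trunc * sd] <- 0
  k
}

#' Build a smoothing operator for a grid and study-region mask
#'
#' Precomputes the truncated separable Gaussian kernel and the symmetric
#' Sinkhorn balancing weights over the masked cells. The returned object is
#' reusable across many \code{\link{apply_smoother}} calls (the expensive
#' part of repeated local-EM fits).
#'
#' @param grid A \code{grid_spec}.
#' @param kernel A \code{kernel_spec}.
#' @param mask Logical vector over cells (TRUE = inside the study region);
#'   default all cells.
#' @return A \code{smoother} object.
#' @export
make_smoother <- function(grid, kernel, mask = NULL) {
  stopifnot(inherits(kernel, "kernel_spec"))
  h_m <- kernel$h_km * 1000
  if (h_m < grid$cell_m / 2) {
    warning(sprintf(paste0("bandwidth %.2f km is below half a grid cell ",
                           "(%.2f km); expect undersmoothing artifacts"),
                    kernel$h_km, grid$cell_m / 1000))
  }
  if (is.null(mask)) mask <- rep(TRUE, grid$nx * grid$ny)
  stopifnot(length(mask) == grid$nx * grid$ny, any(mask))
  cx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell_m
  cy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell_m
  kx <- gauss_kernel_matrix(cx, h_m, kernel$truncation)
  ky <- gauss_kernel_matrix(cy, h_m, kernel$truncation)
  mmat <- field_matrix(grid, as.numeric(mask))
  apply_raw <- function(fm) kx %*% fm %*% t(ky)
  # symmetric Sinkhorn balancing: find d > 0 on the mask with
  # d * K(d) = 1, making diag(d) K diag(d) doubly stochastic there
  d <- mmat
  row_mass <- apply_raw(mmat)
  d[mmat > 0] <- 1 / sqrt(row_mass[mmat > 0])
  for (it in 1:500) {
    kd <- apply_raw(d)
    resid <- abs(d * kd - 1)[mmat > 0]
    if (max(resid) < 1e-13) break
    d[mmat > 0] <- sqrt(d[mmat > 0] / kd[mmat > 0])
  }
  structure(list(grid = grid, kernel = kernel, mask = mask,
                 kx = kx, ky = ky, d = d, balance_resid = max(resid)),
            class = "smoother")
}

#' Apply a smoothing operator to a field
#'
#' @param sm A \code{smoother} from \code{\link{make_smoother}}.
#' @param field Numeric vector over grid cells (values outside the mask are
#'   ignored) or a matrix with one column per band.
#' @return Smoothed field of the same shape; zero outside the mask.
#' @export
apply_smoother <- function(sm, field) {
  one <- function(v) {
    fm <- field_matrix(sm$grid, ifelse(sm$mask, v, 0)) * sm$d
    out <- (sm$kx %*% fm %*% t(sm$ky)) * sm$d
    field_vector(out)
  }
  if (is.matrix(field)) apply(field, 2, one) else one(field)
}

#' Smooth a gridded field with an edge-corrected Gaussian kernel
#'
#' One-shot convenience wrapper around \code{\link{make_smoother}} /
#' \code{\link{apply_smoother}}. Mass-preserving over the mask and exact on
#' constant fields (symmetric doubly stochastic edge correction).
#'
#' @param field Numeric vector over grid cells.
#' @param grid A \code{grid_spec}.
#' @param kernel A \code{kernel_spec}.
#' @param mask Optional logical study-region mask.
#' @return Smoothed field.
#' @export
smooth_field <- function(field, grid, kernel, mask = NULL) {
  if (any(!is.finite(field[if (is.null(mask)) TRUE else mask]))) {
    stop("field must be finite")
  }
  apply_smoother(make_smoother(grid, kernel, mask), field)
}

# Temporal smoother over a vector of years: symmetric doubly stochastic
# (Sinkhorn-balanced truncated Gaussian), i.e. renormalized over the
# observed year range. Returns the T x T matrix.
time_smoother_matrix <- function(years, tau_years, truncation = 4) {
  k <- gauss_kernel_matrix(as.numeric(years), tau_years, truncation)
  d <- 1 / sqrt(rowSums(k))
  for (it in 1:500) {
    kd <- as.numeric(k %*% d)
    if (max(abs(d * kd - 1)) < 1e-13) break
    d <- sqrt(d / kd)
  }
  k * outer(d, d)
}
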