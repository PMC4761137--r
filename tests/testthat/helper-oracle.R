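# Independent brute-force implementations used as oracles. These share only
# the published definitions with the package (truncated Gaussian kernel,
# symmetric balancing, E/M steps) and are written as plain loops over cells
# without any of the package's operator machinery.

# dense kernel matrix over all cells of a grid, by explicit double loop
brute_kernel_matrix <- function(grid, h_m, trunc = 4) {
  centers <- grid_centers(grid)
  n <- nrow(centers)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dx <- abs(centers[i, 1] - centers[j, 1])
      dy <- abs(centers[i, 2] - centers[j, 2])
      if (dx <= trunc * h_m && dy <= trunc * h_m) {
        K[i, j] <- exp(-(dx^2 + dy^2) / (2 * h_m^2))
      }
    }
  }
  K
}

# symmetric doubly stochastic balancing + application, by plain iteration
brute_smoother <- function(K, mask) {
  Km <- K[mask, mask, drop = FALSE]
  d <- rep(1, nrow(Km)) / sqrt(as.numeric(Km %*% rep(1, nrow(Km))))
  for (it in 1:1000) {
    kd <- as.numeric(Km %*% d)
    if (max(abs(d * kd - 1)) < 1e-13) break
    d <- sqrt(d / kd)
  }
  function(f) {
    out <- numeric(length(mask))
    out[mask] <- d * as.numeric(Km %*% (d * f[mask]))
    out
  }
}

# brute-force local-EM: cases given as a list of integer cell-index vectors
# (length-1 = exact); e_cells = expected counts per cell
brute_localem <- function(grid, h_m, e_cells, case_cells, mask = NULL,
                          tol = 1e-10, max_iter = 500) {
  if (is.null(mask)) mask <- rep(TRUE, length(e_cells))
  S <- brute_smoother(brute_kernel_matrix(grid, h_m), mask)
  den <- S(e_cells)
  n <- length(case_cells)
  lam <- as.numeric(mask)
  for (it in seq_len(max_iter)) {
    w <- numeric(length(e_cells))
    for (cc in case_cells) {
      wt <- lam[cc] * e_cells[cc]
      if (sum(wt) <= 0) wt <- e_cells[cc]
      w[cc] <- w[cc] + wt / sum(wt)
    }
    num <- S(w)
    lam_new <- ifelse(den > 0, num / den, 0)
    tot <- sum(lam_new * e_cells)
    if (n > 0 && tot > 0) lam_new <- lam_new * n / tot
    delta <- max(abs(lam_new - lam) / pmax(lam, 1e-8))
    lam <- lam_new
    if (delta < tol) break
  }
  lam
}
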