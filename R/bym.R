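# Community-level Besag-York-Mollie spatial autoregression.

#' Fit the BYM model by MCMC
#'
#' Poisson counts with log-relative-risk decomposed into an intercept,
#' covariate effects, a spatially structured ICAR effect S and an
#' unstructured effect V:
#' \deqn{Y_i \sim Poisson(E_i \lambda_i), \quad
#'       \log \lambda_i = \mu + X_i \beta + S_i + V_i.}
#' S carries a per-component sum-to-zero constraint; islands have S_i = 0
#' and rely on V. Priors are weakly informative: Normal(0, 10^2) on mu and
#' beta, half-Normal(0, 1) on both standard deviations. Inference is
#' Metropolis-within-Gibbs with slice updates for the variance parameters
#' and proposal-scale adaptation during burn-in.
#'
#' @param data data.frame with columns \code{community_id}, \code{Y},
#'   \code{E} (> 0) and optionally covariate columns; typically from
#'   \code{\link{community_data}}.
#' @param covariate_cols Character vector naming covariate columns in
#'   \code{data} (default: the deprivation/well-water trio when present).
#' @param neighbours Named list of neighbour id vectors (defaults to
#'   \code{attr(data, "neighbours")}).
#' @param priors List: \code{mu_sd}, \code{beta_sd}, \code{sigma_sd},
#'   optional \code{sigma_s_fixed} / \code{sigma_v_fixed} to hold a standard
#'   deviation at a constant value.
#' @param mcmc List: \code{n_iter} (20000), \code{burn_in} (5000),
#'   \code{thin} (5), \code{seed}.
#' @return A \code{bym_posterior}: thinned draws, summary table
#'   (mean / 2.5\% / 97.5\% for mu, beta, sigma_S, sigma_V), acceptance
#'   rates and effective sample sizes. Warns (does not fail) when the ESS of
#'   either standard deviation falls below 100.
#' @export
fit_bym <- function(data, covariate_cols = NULL, neighbours = NULL,
                    priors = list(), mcmc = list()) {
  stopifnot(all(c("community_id", "Y", "E") %in% names(data)))
  if (any(data$E <= 0)) stop("all expected counts must be positive")
  if (any(data$Y < 0 | data$Y != round(data$Y))) {
    stop("observed counts must be non-negative integers")
  }
  if (is.null(neighbours)) neighbours <- attr(data, "neighbours")
  if (is.null(neighbours)) stop("no neighbour structure supplied")
  if (is.null(covariate_cols)) {
    covariate_cols <- intersect(c("well_water_pct", "material", "social"),
                                names(data))
  }
  pri <- utils::modifyList(list(mu_sd = 10, beta_sd = 10, sigma_sd = 1,
                                sigma_s_fixed = NA, sigma_v_fixed = NA),
                           priors)
  mc <- utils::modifyList(list(n_iter = 20000L, burn_in = 5000L, thin = 5L,
                               seed = 1L), mcmc)

  ids <- data$community_id
  nb_idx <- lapply(neighbours[ids], function(v) match(v, ids))
  if (any(vapply(nb_idx, anyNA, TRUE))) {
    stop("neighbour lists reference unknown community ids")
  }
  sym <- vapply(seq_along(nb_idx), function(i) {
    all(vapply(nb_idx[[i]], function(j) i %in% nb_idx[[j]], TRUE))
  }, TRUE)
  if (!all(sym)) stop("neighbour relation is not symmetric")
  comp <- graph_components(nb_idx)

  X <- if (length(covariate_cols)) {
    as.matrix(data[, covariate_cols, drop = FALSE])
  } else matrix(numeric(0), nrow(data), 0)
  adj <- unlist(lapply(nb_idx, function(v) v - 1L))
  if (is.null(adj)) adj <- integer(0)
  adj_start <- c(0L, cumsum(vapply(nb_idx, length, 0L)))

  set.seed(mc$seed)
  init_mu <- log(max(sum(data$Y) / sum(data$E), 1e-6))
  draws <- .bym_mcmc_cpp(
    as.integer(data$Y), log(data$E), X,
    as.integer(adj), as.integer(adj_start), as.integer(comp),
    as.integer(mc$n_iter), as.integer(mc$burn_in), as.integer(mc$thin),
    pri$mu_sd, pri$beta_sd, pri$sigma_sd,
    ifelse(is.na(pri$sigma_s_fixed), -1, pri$sigma_s_fixed),
    ifelse(is.na(pri$sigma_v_fixed), -1, pri$sigma_v_fixed),
    init_mu, rep(0, ncol(X)))

  colnames(draws$beta) <- covariate_cols
  colnames(draws$S) <- ids
  colnames(draws$V) <- ids
  ess <- c(sigma_S = ess_batch(draws$sigma_S),
           sigma_V = ess_batch(draws$sigma_V))
  if (any(is.na(pri[c("sigma_s_fixed", "sigma_v_fixed")])) &&
      any(ess < 100, na.rm = TRUE)) {
    warning("low effective sample size on a variance parameter (",
            paste(sprintf("%s=%.0f", names(ess), ess), collapse = ", "),
            "); consider longer chains")
  }
  params <- cbind(mu = draws$mu, draws$beta,
                  sigma_S = draws$sigma_S, sigma_V = draws$sigma_V)
  summ <- t(apply(params, 2, function(v) {
    c(mean = mean(v), stats::quantile(v, c(0.025, 0.975)))
  }))
  colnames(summ) <- c("mean", "q2.5", "q97.5")
  structure(list(community_id = ids, draws = draws, summary = summ,
                 covariate_cols = covariate_cols, ess = ess,
                 acc_rates = draws$acc_rates, mcmc = mc, priors = pri),
            class = "bym_posterior")
}

#' @export
print.bym_posterior <- function(x, ...) {
  cat(sprintf("bym_posterior: %d communities, %d retained draws\n",
              length(x$community_id), length(x$draws$mu)))
  print(round(x$summary, 4))
  invisible(x)
}

# connected components of the adjacency graph; islands get -1
graph_components <- function(nb_idx) {
  n <- length(nb_idx)
  comp <- rep(-1L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] >= 0 || length(nb_idx[[s]]) == 0) next
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      i <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (j in nb_idx[[i]]) {
        if (comp[j] < 0 && length(nb_idx[[j]]) > 0) {
          comp[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
    cur <- cur + 1L
  }
  comp
}

# effective sample size by the batch-means method
ess_batch <- function(v) {
  n <- length(v)
  if (n < 40 || stats::sd(v) == 0) return(NA_real_)
  b <- max(10L, floor(sqrt(n)))
  nb <- floor(n / b)
  bm <- vapply(seq_len(nb), function(k) mean(v[((k - 1) * b + 1):(k * b)]), 0)
  var_mean <- stats::var(bm) / nb
  if (var_mean <= 0) return(NA_real_)
  min(n, stats::var(v) / var_mean / 1)
}

#' Posterior relative risks E[exp(U_i) | data]
#'
#' Mean over draws of exp(S_i + V_i): the ratio between each community's
#' risk and the risk typical for its covariates.
#'
#' @param post A \code{bym_posterior}.
#' @return Named numeric vector, one value per community.
#' @export
posterior_relative_risk <- function(post) {
  stopifnot(inherits(post, "bym_posterior"))
  colMeans(exp(post$draws$S + post$draws$V))
}

#' Posterior exceedance probabilities P_i(10\%)
#'
#' Fraction of posterior draws with exp(S_i + V_i) above \code{threshold}
#' (default 1.1, i.e. risk at least 10\% above what is typical given the
#' community's covariates). Reported alongside the 0.8 / 0.95 bands used
#' for mapping.
#'
#' @param post A \code{bym_posterior}.
#' @param threshold Relative-risk threshold, > 0.
#' @return data.frame (community_id, prob, band) where band is one of
#'   \code{"<0.8"}, \code{">0.8"}, \code{">0.95"}.
#' @export
exceedance_prob <- function(post, threshold = 1.1) {
  stopifnot(inherits(post, "bym_posterior"))
  if (threshold <= 0) stop("threshold must be positive")
  pr <- colMeans(exp(post$draws$S + post$draws$V) > threshold)
  data.frame(community_id = post$community_id, prob = unname(pr),
             band = cut(unname(pr), c(-Inf, 0.8, 0.95, Inf),
                        labels = c("<0.8", ">0.8", ">0.95")),
             stringsAsFactors = FALSE)
}
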