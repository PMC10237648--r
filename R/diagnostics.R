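#' Effective sample size
#'
#' Autocorrelation-based ESS with Geyer's initial monotone positive sequence
#' truncation: the number of i.i.d. draws an autocorrelated chain is worth.
#'
#' @param x numeric vector of (post-warmup) draws.
#' @return The ESS; `NA` for a constant chain (undefined, not an error).
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) return(NA_real_)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 2L, 10000L), plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  # Geyer: sum consecutive-pair autocorrelations while positive and monotone
  max_pairs <- floor((length(ac) - 1L) / 2L)
  pair <- numeric(max_pairs)
  tau <- 1
  running_min <- Inf
  for (m in seq_len(max_pairs)) {
    g <- ac[2L * m] + ac[2L * m + 1L]
    if (g <= 0) break
    running_min <- min(running_min, g)
    tau <- tau + 2 * running_min
  }
  max(n / tau, 1e-12)
}

#' Minimum ESS across the dimensions of a chain
#'
#' @param chain a `chain_result` or a draws matrix.
#' @param dims optional subset of column names/indices.
#' @return Named vector of ESS values for `ess_per_dim`; scalar minimum for
#'   `min_ess`.
#' @export
ess_per_dim <- function(chain, dims = NULL) {
  draws <- if (inherits(chain, "chain_result")) posterior_draws(chain)
           else as.matrix(chain)
  if (!is.null(dims)) draws <- draws[, dims, drop = FALSE]
  apply(draws, 2L, effective_sample_size)
}

#' @rdname ess_per_dim
#' @export
min_ess <- function(chain, dims = NULL) {
  e <- ess_per_dim(chain, dims)
  if (all(is.na(e))) NA_real_ else min(e, na.rm = TRUE)
}

#' Rank-normalised split R-hat
#'
#' Potential scale reduction computed on rank-normalised draws after
#' splitting each chain in half; values near 1 indicate convergence.
#'
#' @param chains list of numeric vectors (one per chain, equal length), or a
#'   matrix with one column per chain.
#' @return The split R-hat.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2L)
  chains <- lapply(chains, as.numeric)
  if (length(chains) < 2L) stop("R-hat needs at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal lengths")
  half <- floor(n / 2L)
  splits <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[seq.int(n - half + 1L, n)])), recursive = FALSE)
  pooled <- unlist(splits)
  r <- rank(pooled, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(pooled) + 1 / 4))
  zs <- split(z, rep(seq_along(splits), each = half))
  m <- length(zs)
  means <- vapply(zs, mean, numeric(1L))
  vars <- vapply(zs, stats::var, numeric(1L))
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(if (b == 0) 1 else Inf)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Posterior-averaged population density on a grid
#'
#' The pointwise average over (thinned) posterior draws of theta of the
#' population density `p(psi | theta)`, i.e. an estimate of
#' `E_{theta|D}[p(psi|theta)]`, evaluated over the free psi dimensions.
#'
#' @param theta_draws matrix of posterior draws with named theta columns
#'   (free columns suffice; fixed entries are taken from `theta_fill`).
#' @param pop a [population_model()].
#' @param grid matrix with one column per free psi dimension.
#' @param theta_fill named vector supplying any theta entries absent from
#'   `theta_draws` (e.g. fixed parameters).
#' @param covariate_levels,covariate_weights covariate mixture, as in
#'   [population_density()].
#' @param thin keep every `thin`-th draw.
#' @return Vector of averaged densities over the grid rows.
#' @export
posterior_mean_density <- function(theta_draws, pop, grid,
                                   theta_fill = NULL,
                                   covariate_levels = 0,
                                   covariate_weights = 1, thin = 1L) {
  theta_draws <- as.matrix(theta_draws)
  rows <- seq(1L, nrow(theta_draws), by = thin)
  dens <- 0
  for (r in rows) {
    theta <- theta_draws[r, ]
    if (!is.null(theta_fill))
      theta <- c(theta, theta_fill[setdiff(names(theta_fill), names(theta))])
    dens <- dens + population_density(pop, theta, grid,
                                      covariate_levels, covariate_weights)
  }
  dens / length(rows)
}

#' KL divergence from the data-generating population distribution
#'
#' `KL(p_true || E_{theta|D}[p(psi|theta)])` by quadrature over a regular
#' grid covering the bulk of the true population mass. The grid is built
#' from the true distribution's component quantiles (width `q_span` each
#' side); coverage of the true mass on the grid is reported and a warning
#' raised when it falls below 99.9%.
#'
#' @param theta_true named data-generating parameter vector.
#' @param theta_draws posterior draws of theta (named columns).
#' @param pop a [population_model()].
#' @param covariate_levels,covariate_weights covariate mixture for both
#'   densities (e.g. `0:1` with equal weights for the bimodal model).
#' @param n_grid grid points per free dimension.
#' @param q_span number of component standard deviations each side.
#' @param theta_fill fixed theta entries missing from the draws.
#' @param thin thinning applied to the posterior draws.
#' @return List with `kl`, `coverage` (true mass on the grid) and the grid
#'   axes.
#' @export
kl_population <- function(theta_true, theta_draws, pop,
                          covariate_levels = 0, covariate_weights = 1,
                          n_grid = 80L, q_span = 6, theta_fill = NULL,
                          thin = 1L) {
  free <- pop$psi_free
  axes <- lapply(seq_along(pop$components), function(k) {
    cmp <- pop$components[[k]]
    if (cmp$type == "pointmass") return(NULL)
    if (cmp$type == "lognormal") {
      m <- theta_true[[cmp$meanlog]]; s <- theta_true[[cmp$sdlog]]
      return(seq(exp(m - q_span * s), exp(m + q_span * s),
                 length.out = n_grid))
    }
    ms <- lapply(covariate_levels, function(chi)
      component_mean_sd(cmp, theta_true, chi))
    lo <- min(vapply(ms, function(z) z$mean - q_span * z$sd, numeric(1L)))
    hi <- max(vapply(ms, function(z) z$mean + q_span * z$sd, numeric(1L)))
    seq(lo, hi, length.out = n_grid)
  })
  axes <- axes[!vapply(axes, is.null, logical(1L))]
  names(axes) <- free
  grid <- as.matrix(expand.grid(axes))
  cell <- prod(vapply(axes, function(a) a[2L] - a[1L], numeric(1L)))

  p_true <- population_density(pop, theta_true, grid,
                               covariate_levels, covariate_weights)
  coverage <- sum(p_true) * cell
  if (coverage < 0.999)
    warning(sprintf("grid covers only %.4f of the true population mass",
                    coverage))
  p_post <- posterior_mean_density(theta_draws, pop, grid,
                                   theta_fill = theta_fill,
                                   covariate_levels = covariate_levels,
                                   covariate_weights = covariate_weights,
                                   thin = thin)
  sel <- p_true > 0
  kl <- sum(p_true[sel] * (log(p_true[sel]) - log(pmax(p_post[sel],
                                                       1e-300)))) * cell
  list(kl = kl, coverage = coverage, axes = axes)
}

#' Posterior predictive percentile bands
#'
#' For each posterior draw of theta, individuals are sampled from the
#' population model and measured through the error model; the pooled
#' samples per time give predictive quantiles of the inferred measurement
#' distribution `E_{theta|D}[p(y|theta,t)]`.
#'
#' @param theta_draws matrix of posterior draws (named columns).
#' @param model an [nlme_model()].
#' @param times time points to predict at.
#' @param percentiles percentiles of the pooled predictive samples.
#' @param n_per_draw individuals sampled per posterior draw.
#' @param sim_covariate optional covariates for the sampled individuals.
#' @param theta_fill fixed theta entries missing from the draws.
#' @param thin thinning of the posterior draws.
#' @param seed RNG seed.
#' @return Array (length(times) x length(percentiles) x n_observables) of
#'   predictive quantiles.
#' @export
predictive_band <- function(theta_draws, model, times,
                            percentiles = c(5, 50, 95), n_per_draw = 10L,
                            sim_covariate = NULL, theta_fill = NULL,
                            thin = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta_draws <- as.matrix(theta_draws)
  rows <- seq(1L, nrow(theta_draws), by = thin)
  O <- model$time_series$n_observables
  pool <- array(0, dim = c(length(rows) * n_per_draw, length(times), O))
  for (ri in seq_along(rows)) {
    theta <- theta_draws[rows[ri], ]
    if (!is.null(theta_fill))
      theta <- c(theta, theta_fill[setdiff(names(theta_fill), names(theta))])
    Psi <- population_sample(model$population, theta, n_per_draw,
                             covariate = sim_covariate)
    y <- simulate_measurements(model, Psi, times)
    pool[(ri - 1L) * n_per_draw + seq_len(n_per_draw), , ] <- y
  }
  out <- array(0, dim = c(length(times), length(percentiles), O),
               dimnames = list(format(times, trim = TRUE),
                               paste0("p", percentiles),
                               model$time_series$observable_names))
  for (o in seq_len(O)) {
    for (j in seq_along(times)) {
      out[j, , o] <- stats::quantile(pool[, j, o], percentiles / 100,
                                     names = FALSE)
    }
  }
  out
}

#' Accepted summary-statistic trace of a Gaussian-filter run
#'
#' For a chain over the deterministic filter-posterior state, extracts the
#' accepted simulated measurements at one (time, observable) and returns
#' their per-draw empirical mean and variance — the summary statistics the
#' Gaussian filter compares to the data, visualising the implicit ABC error
#' margin.
#'
#' @param chain a `chain_result` from a [filter_posterior()] run (the state
#'   stores the simulated measurements).
#' @param post the `posterior_target` the chain was sampled from.
#' @param j time index.
#' @param observable observable index.
#' @return Data frame with columns `mean` and `variance`, one row per
#'   post-warmup draw.
#' @export
summary_statistic_trace <- function(chain, post, j, observable = 1L) {
  stopifnot(inherits(chain, "chain_result"),
            inherits(post, "posterior_target"))
  draws <- posterior_draws(chain)
  pat <- sprintf("^ytilde\\[\\d+,%d,%d\\]$", j, observable)
  cols <- grep(pat, post$names)
  if (!length(cols))
    stop("chain does not store simulated measurements for this index")
  if (identical(post$parameterization, "noncentered")) {
    # the chain stores z-scores; reconstruct the natural measurements
    yt <- t(apply(draws, 1L, function(x)
      post$unpack(x)$Ytilde[, j, observable]))
  } else {
    yt <- draws[, cols, drop = FALSE]
    # undo a log-scale state if the target samples log measurements
    if (post$model$error$family == "lognormal" || post$filter$log_domain)
      yt <- exp(yt)
  }
  data.frame(mean = rowMeans(yt), variance = apply(yt, 1L, stats::var))
}

#' Overlap coefficient between posterior samples and a prior
#'
#' `integral min(post, prior)` with the posterior density estimated by a
#' Gaussian KDE on the samples; 1 means the marginal equals the prior (the
#' data carry no information about this parameter).
#'
#' @param samples posterior samples of one parameter.
#' @param prior a prior object (e.g. [prior_normal()]).
#' @param n_grid grid resolution.
#' @return Overlap in `[0, 1]`.
#' @export
prior_overlap <- function(samples, prior, n_grid = 512L) {
  dens <- stats::density(samples, n = n_grid)
  cell <- dens$x[2L] - dens$x[1L]
  pr <- exp(prior$logpdf(dens$x))
  pr[!is.finite(pr)] <- 0
  sum(pmin(dens$y, pr)) * cell
}
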