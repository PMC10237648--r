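#' Stochastic filter log-likelihood estimate
#'
#' Estimates the population-level log-likelihood of theta by ancestral
#' sampling: S simulated individuals are drawn from the population model,
#' one trajectory per simulated individual covers all measurement times
#' (exactly S time-series-model evaluations per call), measurement noise is
#' added independently per (individual, time, observable), a filter is
#' constructed per (time point, observable) and the observed measurements
#' are scored against it.
#'
#' @param d a [snapshot_dataset()].
#' @param theta named numeric vector of population parameters.
#' @param model an [nlme_model()].
#' @param filter a [filter_spec()].
#' @param S number of simulated individuals.
#' @param seed optional RNG seed (estimates are reproducible under a seed,
#'   but change from call to call otherwise — this is the stochastic form).
#' @param sim_covariate optional covariate values for the S simulated
#'   individuals (covariate population models).
#' @return Scalar log-likelihood estimate.
#' @export
estimate_loglik_stochastic <- function(d, theta, model, filter, S,
                                       seed = NULL, sim_covariate = NULL) {
  stopifnot(inherits(d, "snapshot_dataset"), inherits(model, "nlme_model"),
            inherits(filter, "filter_spec"), S >= 2)
  if (!is.null(seed)) set.seed(seed)
  terms <- dataset_filter_terms(d, model, filter)
  Psi <- population_sample(model$population, theta, S,
                           covariate = sim_covariate)
  Ytilde <- simulate_measurements(model, Psi, d$times)
  total <- 0
  for (o in seq_len(dim(Ytilde)[3L])) {
    for (j in seq_along(d$times)) {
      term <- terms[[o]][[j]]
      if (is.null(term)) next
      total <- total + term$eval(Ytilde[, j, o], grad = FALSE)$value
    }
  }
  total
}

# Precompute the per-(time, observable) data terms of Eq-style sum_ij
# log p(y_ij | Ytilde_j). Summary-statistic filters reduce the data to
# sufficient statistics so the cost per evaluation is O(S), independent of N.
dataset_filter_terms <- function(d, model, filter) {
  by_time <- dataset_by_time(d)
  obs <- model$time_series$observable_names
  if (length(obs) == 1L && length(d$observables) == 1L) {
    names(by_time) <- obs   # single observable: names need not agree
  } else if (!all(d$observables %in% obs)) {
    stop("dataset observables not produced by the model: ",
         paste(setdiff(d$observables, obs), collapse = ", "))
  }
  lapply(seq_along(obs), function(o) {
    vals <- if (obs[o] %in% names(by_time)) by_time[[obs[o]]] else NULL
    lapply(seq_along(d$times), function(j) {
      y <- if (is.null(vals)) numeric(0) else vals[[j]]
      if (length(y) == 0L) return(NULL)
      make_data_term(filter, y)
    })
  })
}

make_data_term <- function(filter, y) {
  fam <- filter$family
  if (fam %in% c("lognormal", "lognormal_kde") && any(y <= 0))
    stop("log-domain filters require strictly positive measurements")
  if (fam == "gaussian") {
    st <- list(n = length(y), sy = sum(y), syy = sum(y^2))
    eval <- function(yt, grad = TRUE) gauss_data_term_stats(st, yt, grad)
  } else if (fam == "lognormal") {
    z <- log(y)
    st <- list(n = length(y), sy = sum(z), syy = sum(z^2))
    const <- -sum(z)
    eval <- function(yt, grad = TRUE) {
      res <- gauss_data_term_stats(st, log(yt), grad)
      res$value <- res$value + const
      if (grad) res$grad_ytilde <- res$grad_ytilde / yt
      res
    }
  } else if (fam == "gaussian_mixture") {
    M <- filter$M
    eval <- function(yt, grad = TRUE) mixture_filter_eval(y, yt, M, grad)
  } else if (fam == "gaussian_kde") {
    fb <- filter$freeze_bandwidth
    eval <- function(yt, grad = TRUE) kde_filter_eval(y, yt, grad, fb)
  } else {  # lognormal_kde
    z <- log(y)
    const <- -sum(z)
    fb <- filter$freeze_bandwidth
    eval <- function(yt, grad = TRUE) {
      res <- kde_filter_eval(z, log(yt), grad, fb)
      res$value <- res$value + const
      if (grad) res$grad_ytilde <- res$grad_ytilde / yt
      res
    }
  }
  list(n = length(y), eval = eval)
}

#' Deterministic filter log-likelihood
#'
#' The hierarchical form of the filter likelihood: a deterministic,
#' differentiable function of the extended state (theta, Ytilde, Psi~) that
#' sums (a) the data-versus-filter term, (b) the error-model term for the
#' simulated measurements given the simulated individuals, and (c) the
#' population term for the simulated individuals. Identical states give
#' identical values; all gradients are exact.
#'
#' @param d a [snapshot_dataset()].
#' @param state list with `theta` (named, full), `Psi` (S x n_free matrix of
#'   simulated individual-level parameters, free dimensions) and `Ytilde`
#'   (S x K x n_observables array of simulated measurements, natural scale).
#' @param model an [nlme_model()].
#' @param filter a [filter_spec()].
#' @param sim_covariate optional covariates of the simulated individuals.
#' @param grad logical; also return gradients.
#' @return Scalar log-likelihood (with attribute-free decomposition via
#'   `grad = TRUE`: list with `value`, `terms` = c(data, error, population),
#'   `grad_theta`, `grad_Psi`, `grad_Ytilde`).
#' @export
deterministic_loglik <- function(d, state, model, filter,
                                 sim_covariate = NULL, grad = FALSE) {
  terms <- dataset_filter_terms(d, model, filter)
  filter_loglik_core(d$times, terms, model, filter, state$theta, state$Psi,
                     state$Ytilde, sim_covariate, grad)
}

#' @rdname deterministic_loglik
#' @param prior a [prior_spec()]; adds `log p(theta)` over the free
#'   population parameters. Outside the prior support the value is `-Inf`.
#' @export
deterministic_logposterior <- function(d, state, model, filter, prior,
                                       sim_covariate = NULL, grad = FALSE) {
  check_prior(prior, model)
  free <- free_theta_names(prior, model)
  pr <- prior_logpdf(prior, state$theta[free], grad = grad)
  pr_val <- if (grad) pr$value else pr
  if (!is.finite(pr_val)) {
    if (!grad) return(-Inf)
    ll <- deterministic_loglik(d, state, model, filter, sim_covariate, TRUE)
    ll$value <- -Inf
    return(ll)
  }
  ll <- deterministic_loglik(d, state, model, filter, sim_covariate, grad)
  if (!grad) return(ll + pr_val)
  ll$value <- ll$value + pr_val
  ll$grad_theta[free] <- ll$grad_theta[free] + pr$grad
  ll
}

filter_loglik_core <- function(times, terms, model, filter, theta, Psi_free,
                               Ytilde, sim_covariate = NULL, grad = FALSE) {
  S <- if (is.null(dim(Psi_free))) 1L else nrow(Psi_free)
  K <- length(times)
  O <- model$time_series$n_observables
  Ytilde <- array(Ytilde, dim = c(S, K, O))
  Psi <- assemble_psi(model, theta, Psi_free, S)
  mech_names <- model$time_series$parameter_names
  mech <- Psi[, mech_names, drop = FALSE]
  sigma <- psi_sigma(model, Psi)

  bad <- function() {
    if (!grad) return(-Inf)
    list(value = -Inf, terms = c(data = NA, error = NA, population = NA),
         grad_theta = stats::setNames(numeric(length(model$theta_names)),
                                      model$theta_names),
         grad_Psi = matrix(0, S, length(model$psi_free)),
         grad_Ytilde = array(0, dim = c(S, K, O)))
  }
  if (any(sigma <= 0) || any(!is.finite(Psi))) return(bad())
  vfun <- model$time_series$validate
  if (!is.null(vfun) && !vfun(mech)) return(bad())

  ybar <- model$time_series$output(mech, times)
  if (!all(model$error$support(as.vector(Ytilde), as.vector(ybar))))
    return(bad())

  # (b) simulated measurements given simulated individuals
  term_b <- sum(model$error$logpdf(Ytilde, ybar, sigma))
  # (c) simulated individuals given theta
  popres <- population_logpdf(model$population, Psi, theta,
                              covariate = sim_covariate, grad = grad)
  term_c <- if (grad) popres$value else popres
  # (a) observed measurements against the per-(time, observable) filters
  term_a <- 0
  if (grad) grad_Ytilde <- array(0, dim = c(S, K, O))
  a_results <- vector("list", K * O)
  ok <- TRUE
  for (o in seq_len(O)) {
    for (j in seq_len(K)) {
      term <- terms[[o]][[j]]
      if (is.null(term)) next
      res <- term$eval(Ytilde[, j, o], grad = grad)
      if (!is.finite(res$value)) { ok <- FALSE; break }
      term_a <- term_a + res$value
      if (grad) grad_Ytilde[, j, o] <- res$grad_ytilde
    }
    if (!ok) break
  }
  if (!ok || !is.finite(term_a + term_b + term_c)) return(bad())
  value <- term_a + term_b + term_c
  if (!grad) return(value)

  eg <- model$error$logpdf_grad(Ytilde, ybar, sigma)
  grad_Ytilde <- grad_Ytilde + eg$y
  grad_theta <- stats::setNames(numeric(length(model$theta_names)),
                                model$theta_names)
  grad_Psi <- matrix(0, S, length(model$psi_free),
                     dimnames = list(NULL, model$psi_free))
  sens <- model$time_series$sensitivities(mech, times)
  dim(sens) <- c(S, K, O, length(mech_names))
  gy <- array(eg$ybar, dim = c(S, K, O))
  for (pk in seq_along(mech_names)) {
    nm <- mech_names[pk]
    sl <- as.vector(sens[, , , pk, drop = FALSE])
    contrib <- rowSums(matrix(as.vector(gy) * sl, S, K * O))
    cmp <- model$population$components[[nm]]
    if (cmp$type == "pointmass") {
      grad_theta[cmp$value] <- grad_theta[cmp$value] + sum(contrib)
    } else {
      grad_Psi[, nm] <- grad_Psi[, nm] + contrib
    }
  }
  gsig <- rowSums(array(eg$sigma, dim = c(S, K * O)))
  sig_cmp <- model$population$components[["sigma"]]
  if (sig_cmp$type == "pointmass") {
    grad_theta[sig_cmp$value] <- grad_theta[sig_cmp$value] + sum(gsig)
  } else {
    grad_Psi[, "sigma"] <- grad_Psi[, "sigma"] + gsig
  }
  grad_Psi <- grad_Psi + popres$grad_psi[, model$psi_free, drop = FALSE]
  grad_theta <- grad_theta + popres$grad_theta
  list(value = value,
       terms = c(data = term_a, error = term_b, population = term_c),
       grad_theta = grad_theta, grad_Psi = grad_Psi,
       grad_Ytilde = grad_Ytilde)
}

#' Initialise a deterministic filter-posterior state
#'
#' Draws theta from the prior (unless supplied), simulated individuals from
#' the population model and simulated measurements by ancestral sampling,
#' retrying a bounded number of times until the log-posterior is finite.
#'
#' @inheritParams deterministic_logposterior
#' @param S number of simulated individuals.
#' @param seed optional RNG seed.
#' @param theta optional starting population parameters (named, full).
#' @return A state list (`theta`, `Psi`, `Ytilde`) accepted by
#'   [deterministic_logposterior()].
#' @export
initialize_state <- function(d, model, prior, S, seed = NULL, theta = NULL,
                             filter = filter_spec("gaussian"),
                             sim_covariate = NULL) {
  check_prior(prior, model)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(25L)) {
    state <- tryCatch({
      th <- if (is.null(theta)) prior_sample_theta(prior, model) else theta
      Psi <- population_sample(model$population, th, S,
                               covariate = sim_covariate)
      Ytilde <- simulate_measurements(model, Psi, d$times)
      list(theta = th, Psi = Psi[, model$psi_free, drop = FALSE],
           Ytilde = Ytilde)
    }, error = function(e) NULL)
    if (is.null(state)) next
    lp <- tryCatch(
      deterministic_logposterior(d, state, model, filter, prior,
                                 sim_covariate = sim_covariate),
      error = function(e) -Inf)
    if (is.finite(lp)) return(state)
  }
  stop("could not initialise a finite filter-posterior state in 25 attempts")
}

#' Build a packed deterministic filter posterior for MCMC
#'
#' Packs the extended state `(theta, Ytilde, Psi~)` into one unconstrained
#' vector: free theta entries on their declared sampling scale, free
#' simulated individual-level parameters on the natural scale, and simulated
#' measurements on the log scale when the error model or filter lives on the
#' log domain (Jacobians included). One or several experimental conditions
#' (dataset/model pairs sharing theta) may be supplied; the EGF study pools
#' a low- and a high-concentration dataset this way.
#'
#' @param d a [snapshot_dataset()] or list of datasets (one per condition).
#' @param model an [nlme_model()] or list of models matching `d`.
#' @param filter a [filter_spec()].
#' @param prior a [prior_spec()].
#' @param S number of simulated individuals per condition.
#' @param sim_covariate covariate vector for the simulated individuals (or
#'   list per condition).
#' @param parameterization `"noncentered"` (default) samples standardised
#'   coordinates: simulated individual-level parameters and measurements are
#'   represented by their population/noise z-scores, which decorrelates the
#'   hierarchy and lets NUTS use far shorter trajectories; the population
#'   and error terms collapse to standard-normal log-densities and only the
#'   data-versus-filter term couples dimensions. `"centered"` samples the
#'   natural-state coordinates directly. Both target the same posterior;
#'   `pack`/`unpack` always speak natural states.
#' @return A `posterior_target` with `fn`, `dim`, `names`, `pack(state)` /
#'   `unpack(x)` (single condition: a state list; several: list of states)
#'   and `init(seed, theta)`.
#' @export
filter_posterior <- function(d, model, filter, prior, S,
                             sim_covariate = NULL,
                             parameterization = c("noncentered",
                                                  "centered")) {
  parameterization <- match.arg(parameterization)
  single <- inherits(d, "snapshot_dataset")
  ds <- if (single) list(d) else d
  models <- if (single) list(model) else model
  covs <- if (single || is.null(sim_covariate)) {
    rep(list(sim_covariate), length(ds))
  } else sim_covariate
  if (single && !is.null(sim_covariate)) covs <- list(sim_covariate)
  stopifnot(length(ds) == length(models))
  ref <- models[[1L]]
  check_prior(prior, ref)
  free <- free_theta_names(prior, ref)
  trans <- ref$theta_transforms[free]
  nf <- length(ref$psi_free)

  conds <- lapply(seq_along(ds), function(c) {
    m <- models[[c]]
    stopifnot(identical(m$theta_names, ref$theta_names))
    K <- length(ds[[c]]$times)
    O <- m$time_series$n_observables
    list(model = m, times = ds[[c]]$times, K = K, O = O,
         terms = dataset_filter_terms(ds[[c]], m, filter),
         cov = covs[[c]],
         log_y = m$error$family == "lognormal" || filter$log_domain,
         n_psi = S * nf, n_y = S * K * O)
  })
  block <- vapply(conds, function(cc) cc$n_psi + cc$n_y, numeric(1L))
  dim_total <- as.integer(length(free) + sum(block))
  offsets <- length(free) + c(0, cumsum(block))[seq_along(conds)]

  nm <- c(free, unlist(lapply(seq_along(conds), function(c) {
    cc <- conds[[c]]
    tag <- if (length(conds) > 1L) paste0("c", c, ".") else ""
    c(paste0(tag, rep(ref$psi_free, each = S), "[", rep(seq_len(S), nf), "]"),
      paste0(tag, "ytilde[", rep(seq_len(S), cc$K * cc$O), ",",
             rep(rep(seq_len(cc$K), each = S), cc$O), ",",
             rep(seq_len(cc$O), each = S * cc$K), "]"))
  })))

  unpack_cond <- function(x, c, theta) {
    cc <- conds[[c]]
    off <- offsets[c]
    Psi <- matrix(x[off + seq_len(cc$n_psi)], S, nf,
                  dimnames = list(NULL, ref$psi_free))
    yv <- x[off + cc$n_psi + seq_len(cc$n_y)]
    if (cc$log_y) yv <- exp(yv)
    list(theta = theta, Psi = Psi,
         Ytilde = array(yv, dim = c(S, cc$K, cc$O)))
  }
  unpack <- function(x) {
    theta_free <- x[seq_along(free)]
    theta_free[trans == "log"] <- exp(theta_free[trans == "log"])
    names(theta_free) <- free
    theta <- assemble_theta(theta_free, prior, ref)
    states <- lapply(seq_along(conds), function(c) unpack_cond(x, c, theta))
    if (single) states[[1L]] else states
  }
  pack <- function(state) {
    states <- if (single) list(state) else state
    tf <- states[[1L]]$theta[free]
    tf[trans == "log"] <- log(tf[trans == "log"])
    c(tf, unlist(lapply(seq_along(conds), function(c) {
      cc <- conds[[c]]
      yv <- as.vector(states[[c]]$Ytilde)
      if (cc$log_y) yv <- log(yv)
      c(as.vector(as_psi_matrix(states[[c]]$Psi, ref$psi_free)), yv)
    }), use.names = FALSE))
  }
  eval_state <- function(x, grad) {
    theta_free <- x[seq_along(free)]
    theta_free[trans == "log"] <- exp(theta_free[trans == "log"])
    names(theta_free) <- free
    pr <- prior_logpdf(prior, theta_free, grad = grad)
    pr_val <- if (grad) pr$value else pr
    if (!is.finite(pr_val)) {
      if (!grad) return(-Inf)
      return(list(lp = -Inf, grad = numeric(dim_total)))
    }
    theta <- assemble_theta(theta_free, prior, ref)
    lp <- pr_val
    if (grad) { gt <- pr$grad; gvec <- numeric(dim_total) }
    for (c in seq_along(conds)) {
      cc <- conds[[c]]
      st <- unpack_cond(x, c, theta)
      res <- filter_loglik_core(cc$times, cc$terms, cc$model, filter, theta,
                                st$Psi, st$Ytilde, cc$cov, grad = grad)
      val <- if (grad) res$value else res
      if (!is.finite(val)) {
        if (!grad) return(-Inf)
        return(list(lp = -Inf, grad = numeric(dim_total)))
      }
      lp <- lp + val
      off <- offsets[c]
      if (cc$log_y) lp <- lp + sum(x[off + cc$n_psi + seq_len(cc$n_y)])
      if (grad) {
        gt <- gt + res$grad_theta[free]
        gy <- as.vector(res$grad_Ytilde)
        if (cc$log_y) gy <- gy * as.vector(st$Ytilde) + 1
        gvec[off + seq_len(cc$n_psi)] <- as.vector(res$grad_Psi)
        gvec[off + cc$n_psi + seq_len(cc$n_y)] <- gy
      }
    }
    is_log <- trans == "log"
    lp <- lp + sum(log(theta_free[is_log]))
    if (!grad) return(lp)
    gt[is_log] <- gt[is_log] * theta_free[is_log] + 1
    if (!is.finite(lp)) return(list(lp = -Inf, grad = numeric(dim_total)))
    gvec[seq_along(free)] <- gt
    list(lp = lp, grad = gvec)
  }
  fn <- function(x) eval_state(x, grad = TRUE)
  lp_only <- function(x) eval_state(x, grad = FALSE)
  # per-dimension scale guesses for mass-matrix initialisation: prior sds
  # for theta, empirical spreads of the simulated blocks for Psi~ and Ytilde
  scale_hint <- function(x) {
    out <- numeric(dim_total)
    out[seq_along(free)] <- vapply(free, function(nm) {
      p <- prior[[nm]]
      switch(p$type, normal = p$sd, lognormal = p$sdlog,
             uniform = (p$max - p$min) / 3.5, 1)
    }, numeric(1L))
    states <- unpack(x)
    if (single) states <- list(states)
    for (c in seq_along(conds)) {
      cc <- conds[[c]]
      off <- offsets[c]
      psd <- apply(states[[c]]$Psi, 2L, stats::sd)
      psd[!is.finite(psd) | psd <= 0] <- 1
      out[off + seq_len(cc$n_psi)] <- rep(psd, each = S)
      yv <- states[[c]]$Ytilde
      if (cc$log_y) yv <- log(yv)
      ysd <- apply(array(yv, dim = c(S, cc$K * cc$O)), 2L, stats::sd)
      ysd[!is.finite(ysd) | ysd <= 0] <- 1
      out[off + cc$n_psi + seq_len(cc$n_y)] <- rep(ysd, each = S)
    }
    out
  }
  # ---- non-centered parameterization -------------------------------------
  # z_psi and z_y are population/noise z-scores; the population and error
  # terms plus their Jacobians reduce to standard normal log-densities, so
  # the target is log prior + data term - 0.5 * sum(z^2) + const.
  comps_free <- lapply(ref$psi_free,
                       function(k) ref$population$components[[k]])
  sigma_cmp <- ref$population$components[["sigma"]]
  ncp_ok <- sigma_cmp$type == "pointmass" &&
    all(vapply(comps_free, function(cmp)
      cmp$type %in% c("normal", "covariate_normal", "lognormal"),
      logical(1L)))
  if (parameterization == "noncentered" && !ncp_ok)
    stop("noncentered parameterization needs normal/lognormal IIV ",
         "components and a pooled noise scale; use 'centered'")
  mech_names <- ref$time_series$parameter_names
  free_mech_idx <- match(ref$psi_free, mech_names)

  comp_ms <- function(cmp, theta, chi) {
    switch(cmp$type,
      normal = list(m = rep(theta[[cmp$mean]], S), s = theta[[cmp$sd]]),
      covariate_normal = list(
        m = theta[[cmp$mean]] + (if (is.null(chi)) 0 else chi) *
          theta[[cmp$delta]],
        s = theta[[cmp$sd]]),
      lognormal = list(m = rep(theta[[cmp$meanlog]], S),
                       s = theta[[cmp$sdlog]]))
  }
  psi_from_z <- function(theta, Z, chi) {
    out <- matrix(0, S, nf, dimnames = list(NULL, ref$psi_free))
    for (k in seq_len(nf)) {
      ms <- comp_ms(comps_free[[k]], theta, chi)
      out[, k] <- if (comps_free[[k]]$type == "lognormal")
        exp(ms$m + ms$s * Z[, k]) else ms$m + ms$s * Z[, k]
    }
    out
  }
  y_from_z <- function(model_c, ybar, sigma, Zy) {
    if (model_c$error$family == "lognormal") ybar * exp(sigma * Zy)
    else ybar + sigma * Zy
  }

  ncp_unpack_cond <- function(x, c, theta) {
    cc <- conds[[c]]
    off <- offsets[c]
    Z <- matrix(x[off + seq_len(cc$n_psi)], S, nf)
    Zy <- array(x[off + cc$n_psi + seq_len(cc$n_y)],
                dim = c(S, cc$K, cc$O))
    Psi_free_m <- psi_from_z(theta, Z, cc$cov)
    Psi <- assemble_psi(ref, theta, Psi_free_m, S)
    mech <- Psi[, mech_names, drop = FALSE]
    ybar <- cc$model$time_series$simulate(mech, cc$times)
    sigma <- psi_sigma(ref, Psi)
    list(theta = theta, Psi = Psi_free_m,
         Ytilde = array(y_from_z(cc$model, ybar, sigma, Zy),
                        dim = c(S, cc$K, cc$O)))
  }
  ncp_unpack <- function(x) {
    theta_free <- x[seq_along(free)]
    theta_free[trans == "log"] <- exp(theta_free[trans == "log"])
    names(theta_free) <- free
    theta <- assemble_theta(theta_free, prior, ref)
    states <- lapply(seq_along(conds),
                     function(c) ncp_unpack_cond(x, c, theta))
    if (single) states[[1L]] else states
  }
  ncp_pack <- function(state) {
    states <- if (single) list(state) else state
    theta <- states[[1L]]$theta
    tf <- theta[free]
    tf[trans == "log"] <- log(tf[trans == "log"])
    c(tf, unlist(lapply(seq_along(conds), function(c) {
      cc <- conds[[c]]
      Psi_free_m <- as_psi_matrix(states[[c]]$Psi, ref$psi_free)
      Z <- matrix(0, S, nf)
      for (k in seq_len(nf)) {
        ms <- comp_ms(comps_free[[k]], theta, cc$cov)
        v <- Psi_free_m[, k]
        Z[, k] <- if (comps_free[[k]]$type == "lognormal")
          (log(v) - ms$m) / ms$s else (v - ms$m) / ms$s
      }
      Psi <- assemble_psi(ref, theta, Psi_free_m, S)
      mech <- Psi[, mech_names, drop = FALSE]
      ybar <- cc$model$time_series$simulate(mech, cc$times)
      sigma <- psi_sigma(ref, Psi)
      Zy <- if (cc$model$error$family == "lognormal")
        (log(states[[c]]$Ytilde) - log(ybar)) / sigma
      else (states[[c]]$Ytilde - ybar) / sigma
      c(as.vector(Z), as.vector(Zy))
    }), use.names = FALSE))
  }

  ncp_eval <- function(x, grad) {
    theta_free <- x[seq_along(free)]
    theta_free[trans == "log"] <- exp(theta_free[trans == "log"])
    names(theta_free) <- free
    pr <- prior_logpdf(prior, theta_free, grad = grad)
    pr_val <- if (grad) pr$value else pr
    bad <- function() if (!grad) -Inf else
      list(lp = -Inf, grad = numeric(dim_total))
    if (!is.finite(pr_val)) return(bad())
    theta <- assemble_theta(theta_free, prior, ref)
    lp <- pr_val
    if (grad) { gt <- pr$grad; gvec <- numeric(dim_total) }
    for (c in seq_along(conds)) {
      cc <- conds[[c]]
      off <- offsets[c]
      Z <- matrix(x[off + seq_len(cc$n_psi)], S, nf)
      Zy <- array(x[off + cc$n_psi + seq_len(cc$n_y)],
                  dim = c(S, cc$K, cc$O))
      ms_list <- lapply(comps_free, comp_ms, theta = theta, chi = cc$cov)
      Psi_free_m <- matrix(0, S, nf, dimnames = list(NULL, ref$psi_free))
      for (k in seq_len(nf)) {
        Psi_free_m[, k] <- if (comps_free[[k]]$type == "lognormal")
          exp(ms_list[[k]]$m + ms_list[[k]]$s * Z[, k])
        else ms_list[[k]]$m + ms_list[[k]]$s * Z[, k]
      }
      Psi <- assemble_psi(ref, theta, Psi_free_m, S)
      mech <- Psi[, mech_names, drop = FALSE]
      vfun <- cc$model$time_series$validate
      if (!is.null(vfun) && !vfun(mech)) return(bad())
      if (any(!is.finite(mech))) return(bad())
      sigma <- psi_sigma(ref, Psi)
      if (any(sigma <= 0)) return(bad())
      ybar <- cc$model$time_series$output(mech, cc$times)
      if (any(!is.finite(ybar))) return(bad())
      logn <- cc$model$error$family == "lognormal"
      if (logn && any(ybar <= 0)) return(bad())
      Yt <- array(y_from_z(cc$model, ybar, sigma, Zy),
                  dim = c(S, cc$K, cc$O))
      if (any(!is.finite(Yt))) return(bad())
      # data-versus-filter term per (time, observable)
      term_a <- 0
      if (grad) ga <- array(0, dim = c(S, cc$K, cc$O))
      for (o in seq_len(cc$O)) {
        for (j in seq_len(cc$K)) {
          term <- cc$terms[[o]][[j]]
          if (is.null(term)) next
          res <- suppressWarnings(term$eval(Yt[, j, o], grad = grad))
          if (!is.finite(res$value)) return(bad())
          term_a <- term_a + res$value
          if (grad) ga[, j, o] <- res$grad_ytilde
        }
      }
      lp <- lp + term_a -
        0.5 * sum(Z^2) - 0.5 * sum(Zy^2) -
        0.5 * log(2 * pi) * (cc$n_psi + cc$n_y)
      if (!is.finite(lp)) return(bad())
      if (grad) {
        gth <- stats::setNames(numeric(length(ref$theta_names)),
                               ref$theta_names)
        w <- if (logn) Yt / ybar else 1
        gaw <- ga * w                       # d term_a / d ybar-path
        sens <- cc$model$time_series$sensitivities(mech, cc$times)
        dim(sens) <- c(S, cc$K, cc$O, length(mech_names))
        geff <- matrix(0, S, length(mech_names))
        for (pk in seq_along(mech_names)) {
          sl <- as.vector(sens[, , , pk, drop = FALSE])
          geff[, pk] <- rowSums(matrix(as.vector(gaw) * sl,
                                       S, cc$K * cc$O))
        }
        # z_y block: d Yt / d Zy = sigma (or sigma * Yt), minus the
        # standard-normal score
        sig_eff <- if (logn) sigma * Yt else
          array(sigma, dim = c(S, cc$K, cc$O))
        g_zy <- ga * sig_eff - Zy
        # z_psi block and theta contributions through the free components
        g_z <- matrix(0, S, nf)
        for (k in seq_len(nf)) {
          cmp <- comps_free[[k]]
          gk <- geff[, free_mech_idx[k]]
          if (cmp$type == "lognormal") {
            psi_k <- Psi_free_m[, k]
            g_z[, k] <- gk * psi_k * ms_list[[k]]$s - Z[, k]
            gth[cmp$meanlog] <- gth[cmp$meanlog] + sum(gk * psi_k)
            gth[cmp$sdlog] <- gth[cmp$sdlog] + sum(gk * psi_k * Z[, k])
          } else {
            g_z[, k] <- gk * ms_list[[k]]$s - Z[, k]
            gth[cmp$mean] <- gth[cmp$mean] + sum(gk)
            if (cmp$type == "covariate_normal" && !is.null(cc$cov))
              gth[cmp$delta] <- gth[cmp$delta] + sum(gk * cc$cov)
            gth[cmp$sd] <- gth[cmp$sd] + sum(gk * Z[, k])
          }
        }
        # pooled mechanistic rates enter every trajectory directly
        for (pk in seq_along(mech_names)) {
          if (mech_names[pk] %in% ref$psi_free) next
          cmp_pm <- ref$population$components[[mech_names[pk]]]
          gth[cmp_pm$value] <- gth[cmp_pm$value] + sum(geff[, pk])
        }
        # pooled noise scale: d Yt / d sigma = Zy (or Yt * Zy)
        dsig <- if (logn) ga * Yt * Zy else ga * Zy
        gth[sigma_cmp$value] <- gth[sigma_cmp$value] + sum(dsig)
        gt <- gt + gth[free]
        gvec[off + seq_len(cc$n_psi)] <- as.vector(g_z)
        gvec[off + cc$n_psi + seq_len(cc$n_y)] <- as.vector(g_zy)
      }
    }
    is_log <- trans == "log"
    lp <- lp + sum(log(theta_free[is_log]))
    if (!grad) return(lp)
    gt[is_log] <- gt[is_log] * theta_free[is_log] + 1
    if (!is.finite(lp)) return(bad())
    gvec[seq_along(free)] <- gt
    list(lp = lp, grad = gvec)
  }

  ncp_scale_hint <- function(x) {
    out <- rep(1, dim_total)
    out[seq_along(free)] <- vapply(free, function(p_nm) {
      p <- prior[[p_nm]]
      switch(p$type, normal = p$sd, lognormal = p$sdlog,
             uniform = (p$max - p$min) / 3.5, 1)
    }, numeric(1L))
    out
  }

  if (parameterization == "noncentered") {
    fn <- function(x) ncp_eval(x, grad = TRUE)
    lp_only <- function(x) ncp_eval(x, grad = FALSE)
    pack <- ncp_pack
    unpack <- ncp_unpack
    scale_hint <- ncp_scale_hint
  }
  init <- function(seed = NULL, theta = NULL) {
    if (!is.null(seed)) set.seed(seed)
    states <- lapply(seq_along(conds), function(c) {
      initialize_state(ds[[c]], models[[c]], prior, S, theta = theta,
                       filter = filter, sim_covariate = conds[[c]]$cov)
    })
    # share one theta draw across conditions
    th <- states[[1L]]$theta
    for (c in seq_along(states)) states[[c]]$theta <- th
    pack(if (single) states[[1L]] else states)
  }
  structure(list(fn = fn, lp = lp_only, dim = dim_total, names = nm,
                 pack = pack, scale_hint = scale_hint,
                 unpack = unpack, init = init, S = S,
                 parameterization = parameterization,
                 model = ref, prior = prior, filter = filter,
                 free_theta = free, n_conditions = length(conds)),
            class = "posterior_target")
}
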