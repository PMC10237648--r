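#' Traditional hierarchical NLME log-likelihood
#'
#' The hierarchical log-likelihood of population parameters theta and
#' individual-level parameters Psi given a snapshot dataset:
#' the sum over measurements of the error-model log-density plus the sum
#' over individuals of the population log-density. Missing (id, time) cells
#' contribute nothing. Evaluation costs one time-series trajectory per
#' measured individual (the evaluation counter increases by N per call).
#'
#' @param d a [snapshot_dataset()].
#' @param state list with `theta` (named, full population vector) and `Psi`
#'   (N x n_free matrix of the free individual-level dimensions, rows in
#'   `d$ids` order, columns in `model$psi_free` order).
#' @param model an [nlme_model()].
#' @param grad logical; also return gradients.
#' @return The scalar log-likelihood, or (with `grad = TRUE`) a list with
#'   `value`, `grad_theta` (named) and `grad_Psi`.
#' @export
hierarchical_loglik <- function(d, state, model, grad = FALSE) {
  stopifnot(inherits(d, "snapshot_dataset"), inherits(model, "nlme_model"))
  info <- dataset_index(d, model)
  hierarchical_core(info, state$theta, state$Psi, model,
                    covariate = dataset_covariates(d), grad = grad)
}

# precomputed record indexing shared by likelihood code
dataset_index <- function(d, model) {
  obs <- model$time_series$observable_names
  rec <- d$records
  if (length(obs) == 1L && length(d$observables) == 1L) {
    o <- rep(1L, nrow(rec))  # single observable: names need not agree
  } else {
    if (!all(d$observables %in% obs))
      stop("dataset observables not produced by the model: ",
           paste(setdiff(d$observables, obs), collapse = ", "))
    o <- match(rec$observable, obs)
  }
  list(ids = d$ids, times = d$times,
       i = match(rec$id, d$ids),
       j = match(rec$time, d$times),
       o = o,
       y = rec$value,
       n = d$n_individuals)
}

# full N x dim(psi) matrix: free columns from Psi_free, point-mass columns
# pinned to theta
assemble_psi <- function(model, theta, Psi_free, n) {
  Psi_free <- as_psi_matrix(Psi_free, model$psi_free)
  full <- matrix(0, n, length(model$psi_names),
                 dimnames = list(NULL, model$psi_names))
  full[, model$psi_free] <- Psi_free
  for (k in seq_along(model$population$components)) {
    cmp <- model$population$components[[k]]
    if (cmp$type == "pointmass")
      full[, k] <- theta[[cmp$value]]
  }
  full
}

hierarchical_core <- function(info, theta, Psi_free, model,
                              covariate = NULL, grad = FALSE) {
  n <- info$n
  if (n == 0L || is.null(info$y) || length(info$y) == 0L) {
    if (!grad) return(0)
  }
  Psi_free <- as_psi_matrix(Psi_free, model$psi_free)
  if (nrow(Psi_free) != n)
    stop("state$Psi must have one row per measured individual")
  Psi <- assemble_psi(model, theta, Psi_free, n)
  mech_names <- model$time_series$parameter_names
  mech <- Psi[, mech_names, drop = FALSE]
  sigma <- psi_sigma(model, Psi)
  vfun <- model$time_series$validate
  if ((!is.null(vfun) && !vfun(mech)) || any(sigma <= 0) ||
      any(!is.finite(Psi))) {
    if (!grad) return(-Inf)
    return(list(value = -Inf,
                grad_theta = stats::setNames(
                  numeric(length(model$theta_names)), model$theta_names),
                grad_Psi = matrix(0, n, length(model$psi_free))))
  }

  ybar <- model$time_series$output(mech, info$times)
  idx <- cbind(info$i, info$j, info$o)
  ybar_rec <- ybar[idx]
  sigma_rec <- sigma[info$i]
  if (!all(model$error$support(info$y, ybar_rec))) {
    val <- -Inf
  } else {
    val <- sum(model$error$logpdf(info$y, ybar_rec, sigma_rec))
  }
  popres <- population_logpdf(model$population, Psi, theta,
                              covariate = covariate, grad = grad)
  if (!grad) return(val + popres)

  grad_theta <- stats::setNames(numeric(length(model$theta_names)),
                                model$theta_names)
  grad_Psi <- matrix(0, n, length(model$psi_free),
                     dimnames = list(NULL, model$psi_free))
  value <- val + popres$value
  if (is.finite(value)) {
    eg <- model$error$logpdf_grad(info$y, ybar_rec, sigma_rec)
    sens <- model$time_series$sensitivities(mech, info$times)
    # chain d l / d ybar through trajectory sensitivities
    for (pk in seq_along(mech_names)) {
      nm <- mech_names[pk]
      contrib <- eg$ybar * sens[cbind(info$i, info$j, info$o,
                                      rep(pk, length(info$i)))]
      per_id <- rowsum_by(contrib, info$i, n)
      cmp <- model$population$components[[nm]]
      if (cmp$type == "pointmass") {
        grad_theta[cmp$value] <- grad_theta[cmp$value] + sum(per_id)
      } else {
        grad_Psi[, nm] <- grad_Psi[, nm] + per_id
      }
    }
    # noise scale: point-mass (pooled) or free individual dimension
    sig_cmp <- model$population$components[["sigma"]]
    sig_per_id <- rowsum_by(eg$sigma, info$i, n)
    if (sig_cmp$type == "pointmass") {
      grad_theta[sig_cmp$value] <- grad_theta[sig_cmp$value] + sum(sig_per_id)
    } else {
      grad_Psi[, "sigma"] <- grad_Psi[, "sigma"] + sig_per_id
    }
    grad_Psi <- grad_Psi + popres$grad_psi[, model$psi_free, drop = FALSE]
    grad_theta <- grad_theta + popres$grad_theta
  }
  list(value = value, grad_theta = grad_theta, grad_Psi = grad_Psi)
}

rowsum_by <- function(x, group, n) {
  out <- numeric(n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Traditional NLME log-posterior
#'
#' Hierarchical log-likelihood plus the log-prior of the free population
#' parameters (up to a constant). Parameter values outside the prior support
#' return `-Inf` rather than raising an error.
#'
#' @inheritParams hierarchical_loglik
#' @param prior a [prior_spec()] covering all free theta components.
#' @return Scalar log-posterior, or a list with gradients when
#'   `grad = TRUE`.
#' @export
nlme_logposterior <- function(d, state, model, prior, grad = FALSE) {
  check_prior(prior, model)
  free <- free_theta_names(prior, model)
  theta_free <- state$theta[free]
  pr <- prior_logpdf(prior, theta_free, grad = grad)
  pr_val <- if (grad) pr$value else pr
  if (!is.finite(pr_val)) {
    if (!grad) return(-Inf)
    return(list(value = -Inf,
                grad_theta = stats::setNames(
                  numeric(length(model$theta_names)), model$theta_names),
                grad_Psi = matrix(0, nrow(as_psi_matrix(state$Psi,
                                                        model$psi_free)),
                                  length(model$psi_free))))
  }
  ll <- hierarchical_loglik(d, state, model, grad = grad)
  if (!grad) return(ll + pr_val)
  ll$value <- ll$value + pr_val
  ll$grad_theta[free] <- ll$grad_theta[free] + pr$grad
  ll
}

#' Build a packed hierarchical posterior for MCMC
#'
#' Packs `(theta_free, Psi)` into one unconstrained vector (log-scale for
#' theta entries declared `log` in the model's transforms, with the Jacobian
#' included) and returns the log-posterior-with-gradient closure that the
#' samplers consume.
#'
#' @inheritParams nlme_logposterior
#' @return An object of class `posterior_target`: list with `fn(x)`
#'   returning `list(lp, grad)`, `dim`, `names`, `pack(theta, Psi)` and
#'   `unpack(x)`.
#' @export
nlme_posterior <- function(d, model, prior) {
  check_prior(prior, model)
  info <- dataset_index(d, model)
  covariate <- dataset_covariates(d)
  free <- free_theta_names(prior, model)
  trans <- model$theta_transforms[free]
  n <- info$n
  nf <- length(model$psi_free)
  dim_total <- as.integer(length(free) + n * nf)
  nm <- c(free, paste0(rep(model$psi_free, each = n), "[",
                       rep(seq_len(n), nf), "]"))

  unpack <- function(x) {
    theta_free <- x[seq_along(free)]
    theta_free[trans == "log"] <- exp(theta_free[trans == "log"])
    names(theta_free) <- free
    Psi <- matrix(x[-seq_along(free)], n, nf,
                  dimnames = list(NULL, model$psi_free))
    list(theta = assemble_theta(theta_free, prior, model), Psi = Psi)
  }
  pack <- function(theta, Psi) {
    tf <- theta[free]
    tf[trans == "log"] <- log(tf[trans == "log"])
    c(tf, as.vector(as_psi_matrix(Psi, model$psi_free)))
  }
  eval_state <- function(x, grad) {
    st <- unpack(x)
    theta_free <- st$theta[free]
    pr <- prior_logpdf(prior, theta_free, grad = grad)
    pr_val <- if (grad) pr$value else pr
    if (!is.finite(pr_val)) {
      if (!grad) return(-Inf)
      return(list(lp = -Inf, grad = numeric(dim_total)))
    }
    res <- hierarchical_core(info, st$theta, st$Psi, model,
                             covariate = covariate, grad = grad)
    val <- if (grad) res$value else res
    lp <- val + pr_val + sum(log(theta_free[trans == "log"]))
    if (!grad) return(lp)
    if (!is.finite(lp)) return(list(lp = -Inf, grad = numeric(dim_total)))
    gt <- res$grad_theta[free] + pr$grad
    # log-transform chain rule + Jacobian of the change of variables
    is_log <- trans == "log"
    gt[is_log] <- gt[is_log] * theta_free[is_log] + 1
    list(lp = lp, grad = c(gt, as.vector(res$grad_Psi)))
  }
  fn <- function(x) eval_state(x, grad = TRUE)
  lp_only <- function(x) eval_state(x, grad = FALSE)
  scale_hint <- function(x) {
    out <- numeric(dim_total)
    out[seq_along(free)] <- vapply(free, function(p_nm) {
      p <- prior[[p_nm]]
      switch(p$type, normal = p$sd, lognormal = p$sdlog,
             uniform = (p$max - p$min) / 3.5, 1)
    }, numeric(1L))
    st <- unpack(x)
    psd <- apply(st$Psi, 2L, stats::sd)
    psd[!is.finite(psd) | psd <= 0] <- 1
    out[-seq_along(free)] <- rep(psd, each = n)
    out
  }
  structure(list(fn = fn, lp = lp_only, dim = dim_total, names = nm,
                 pack = pack, unpack = unpack, scale_hint = scale_hint,
                 model = model, prior = prior, free_theta = free),
            class = "posterior_target")
}
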