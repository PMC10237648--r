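#' Prior specifications
#'
#' A prior specification assigns each population parameter either a prior
#' distribution or a fixed value (excluded from sampling). Priors are
#' expressed on the natural parameter scale; samplers work on the
#' unconstrained scale declared by the model's `theta_transforms`, with the
#' Jacobian handled internally.
#'
#' @param ... named prior objects ([prior_normal()], [prior_lognormal()],
#'   [prior_uniform()]) or [prior_fixed()] values, one per theta entry.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(...) {
  priors <- list(...)
  if (length(priors) == 1L && is.list(priors[[1L]]) &&
      is.null(attr(priors[[1L]], "class")))
    priors <- priors[[1L]]
  stopifnot(length(names(priors)) == length(priors))
  structure(priors, class = "prior_spec")
}

#' @rdname prior_spec
#' @param mean,sd mean and standard deviation (normal prior).
#' @export
prior_normal <- function(mean, sd) {
  structure(list(type = "normal", mean = mean, sd = sd,
                 logpdf = function(x) stats::dnorm(x, mean, sd, log = TRUE),
                 grad = function(x) -(x - mean) / sd^2,
                 sample = function(n) stats::rnorm(n, mean, sd),
                 support = function(x) rep(TRUE, length(x))),
            class = "prior_dist")
}

#' @rdname prior_spec
#' @param meanlog,sdlog location and scale of a lognormal prior.
#' @export
prior_lognormal <- function(meanlog, sdlog) {
  structure(list(type = "lognormal", meanlog = meanlog, sdlog = sdlog,
                 logpdf = function(x)
                   stats::dlnorm(x, meanlog, sdlog, log = TRUE),
                 grad = function(x) (-1 - (log(x) - meanlog) / sdlog^2) / x,
                 sample = function(n) stats::rlnorm(n, meanlog, sdlog),
                 support = function(x) x > 0),
            class = "prior_dist")
}

#' @rdname prior_spec
#' @param min,max bounds of a uniform prior.
#' @export
prior_uniform <- function(min, max) {
  structure(list(type = "uniform", min = min, max = max,
                 logpdf = function(x)
                   stats::dunif(x, min, max, log = TRUE),
                 grad = function(x) rep(0, length(x)),
                 sample = function(n) stats::runif(n, min, max),
                 support = function(x) x >= min & x <= max),
            class = "prior_dist")
}

#' @rdname prior_spec
#' @param value the fixed parameter value.
#' @export
prior_fixed <- function(value) {
  structure(list(type = "fixed", value = value), class = "prior_fixed")
}

is_fixed <- function(p) inherits(p, "prior_fixed")

check_prior <- function(prior, model) {
  stopifnot(inherits(prior, "prior_spec"), inherits(model, "nlme_model"))
  missing <- setdiff(model$theta_names, names(prior))
  if (length(missing))
    stop("prior does not cover theta components: ",
         paste(missing, collapse = ", "))
  invisible(prior)
}

free_theta_names <- function(prior, model) {
  model$theta_names[!vapply(prior[model$theta_names], is_fixed, logical(1L))]
}

fixed_theta_values <- function(prior, model) {
  fixed <- vapply(prior[model$theta_names], is_fixed, logical(1L))
  vals <- vapply(prior[model$theta_names][fixed],
                 function(p) p$value, numeric(1L))
  stats::setNames(vals, model$theta_names[fixed])
}

# full named theta vector from free values + fixed entries
assemble_theta <- function(theta_free, prior, model) {
  theta <- stats::setNames(numeric(length(model$theta_names)),
                           model$theta_names)
  theta[names(theta_free)] <- theta_free
  fixed <- fixed_theta_values(prior, model)
  theta[names(fixed)] <- fixed
  theta
}

# log p(theta) and gradient over the free components (natural scale)
prior_logpdf <- function(prior, theta_free, grad = FALSE) {
  value <- 0
  g <- stats::setNames(numeric(length(theta_free)), names(theta_free))
  for (nm in names(theta_free)) {
    p <- prior[[nm]]
    x <- theta_free[[nm]]
    if (!p$support(x)) {
      if (!grad) return(-Inf)
      return(list(value = -Inf, grad = g))
    }
    value <- value + p$logpdf(x)
    if (grad) g[nm] <- p$grad(x)
  }
  if (!grad) value else list(value = value, grad = g)
}

# median/centre of each free prior: a deterministic, moderate starting
# point for samplers (random prior draws can land far into the tails of
# stiff posteriors and strand the chain)
prior_center_theta <- function(prior, model) {
  free <- free_theta_names(prior, model)
  vals <- vapply(free, function(nm) {
    p <- prior[[nm]]
    switch(p$type, normal = p$mean, lognormal = exp(p$meanlog),
           uniform = (p$min + p$max) / 2, 1)
  }, numeric(1L))
  assemble_theta(stats::setNames(vals, free), prior, model)
}

prior_sample_theta <- function(prior, model) {
  free <- free_theta_names(prior, model)
  vals <- vapply(free, function(nm) prior[[nm]]$sample(1L), numeric(1L))
  assemble_theta(stats::setNames(vals, free), prior, model)
}

#' Default priors for the study models
#'
#' Weakly informative defaults covering the data-generating parameter values.
#' The noise prior for the cancer models concentrates on scales between
#' roughly 0.5 and 1 (an informative noise prior is needed because snapshot
#' measurements cannot separate IIV from noise). The EGF noise scale is
#' fixed to its data-generating value, and degradation/deactivation rates
#' get broad lognormal priors.
#'
#' @param name model name as in [get_model()].
#' @return A [prior_spec()].
#' @export
default_prior <- function(name = c("cancer", "egf", "cancer-bimodal")) {
  name <- match.arg(name)
  switch(name,
    cancer = prior_spec(
      mu_y0 = prior_normal(9, 2),
      sigma_y0 = prior_lognormal(log(1), 0.6),
      mu_lambda = prior_normal(1.5, 1),
      sigma_lambda = prior_lognormal(log(0.4), 0.6),
      mu_sigma = prior_lognormal(log(0.75), 0.2)),
    egf = prior_spec(
      mu_p = prior_normal(1.5, 0.5),
      sigma_p = prior_lognormal(log(0.05), 0.5),
      mu_kon = prior_normal(1.5, 0.5),
      sigma_kon = prior_lognormal(log(0.05), 0.5),
      mu_koff = prior_lognormal(log(6), 0.5),
      mu_kdeg_r = prior_lognormal(log(0.2), 0.5),
      mu_kdeg_a = prior_lognormal(log(0.02), 0.7),
      mu_sigma = prior_fixed(0.05)),
    `cancer-bimodal` = prior_spec(
      mu_y0 = prior_normal(9, 2),
      sigma_y0 = prior_lognormal(log(1), 0.6),
      mu_lambda_m = prior_normal(1.5, 1),
      delta_mu_lambda = prior_normal(0, 2),
      sigma_lambda = prior_lognormal(log(0.4), 0.6),
      mu_sigma = prior_lognormal(log(0.75), 0.2)))
}
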