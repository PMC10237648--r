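#' Assemble an NLME model
#'
#' Bundles a time-series model, an error model and a population model. The
#' individual-level parameter vector psi consists of the mechanistic
#' parameters followed by the error scale `sigma`; the population model must
#' have one component per psi dimension, in that order. Pooled parameters
#' (identical across individuals) are represented as point-mass components,
#' so the same machinery covers cell-specific and shared rates.
#'
#' @param time_series a [ts_model()].
#' @param error an [error_model()].
#' @param population a [population_model()] whose psi names are
#'   `c(time_series$parameter_names, "sigma")`.
#' @param theta_transforms named character vector, `"identity"` or `"log"`,
#'   giving the unconstrained sampling scale of each theta entry (defaults:
#'   log for every entry whose name starts with `sigma_` or equals
#'   `mu_sigma`, identity otherwise).
#' @return An `nlme_model` object.
#' @export
nlme_model <- function(time_series, error, population,
                       theta_transforms = NULL) {
  stopifnot(inherits(time_series, "ts_model"),
            inherits(error, "error_model"),
            inherits(population, "population_model"))
  expected <- c(time_series$parameter_names, "sigma")
  if (!identical(population$psi_names, expected))
    stop("population psi names must be (",
         paste(expected, collapse = ", "), ")")
  if (is.null(theta_transforms)) {
    theta_transforms <- ifelse(
      grepl("^sigma", population$theta_names) |
        population$theta_names == "mu_sigma", "log", "identity")
    names(theta_transforms) <- population$theta_names
  }
  structure(
    list(time_series = time_series, error = error, population = population,
         psi_names = population$psi_names,
         psi_free = population$psi_free,
         theta_names = population$theta_names,
         theta_transforms = theta_transforms),
    class = "nlme_model")
}

#' @export
print.nlme_model <- function(x, ...) {
  cat(sprintf("nlme_model '%s': psi = (%s), theta = (%s), %s error\n",
              x$time_series$name, paste(x$psi_names, collapse = ", "),
              paste(x$theta_names, collapse = ", "), x$error$family))
  invisible(x)
}

# sigma of each individual from the full psi matrix
psi_sigma <- function(model, Psi) Psi[, "sigma"]

#' Simulate measurements by ancestral sampling
#'
#' Draws one measurement per (individual, time, observable) from the error
#' model around the simulated trajectories. One trajectory per individual
#' covers all requested times (a single batched time-series evaluation).
#'
#' @param model an [nlme_model()].
#' @param Psi n x dim(psi) matrix of individual-level parameters.
#' @param times numeric vector of measurement times.
#' @param seed optional RNG seed.
#' @return Array (n, K, n_observables) of noisy measurements.
#' @export
simulate_measurements <- function(model, Psi, times, seed = NULL) {
  stopifnot(inherits(model, "nlme_model"))
  if (!is.null(seed)) set.seed(seed)
  Psi <- as_psi_matrix(Psi, model$psi_names)
  mech <- Psi[, model$time_series$parameter_names, drop = FALSE]
  ybar <- model$time_series$output(mech, times)
  sigma <- psi_sigma(model, Psi)
  out <- array(0, dim = dim(ybar))
  for (o in seq_len(dim(ybar)[3L])) {
    out[, , o] <- model$error$sample(ybar[, , o], sigma)
  }
  out
}

# ---------------------------------------------------------------------------
# Model registry: the three study models
# ---------------------------------------------------------------------------

#' Study models
#'
#' * `"cancer"` — exponential early cancer growth with Gaussian noise;
#'   psi = (y0, lambda, sigma) with normal IIV on (y0, lambda) and pooled
#'   sigma; theta = (mu_y0, sigma_y0, mu_lambda, sigma_lambda, mu_sigma).
#' * `"egf"` — EGF receptor signalling with lognormal noise; cell-specific
#'   (p, kon) with normal IIV, pooled (koff, kdeg_r, kdeg_a, sigma);
#'   theta = (mu_p, sigma_p, mu_kon, sigma_kon, mu_koff, mu_kdeg_r,
#'   mu_kdeg_a, mu_sigma). Requires the EGF concentration `c_l`.
#' * `"cancer-bimodal"` — cancer growth with a covariate-dependent mean
#'   growth rate mu_lambda(chi) = mu_lambda_m + chi * delta_mu_lambda
#'   (chi = 0 moderate, chi = 1 aggressive variant), giving a bimodal
#'   population distribution; theta = (mu_y0, sigma_y0, mu_lambda_m,
#'   delta_mu_lambda, sigma_lambda, mu_sigma).
#'
#' @param name one of `"cancer"`, `"egf"`, `"cancer-bimodal"`.
#' @param c_l EGF concentration in ng/mL (EGF model only).
#' @param egf_variability `"normal"` (default) or `"lognormal"` IIV for the
#'   EGF cell-specific rates (p, kon).
#' @return An [nlme_model()].
#' @export
get_model <- function(name = c("cancer", "egf", "cancer-bimodal"),
                      c_l = NULL, egf_variability = c("normal", "lognormal")) {
  name <- match.arg(name)
  egf_variability <- match.arg(egf_variability)
  switch(name,
    cancer = nlme_model(
      time_series = cancer_timeseries(),
      error = error_model("gaussian"),
      population = population_model(list(
        y0 = pop_normal("mu_y0", "sigma_y0"),
        lambda = pop_normal("mu_lambda", "sigma_lambda"),
        sigma = pop_pointmass("mu_sigma")))),
    egf = {
      if (is.null(c_l)) stop("the EGF model needs the EGF concentration c_l")
      cmp <- if (egf_variability == "normal") {
        list(p = pop_normal("mu_p", "sigma_p"),
             kon = pop_normal("mu_kon", "sigma_kon"))
      } else {
        list(p = pop_lognormal("mu_p", "sigma_p"),
             kon = pop_lognormal("mu_kon", "sigma_kon"))
      }
      nlme_model(
        time_series = egf_timeseries(c_l = c_l),
        error = error_model("lognormal"),
        population = population_model(c(cmp, list(
          koff = pop_pointmass("mu_koff"),
          kdeg_r = pop_pointmass("mu_kdeg_r"),
          kdeg_a = pop_pointmass("mu_kdeg_a"),
          sigma = pop_pointmass("mu_sigma")))),
        theta_transforms = c(
          mu_p = "identity", sigma_p = "log", mu_kon = "identity",
          sigma_kon = "log", mu_koff = "log", mu_kdeg_r = "log",
          mu_kdeg_a = "log", mu_sigma = "log"))
    },
    `cancer-bimodal` = nlme_model(
      time_series = cancer_timeseries(),
      error = error_model("gaussian"),
      population = population_model(list(
        y0 = pop_normal("mu_y0", "sigma_y0"),
        lambda = pop_covariate_normal("mu_lambda_m", "delta_mu_lambda",
                                      "sigma_lambda"),
        sigma = pop_pointmass("mu_sigma")))))
}

#' Data-generating parameter values of the study models
#'
#' @param name model name as in [get_model()].
#' @return Named numeric vector theta used for data generation.
#' @export
true_theta <- function(name = c("cancer", "egf", "cancer-bimodal")) {
  name <- match.arg(name)
  switch(name,
    cancer = c(mu_y0 = 10, sigma_y0 = 1, mu_lambda = 2, sigma_lambda = 0.5,
               mu_sigma = 0.8),
    egf = c(mu_p = 1.7, sigma_p = 0.05, mu_kon = 1.7, sigma_kon = 0.05,
            mu_koff = 8, mu_kdeg_r = 0.25, mu_kdeg_a = 0.015,
            mu_sigma = 0.05),
    `cancer-bimodal` = c(mu_y0 = 10, sigma_y0 = 1, mu_lambda_m = 2,
                         delta_mu_lambda = 2, sigma_lambda = 0.5,
                         mu_sigma = 0.8))
}
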