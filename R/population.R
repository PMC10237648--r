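#' Population models
#'
#' A population model describes the distribution of individual-level
#' parameters psi across individuals, `p(psi | theta)`, as a product of
#' independent per-dimension components. Supported components:
#'
#' * `pop_normal(mean, sd)` — psi_k normally distributed across individuals;
#' * `pop_lognormal(meanlog, sdlog)` — lognormal IIV for positive parameters;
#' * `pop_pointmass(value)` — a pooled parameter, identical across
#'   individuals (a Dirac delta at the theta component); it is never a free
#'   individual-level dimension and contributes 0 to the log-density;
#' * `pop_covariate_normal(mean, delta, sd)` — normal with covariate-shifted
#'   mean `mean + chi * delta`, giving a multi-modal marginal when covariate
#'   groups are mixed.
#'
#' Component arguments name entries of the population parameter vector theta.
#'
#' @param components named list of components; names are the psi dimensions
#'   in order (the error-model scale must be named `sigma`).
#' @return A `population_model` object.
#' @export
population_model <- function(components) {
  stopifnot(length(names(components)) == length(components))
  theta_names <- unlist(lapply(components, function(cmp) cmp$theta_names),
                        use.names = FALSE)
  if (anyDuplicated(theta_names))
    stop("theta parameter names must be unique across components")
  free <- vapply(components, function(cmp) cmp$type != "pointmass",
                 logical(1L))
  structure(
    list(components = components,
         psi_names = names(components),
         psi_free = names(components)[free],
         theta_names = theta_names),
    class = "population_model")
}

#' @rdname population_model
#' @param mean,sd,meanlog,sdlog,value,delta names of theta entries
#'   parameterising the component.
#' @export
pop_normal <- function(mean, sd) {
  structure(list(type = "normal", theta_names = c(mean, sd),
                 mean = mean, sd = sd), class = "pop_component")
}

#' @rdname population_model
#' @export
pop_lognormal <- function(meanlog, sdlog) {
  structure(list(type = "lognormal", theta_names = c(meanlog, sdlog),
                 meanlog = meanlog, sdlog = sdlog), class = "pop_component")
}

#' @rdname population_model
#' @export
pop_pointmass <- function(value) {
  structure(list(type = "pointmass", theta_names = value, value = value),
            class = "pop_component")
}

#' @rdname population_model
#' @export
pop_covariate_normal <- function(mean, delta, sd) {
  structure(list(type = "covariate_normal", theta_names = c(mean, delta, sd),
                 mean = mean, delta = delta, sd = sd),
            class = "pop_component")
}

check_theta <- function(pop, theta) {
  missing <- setdiff(pop$theta_names, names(theta))
  if (length(missing))
    stop("theta is missing components: ", paste(missing, collapse = ", "))
  for (cmp in pop$components) {
    sd_name <- switch(cmp$type, normal = cmp$sd, lognormal = cmp$sdlog,
                      covariate_normal = cmp$sd, NULL)
    if (!is.null(sd_name) && theta[[sd_name]] <= 0)
      stop("population sd component '", sd_name, "' must be positive")
  }
  invisible(theta)
}

component_mean_sd <- function(cmp, theta, covariate = NULL) {
  switch(cmp$type,
    normal = list(mean = theta[[cmp$mean]], sd = theta[[cmp$sd]]),
    lognormal = list(mean = theta[[cmp$meanlog]], sd = theta[[cmp$sdlog]]),
    covariate_normal = {
      chi <- if (is.null(covariate)) 0 else covariate
      list(mean = theta[[cmp$mean]] + chi * theta[[cmp$delta]],
           sd = theta[[cmp$sd]])
    },
    stop("no mean/sd for component type ", cmp$type))
}

#' Sample individual-level parameters from a population model
#'
#' @param pop a [population_model()].
#' @param theta named numeric vector of population parameters.
#' @param n number of individuals to draw.
#' @param covariate optional covariate vector chi (length n, recycled) for
#'   covariate-dependent components.
#' @param seed optional RNG seed.
#' @return An n x dim(psi) matrix with columns named after psi dimensions;
#'   point-mass dimensions equal the theta value exactly.
#' @export
population_sample <- function(pop, theta, n, covariate = NULL, seed = NULL) {
  stopifnot(inherits(pop, "population_model"))
  check_theta(pop, theta)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(covariate)) covariate <- rep_len(covariate, n)
  out <- matrix(0, nrow = n, ncol = length(pop$components),
                dimnames = list(NULL, pop$psi_names))
  for (k in seq_along(pop$components)) {
    cmp <- pop$components[[k]]
    out[, k] <- switch(cmp$type,
      normal = stats::rnorm(n, theta[[cmp$mean]], theta[[cmp$sd]]),
      lognormal = stats::rlnorm(n, theta[[cmp$meanlog]], theta[[cmp$sdlog]]),
      pointmass = rep(theta[[cmp$value]], n),
      covariate_normal = {
        ms <- component_mean_sd(cmp, theta, covariate)
        stats::rnorm(n, ms$mean, ms$sd)
      })
  }
  out
}

#' Population log-density and gradients
#'
#' Sum over individuals of `log p(psi_i | theta)`; point-mass components
#' contribute 0 (their psi dimension is pinned to theta, not sampled).
#'
#' @param pop a [population_model()].
#' @param Psi n x dim(psi) matrix (columns in `pop$psi_names` order).
#' @param theta named numeric vector.
#' @param covariate optional covariate vector (length n).
#' @param grad logical; also return gradients.
#' @return If `grad = FALSE`, the scalar log-density. Otherwise a list with
#'   `value`, `grad_psi` (n x dim(psi), zero for point-mass dims) and
#'   `grad_theta` (named, full theta length).
#' @export
population_logpdf <- function(pop, Psi, theta, covariate = NULL, grad = FALSE) {
  stopifnot(inherits(pop, "population_model"))
  check_theta(pop, theta)
  Psi <- as_psi_matrix(Psi, pop$psi_names)
  n <- nrow(Psi)
  if (!is.null(covariate)) covariate <- rep_len(covariate, n)
  value <- 0
  if (grad) {
    grad_psi <- matrix(0, n, ncol(Psi), dimnames = list(NULL, pop$psi_names))
    grad_theta <- stats::setNames(numeric(length(pop$theta_names)),
                                  pop$theta_names)
  }
  for (k in seq_along(pop$components)) {
    cmp <- pop$components[[k]]
    x <- Psi[, k]
    if (cmp$type == "pointmass") next
    if (cmp$type == "lognormal") {
      if (any(x <= 0)) return(neg_inf_result(grad, n, pop))
      m <- theta[[cmp$meanlog]]; s <- theta[[cmp$sdlog]]
      z <- (log(x) - m) / s^2
      value <- value + sum(stats::dlnorm(x, m, s, log = TRUE))
      if (grad) {
        grad_psi[, k] <- -1 / x - z / x
        grad_theta[cmp$meanlog] <- grad_theta[cmp$meanlog] + sum(z)
        grad_theta[cmp$sdlog] <- grad_theta[cmp$sdlog] +
          sum(-1 / s + (log(x) - m)^2 / s^3)
      }
    } else {
      ms <- component_mean_sd(cmp, theta, covariate)
      m <- ms$mean; s <- ms$sd
      z <- (x - m) / s^2
      value <- value + sum(stats::dnorm(x, m, s, log = TRUE))
      if (grad) {
        grad_psi[, k] <- -z
        mean_name <- cmp$mean
        grad_theta[mean_name] <- grad_theta[mean_name] + sum(z)
        if (cmp$type == "covariate_normal")
          grad_theta[cmp$delta] <- grad_theta[cmp$delta] + sum(covariate * z)
        sd_name <- if (cmp$type == "normal") cmp$sd else cmp$sd
        grad_theta[sd_name] <- grad_theta[sd_name] +
          sum(-1 / s + (x - m)^2 / s^3)
      }
    }
  }
  if (!grad) return(value)
  list(value = value, grad_psi = grad_psi, grad_theta = grad_theta)
}

neg_inf_result <- function(grad, n, pop) {
  if (!grad) return(-Inf)
  list(value = -Inf,
       grad_psi = matrix(0, n, length(pop$psi_names)),
       grad_theta = stats::setNames(numeric(length(pop$theta_names)),
                                    pop$theta_names))
}

#' Population density on a grid (for IIV summaries)
#'
#' Evaluates `p(psi | theta)` over the free (non-point-mass) psi dimensions
#' at the rows of `grid`. For covariate models the density is the covariate
#' mixture with the supplied weights.
#'
#' @param pop a [population_model()].
#' @param theta named numeric vector.
#' @param grid matrix with one column per free psi dimension.
#' @param covariate_levels,covariate_weights optional covariate values and
#'   mixture weights (default: single level 0 with weight 1, i.e. no
#'   covariate structure).
#' @return Numeric vector of densities at the grid rows.
#' @export
population_density <- function(pop, theta, grid,
                               covariate_levels = 0,
                               covariate_weights = 1) {
  stopifnot(inherits(pop, "population_model"))
  check_theta(pop, theta)
  grid <- as.matrix(grid)
  free <- pop$psi_free
  stopifnot(ncol(grid) == length(free))
  colnames(grid) <- free
  dens <- numeric(nrow(grid))
  covariate_weights <- covariate_weights / sum(covariate_weights)
  for (g in seq_along(covariate_levels)) {
    d <- rep(1, nrow(grid))
    for (k in seq_along(pop$components)) {
      cmp <- pop$components[[k]]
      if (cmp$type == "pointmass") next
      x <- grid[, pop$psi_names[k]]
      d <- d * switch(cmp$type,
        normal = ,
        covariate_normal = {
          ms <- component_mean_sd(cmp, theta, covariate_levels[g])
          stats::dnorm(x, ms$mean, ms$sd)
        },
        lognormal = stats::dlnorm(x, theta[[cmp$meanlog]], theta[[cmp$sdlog]]))
    }
    dens <- dens + covariate_weights[g] * d
  }
  dens
}
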