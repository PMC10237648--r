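#' @title Model abstractions for NLME inference
#' @description An NLME model bundles a deterministic time-series model
#'   `ybar(psi, t)`, an error model `p(y | ybar, sigma)` and a population
#'   model `p(psi | theta)` describing inter-individual variability (IIV).
#' @name nlme-models
NULL

# ---------------------------------------------------------------------------
# Time-series models
# ---------------------------------------------------------------------------

#' Construct a time-series model
#'
#' A time-series model provides the deterministic output `ybar(psi, t)` for a
#' batch of individuals and its sensitivities with respect to the mechanistic
#' parameters. Calls to `$output()` increment an evaluation counter by the
#' number of individual trajectories simulated; the counter underpins the
#' cost-scaling contracts (N trajectory evaluations per hierarchical
#' likelihood, S per filter likelihood).
#'
#' @param name model name.
#' @param parameter_names names of the mechanistic parameters psi.
#' @param observable_names names of the model outputs.
#' @param simulate function(Psi, times) -> array (n, K, n_obs).
#' @param sensitivities function(Psi, times) -> array (n, K, n_obs, n_par).
#' @param validate optional function(Psi) -> logical; FALSE marks parameter
#'   values outside the model domain (samplers treat them as log-density
#'   -Inf rather than an error).
#' @return A `ts_model` object.
#' @export
ts_model <- function(name, parameter_names, observable_names,
                     simulate, sensitivities, validate = NULL) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  obj <- list(name = name,
              parameter_names = parameter_names,
              observable_names = observable_names,
              n_parameters = length(parameter_names),
              n_observables = length(observable_names),
              simulate = simulate,
              sensitivities = sensitivities,
              validate = validate,
              counter = counter)
  obj$output <- function(Psi, times) {
    Psi <- as_psi_matrix(Psi, parameter_names)
    counter$n <- counter$n + nrow(Psi)
    simulate(Psi, times)
  }
  structure(obj, class = "ts_model")
}

as_psi_matrix <- function(Psi, names) {
  if (is.null(dim(Psi))) Psi <- matrix(Psi, nrow = 1L,
                                       dimnames = list(NULL, names(Psi)))
  if (!is.null(colnames(Psi))) Psi <- Psi[, names, drop = FALSE]
  Psi
}

#' Trajectory evaluation counter
#'
#' @param model a `ts_model` or `nlme_model`.
#' @return Number of individual trajectories simulated since the last reset.
#' @export
eval_count <- function(model) {
  ts <- if (inherits(model, "nlme_model")) model$time_series else model
  ts$counter$n
}

#' @rdname eval_count
#' @export
reset_eval_count <- function(model) {
  ts <- if (inherits(model, "nlme_model")) model$time_series else model
  ts$counter$n <- 0L
  invisible(model)
}

#' Exponential early cancer growth output
#'
#' Tumour volume `y0 * exp(lambda * t)` for initial volume `y0` and growth
#' rate `lambda`, with sensitivities `(exp(lambda t), y0 t exp(lambda t))`.
#'
#' @param psi numeric vector `(y0, lambda)` or an n x 2 matrix.
#' @param t numeric vector of times.
#' @return Matrix (n x length(t)) of tumour volumes.
#' @export
cancer_output <- function(psi, t) {
  vec <- is.null(dim(psi))
  psi <- as_psi_matrix(psi, c("y0", "lambda"))
  out <- psi[, 1L] * exp(outer(psi[, 2L], t))
  if (vec) drop(out) else out
}

#' Early cancer growth time-series model
#' @return A [ts_model()] with parameters `(y0, lambda)` and one observable.
#' @export
cancer_timeseries <- function() {
  ts_model(
    name = "cancer", parameter_names = c("y0", "lambda"),
    observable_names = "volume",
    simulate = function(Psi, times) {
      out <- Psi[, 1L] * exp(outer(Psi[, 2L], times))
      array(out, dim = c(nrow(Psi), length(times), 1L))
    },
    sensitivities = function(Psi, times) {
      e <- exp(outer(Psi[, 2L], times))
      sens <- array(0, dim = c(nrow(Psi), length(times), 1L, 2L))
      sens[, , 1L, 1L] <- e
      sens[, , 1L, 2L] <- Psi[, 1L] * e * rep(times, each = nrow(Psi))
      sens
    })
}

# ---------------------------------------------------------------------------
# EGF receptor model (linear two-state ODE, closed-form solution)
# ---------------------------------------------------------------------------

#' Solve the EGF receptor model
#'
#' Inactive (`c_r`) and active (`c_a`) EGF receptor concentrations follow the
#' linear system
#' \deqn{dc_r/dt = p - k_{on} c_l c_r + k_{off} c_a - k_{deg,r} c_r}
#' \deqn{dc_a/dt = k_{on} c_l c_r - k_{off} c_a - k_{deg,a} c_a}
#' with both concentrations initialised at 0 ng/mL. The system is linear and
#' time-invariant, so it is solved exactly by spectral decomposition of the
#' 2 x 2 rate matrix (the eigenvalues are always real because the
#' off-diagonal product is non-negative); sensitivities with respect to the
#' rates are exact, via the Frechet derivative of the propagator
#' `phi(A) = A^-1 (e^(At) - I)`.
#'
#' @param psi vector `(p, kon)` or n x 2 matrix of cell-specific rates.
#' @param fixed named vector with `koff`, `kdeg_r`, `kdeg_a` (rates shared
#'   across cells).
#' @param c_l extracellular EGF concentration in ng/mL.
#' @param times numeric vector of times (minutes).
#' @param sensitivities logical; also return d(c_r, c_a)/d(p, kon).
#' @return List with matrices `c_r`, `c_a` (n x K) and, when requested,
#'   `sens`, an array (n, K, 2 observables, 2 parameters).
#' @export
egf_solve <- function(psi, fixed, c_l, times, sensitivities = FALSE) {
  psi <- as_psi_matrix(psi, c("p", "kon"))
  rates <- cbind(p = psi[, 1L], kon = psi[, 2L],
                 koff = rep(fixed[["koff"]], nrow(psi)),
                 kdeg_r = rep(fixed[["kdeg_r"]], nrow(psi)),
                 kdeg_a = rep(fixed[["kdeg_a"]], nrow(psi)))
  sol <- egf_rates_solve(rates, c_l, times, sensitivities = sensitivities)
  if (sensitivities) sol$sens <- sol$sens[, , , 1:2, drop = FALSE]
  sol
}

# Full solver over all five rates; `rates` is an n x 5 matrix with columns
# (p, kon, koff, kdeg_r, kdeg_a). Sensitivities cover all five rates.
egf_rates_solve <- function(rates, c_l, times, sensitivities = FALSE) {
  if (any(rates < 0) || c_l < 0) stop("rates must be non-negative")
  p <- rates[, 1L]; kon <- rates[, 2L]; koff <- rates[, 3L]
  kdr <- rates[, 4L]; kda <- rates[, 5L]
  n <- length(p); K <- length(times)

  k1 <- kon * c_l
  a11 <- -(k1 + kdr); a12 <- koff; a21 <- k1; a22 <- -(koff + kda)
  tr <- a11 + a22
  disc <- sqrt((a11 - a22)^2 + 4 * a12 * a21)  # always real: a12*a21 >= 0
  if (any(disc < 1e-10 * pmax(abs(tr), 1)))
    stop("EGF rate matrix has (near-)degenerate eigenvalues; cannot solve")
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2

  phi <- function(l, t) {  # (exp(l t) - 1)/l, safe as l t -> 0
    lt <- outer(l, t)
    ifelse(abs(lt) < 1e-12, rep(t, each = length(l)), expm1(lt) / l)
  }
  p1 <- phi(l1, times); p2 <- phi(l2, times)      # n x K
  alpha <- a11 - l2
  beta <- a22 - l2                                 # alpha + beta = disc
  u_r <- (p1 * alpha - p2 * (a11 - l1)) / disc    # phi(A) e1, first row
  u_a <- a21 * (p1 - p2) / disc                   # phi(A) e1, second row
  out <- list(c_r = p * u_r, c_a = p * u_a)

  if (sensitivities) {
    e1t <- exp(outer(l1, times)); e2t <- exp(outer(l2, times))
    tmat <- matrix(times, n, K, byrow = TRUE)
    dp1 <- (tmat * e1t - p1) / l1                 # d phi / d lambda
    dp2 <- (tmat * e2t - p2) / l2
    phi12 <- (p1 - p2) / disc
    # spectral projectors applied to a 2-vector (per-cell scalars)
    P1y <- function(y1, y2) list((alpha * y1 + a12 * y2) / disc,
                                 (a21 * y1 + beta * y2) / disc)
    P2y <- function(y1, y2) list((beta * y1 - a12 * y2) / disc,
                                 (-a21 * y1 + alpha * y2) / disc)
    u1 <- list(alpha / disc, a21 / disc)          # P1 e1
    u2 <- list(beta / disc, -a21 / disc)          # P2 e1
    # directions B = dA/d(rate); entries may be per-cell constants
    zero <- rep(0, n)
    dirs <- list(
      kon = list(b11 = rep(-c_l, n), b12 = zero, b21 = rep(c_l, n),
                 b22 = zero),
      koff = list(b11 = zero, b12 = rep(1, n), b21 = zero, b22 = rep(-1, n)),
      kdeg_r = list(b11 = rep(-1, n), b12 = zero, b21 = zero, b22 = zero),
      kdeg_a = list(b11 = zero, b12 = zero, b21 = zero, b22 = rep(-1, n)))
    sens <- array(0, dim = c(n, K, 2L, 5L),
                  dimnames = list(NULL, NULL, c("c_r", "c_a"), colnames(rates)))
    sens[, , 1L, 1L] <- u_r                        # d c_r / d p = c_r / p
    sens[, , 2L, 1L] <- u_a
    for (d in seq_along(dirs)) {
      B <- dirs[[d]]
      Bv <- function(y) list(B$b11 * y[[1L]] + B$b12 * y[[2L]],
                             B$b21 * y[[1L]] + B$b22 * y[[2L]])
      x1 <- Bv(u1); x2 <- Bv(u2)
      t11 <- P1y(x1[[1L]], x1[[2L]]); t22 <- P2y(x2[[1L]], x2[[2L]])
      t12 <- P1y(x2[[1L]], x2[[2L]]); t21 <- P2y(x1[[1L]], x1[[2L]])
      w_r <- dp1 * t11[[1L]] + dp2 * t22[[1L]] + phi12 * (t12[[1L]] + t21[[1L]])
      w_a <- dp1 * t11[[2L]] + dp2 * t22[[2L]] + phi12 * (t12[[2L]] + t21[[2L]])
      sens[, , 1L, d + 1L] <- p * w_r
      sens[, , 2L, d + 1L] <- p * w_a
    }
    if (any(!is.finite(sens))) stop("EGF sensitivity computation failed")
    out$sens <- sens
  }
  if (any(!is.finite(out$c_r)) || any(!is.finite(out$c_a)))
    stop("EGF solver produced non-finite concentrations")
  out
}

#' EGF receptor time-series model
#'
#' All five rates are model parameters (shared rates enter as point-mass
#' population components, so gradients with respect to their population
#' means are available); the EGF concentration `c_l` is an experimental
#' condition fixed per dataset.
#'
#' @param c_l EGF concentration (ng/mL) the cells are exposed to.
#' @return A [ts_model()] with parameters `(p, kon, koff, kdeg_r, kdeg_a)`
#'   and observables `c_r`, `c_a`.
#' @export
egf_timeseries <- function(c_l) {
  ts_model(
    name = sprintf("egf(c_l=%g)", c_l),
    parameter_names = c("p", "kon", "koff", "kdeg_r", "kdeg_a"),
    observable_names = c("c_r", "c_a"),
    validate = function(Psi) all(Psi >= 0),
    simulate = function(Psi, times) {
      sol <- egf_rates_solve(Psi, c_l, times)
      out <- array(0, dim = c(nrow(Psi), length(times), 2L))
      out[, , 1L] <- sol$c_r
      out[, , 2L] <- sol$c_a
      out
    },
    sensitivities = function(Psi, times) {
      unname(egf_rates_solve(Psi, c_l, times, sensitivities = TRUE)$sens)
    })
}

# ---------------------------------------------------------------------------
# Error models
# ---------------------------------------------------------------------------

#' Error models
#'
#' Gaussian residual errors, `y ~ N(ybar, sigma^2)`, or lognormal errors
#' centred on the model output (location `log(ybar)`, scale `sigma`, so the
#' model output is the median of the measurement distribution).
#'
#' @param family `"gaussian"` or `"lognormal"`.
#' @return An `error_model` object with elements `family`, `logpdf`,
#'   `logpdf_grad` (gradients w.r.t. `y`, `ybar`, `sigma`) and `sample`.
#' @export
error_model <- function(family = c("gaussian", "lognormal")) {
  family <- match.arg(family)
  if (family == "gaussian") {
    obj <- list(
      family = family,
      logpdf = function(y, ybar, sigma) {
        -0.5 * log(2 * pi * sigma^2) - (y - ybar)^2 / (2 * sigma^2)
      },
      logpdf_grad = function(y, ybar, sigma) {
        z <- (y - ybar) / sigma^2
        list(y = -z, ybar = z, sigma = -1 / sigma + (y - ybar)^2 / sigma^3)
      },
      sample = function(ybar, sigma) {
        ybar + sigma * stats::rnorm(length(ybar))
      },
      support = function(y, ybar) rep(TRUE, length(y)))
  } else {
    obj <- list(
      family = family,
      logpdf = function(y, ybar, sigma) {
        stats::dlnorm(y, meanlog = log(ybar), sdlog = sigma, log = TRUE)
      },
      logpdf_grad = function(y, ybar, sigma) {
        z <- (log(y) - log(ybar)) / sigma^2
        list(y = -1 / y - z / y, ybar = z / ybar,
             sigma = -1 / sigma + (log(y) - log(ybar))^2 / sigma^3)
      },
      sample = function(ybar, sigma) {
        ybar * exp(sigma * stats::rnorm(length(ybar)))
      },
      support = function(y, ybar) y > 0 & ybar > 0)
  }
  structure(obj, class = "error_model")
}

#' Error-model log-density
#'
#' @param model an [error_model()].
#' @param y measurement value(s).
#' @param ybar model output(s).
#' @param sigma noise scale, `sigma > 0`.
#' @return Log-density values (vectorised).
#' @export
error_logpdf <- function(model, y, ybar, sigma) {
  stopifnot(inherits(model, "error_model"))
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (!all(model$support(y, ybar)))
    stop("value outside error-model support (lognormal requires y, ybar > 0)")
  model$logpdf(y, ybar, sigma)
}

#' @rdname error_logpdf
#' @return For `error_logpdf_grad`: list of gradients w.r.t. `y`, `ybar`,
#'   `sigma`.
#' @export
error_logpdf_grad <- function(model, y, ybar, sigma) {
  stopifnot(inherits(model, "error_model"))
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (!all(model$support(y, ybar)))
    stop("value outside error-model support")
  model$logpdf_grad(y, ybar, sigma)
}
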