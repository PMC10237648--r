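#' Synthetic snapshot datasets for the three study designs
#'
#' Seeded generators reproducing the study's data-generating processes.
#' Each individual is measured exactly once (snapshot design); individuals
#' are assigned to time points deterministically in blocks, and ids are
#' zero-padded so lexicographic order equals generation order.
#'
#' `generate_cancer()` draws `15 * m` patients per time point at 6 evenly
#' spaced times on `[0, 0.6]` (time 0 included) from the early cancer
#' growth model with theta = (10, 1, 2, 0.5, 0.8) and Gaussian noise.
#'
#' @param m dataset-size multiplier (1, 3, 9, 27 give N = 90, 270, 810,
#'   2430).
#' @param seed RNG seed.
#' @param theta data-generating parameters (defaults to the study values).
#' @return A [snapshot_dataset()].
#' @export
generate_cancer <- function(m = 1L, seed = NULL,
                            theta = true_theta("cancer")) {
  stopifnot(m >= 1, m == round(m))
  if (!is.null(seed)) set.seed(seed)
  model <- get_model("cancer")
  times <- seq(0, 0.6, length.out = 6L)
  per_time <- 15L * as.integer(m)
  n <- per_time * length(times)
  t_i <- rep(times, each = per_time)
  Psi <- population_sample(model$population, theta, n)
  ybar <- Psi[, "y0"] * exp(Psi[, "lambda"] * t_i)
  y <- ybar + Psi[, "sigma"] * stats::rnorm(n)
  snapshot_dataset(id = sprintf("%05d", seq_len(n)), time = t_i, value = y,
                   observable = "volume")
}

#' @rdname generate_cancer
#'
#' @description
#' `generate_egf()` draws `n_cells` cells with cell-specific (p, kon),
#' exposed to a constant EGF concentration `c_l`, snapshot-measured for
#' both receptor observables over 25 minutes with lognormal noise of scale
#' 0.05; `n_cells / K` cells per time point.
#'
#' @param c_l EGF concentration in ng/mL (the study uses 2 and 10).
#' @param n_cells number of cells (must be divisible by `K`).
#' @param K number of measurement time points on `(0, 25]` minutes.
#' @export
generate_egf <- function(c_l = 2, n_cells = 1200L, K = 6L, seed = NULL,
                         theta = true_theta("egf")) {
  if (n_cells %% K != 0)
    stop("n_cells must be divisible by K (equal cells per time point)")
  if (!is.null(seed)) set.seed(seed)
  model <- get_model("egf", c_l = c_l)
  # measurements start after exposure; receptor levels at t = 0 are exactly
  # 0 ng/mL, where lognormal noise is undefined
  times <- seq(0, 25, length.out = K + 1L)[-1L]
  per_time <- n_cells %/% K
  t_i <- rep(times, each = per_time)
  Psi <- population_sample(model$population, theta, n_cells)
  sol <- egf_rates_solve(Psi[, 1:5, drop = FALSE], c_l, times)
  jj <- rep(seq_len(K), each = per_time)
  ybar_r <- sol$c_r[cbind(seq_len(n_cells), jj)]
  ybar_a <- sol$c_a[cbind(seq_len(n_cells), jj)]
  if (any(ybar_r <= 0) || any(ybar_a <= 0))
    stop("EGF outputs are not positive (c_l = 0 or degenerate rates); ",
         "lognormal measurement noise is undefined")
  sig <- Psi[, "sigma"]
  ids <- sprintf("%05d", seq_len(n_cells))
  y_r <- ybar_r * exp(sig * stats::rnorm(n_cells))
  y_a <- ybar_a * exp(sig * stats::rnorm(n_cells))
  snapshot_dataset(id = c(ids, ids), time = c(t_i, t_i),
                   value = c(y_r, y_a),
                   observable = rep(c("c_r", "c_a"), each = n_cells))
}

#' @rdname generate_cancer
#'
#' @description
#' `generate_bimodal_cancer()` extends the cancer design with two patient
#' subpopulations: a moderate (chi = 0) and an aggressive (chi = 1) cancer
#' variant with covariate-shifted mean growth rate
#' `mu_lambda(chi) = mu_lambda_m + chi * delta_mu_lambda`, theta =
#' (10, 1, 2, 2, 0.5, 0.8). Half the individuals carry each variant,
#' balanced within every time point.
#'
#' @param n_total total number of individuals (divisible by 2 and by 6; the
#'   study uses 120 and 3000).
#' @export
generate_bimodal_cancer <- function(n_total = 120L, seed = NULL,
                                    theta = true_theta("cancer-bimodal")) {
  times <- seq(0, 0.6, length.out = 6L)
  if (n_total %% 2L != 0L || n_total %% length(times) != 0L ||
      (n_total %/% length(times)) %% 2L != 0L)
    stop("n_total must be divisible by 2 and by the number of time points, ",
         "with an even number of individuals per time point")
  if (!is.null(seed)) set.seed(seed)
  model <- get_model("cancer-bimodal")
  per_time <- n_total %/% length(times)
  t_i <- rep(times, each = per_time)
  chi <- rep(rep(0:1, each = per_time %/% 2L), times = length(times))
  Psi <- population_sample(model$population, theta, n_total, covariate = chi)
  ybar <- Psi[, "y0"] * exp(Psi[, "lambda"] * t_i)
  y <- ybar + Psi[, "sigma"] * stats::rnorm(n_total)
  snapshot_dataset(id = sprintf("%05d", seq_len(n_total)), time = t_i,
                   value = y, observable = "volume", covariate = chi)
}
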