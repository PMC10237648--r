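test_that("cancer growth output and sensitivities are exact", {
  expect_equal(cancer_output(c(10, 2), 0), 10)
  expect_equal(cancer_output(c(10, 0), c(0.3, 5, 100)), rep(10, 3))
  expect_equal(cancer_output(c(10, 2), 0.6), 10 * exp(1.2),
               tolerance = 1e-12)

  ts <- cancer_timeseries()
  Psi <- rbind(c(10, 2), c(7, -0.5))
  times <- c(0, 0.2, 0.6)
  sens <- ts$sensitivities(Psi, times)
  for (i in 1:2) for (j in seq_along(times)) {
    fdg <- fd_gradient(function(p) cancer_output(p, times[j]), Psi[i, ])
    expect_lt(max_rel_err(sens[i, j, 1L, ], fdg), 1e-5)
  }
})

test_that("the EGF solver matches the steady state of the linear system", {
  fixed <- c(koff = 8, kdeg_r = 0.25, kdeg_a = 0.015)
  sol <- egf_solve(c(1.7, 1.7), fixed, c_l = 2, times = c(0, 2000))
  # oracle: steady state solves A c = -b for the 2x2 rate matrix
  A <- matrix(c(-(1.7 * 2 + 0.25), 1.7 * 2, 8, -(8 + 0.015)), 2, 2)
  ss <- solve(A, -c(1.7, 0))
  expect_equal(unname(sol$c_r[1, ]), c(0, ss[1L]), tolerance = 1e-8)
  expect_equal(unname(sol$c_a[1, ]), c(0, ss[2L]), tolerance = 1e-8)
  expect_equal(round(ss, 3), c(6.631, 2.813))

  # null system: no production, no ligand
  sol0 <- egf_solve(c(0, 1.7), fixed, c_l = 0, times = c(0, 1, 10))
  expect_equal(unname(sol0$c_r[1, ]), rep(0, 3))
  expect_equal(unname(sol0$c_a[1, ]), rep(0, 3))

  expect_error(egf_solve(c(1, 1), c(koff = -1, kdeg_r = 0, kdeg_a = 0), 2, 1),
               "non-negative")
})

test_that("EGF trajectories agree with a stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  r <- c(p = 1.7, kon = 1.7, koff = 8, kdeg_r = 0.25, kdeg_a = 0.015)
  times <- c(0, 1, 5, 12.5, 25)
  deriv <- function(t, y, p) {
    list(c(p["p"] - p["kon"] * 2 * y[1] + p["koff"] * y[2] -
             p["kdeg_r"] * y[1],
           p["kon"] * 2 * y[1] - p["koff"] * y[2] - p["kdeg_a"] * y[2]))
  }
  o <- deSolve::ode(c(0, 0), times, deriv, r, rtol = 1e-10, atol = 1e-12)
  sol <- egf_solve(r[1:2], r[3:5], c_l = 2, times = times)
  expect_lt(max(abs(sol$c_r[1, ] - o[, 2L])), 1e-7)
  expect_lt(max(abs(sol$c_a[1, ] - o[, 3L])), 1e-7)
})

test_that("EGF sensitivities match finite differences for every rate", {
  r0 <- c(p = 1.7, kon = 1.7, koff = 8, kdeg_r = 0.25, kdeg_a = 0.015)
  times <- c(1, 5, 12.5, 25)
  sol <- snapfilter:::egf_rates_solve(matrix(r0, 1), 2, times,
                                      sensitivities = TRUE)
  for (k in seq_along(r0)) {
    fd_r <- fd_gradient(function(r)
      sum(snapfilter:::egf_rates_solve(matrix(r, 1), 2, times)$c_r), r0)[k]
    fd_a <- fd_gradient(function(r)
      sum(snapfilter:::egf_rates_solve(matrix(r, 1), 2, times)$c_a), r0)[k]
    expect_lt(abs(sum(sol$sens[1, , 1L, k]) - fd_r) / max(abs(fd_r), 1e-8),
              1e-4)
    expect_lt(abs(sum(sol$sens[1, , 2L, k]) - fd_a) / max(abs(fd_a), 1e-8),
              1e-4)
  }
})

test_that("EGF trajectories stay non-negative for non-negative rates", {
  set.seed(11)
  for (rep in 1:20) {
    r <- stats::runif(5, 0.01, 5)
    sol <- egf_solve(r[1:2],
                     c(koff = r[3], kdeg_r = r[4], kdeg_a = r[5]),
                     c_l = stats::runif(1, 0, 10),
                     times = seq(0, 30, length.out = 7))
    expect_gte(min(sol$c_r, sol$c_a), 0)
  }
})

test_that("error model log-densities are exact with exact gradients", {
  g <- error_model("gaussian")
  expect_equal(error_logpdf(g, 1.3, 1.3, 1), -0.5 * log(2 * pi))
  expect_equal(error_logpdf(g, 2, 1, 0.5), dnorm(2, 1, 0.5, log = TRUE))
  eg <- error_logpdf_grad(g, 1.3, 1.0, 0.5)
  fdg <- fd_gradient(function(v) error_logpdf(g, v[1], v[2], v[3]),
                     c(1.3, 1.0, 0.5), h = 1e-6)
  expect_lt(max_rel_err(c(eg$y, eg$ybar, eg$sigma), fdg), 1e-6)

  ln <- error_model("lognormal")
  # the model output is the median of the lognormal measurement distribution
  y <- 2.7
  expect_equal(error_logpdf(ln, y, y, 0.4),
               -log(y) - 0.5 * log(2 * pi * 0.4^2))
  # density integrates to 1
  expect_equal(stats::integrate(function(x)
    exp(error_logpdf(ln, x, 2.7, 0.4)), 0, Inf)$value, 1, tolerance = 1e-6)
  el <- error_logpdf_grad(ln, 3.1, 2.7, 0.4)
  fdl <- fd_gradient(function(v) error_logpdf(ln, v[1], v[2], v[3]),
                     c(3.1, 2.7, 0.4), h = 1e-6)
  expect_lt(max_rel_err(c(el$y, el$ybar, el$sigma), fdl), 1e-6)

  expect_error(error_logpdf(g, 1, 1, -1), "positive")
  expect_error(error_logpdf(ln, -1, 1, 1), "support")
})

test_that("population sampling honours point masses and moments", {
  model <- get_model("cancer")
  theta <- true_theta("cancer")
  Psi <- population_sample(model$population, theta, 200L, seed = 4)
  expect_true(all(Psi[, "sigma"] == 0.8))           # delta(mu_sigma - sigma)
  # CLT bound on the growth-rate mean: mu 2, sd 0.5
  n <- 1e5
  draws <- population_sample(model$population, theta, n, seed = 9)
  expect_lt(abs(mean(draws[, "lambda"]) - 2), 3 * 0.5 / sqrt(n))
  expect_lt(abs(stats::sd(draws[, "y0"]) - 1), 3 / sqrt(n) * 3)

  expect_error(population_sample(model$population,
                                 c(theta[-2], sigma_y0 = -1), 5),
               "positive")
  tiny <- theta; tiny["sigma_lambda"] <- 1e-12
  d2 <- population_sample(model$population, tiny, 10L, seed = 1)
  expect_equal(unname(d2[, "lambda"]), rep(2, 10L), tolerance = 1e-9)
})

test_that("covariate population model shifts the growth-rate mean", {
  model <- get_model("cancer-bimodal")
  theta <- true_theta("cancer-bimodal")
  n <- 4e4
  chi <- rep(0:1, each = n / 2)
  Psi <- population_sample(model$population, theta, n, covariate = chi,
                           seed = 2)
  expect_lt(abs(mean(Psi[chi == 0, "lambda"]) - 2), 3 * 0.5 / sqrt(n / 2))
  expect_lt(abs(mean(Psi[chi == 1, "lambda"]) - 4), 3 * 0.5 / sqrt(n / 2))
})

test_that("simulated outputs converge to the population measurement law", {
  # Monte-Carlo histogram of ybar(psi, t) vs 1-D quadrature of the
  # noise-free population distribution for the cancer model at t = 0.3
  model <- get_model("cancer")
  theta <- true_theta("cancer")
  t0 <- 0.3
  pop_cdf <- function(q) {
    # P(y0 e^{lambda t} <= q) integrated over the population
    vapply(q, function(qq) {
      stats::integrate(function(l)
        stats::pnorm(qq / exp(l * t0), 10, 1) * stats::dnorm(l, 2, 0.5),
        -4, 8, rel.tol = 1e-8)$value
    }, numeric(1L))
  }
  ks <- numeric(2)
  for (i in seq_along(ks)) {
    n <- c(500L, 8000L)[i]
    Psi <- population_sample(model$population, theta, n, seed = 21)
    y <- cancer_output(Psi[, 1:2], t0)[, 1L]
    ks[i] <- max(abs(stats::ecdf(y)(sort(y)) - pop_cdf(sort(y))))
  }
  expect_lt(ks[2L], ks[1L])        # KS distance decreases with n
  expect_lt(ks[2L], 0.02)
})
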