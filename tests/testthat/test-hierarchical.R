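test_that("hierarchical log-likelihood decomposes into closed-form terms", {
  model <- get_model("cancer")
  theta <- c(mu_y0 = 10, sigma_y0 = 1, mu_lambda = 2, sigma_lambda = 0.5,
             mu_sigma = 0.8)
  # one individual measured once at t = 0 with psi = (10, 2, sigma = 0.8)
  d <- snapshot_dataset(id = "1", time = 0, value = 10)
  st <- list(theta = theta, Psi = matrix(c(10, 2), 1,
                                         dimnames = list(NULL,
                                                         c("y0", "lambda"))))
  expected <- dnorm(10, 10, 0.8, log = TRUE) +   # measurement | psi
    dnorm(10, 10, 1, log = TRUE) +               # y0 | population
    dnorm(2, 2, 0.5, log = TRUE)                 # lambda | population
  expect_equal(hierarchical_loglik(d, st, model), expected,
               tolerance = 1e-12)
})

test_that("hierarchical evaluation costs one trajectory per individual", {
  model <- get_model("cancer")
  for (m in c(1L, 3L)) {
    d <- cancer_fixture(m = m)
    theta <- true_theta("cancer")
    Psi <- population_sample(model$population, theta, d$n_individuals,
                             seed = 1)
    reset_eval_count(model)
    hierarchical_loglik(d, list(theta = theta, Psi = Psi[, model$psi_free]),
                        model)
    expect_identical(eval_count(model), d$n_individuals)
  }
})

test_that("posterior handles flat priors and support violations", {
  model <- get_model("cancer")
  d <- cancer_fixture()
  flat <- prior_spec(mu_y0 = prior_uniform(-100, 100),
                     sigma_y0 = prior_uniform(1e-6, 100),
                     mu_lambda = prior_uniform(-100, 100),
                     sigma_lambda = prior_uniform(1e-6, 100),
                     mu_sigma = prior_uniform(1e-6, 100))
  theta <- true_theta("cancer")
  Psi <- population_sample(model$population, theta, d$n_individuals,
                           seed = 2)[, model$psi_free]
  st <- list(theta = theta, Psi = Psi)
  const <- -sum(log(c(200, 100 - 1e-6, 200, 100 - 1e-6, 100 - 1e-6)))
  expect_equal(nlme_logposterior(d, st, model, flat),
               hierarchical_loglik(d, st, model) + const, tolerance = 1e-9)
  st_bad <- st; st_bad$theta["mu_y0"] <- 1000
  expect_identical(nlme_logposterior(d, st_bad, model, flat), -Inf)
})

test_that("packed hierarchical posterior gradient matches finite differences", {
  set.seed(8)
  d <- cancer_fixture()
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  hp <- nlme_posterior(d, model, prior)
  theta <- prior_sample_theta(prior, model)
  Psi <- population_sample(model$population, theta, d$n_individuals)
  x <- hp$pack(theta, Psi[, model$psi_free])
  g <- hp$fn(x)
  ks <- sort(sample(length(x), 40L))
  fdg <- fd_gradient(function(z) hp$fn(z)$lp, x, ks)
  expect_lt(max_rel_err(g$grad[ks], fdg), 1e-5)
  expect_equal(hp$dim, 5L + 90L * 2L)
})

test_that("linear-Gaussian toy recovers the conjugate posterior of the mean", {
  # y_i = psi_i + eps, psi ~ N(mu, 1), eps ~ N(0, sigma = 1 fixed);
  # with a flat prior the marginal posterior of mu is
  # N(mean(y), (1 + 1)/n) by conjugacy
  set.seed(9)
  n <- 40L
  y <- rnorm(n, 1.5, sqrt(2))
  d <- snapshot_dataset(id = sprintf("%03d", 1:n), time = rep(0, n),
                        value = y)
  toy_ts <- ts_model("toy", "psi1", "value",
                     simulate = function(Psi, times)
                       array(Psi[, 1L], dim = c(nrow(Psi), length(times), 1L)),
                     sensitivities = function(Psi, times)
                       array(1, dim = c(nrow(Psi), length(times), 1L, 1L)))
  model <- nlme_model(toy_ts, error_model("gaussian"),
                      population_model(list(
                        psi1 = pop_normal("mu", "sigma_pop"),
                        sigma = pop_pointmass("mu_sigma"))),
                      theta_transforms = c(mu = "identity",
                                           sigma_pop = "log",
                                           mu_sigma = "log"))
  prior <- prior_spec(mu = prior_uniform(-50, 50),
                      sigma_pop = prior_fixed(1),
                      mu_sigma = prior_fixed(1))
  post <- nlme_posterior(d, model, prior)
  x0 <- post$pack(c(mu = 0, sigma_pop = 1, mu_sigma = 1),
                  matrix(y, ncol = 1))
  ch <- sample_posterior(post, "nuts", x0 = x0, n_warmup = 300L,
                         n_main = 700L, seed = 10)
  mu_draws <- posterior_draws(ch)[, 1L]
  se <- sqrt(2 / n)
  mc_se <- sd(mu_draws) / sqrt(max(effective_sample_size(mu_draws), 1))
  expect_lt(abs(mean(mu_draws) - mean(y)), 3 * mc_se + 0.02)
  expect_equal(sd(mu_draws), se, tolerance = 0.2)
})
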