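test_that("stochastic estimates are seeded and cost S evaluations", {
  model <- get_model("cancer")
  theta <- true_theta("cancer")
  f <- filter_spec("gaussian")
  d <- cancer_fixture()
  l1 <- estimate_loglik_stochastic(d, theta, model, f, S = 50, seed = 3)
  l2 <- estimate_loglik_stochastic(d, theta, model, f, S = 50, seed = 3)
  expect_identical(l1, l2)

  # the optimised implementation contract: exactly S trajectory evaluations
  # per likelihood estimate, whatever the dataset size
  for (m in c(1L, 27L)) {
    dm <- cancer_fixture(m = m)
    reset_eval_count(model)
    estimate_loglik_stochastic(dm, theta, model, f, S = 100, seed = 1)
    expect_identical(eval_count(model), 100L)
  }
})

test_that("stochastic estimate approaches the closed-form marginal on a toy", {
  # y = psi + eps with psi ~ N(mu, 1), eps ~ N(0, 1): marginally
  # y ~ N(mu, 2), and the Gaussian filter is exact for large S
  set.seed(12)
  n <- 25L
  y <- rnorm(n, 1, sqrt(2))
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
  theta <- c(mu = 1, sigma_pop = 1, mu_sigma = 1)
  exact <- sum(dnorm(y, 1, sqrt(2), log = TRUE))
  ests <- vapply(1:40, function(s)
    estimate_loglik_stochastic(d, theta, model, filter_spec("gaussian"),
                               S = 10000L, seed = 100 + s), numeric(1L))
  expect_lt(abs(mean(ests) - exact), 3 * sd(ests) / sqrt(length(ests)) + 0.5)
})

test_that("the deterministic state has the documented dimension", {
  d <- cancer_fixture()                       # K = 6 time points
  model <- get_model("cancer")                # 2 free psi, 5 free theta dims
  fp <- filter_posterior(d, model, filter_spec("gaussian"),
                         default_prior("cancer"), S = 100)
  expect_identical(fp$dim, 5L + 100L * 2L + 100L * 6L)
  expect_identical(fp$dim, 805L)
})

test_that("deterministic log-likelihood is reproducible and decomposes", {
  set.seed(13)
  d <- cancer_fixture()
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  f <- filter_spec("gaussian")
  st <- initialize_state(d, model, prior, S = 30, seed = 14)
  v1 <- deterministic_loglik(d, st, model, f)
  v2 <- deterministic_loglik(d, st, model, f)
  expect_identical(v1, v2)                      # bitwise deterministic

  res <- deterministic_loglik(d, st, model, f, grad = TRUE)
  # term (a) equals the independently computed filter data term
  by_time <- split(d$records$value, d$records$time)
  term_a <- sum(vapply(seq_along(d$times), function(j)
    sum(gaussian_filter_logpdf(by_time[[j]], st$Ytilde[, j, 1L])),
    numeric(1L)))
  expect_equal(unname(res$terms["data"]), term_a, tolerance = 1e-10)
  # term (b) is the error model over simulated measurements
  ybar <- cancer_output(st$Psi, d$times)
  term_b <- sum(dnorm(st$Ytilde[, , 1L], ybar, st$theta["mu_sigma"],
                      log = TRUE))
  expect_equal(unname(res$terms["error"]), term_b, tolerance = 1e-10)
  expect_equal(res$value, sum(res$terms), tolerance = 1e-10)
})

test_that("deterministic evaluation costs S evaluations regardless of N", {
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  f <- filter_spec("gaussian")
  for (m in c(1L, 27L)) {
    d <- cancer_fixture(m = m)
    st <- initialize_state(d, model, prior, S = 40, seed = 15)
    reset_eval_count(model)
    deterministic_loglik(d, st, model, f)
    expect_identical(eval_count(model), 40L)
    reset_eval_count(model)
    deterministic_loglik(d, st, model, f, grad = TRUE)
    expect_identical(eval_count(model), 40L)
  }
})

test_that("packed filter-posterior gradients match finite differences", {
  set.seed(16)
  d <- cancer_fixture()
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  for (fam in c("gaussian", "lognormal", "gaussian_mixture",
                "gaussian_kde", "lognormal_kde")) {
    for (par in c("noncentered", "centered")) {
      fp <- filter_posterior(d, model, filter_spec(fam, M = 5), prior,
                             S = 20, parameterization = par)
      x0 <- fp$init(seed = 17)
      g <- fp$fn(x0)
      ks <- sort(sample(fp$dim, 50L))
      fdg <- fd_gradient(function(z) fp$fn(z)$lp, x0, ks)
      expect_lt(max_rel_err(g$grad[ks], fdg), 1e-5)
    }
  }
})

test_that("both parameterizations round-trip states exactly", {
  d <- cancer_fixture()
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  st <- initialize_state(d, model, prior, S = 15, seed = 90)
  for (par in c("noncentered", "centered")) {
    fp <- filter_posterior(d, model, filter_spec("gaussian"), prior,
                           S = 15, parameterization = par)
    st2 <- fp$unpack(fp$pack(st))
    expect_equal(st2$theta, st$theta, tolerance = 1e-12)
    expect_equal(st2$Psi, st$Psi, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(st2$Ytilde, st$Ytilde, tolerance = 1e-10)
  }
})

test_that("deterministic posterior adds the prior on theta only", {
  set.seed(18)
  d <- cancer_fixture()
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  f <- filter_spec("gaussian")
  st <- initialize_state(d, model, prior, S = 25, seed = 19)
  ll <- deterministic_loglik(d, st, model, f, grad = TRUE)
  lp <- deterministic_logposterior(d, st, model, f, prior, grad = TRUE)
  # prior gradient touches only theta dimensions
  expect_equal(lp$grad_Psi, ll$grad_Psi)
  expect_equal(lp$grad_Ytilde, ll$grad_Ytilde)
  expect_false(isTRUE(all.equal(lp$grad_theta, ll$grad_theta)))

  flat <- prior_spec(mu_y0 = prior_uniform(-100, 100),
                     sigma_y0 = prior_uniform(1e-6, 100),
                     mu_lambda = prior_uniform(-100, 100),
                     sigma_lambda = prior_uniform(1e-6, 100),
                     mu_sigma = prior_uniform(1e-6, 100))
  const <- -sum(log(c(200, 100 - 1e-6, 200, 100 - 1e-6, 100 - 1e-6)))
  expect_equal(deterministic_logposterior(d, st, model, f, flat),
               deterministic_loglik(d, st, model, f) + const,
               tolerance = 1e-9)
  st_bad <- st; st_bad$theta["mu_y0"] <- 1e4
  expect_identical(deterministic_logposterior(d, st_bad, model, f, flat),
                   -Inf)
})

test_that("initialised states are reproducible with finite log-posterior", {
  d <- cancer_fixture()
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  s1 <- initialize_state(d, model, prior, S = 30, seed = 20)
  s2 <- initialize_state(d, model, prior, S = 30, seed = 20)
  expect_identical(s1, s2)
  lp <- deterministic_logposterior(d, s1, model, filter_spec("gaussian"),
                                   prior)
  expect_true(is.finite(lp))

  # with theta pinned at truth the population term averages its expectation:
  # E[log p(psi|theta)] for two independent normals is
  # -(1 + log(2 pi sigma1^2))/2 - (1 + log(2 pi sigma2^2))/2
  theta <- true_theta("cancer")
  st <- initialize_state(d, model, prior, S = 4000, seed = 21, theta = theta)
  res <- deterministic_loglik(d, st, model, filter_spec("gaussian"),
                              grad = TRUE)
  expected <- -(1 + log(2 * pi * 1^2)) / 2 - (1 + log(2 * pi * 0.5^2)) / 2
  expect_equal(unname(res$terms["population"]) / 4000, expected,
               tolerance = 0.05)
})

test_that("MAP refinement does not decrease the posterior near the truth", {
  set.seed(22)
  d <- cancer_fixture()
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  fp <- filter_posterior(d, model, filter_spec("gaussian"), prior, S = 20)
  x0 <- fp$init(seed = 23, theta = true_theta("cancer"))
  lp0 <- fp$fn(x0)$lp
  opt <- stats::optim(x0, function(z) -fp$fn(z)$lp,
                      function(z) -fp$fn(z)$grad, method = "L-BFGS-B",
                      control = list(maxit = 50L))
  expect_gte(-opt$value, lp0)
})

test_that("the filter data term tracks the KL divergence to the data", {
  # Eq-18 style property: over a grid of simulated-measurement
  # configurations, the data term is largest where the KL divergence
  # between the empirical data distribution and the filter is smallest
  set.seed(29)
  y <- rnorm(400, 10, 2)
  shifts <- seq(-3, 3, by = 0.5)
  vals <- ranks <- numeric(length(shifts))
  for (i in seq_along(shifts)) {
    yt <- rnorm(100, 10 + shifts[i], 2)
    vals[i] <- sum(gaussian_filter_logpdf(y, yt))
    p <- filter_params(filter_spec("gaussian"), yt)
    # KL(N(10,4) || filter) in closed form
    ranks[i] <- 0.5 * (log(p$variance / 4) +
                       (4 + (10 - p$mean)^2) / p$variance - 1)
  }
  expect_lt(cor(vals, ranks, method = "spearman"), -0.9)
})
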