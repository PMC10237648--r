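test_that("ESS is calibrated on white noise and AR(1) chains", {
  set.seed(52)
  n <- 1e4L
  x <- rnorm(n)
  expect_lt(abs(effective_sample_size(x) - n) / n, 0.1)

  # AR(1) with rho = 0.9: ESS ~ n (1 - rho)/(1 + rho)
  rho <- 0.9
  m <- 1e5L
  ar <- as.numeric(stats::arima.sim(list(ar = rho), m))
  target <- m * (1 - rho) / (1 + rho)
  expect_lt(abs(effective_sample_size(ar) - target) / target, 0.15)

  # duplicating every draw halves the ESS per draw
  dup <- rep(x[1:2000], each = 2L)
  e1 <- effective_sample_size(x[1:2000]) / 2000
  e2 <- effective_sample_size(dup) / 4000
  expect_equal(e2 / e1, 0.5, tolerance = 0.2)

  expect_true(is.na(effective_sample_size(rep(1, 100))))
})

test_that("split R-hat separates mixed from disjoint chains", {
  set.seed(53)
  same <- replicate(4, rnorm(1000), simplify = FALSE)
  expect_equal(rhat(same), 1, tolerance = 0.01)
  apart <- list(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(rhat(apart), 1.5)
  expect_error(rhat(list(rnorm(10))), "two chains")

  # direct-formula oracle on a seeded fixture without rank normalisation:
  # chains drawn from the same normal stay near 1 even after shifting one
  # by a small amount
  mix <- list(rnorm(2000), rnorm(2000, 0.1))
  expect_lt(rhat(mix), 1.1)
})

test_that("population KL quadrature matches Gaussian closed forms", {
  # 1-D unit-variance normals with means 0 and 1: KL = 0.5
  pop <- population_model(list(psi1 = pop_normal("mu", "sd1"),
                               sigma = pop_pointmass("mu_sigma")))
  theta_true <- c(mu = 0, sd1 = 1, mu_sigma = 1)
  draws <- matrix(1, nrow = 1L, dimnames = list(NULL, "mu"))
  res <- kl_population(theta_true, draws, pop,
                       theta_fill = c(sd1 = 1, mu_sigma = 1),
                       n_grid = 2000L, q_span = 8)
  expect_equal(res$kl, 0.5, tolerance = 1e-4)
  expect_gt(res$coverage, 0.999)

  # posterior concentrated at the truth: KL -> 0; and KL >= 0 always
  draws0 <- matrix(0, nrow = 1L, dimnames = list(NULL, "mu"))
  res0 <- kl_population(theta_true, draws0, pop,
                        theta_fill = c(sd1 = 1, mu_sigma = 1),
                        n_grid = 2000L, q_span = 8)
  expect_lt(abs(res0$kl), 1e-6)
  set.seed(54)
  for (mu in rnorm(4)) {
    r <- kl_population(theta_true,
                       matrix(mu, 1, dimnames = list(NULL, "mu")), pop,
                       theta_fill = c(sd1 = 1, mu_sigma = 1),
                       n_grid = 600L, q_span = 8)
    expect_gte(r$kl, -1e-10)
  }
})

test_that("2-D population KL agrees with the closed form for the cancer model", {
  pop <- get_model("cancer")$population
  theta_true <- true_theta("cancer")
  shifted <- theta_true; shifted["mu_lambda"] <- 2.5
  draws <- matrix(shifted[1:4], 1,
                  dimnames = list(NULL, names(shifted)[1:4]))
  res <- kl_population(theta_true, draws, pop,
                       theta_fill = c(mu_sigma = 0.8), n_grid = 300L,
                       q_span = 7)
  # independent components: KL adds; only mu_lambda moved by 0.5 with
  # sd 0.5 -> KL = 0.5 * (0.5/0.5)^2 = 0.5
  expect_equal(res$kl, 0.5, tolerance = 1e-3)
})

test_that("predictive bands reduce to the trajectory in the noiseless limit", {
  model <- get_model("cancer")
  theta <- c(mu_y0 = 10, sigma_y0 = 1e-9, mu_lambda = 2,
             sigma_lambda = 1e-9, mu_sigma = 1e-9)
  draws <- matrix(theta, 1, dimnames = list(NULL, names(theta)))
  band <- predictive_band(draws, model, times = c(0, 0.3),
                          n_per_draw = 50L, seed = 55)
  expect_equal(band[1L, , 1L], rep(10, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(band[2L, , 1L], rep(10 * exp(0.6), 3), tolerance = 1e-5,
               ignore_attr = TRUE)

  # pooled variance at t = 0 under the data-generating parameters is 1.64
  truth <- matrix(true_theta("cancer"), 1,
                  dimnames = list(NULL, names(true_theta("cancer"))))
  set.seed(56)
  Psi <- population_sample(model$population, true_theta("cancer"), 20000L)
  y <- Psi[, "y0"] + Psi[, "sigma"] * rnorm(20000L)
  expect_equal(var(y), 1.64, tolerance = 3 * 1.64 * sqrt(2 / 20000))

  bands <- predictive_band(truth, model, times = seq(0, 0.6, 0.2),
                           percentiles = c(5, 25, 50, 75, 95),
                           n_per_draw = 4000L, seed = 57)
  expect_true(all(diff(bands[1L, , 1L]) > 0))   # quantiles monotone
})

test_that("summary-statistic traces recompute from stored draws exactly", {
  set.seed(58)
  d <- cancer_fixture()
  model <- get_model("cancer")
  prior <- default_prior("cancer")
  fp <- filter_posterior(d, model, filter_spec("gaussian"), prior, S = 15)
  x0 <- fp$init(seed = 59, theta = true_theta("cancer"))
  ch <- sample_posterior(fp, "mh", x0 = x0, n_warmup = 200L, n_main = 300L,
                         scale = 0.02, seed = 60)
  tr <- summary_statistic_trace(ch, fp, j = 6L)
  expect_equal(nrow(tr), 300L)
  # bookkeeping identity: recompute from the raw state of one draw
  dr <- posterior_draws(ch)
  st <- fp$unpack(dr[17L, ])
  expect_equal(tr$mean[17L], mean(st$Ytilde[, 6L, 1L]), tolerance = 1e-12)
  expect_equal(tr$variance[17L], var(st$Ytilde[, 6L, 1L]), tolerance = 1e-12)

  # constant chain collapses to a single point
  ch0 <- sample_posterior(fp, "mh", x0 = x0, n_warmup = 10L, n_main = 20L,
                          scale = 0, seed = 61)
  tr0 <- summary_statistic_trace(ch0, fp, j = 6L)
  expect_equal(length(unique(tr0$mean)), 1L)
})

test_that("prior overlap is near 1 for prior samples and small for shifts", {
  set.seed(62)
  pr <- prior_lognormal(log(0.75), 0.2)
  expect_gt(prior_overlap(pr$sample(20000L), pr), 0.9)
  expect_lt(prior_overlap(pr$sample(20000L) * 3, pr), 0.2)
})
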