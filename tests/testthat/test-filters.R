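test_that("Gaussian filter equals the closed-form normal density", {
  # mean 2, variance 2 from simulations [1, 3]
  expect_equal(gaussian_filter_logpdf(2, c(1, 3)), -0.5 * log(4 * pi),
               tolerance = 1e-12)
  expect_equal(gaussian_filter_logpdf(2, c(1, 3)),
               dnorm(2, 2, sqrt(2), log = TRUE))
  # symmetric simulations: density maximised at zero
  ys <- seq(-3, 3, by = 0.01)
  lp <- gaussian_filter_logpdf(ys, c(-1.7, 1.7))
  expect_equal(ys[which.max(lp)], 0)
  expect_error(gaussian_filter_logpdf(1, 3), "S = 2")
  expect_error(gaussian_filter_logpdf(1, c(2, 2)), "zero variance")
})

test_that("lognormal filter is the Gaussian filter after log transform", {
  # log-domain mean 2, variance 2 from [e, e^3]
  expect_equal(lognormal_filter_logpdf(exp(2), c(exp(1), exp(3))),
               -2 - 0.5 * log(4 * pi), tolerance = 1e-12)
  set.seed(1)
  yt <- rlnorm(40, 1, 0.5)
  y <- rlnorm(9, 1, 0.5)
  expect_equal(lognormal_filter_logpdf(y, yt),
               gaussian_filter_logpdf(log(y), log(yt)) - log(y),
               tolerance = 1e-12)
  # filter median is exp(mean of log simulations)
  med <- exp(mean(log(yt)))
  ps <- filter_params(filter_spec("lognormal"), yt)
  expect_equal(qlnorm(0.5, ps$location, ps$scale), med)
  expect_error(lognormal_filter_logpdf(-1, yt), "positive")
})

test_that("mixture filter matches per-block closed forms", {
  set.seed(2)
  yt <- rnorm(30, 5, 2)
  y <- rnorm(10, 5, 2)
  # M = 1 reduces to the Gaussian filter
  expect_equal(mixture_filter_logpdf(y, yt, M = 1),
               gaussian_filter_logpdf(y, yt), tolerance = 1e-12)
  # two well-separated blocks
  yb <- c(0, 2, 10, 12)
  oracle <- function(v) log(0.5 * dnorm(v, 1, sqrt(2)) +
                            0.5 * dnorm(v, 11, sqrt(2)))
  expect_equal(mixture_filter_logpdf(c(1, 6), yb, M = 2), oracle(c(1, 6)),
               tolerance = 1e-12)
  expect_gt(mixture_filter_logpdf(1, yb, 2), mixture_filter_logpdf(6, yb, 2))
  # density integrates to 1 on a wide grid
  grid <- seq(-40, 60, length.out = 40001)
  dens <- exp(mixture_filter_logpdf(grid, yb, 2))
  expect_equal(sum(dens) * (grid[2] - grid[1]), 1, tolerance = 1e-6)
  expect_error(mixture_filter_logpdf(1, yb, 3), "divisible")
  expect_error(mixture_filter_logpdf(1, yb, 4), "at least 2")
})

test_that("the KDE bandwidth follows the rule of thumb", {
  set.seed(3)
  yt <- rnorm(100)
  yt <- (yt - mean(yt)) / sd(yt)           # unit empirical variance
  expect_equal(kde_bandwidth(yt), (4 / 300)^(2 / 5), tolerance = 1e-12)
  expect_equal(round(kde_bandwidth(yt), 5), 0.17782)
  # homogeneity in the variance, monotone decreasing in S
  expect_equal(kde_bandwidth(3 * yt), 9 * kde_bandwidth(yt))
  expect_gt(kde_bandwidth(yt[1:50] / sd(yt[1:50])),
            kde_bandwidth(yt / sd(yt)))
  expect_error(kde_bandwidth(rep(1, 10)), "zero variance")
})

test_that("KDE filters match naive kernel summation oracles", {
  set.seed(4)
  yt <- rnorm(25, 10, 3)
  y <- rnorm(12, 10, 3)
  b2 <- kde_bandwidth(yt)
  naive <- vapply(y, function(v)
    log(mean(dnorm(v, yt, sqrt(b2)))), numeric(1L))
  expect_equal(gaussian_kde_filter_logpdf(y, yt), naive, tolerance = 1e-12)

  ylt <- rlnorm(25, 2, 0.4)
  yl <- rlnorm(8, 2, 0.4)
  b2l <- kde_bandwidth(ylt, log_domain = TRUE)
  naive_l <- vapply(yl, function(v)
    log(mean(dlnorm(v, log(ylt), sqrt(b2l)))), numeric(1L))
  expect_equal(lognormal_kde_filter_logpdf(yl, ylt), naive_l,
               tolerance = 1e-12)
  # change of variables identity
  expect_equal(lognormal_kde_filter_logpdf(yl, ylt),
               gaussian_kde_filter_logpdf(log(yl), log(ylt)) - log(yl),
               tolerance = 1e-12)
  # normalisation over (0, Inf)
  expect_equal(stats::integrate(function(x)
    exp(lognormal_kde_filter_logpdf(x, ylt)), 0, Inf)$value, 1,
    tolerance = 1e-5)
  # symmetric simulations give a density symmetric about the mean
  ysym <- c(-2, -1, 1, 2)
  g <- seq(0.1, 3, by = 0.1)
  expect_lt(max(abs(gaussian_kde_filter_logpdf(g, ysym) -
                    gaussian_kde_filter_logpdf(-g, ysym))), 1e-10)
  expect_error(gaussian_kde_filter_logpdf(1, rep(2, 5)), "zero variance")
})

test_that("all filter gradients match central finite differences", {
  set.seed(5)
  yt <- rlnorm(20, 1, 0.5)
  y <- rlnorm(7, 1, 0.4)
  specs <- list(filter_spec("gaussian"), filter_spec("lognormal"),
                filter_spec("gaussian_mixture", M = 4),
                filter_spec("gaussian_kde"), filter_spec("lognormal_kde"),
                filter_spec("gaussian_kde", freeze_bandwidth = TRUE))
  for (sp in specs) {
    g <- filter_logpdf_grad(sp, y, yt)
    if (!sp$freeze_bandwidth) {
      fdg <- fd_gradient(function(z) sum(filter_logpdf(sp, y, z)), yt,
                         h = 1e-6)
      expect_lt(max_rel_err(g$grad_ytilde, fdg), 1e-5)
    }
    fdy <- fd_gradient(function(z) sum(filter_logpdf(sp, z, yt)), y,
                       h = 1e-6)
    expect_lt(max_rel_err(g$grad_y, fdy), 1e-5)
  }
  # frozen-bandwidth gradient: kernel-centre terms only
  spf <- filter_spec("gaussian_kde", freeze_bandwidth = TRUE)
  b2 <- kde_bandwidth(yt)
  gf <- filter_logpdf_grad(spf, y, yt)
  manual <- vapply(seq_along(yt), function(s) {
    r <- exp(dnorm(y, yt[s], sqrt(b2), log = TRUE) - log(length(yt)) -
               gaussian_kde_filter_logpdf(y, yt))
    sum(r * (y - yt[s]) / b2)
  }, numeric(1L))
  expect_lt(max_rel_err(gf$grad_ytilde, manual), 1e-10)
})

test_that("log-sum-exp evaluation is stable for extreme arguments", {
  set.seed(6)
  yt <- rnorm(50)
  for (y in c(-1e6, 1e6)) {
    expect_true(is.finite(gaussian_kde_filter_logpdf(y, yt)))
    expect_true(is.finite(mixture_filter_logpdf(y, yt, 5)))
    expect_true(is.finite(gaussian_filter_logpdf(y, yt)))
  }
})

test_that("Gaussian filter parameters converge to the sampling moments", {
  set.seed(7)
  err <- vapply(c(100L, 1600L, 25600L), function(S) {
    p <- filter_params(filter_spec("gaussian"), rnorm(S, 3, 2))
    abs(p$mean - 3) + abs(p$variance - 4)
  }, numeric(1L))
  # error shrinks roughly like 1/sqrt(S): a 16-fold S increase should cut
  # the error substantially
  expect_lt(err[3L], err[1L])
  expect_lt(err[3L], 0.2)
})
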