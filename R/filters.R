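#' Population filters
#'
#' A filter is an approximate density over measurements at one time point,
#' constructed from `S` simulated measurements `Ytilde_j = (y~_1j, ...,
#' y~_Sj)`, and used in place of the intractable population measurement
#' distribution `p(y | theta, t_j)`. Five families are provided:
#'
#' * `"gaussian"` — `N(y | mean(Ytilde), var(Ytilde))` (variance with S-1
#'   denominator), matching the mean and variance of the measurements;
#' * `"lognormal"` — lognormal with location/scale from the log-transformed
#'   simulations, matching the median and spread on the log scale;
#' * `"gaussian_mixture"` — `M` Gaussian kernels with equal weights, the
#'   m-th kernel parameterised by the empirical mean/variance of the m-th
#'   contiguous block of `S/M` simulated individuals (when simulated
#'   individuals carry a covariate, storage order groups by covariate so
#'   kernels can align with subpopulations);
#' * `"gaussian_kde"` — Gaussian kernel density estimate with one kernel per
#'   simulated measurement and rule-of-thumb bandwidth
#'   `b^2 = (4/(3S))^(2/5) * var(Ytilde)`;
#' * `"lognormal_kde"` — lognormal KDE with the bandwidth rule applied to
#'   the log-transformed simulations.
#'
#' All filter log-densities have exact gradients with respect to both the
#' evaluation point and every simulated measurement, including the
#' dependence of the KDE bandwidth on the simulations (disable the latter
#' with `freeze_bandwidth = TRUE`).
#'
#' @param family filter family name.
#' @param M number of mixture kernels (`gaussian_mixture` only); `S` must be
#'   divisible by `M` with at least two individuals per kernel.
#' @param freeze_bandwidth if `TRUE`, KDE gradients treat the bandwidth as a
#'   constant.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(family = c("gaussian", "lognormal",
                                   "gaussian_mixture", "gaussian_kde",
                                   "lognormal_kde"),
                        M = 2L, freeze_bandwidth = FALSE) {
  family <- match.arg(family)
  structure(list(family = family, M = as.integer(M),
                 freeze_bandwidth = freeze_bandwidth,
                 log_domain = family %in% c("lognormal", "lognormal_kde")),
            class = "filter_spec")
}

check_sims <- function(ytilde, positive = FALSE) {
  if (length(ytilde) < 2L) stop("need at least S = 2 simulated measurements")
  if (any(!is.finite(ytilde))) stop("non-finite simulated measurements")
  if (positive && any(ytilde <= 0))
    stop("this filter requires strictly positive simulated measurements")
  if (stats::var(ytilde) <= 0)
    stop("simulated measurements have zero variance")
  invisible(ytilde)
}

logsumexp_rows <- function(w) {
  m <- apply(w, 1L, max)
  m + log(rowSums(exp(w - m)))
}

#' Rule-of-thumb KDE bandwidth
#'
#' `b_j^2 = (4/(3S))^(2/5) * var(Ytilde_j)`, with the empirical variance
#' taken of the log-transformed simulations when `log_domain = TRUE`.
#'
#' @param ytilde simulated measurements at one time point.
#' @param log_domain compute the variance of `log(ytilde)`.
#' @return The squared bandwidth `b^2`.
#' @export
kde_bandwidth <- function(ytilde, log_domain = FALSE) {
  check_sims(ytilde, positive = log_domain)
  x <- if (log_domain) log(ytilde) else ytilde
  if (stats::var(x) <= 0) stop("simulated measurements have zero variance")
  (4 / (3 * length(x)))^(2 / 5) * stats::var(x)
}

#' Filter log-density
#'
#' Evaluates `log p(y | Ytilde)` for a filter family; vectorised over `y`.
#' The convenience wrappers `gaussian_filter_logpdf()` etc. fix the family.
#'
#' @param spec a [filter_spec()].
#' @param y evaluation point(s).
#' @param ytilde vector of S simulated measurements at one time point.
#' @return Numeric vector of log-densities.
#' @export
filter_logpdf <- function(spec, y, ytilde) {
  filter_eval(spec, y, ytilde, grad = FALSE)$logpdf
}

#' @rdname filter_logpdf
#' @export
gaussian_filter_logpdf <- function(y, ytilde)
  filter_logpdf(filter_spec("gaussian"), y, ytilde)

#' @rdname filter_logpdf
#' @export
lognormal_filter_logpdf <- function(y, ytilde)
  filter_logpdf(filter_spec("lognormal"), y, ytilde)

#' @rdname filter_logpdf
#' @param M number of Gaussian kernels.
#' @export
mixture_filter_logpdf <- function(y, ytilde, M)
  filter_logpdf(filter_spec("gaussian_mixture", M = M), y, ytilde)

#' @rdname filter_logpdf
#' @export
gaussian_kde_filter_logpdf <- function(y, ytilde)
  filter_logpdf(filter_spec("gaussian_kde"), y, ytilde)

#' @rdname filter_logpdf
#' @export
lognormal_kde_filter_logpdf <- function(y, ytilde)
  filter_logpdf(filter_spec("lognormal_kde"), y, ytilde)

#' Filter log-density with gradients
#'
#' Returns the summed log-density over the data points together with its
#' gradient with respect to every simulated measurement, and the pointwise
#' gradients with respect to the evaluation points.
#'
#' @inheritParams filter_logpdf
#' @return List with `value` (sum of log-densities), `logpdf` (pointwise),
#'   `grad_y` (d logpdf_i / d y_i) and `grad_ytilde` (d value / d y~_s).
#' @export
filter_logpdf_grad <- function(spec, y, ytilde) {
  filter_eval(spec, y, ytilde, grad = TRUE)
}

#' Filter parameters
#'
#' The deterministic summary parameters a filter derives from the simulated
#' measurements (means/variances, block statistics, or kernel bandwidth).
#'
#' @inheritParams filter_logpdf
#' @return Named list of filter parameters.
#' @export
filter_params <- function(spec, ytilde) {
  stopifnot(inherits(spec, "filter_spec"))
  switch(spec$family,
    gaussian = {
      check_sims(ytilde)
      list(mean = mean(ytilde), variance = stats::var(ytilde))
    },
    lognormal = {
      check_sims(ytilde, positive = TRUE)
      z <- log(ytilde)
      list(location = mean(z), scale = stats::sd(z))
    },
    gaussian_mixture = {
      blocks <- mixture_blocks(ytilde, spec$M)
      list(means = vapply(blocks, mean, numeric(1L)),
           variances = vapply(blocks, stats::var, numeric(1L)))
    },
    gaussian_kde = {
      check_sims(ytilde)
      list(centers = ytilde, bandwidth2 = kde_bandwidth(ytilde))
    },
    lognormal_kde = {
      check_sims(ytilde, positive = TRUE)
      list(locations = log(ytilde),
           bandwidth2 = kde_bandwidth(ytilde, log_domain = TRUE))
    })
}

mixture_blocks <- function(ytilde, M) {
  S <- length(ytilde)
  if (M < 1L || S %% M != 0L)
    stop("S = ", S, " is not divisible by M = ", M)
  nb <- S %/% M
  if (nb < 2L)
    stop("each mixture kernel needs at least 2 simulated individuals ",
         "(use a KDE filter for the M = S limit)")
  split(ytilde, rep(seq_len(M), each = nb))
}

# ---------------------------------------------------------------------------
# Core evaluation (value + gradients) per family
# ---------------------------------------------------------------------------

filter_eval <- function(spec, y, ytilde, grad = FALSE) {
  stopifnot(inherits(spec, "filter_spec"))
  switch(spec$family,
    gaussian = gauss_filter_eval(y, ytilde, grad),
    lognormal = {
      check_sims(ytilde, positive = TRUE)
      if (any(y <= 0)) stop("lognormal filter requires positive y")
      res <- gauss_filter_eval(log(y), log(ytilde), grad)
      res$logpdf <- res$logpdf - log(y)
      res$value <- res$value - sum(log(y))
      if (grad) {
        res$grad_y <- (res$grad_y - 1) / y
        res$grad_ytilde <- res$grad_ytilde / ytilde
      }
      res
    },
    gaussian_mixture = {
      blocks <- mixture_blocks(ytilde, spec$M)
      if (any(vapply(blocks, stats::var, numeric(1L)) <= 0))
        stop("a mixture block has zero variance")
      mixture_filter_eval(y, ytilde, spec$M, grad)
    },
    gaussian_kde = {
      check_sims(ytilde)
      kde_filter_eval(y, ytilde, grad, spec$freeze_bandwidth)
    },
    lognormal_kde = {
      check_sims(ytilde, positive = TRUE)
      if (any(y <= 0)) stop("lognormal KDE filter requires positive y")
      res <- kde_filter_eval(log(y), log(ytilde), grad,
                             spec$freeze_bandwidth)
      res$logpdf <- res$logpdf - log(y)
      res$value <- res$value - sum(log(y))
      if (grad) {
        res$grad_y <- (res$grad_y - 1) / y
        res$grad_ytilde <- res$grad_ytilde / ytilde
      }
      res
    })
}

gauss_filter_eval <- function(y, ytilde, grad) {
  check_sims(ytilde)
  S <- length(ytilde)
  mu <- mean(ytilde)
  v <- stats::var(ytilde)
  logpdf <- -0.5 * log(2 * pi * v) - (y - mu)^2 / (2 * v)
  res <- list(value = sum(logpdf), logpdf = logpdf)
  if (grad) {
    dmu <- sum(y - mu) / v
    dv <- -length(y) / (2 * v) + sum((y - mu)^2) / (2 * v^2)
    res$grad_y <- -(y - mu) / v
    res$grad_ytilde <- dmu / S + dv * 2 * (ytilde - mu) / (S - 1)
  }
  res
}

mixture_filter_eval <- function(y, ytilde, M, grad) {
  blocks <- mixture_blocks(ytilde, M)
  S <- length(ytilde)
  nb <- S %/% M
  mus <- vapply(blocks, mean, numeric(1L))
  vs <- vapply(blocks, stats::var, numeric(1L))
  if (any(vs <= 0)) return(list(value = -Inf, logpdf = rep(-Inf, length(y))))
  # w[i, m] = log(1/M) + log N(y_i | mu_m, v_m)
  w <- -log(M) - 0.5 * log(2 * pi * rep(vs, each = length(y))) -
    outer(y, mus, "-")^2 / (2 * rep(vs, each = length(y)))
  dim(w) <- c(length(y), M)
  logpdf <- logsumexp_rows(w)
  res <- list(value = sum(logpdf), logpdf = logpdf)
  if (grad) {
    r <- exp(w - logpdf)                      # responsibilities
    dev <- outer(y, mus, "-")                  # y_i - mu_m
    vmat <- rep(vs, each = length(y))
    res$grad_y <- rowSums(r * (-dev / vmat))
    dmu <- colSums(r * dev / vmat)
    dv <- colSums(r * (-1 / (2 * vmat) + dev^2 / (2 * vmat^2)))
    gyt <- numeric(S)
    idx <- rep(seq_len(M), each = nb)
    for (m in seq_len(M)) {
      sel <- idx == m
      gyt[sel] <- dmu[m] / nb + dv[m] * 2 * (ytilde[sel] - mus[m]) / (nb - 1)
    }
    res$grad_ytilde <- gyt
  }
  res
}

kde_filter_eval <- function(y, ytilde, grad, freeze_bandwidth = FALSE) {
  S <- length(ytilde)
  cS <- (4 / (3 * S))^(2 / 5)
  v <- stats::var(ytilde)
  if (!is.finite(v) || v <= 0)
    return(list(value = -Inf, logpdf = rep(-Inf, length(y))))
  b2 <- cS * v
  dev <- outer(y, ytilde, "-")               # n x S
  w <- -log(S) - 0.5 * log(2 * pi * b2) - dev^2 / (2 * b2)
  logpdf <- logsumexp_rows(w)
  res <- list(value = sum(logpdf), logpdf = logpdf, bandwidth2 = b2)
  if (grad) {
    r <- exp(w - logpdf)
    res$grad_y <- rowSums(r * (-dev / b2))
    gyt <- colSums(r * dev / b2)             # direct kernel-centre term
    if (!freeze_bandwidth) {
      db2 <- sum(r * (-1 / (2 * b2) + dev^2 / (2 * b2^2)))
      gyt <- gyt + db2 * cS * 2 * (ytilde - mean(ytilde)) / (S - 1)
    }
    res$grad_ytilde <- gyt
  }
  res
}

# Fast sufficient-statistic path for the Gaussian filter data term, used by
# the deterministic posterior when the dataset is large: the summed data
# term and its gradient w.r.t. the simulations only need (n, sum y, sum y^2).
gauss_data_term_stats <- function(stats_j, ytilde, grad = TRUE) {
  S <- length(ytilde)
  mu <- mean(ytilde)
  v <- sum((ytilde - mu)^2) / (S - 1)
  if (!is.finite(v) || v <= 0) return(list(value = -Inf))
  n <- stats_j$n; sy <- stats_j$sy; syy <- stats_j$syy
  q <- syy - 2 * mu * sy + n * mu^2          # sum (y_i - mu)^2
  value <- -0.5 * n * log(2 * pi * v) - q / (2 * v)
  if (!grad) return(list(value = value))
  dmu <- (sy - n * mu) / v
  dv <- -n / (2 * v) + q / (2 * v^2)
  list(value = value,
       grad_ytilde = dmu / S + dv * 2 * (ytilde - mu) / (S - 1))
}
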