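#' MCMC chain results
#'
#' Both samplers return a `chain_result`: a list with `draws` (iterations x
#' dims, warmup included), `names`, `warmup` (number of initial draws to
#' discard), `accept_rate`, `n_lp_evals`, `n_grad_evals`, `seed`,
#' `divergences` (NUTS) and `step_size` (NUTS, post-adaptation).
#' [posterior_draws()] extracts the post-warmup draws.
#'
#' @param chain a `chain_result`.
#' @return For `posterior_draws`: matrix of post-warmup draws.
#' @export
posterior_draws <- function(chain) {
  stopifnot(inherits(chain, "chain_result"))
  chain$draws[seq.int(chain$warmup + 1L, nrow(chain$draws)), , drop = FALSE]
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf(
    "chain_result: %d draws (%d warmup) x %d dims; accept %.2f; %d lp evals\n",
    nrow(x$draws), x$warmup, ncol(x$draws), x$accept_rate, x$n_lp_evals))
  invisible(x)
}

target_lp <- function(target, x) {
  v <- target(x)
  if (is.list(v)) v$lp else v
}

#' Random-walk Metropolis-Hastings sampler
#'
#' Gaussian random-walk proposals with component-wise scales. During the
#' warmup phase an optional global scale factor is adapted towards a target
#' acceptance rate (Robbins-Monro on the log scale) and then frozen.
#'
#' @param target log-density: `function(x)` returning a scalar or a list
#'   with element `lp`.
#' @param x0 starting point (finite target value required).
#' @param n total number of iterations (including warmup).
#' @param scale proposal standard deviation(s), scalar or per-dimension.
#' @param seed optional RNG seed.
#' @param warmup iterations treated as warmup (default `n/2`).
#' @param adapt adapt a global scale factor during warmup.
#' @param adapt_diag additionally adapt the per-dimension scales towards the
#'   running standard deviations of the warmup draws (diagonal adaptive
#'   Metropolis).
#' @param target_accept acceptance rate targeted by the adaptation.
#' @return A `chain_result`.
#' @export
mh_sample <- function(target, x0, n, scale, seed = NULL,
                      warmup = floor(n / 2), adapt = TRUE,
                      adapt_diag = FALSE, target_accept = 0.234) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(x0)
  scale <- rep_len(scale, d)
  n_evals <- 0L
  lp <- target_lp(target, x0); n_evals <- n_evals + 1L
  if (!is.finite(lp)) stop("target is not finite at the starting point")
  draws <- matrix(0, n, d)
  x <- x0
  log_c <- 0
  n_acc <- 0L
  win_start <- 1L
  for (i in seq_len(n)) {
    prop <- x + exp(log_c) * scale * stats::rnorm(d)
    lp_prop <- target_lp(target, prop); n_evals <- n_evals + 1L
    ratio <- lp_prop - lp
    accept <- is.finite(lp_prop) && log(stats::runif(1L)) < ratio
    if (accept) { x <- prop; lp <- lp_prop; n_acc <- n_acc + 1L }
    if (adapt && i <= warmup && any(scale > 0)) {
      a <- if (is.finite(lp_prop)) min(1, exp(ratio)) else 0
      log_c <- log_c + i^(-0.6) * (a - target_accept)
    }
    draws[i, ] <- x
    if (adapt_diag && i <= warmup && i - win_start + 1L >= 500L) {
      w_sd <- apply(draws[win_start:i, , drop = FALSE], 2L, stats::sd)
      upd <- w_sd > 0 & is.finite(w_sd)
      # geometric blend keeps unexplored dimensions near their prior scale
      scale[upd] <- sqrt(scale[upd] * w_sd[upd])
      win_start <- i + 1L
    }
  }
  structure(list(draws = draws, names = names(x0), warmup = warmup,
                 accept_rate = n_acc / n, n_lp_evals = n_evals,
                 n_grad_evals = 0L, seed = seed,
                 scale = exp(log_c) * scale),
            class = "chain_result")
}

#' No-U-Turn sampler with dual-averaging warmup
#'
#' Adaptive Hamiltonian Monte Carlo: step size tuned by dual averaging
#' towards a target acceptance statistic, diagonal mass matrix estimated
#' from warmup draws in expanding windows, and trajectory lengths chosen by
#' the no-U-turn criterion with multiplicative tree doubling. Divergent
#' transitions are counted and reported, not fatal. Every leapfrog step
#' evaluates the log-posterior and its gradient once, so the gradient
#' counter equals the log-posterior counter.
#'
#' @param target `function(x)` returning `list(lp, grad)`.
#' @param x0 starting point with finite log-density and gradient.
#' @param n_warmup adaptation iterations (flagged, excluded by
#'   [posterior_draws()]).
#' @param n_main sampling iterations after warmup.
#' @param seed optional RNG seed.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_treedepth maximum number of tree doublings per iteration.
#' @param inv_mass optional initial diagonal inverse mass matrix (per-
#'   dimension posterior variance guesses); refined during warmup. Scaling
#'   it to the known block scales of a hierarchical state shortens early
#'   trajectories considerably.
#' @return A `chain_result` with `divergences` and the adapted `step_size`.
#' @export
nuts_sample <- function(target, x0, n_warmup = 500L, n_main = 1000L,
                        seed = NULL, target_accept = 0.8,
                        max_treedepth = 10L, inv_mass = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(x0)
  evals <- new.env(parent = emptyenv()); evals$n <- 0L
  f <- function(x) {
    evals$n <- evals$n + 1L
    v <- target(x)
    if (!is.finite(v$lp)) v$grad <- numeric(d)
    v
  }
  cur <- f(x0)
  if (!is.finite(cur$lp)) stop("target is not finite at the starting point")
  inv_mass <- if (is.null(inv_mass)) rep(1, d) else rep_len(inv_mass, d)
  inv_mass[!is.finite(inv_mass) | inv_mass <= 0] <- 1

  leapfrog <- function(x, p, grad, eps) {
    p <- p + 0.5 * eps * grad
    x <- x + eps * inv_mass * p
    v <- f(x)
    p <- p + 0.5 * eps * v$grad
    list(x = x, p = p, lp = v$lp, grad = v$grad)
  }
  joint <- function(lp, p) lp - 0.5 * sum(inv_mass * p^2)

  # step-size heuristic: double/halve until the one-step acceptance crosses 1/2
  find_eps <- function(x, val) {
    eps <- 1
    p <- stats::rnorm(d) / sqrt(inv_mass)
    h0 <- joint(val$lp, p)
    st <- leapfrog(x, p, val$grad, eps)
    dh <- joint(st$lp, st$p) - h0
    if (!is.finite(dh)) dh <- -Inf
    a <- if (dh > log(0.5)) 1 else -1
    for (it in seq_len(60L)) {
      eps <- eps * 2^a
      st <- leapfrog(x, p, val$grad, eps)
      dh <- joint(st$lp, st$p) - h0
      if (!is.finite(dh)) dh <- -Inf
      if ((a == 1 && dh <= log(0.5)) || (a == -1 && dh >= log(0.5))) break
    }
    eps
  }

  n_div <- 0L
  # recursive tree building (slice-sampling variant)
  build_tree <- function(x, p, grad, lp, log_u, dir, depth, eps, h0) {
    if (depth == 0L) {
      st <- leapfrog(x, p, grad, dir * eps)
      h <- joint(st$lp, st$p)
      n_ok <- if (is.finite(h) && log_u <= h) 1L else 0L
      div <- !is.finite(h) || (h - log_u) < -1000
      if (div) n_div <<- n_div + 1L
      alpha <- if (is.finite(h)) min(1, exp(h - h0)) else 0
      return(list(x_minus = st$x, p_minus = st$p, grad_minus = st$grad,
                  lp_minus = st$lp,
                  x_plus = st$x, p_plus = st$p, grad_plus = st$grad,
                  lp_plus = st$lp,
                  x_prop = st$x, lp_prop = st$lp, grad_prop = st$grad,
                  n_ok = n_ok,
                  stop = div, alpha = alpha, n_alpha = 1L))
    }
    t1 <- build_tree(x, p, grad, lp, log_u, dir, depth - 1L, eps, h0)
    if (t1$stop) return(t1)
    if (dir == -1) {
      t2 <- build_tree(t1$x_minus, t1$p_minus, t1$grad_minus, t1$lp_minus,
                       log_u, dir, depth - 1L, eps, h0)
      t1$x_minus <- t2$x_minus; t1$p_minus <- t2$p_minus
      t1$grad_minus <- t2$grad_minus; t1$lp_minus <- t2$lp_minus
    } else {
      t2 <- build_tree(t1$x_plus, t1$p_plus, t1$grad_plus, t1$lp_plus,
                       log_u, dir, depth - 1L, eps, h0)
      t1$x_plus <- t2$x_plus; t1$p_plus <- t2$p_plus
      t1$grad_plus <- t2$grad_plus; t1$lp_plus <- t2$lp_plus
    }
    total <- t1$n_ok + t2$n_ok
    if (t2$n_ok > 0L && stats::runif(1L) < t2$n_ok / total) {
      t1$x_prop <- t2$x_prop; t1$lp_prop <- t2$lp_prop
      t1$grad_prop <- t2$grad_prop
    }
    dx <- t1$x_plus - t1$x_minus
    uturn <- sum(dx * (inv_mass * t1$p_minus)) < 0 ||
      sum(dx * (inv_mass * t1$p_plus)) < 0
    t1$n_ok <- total
    t1$stop <- t2$stop || uturn
    t1$alpha <- t1$alpha + t2$alpha
    t1$n_alpha <- t1$n_alpha + t2$n_alpha
    t1
  }

  n_total <- n_warmup + n_main
  draws <- matrix(0, n_total, d)
  x <- x0
  eps <- find_eps(x, cur)
  # dual averaging state
  mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  da_iter <- 0L
  # mass-matrix windows (Stan-like: init buffer, expanding windows, term buffer)
  windows <- integer(0)
  if (n_warmup >= 60L) {
    init_buf <- max(15L, round(0.15 * n_warmup))
    term_buf <- max(10L, round(0.1 * n_warmup))
    span <- n_warmup - term_buf
    w <- max(20L, round(0.12 * n_warmup))
    pos <- init_buf
    while (pos + w < span) {
      pos <- pos + w
      windows <- c(windows, pos)
      w <- w * 2L
    }
    windows <- c(windows, span)
  }
  win_start <- 1L
  acc_sum <- 0; acc_n <- 0L

  for (i in seq_len(n_total)) {
    p0 <- stats::rnorm(d) / sqrt(inv_mass)
    h0 <- joint(cur$lp, p0)
    log_u <- h0 + log(stats::runif(1L))
    minus <- list(x = x, p = p0, grad = cur$grad, lp = cur$lp)
    plus <- minus
    x_new <- x; lp_new <- cur$lp; grad_new <- cur$grad
    n_ok <- 1L
    alpha <- 0; n_alpha <- 0L
    for (depth in 0:(max_treedepth - 1L)) {
      dir <- if (stats::runif(1L) < 0.5) -1 else 1
      if (dir == -1) {
        t <- build_tree(minus$x, minus$p, minus$grad, minus$lp,
                        log_u, dir, depth, eps, h0)
        minus <- list(x = t$x_minus, p = t$p_minus, grad = t$grad_minus,
                      lp = t$lp_minus)
      } else {
        t <- build_tree(plus$x, plus$p, plus$grad, plus$lp,
                        log_u, dir, depth, eps, h0)
        plus <- list(x = t$x_plus, p = t$p_plus, grad = t$grad_plus,
                     lp = t$lp_plus)
      }
      alpha <- alpha + t$alpha; n_alpha <- n_alpha + t$n_alpha
      if (!t$stop && t$n_ok > 0L &&
          stats::runif(1L) < min(1, t$n_ok / n_ok)) {
        x_new <- t$x_prop; lp_new <- t$lp_prop; grad_new <- t$grad_prop
      }
      n_ok <- n_ok + t$n_ok
      if (t$stop) break
      dx <- plus$x - minus$x
      if (sum(dx * (inv_mass * minus$p)) < 0 ||
          sum(dx * (inv_mass * plus$p)) < 0) break
    }
    x <- x_new
    cur <- list(lp = lp_new, grad = grad_new)
    draws[i, ] <- x
    a_stat <- if (n_alpha > 0L) alpha / n_alpha else 0
    acc_sum <- acc_sum + a_stat; acc_n <- acc_n + 1L
    if (i <= n_warmup) {
      da_iter <- da_iter + 1L
      h_bar <- (1 - 1 / (da_iter + t0)) * h_bar +
        (target_accept - a_stat) / (da_iter + t0)
      log_eps <- mu - sqrt(da_iter) / gamma * h_bar
      w_da <- da_iter^(-kappa)
      log_eps_bar <- w_da * log_eps + (1 - w_da) * log_eps_bar
      eps <- exp(log_eps)
      if (length(windows) && i == windows[1L]) {
        sel <- seq.int(win_start, i)
        if (length(sel) >= 10L) {
          v <- apply(draws[sel, , drop = FALSE], 2L, stats::var)
          nw <- length(sel)
          inv_mass <- (nw / (nw + 5)) * v + (5 / (nw + 5)) * 1e-3
          inv_mass[inv_mass <= 0 | !is.finite(inv_mass)] <- 1e-3
        }
        win_start <- i + 1L
        windows <- windows[-1L]
        eps <- find_eps(x, cur)
        mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0; da_iter <- 0L
      }
      if (i == n_warmup) eps <- exp(log_eps_bar)
    }
  }
  structure(list(draws = draws, names = names(x0), warmup = n_warmup,
                 accept_rate = acc_sum / acc_n,
                 n_lp_evals = evals$n, n_grad_evals = evals$n, seed = seed,
                 divergences = n_div, step_size = eps),
            class = "chain_result")
}

#' Run a sampler on a packed posterior target
#'
#' Convenience wrapper dispatching to [mh_sample()] or [nuts_sample()] for a
#' `posterior_target` built by [nlme_posterior()] or [filter_posterior()].
#'
#' @param post a `posterior_target`.
#' @param sampler `"nuts"` or `"mh"`.
#' @param x0 packed starting point (default: `post$init(seed)` for filter
#'   posteriors).
#' @param n_warmup,n_main iteration budget.
#' @param seed RNG seed.
#' @param ... passed to the sampler.
#' @return A `chain_result` whose `names` are the target's dimension names.
#' @export
sample_posterior <- function(post, sampler = c("nuts", "mh"), x0 = NULL,
                             n_warmup = 500L, n_main = 1000L, seed = NULL,
                             ...) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(post, "posterior_target"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) {
    if (is.null(post$init)) stop("supply x0 for this posterior target")
    x0 <- post$init()
  }
  chain <- if (sampler == "nuts") {
    args <- list(...)
    if (is.null(args$inv_mass) && !is.null(post$scale_hint))
      args$inv_mass <- post$scale_hint(x0)^2
    do.call(nuts_sample, c(list(post$fn, x0, n_warmup = n_warmup,
                                n_main = n_main), args))
  } else {
    lp <- if (!is.null(post$lp)) post$lp else function(x) post$fn(x)$lp
    mh_sample(lp, x0, n = n_warmup + n_main, warmup = n_warmup, ...)
  }
  chain$names <- post$names
  colnames(chain$draws) <- post$names
  chain
}
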