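#' Posterior draws of the population parameters on the natural scale
#'
#' Extracts the free theta columns from a packed chain and undoes the
#' log-scale sampling transform, giving draws directly comparable to the
#' data-generating values.
#'
#' @param chain a `chain_result` from [sample_posterior()].
#' @param post the `posterior_target` it was sampled from.
#' @return Matrix of post-warmup draws, one named column per free theta.
#' @export
theta_draws <- function(chain, post) {
  stopifnot(inherits(post, "posterior_target"))
  draws <- posterior_draws(chain)[, seq_along(post$free_theta), drop = FALSE]
  trans <- post$model$theta_transforms[post$free_theta]
  for (k in which(trans == "log")) draws[, k] <- exp(draws[, k])
  colnames(draws) <- post$free_theta
  draws
}

#' Equal-tailed credible interval
#'
#' @param x posterior samples.
#' @param level interval probability mass (default 0.9).
#' @return Vector `c(lower, upper)`.
#' @export
credible_interval <- function(x, level = 0.9) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE)
}

run_manifest <- function(name, seed, settings, counters) {
  list(experiment = name, seed = seed, settings = settings,
       counters = counters, timestamp = format(Sys.time(), "%Y-%m-%d"))
}

#' Write an experiment result to disk
#'
#' Serialises the chains as CSV (one row per draw) and the manifest as
#' JSON, so diagnostics can be recomputed from the stored output.
#'
#' @param result a result list from one of the `run_*` experiments.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result)) {
    el <- result[[nm]]
    if (inherits(el, "chain_result")) {
      utils::write.csv(as.data.frame(el$draws),
                       file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    } else if (inherits(el, "snapshot_dataset")) {
      write_dataset(el, file.path(dir, paste0(nm, ".csv")))
    }
  }
  if (!is.null(result$manifest)) {
    jsonlite::write_json(result$manifest,
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Early cancer growth: filter inference versus traditional NLME
#'
#' Generates a cancer snapshot dataset of `90 * m` individuals, runs filter
#' inference (Gaussian filter, deterministic posterior) and optionally the
#' traditional hierarchical NLME baseline on the same data, and summarises
#' parameter recovery.
#'
#' @param m dataset-size multiplier (N = 90 m).
#' @param S simulated individuals for the filter.
#' @param sampler `"nuts"` or `"mh"`.
#' @param seed RNG seed (drives data generation and sampling).
#' @param n_warmup,n_main sampler budget (defaults are the scaled-down
#'   working budget; the full study budget is 500 + 1000).
#' @param run_traditional also run the hierarchical NLME baseline
#'   (default: only for m = 1, where it is comfortably tractable).
#' @param prior prior specification.
#' @param ... further arguments for [sample_posterior()] (e.g.
#'   `target_accept`).
#' @return List with the dataset, chains, natural-scale theta draws, 90%
#'   credible intervals, the mu_sigma prior overlap, and a manifest.
#' @export
run_cancer_comparison <- function(m = 1L, S = 100L, sampler = "nuts",
                                  seed = 1L, n_warmup = 200L, n_main = 300L,
                                  run_traditional = (m == 1L),
                                  prior = default_prior("cancer"), ...) {
  set.seed(seed)
  d <- generate_cancer(m = m)
  model <- get_model("cancer")
  fpost <- filter_posterior(d, model, filter_spec("gaussian"), prior, S)
  reset_eval_count(model)
  x0 <- fpost$init()
  chain <- sample_posterior(fpost, sampler, x0 = x0,
                            n_warmup = n_warmup, n_main = n_main, ...)
  td <- theta_draws(chain, fpost)
  ci <- apply(td, 2L, credible_interval)
  overlap <- prior_overlap(td[, "mu_sigma"], prior$mu_sigma)
  res <- list(dataset = d, filter_chain = chain, filter_post = fpost,
              filter_theta = td, filter_ci = ci,
              mu_sigma_prior_overlap = overlap)
  counters <- list(filter_evals = eval_count(model))
  if (run_traditional) {
    tmodel <- get_model("cancer")
    tpost <- nlme_posterior(d, tmodel, prior)
    theta0 <- prior_sample_theta(prior, tmodel)
    Psi0 <- population_sample(tmodel$population, theta0, d$n_individuals)
    x0t <- tpost$pack(theta0, Psi0[, tmodel$psi_free, drop = FALSE])
    tchain <- sample_posterior(tpost, sampler, x0 = x0t,
                               n_warmup = n_warmup, n_main = n_main, ...)
    res$traditional_chain <- tchain
    res$traditional_post <- tpost
    res$traditional_theta <- theta_draws(tchain, tpost)
    res$traditional_ci <- apply(res$traditional_theta, 2L, credible_interval)
    counters$traditional_evals <- eval_count(tmodel)
  }
  res$manifest <- run_manifest(
    "cancer-comparison", seed,
    list(m = m, S = S, sampler = sampler, n_warmup = n_warmup,
         n_main = n_main, run_traditional = run_traditional), counters)
  res
}

#' EGF pathway inference from pooled low/high-concentration snapshots
#'
#' Generates the two EGF datasets (c_l = 2 and 10 ng/mL, `n_cells` each),
#' pools them in one deterministic filter posterior with Gaussian filters
#' and shared population parameters, and infers the model parameters with
#' the noise scale fixed to its data-generating value. Optionally the
#' deactivation rate koff is also fixed, which resolves the kon-koff
#' identifiability problem.
#'
#' @param S simulated cells per condition.
#' @param sampler,seed,n_warmup,n_main as in [run_cancer_comparison()].
#' @param n_cells cells per dataset (study value 1200).
#' @param K measurement time points.
#' @param fix_koff fix mu_koff to the data-generating value 8.
#' @param prior prior specification.
#' @return List with datasets, chain, theta draws, the mu_kon/mu_koff
#'   posterior correlation (free-koff runs), credible intervals and a
#'   manifest.
#' @export
run_egf <- function(S = 100L, sampler = "nuts", seed = 1L,
                    n_warmup = 200L, n_main = 300L,
                    n_cells = 1200L, K = 6L, fix_koff = FALSE,
                    prior = default_prior("egf"), ...) {
  set.seed(seed)
  d_low <- generate_egf(c_l = 2, n_cells = n_cells, K = K)
  d_high <- generate_egf(c_l = 10, n_cells = n_cells, K = K)
  m_low <- get_model("egf", c_l = 2)
  m_high <- get_model("egf", c_l = 10)
  if (fix_koff) prior$mu_koff <- prior_fixed(true_theta("egf")[["mu_koff"]])
  fpost <- filter_posterior(list(d_low, d_high), list(m_low, m_high),
                            filter_spec("gaussian"), prior, S)
  # start theta at the prior centre: random prior draws of the rate means
  # frequently strand the sampler in a stiff region of the EGF posterior
  x0 <- fpost$init(theta = snapfilter:::prior_center_theta(prior, m_low))
  chain <- sample_posterior(fpost, sampler, x0 = x0,
                            n_warmup = n_warmup, n_main = n_main, ...)
  td <- theta_draws(chain, fpost)
  res <- list(data_low = d_low, data_high = d_high, chain = chain,
              post = fpost, theta = td,
              ci = apply(td, 2L, credible_interval))
  if (!fix_koff)
    res$kon_koff_correlation <- stats::cor(td[, "mu_kon"], td[, "mu_koff"])
  res$manifest <- run_manifest(
    "egf", seed,
    list(S = S, sampler = sampler, n_warmup = n_warmup, n_main = n_main,
         n_cells = n_cells, K = K, fix_koff = fix_koff),
    list(evals = eval_count(m_low) + eval_count(m_high)))
  res
}

#' Filter-choice bias study on the bimodal covariate cancer model
#'
#' Generates a bimodal (two cancer variant) snapshot dataset and infers the
#' covariate-aware population model with each requested filter. Simulated
#' individuals carry balanced covariates, stored grouped by covariate so
#' mixture-filter kernels can align with the subpopulations. Reports, per
#' filter, the KL divergence between the data-generating population
#' distribution and the posterior-averaged inferred distribution, and the
#' sigma_lambda posterior mean (KDE filters underestimate the IIV).
#'
#' @param filters named list of [filter_spec()] objects.
#' @param n_total dataset size (study values: 120 and 3000).
#' @param S simulated individuals.
#' @param sampler,seed,n_warmup,n_main sampling settings.
#' @param prior prior specification.
#' @return List with the dataset and a per-filter list of chains, KL values
#'   and posterior summaries, plus a manifest.
#' @export
run_filter_bias_study <- function(filters = list(
                                    gaussian = filter_spec("gaussian"),
                                    mixture2 = filter_spec("gaussian_mixture",
                                                           M = 2),
                                    gaussian_kde = filter_spec("gaussian_kde"),
                                    lognormal_kde =
                                      filter_spec("lognormal_kde")),
                                  n_total = 120L, S = 100L,
                                  sampler = "nuts", seed = 1L,
                                  n_warmup = 200L, n_main = 300L,
                                  prior = default_prior("cancer-bimodal"),
                                  ...) {
  set.seed(seed)
  d <- generate_bimodal_cancer(n_total = n_total)
  model <- get_model("cancer-bimodal")
  truth <- true_theta("cancer-bimodal")
  sim_cov <- rep(0:1, each = S %/% 2L)
  out <- list(dataset = d, results = list())
  for (nm in names(filters)) {
    fpost <- filter_posterior(d, model, filters[[nm]], prior, S,
                              sim_covariate = sim_cov)
    x0 <- fpost$init()
    chain <- sample_posterior(fpost, sampler, x0 = x0,
                              n_warmup = n_warmup, n_main = n_main, ...)
    td <- theta_draws(chain, fpost)
    kl <- kl_population(truth, td, model$population,
                        covariate_levels = 0:1,
                        covariate_weights = c(0.5, 0.5),
                        thin = max(1L, nrow(td) %/% 100L))
    out$results[[nm]] <- list(
      chain = chain, post = fpost, theta = td, kl = kl$kl,
      sigma_lambda_mean = mean(td[, "sigma_lambda"]),
      theta_mean = colMeans(td))
  }
  out$manifest <- run_manifest(
    "filter-bias", seed,
    list(filters = names(filters), n_total = n_total, S = S,
         sampler = sampler, n_warmup = n_warmup, n_main = n_main),
    list())
  out
}

#' Information loss versus the number of simulated individuals
#'
#' Runs Gaussian-filter inference on one large cancer dataset with a sweep
#' of S values; fewer simulated individuals lose more information, visible
#' as larger KL divergence to the data-generating population distribution
#' and inflated IIV estimates.
#'
#' @param S_values numbers of simulated individuals to sweep.
#' @param m dataset-size multiplier (study value 27, N = 2430).
#' @param sampler,seed,n_warmup,n_main sampling settings.
#' @param prior prior specification.
#' @return List with the dataset and per-S results (KL, posterior means),
#'   plus a manifest.
#' @export
run_S_sweep <- function(S_values = c(3L, 10L, 100L, 500L), m = 27L,
                        sampler = "nuts", seed = 1L,
                        n_warmup = 200L, n_main = 300L,
                        prior = default_prior("cancer"), ...) {
  set.seed(seed)
  d <- generate_cancer(m = m)
  model <- get_model("cancer")
  truth <- true_theta("cancer")
  out <- list(dataset = d, results = list())
  for (S in S_values) {
    fpost <- filter_posterior(d, model, filter_spec("gaussian"), prior, S)
    x0 <- fpost$init()
    chain <- sample_posterior(fpost, sampler, x0 = x0,
                              n_warmup = n_warmup, n_main = n_main, ...)
    td <- theta_draws(chain, fpost)
    kl <- kl_population(truth, td, model$population,
                        thin = max(1L, nrow(td) %/% 100L))
    out$results[[paste0("S", S)]] <- list(
      S = S, kl = kl$kl, theta_mean = colMeans(td),
      sigma_y0_mean = mean(td[, "sigma_y0"]))
  }
  out$manifest <- run_manifest(
    "S-sweep", seed,
    list(S_values = S_values, m = m, sampler = sampler,
         n_warmup = n_warmup, n_main = n_main), list())
  out
}
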