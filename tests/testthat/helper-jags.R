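# MCMC oracle: fits the same Poisson multiple-membership likelihood in JAGS
# (vague uniform priors on random-effect SDs) and returns 95% credible
# intervals for the shared parameters. Used only as an independent
# cross-check of the Laplace fit.

mcmc_oracle_intervals <- function(observed, expected, structure,
                                  variant = "A", n_iter = 8000,
                                  n_burn = 2000) {
  n <- length(observed)
  dat <- list(O = observed, logE = log(expected),
              Z = as.matrix(structure$Z), n = n)
  if (variant == "B") {
    dat$g <- as.integer(structure$third_level)
    dat$K <- nlevels(structure$third_level)
    model <- "model {
      for (i in 1:n) {
        O[i] ~ dpois(mu[i])
        log(mu[i]) <- logE[i] + alpha + u[i] + inprod(Z[i,], vstar[]) + w[g[i]]
        u[i] ~ dnorm(0, tau_u)
        vstar[i] ~ dnorm(0, tau_v)
      }
      for (k in 1:K) { w[k] ~ dnorm(0, tau_w) }
      alpha ~ dnorm(0, 0.01)
      s_u ~ dunif(0, 4); s_v ~ dunif(0, 4); s_w ~ dunif(0, 4)
      tau_u <- 1/(s_u*s_u); tau_v <- 1/(s_v*s_v); tau_w <- 1/(s_w*s_w)
      s2_u <- s_u*s_u; s2_v <- s_v*s_v; s2_w <- s_w*s_w
    }"
    vars <- c("alpha", "s2_u", "s2_v", "s2_w")
  } else {
    model <- "model {
      for (i in 1:n) {
        O[i] ~ dpois(mu[i])
        log(mu[i]) <- logE[i] + alpha + u[i] + inprod(Z[i,], vstar[])
        u[i] ~ dnorm(0, tau_u)
        vstar[i] ~ dnorm(0, tau_v)
      }
      alpha ~ dnorm(0, 0.01)
      s_u ~ dunif(0, 4); s_v ~ dunif(0, 4)
      tau_u <- 1/(s_u*s_u); tau_v <- 1/(s_v*s_v)
      s2_u <- s_u*s_u; s2_v <- s_v*s_v
    }"
    vars <- c("alpha", "s2_u", "s2_v")
  }
  jm <- rjags::jags.model(
    textConnection(model), data = dat, n.chains = 2,
    inits = list(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
                 list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)),
    quiet = TRUE)
  update(jm, n_burn, progress.bar = "none")
  sm <- rjags::coda.samples(jm, vars, n.iter = n_iter, progress.bar = "none")
  draws <- do.call(rbind, lapply(sm, as.matrix))
  apply(draws, 2, stats::quantile, c(0.025, 0.975))
}

# One small validation instance: synthetic data (strong variance signal so
# ML estimates are interior), Laplace fit, and the oracle intervals.
oracle_instance <- function(n_areas, seed, variant, sigma2_u, sigma2_v,
                            sigma2_w = 0, n_asl = 5) {
  cfg <- synthetic_config(
    n_areas = n_areas, seed = seed, sigma2_u = sigma2_u,
    sigma2_v = sigma2_v, sigma2_w = sigma2_w, n_asl = n_asl,
    n_risk_areas = min(3L, n_areas),
    third_level = if (variant == "B") "asl" else "none",
    region_extent = c(60, 60), population_range = c(30000, 100000))
  syn <- simulate_area_table(cfg)
  ra <- fit_risk_model(syn$strata)
  ord <- match(syn$areas$area_id, names(ra$expected))
  O <- as.numeric(ra$observed[ord])
  E <- as.numeric(ra$expected[ord])
  fit <- fit_poisson_mmm(O, E, syn$structure, variant)
  ci <- mcmc_oracle_intervals(O, E, syn$structure, variant)
  est <- c(alpha = fit$alpha, s2_u = unname(fit$sigma2["u"]),
           s2_v = unname(fit$sigma2["v"]))
  if (variant == "B") est <- c(est, s2_w = unname(fit$sigma2["w"]))
  list(estimates = est, intervals = ci)
}
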