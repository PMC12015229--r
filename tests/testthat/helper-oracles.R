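# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: brute-force enumeration for the
# marginalized likelihood, and a plainly coded WAIC formula.

brute_force_site_loglik <- function(counts, lambda, p, K) {
  s <- 0
  for (N in max(counts):K)
    s <- s + dpois(N, lambda) * prod(dbinom(counts, N, p))
  log(s)
}

reference_waic <- function(ll) {
  # naive formulation, no log-sum-exp stabilization
  lppd <- sum(log(apply(exp(ll), 2, mean)))
  p_waic <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

# small valid raw tables for io/prep tests
tiny_sites <- function(n = 4, seed = 11) generate_site_covariates(n, seed)

tiny_surveys <- function(sites, n_surveys = 2, seed = 12) {
  sv <- generate_survey_covariates(sites, n_surveys, seed)
  sv$count <- seq_len(nrow(sv)) %% 4L
  sv
}

# a minimal deterministic fit for summary/selection plumbing tests
toy_fit <- function(counts = matrix(c(2L, 3L, 1L, 2L), 2, 2),
                    seed = 42, chains = 2, iterations = 600,
                    burnin = 300, thin = 1, random_effect = TRUE) {
  spec <- nmix_model_spec("toy", random_effect = random_effect)
  data <- list(counts = counts,
               X = matrix(1, nrow(counts), 1,
                          dimnames = list(NULL, "Intercept")),
               W = matrix(1, nrow(counts) * ncol(counts), 1,
                          dimnames = list(NULL, "Intercept")))
  fit <- fit_mcmc(spec, data,
                  mcmc_config(chains = chains, iterations = iterations,
                              burnin = burnin, thin = thin), seed = seed)
  list(fit = fit, data = data)
}
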