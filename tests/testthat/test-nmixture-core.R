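test_that("closed-form limits of the marginalized likelihood are exact", {
  # perfect detection collapses to the Poisson pmf at the shared count
  expect_equal(site_log_likelihood(c(2, 2), 2, c(1, 1)),
               log(2 * exp(-2)), tolerance = 1e-12)
  expect_equal(site_log_likelihood(c(5, 5, 5), 3.7, c(1, 1, 1)),
               dpois(5, 3.7, log = TRUE), tolerance = 1e-12)
  # all-zero counts: exp(-lambda (1 - prod(1 - p_j)))
  expect_equal(site_log_likelihood(c(0, 0), 2, c(0.5, 0.5)),
               -2 * (1 - 0.25), tolerance = 1e-12)
  expect_equal(site_log_likelihood(c(0, 0, 0), 7, c(0.2, 0.6, 0.9)),
               -7 * (1 - 0.8 * 0.4 * 0.1), tolerance = 1e-12)
})

test_that("marginalized likelihood equals brute-force enumeration", {
  expect_equal(site_log_likelihood(c(3, 1), 4, c(0.5, 0.4), K = 60),
               brute_force_site_loglik(c(3, 1), 4, c(0.5, 0.4), 60),
               tolerance = 1e-10)
  set.seed(101)
  for (i in 1:400) {
    J <- sample(1:4, 1)
    lambda <- runif(1, 0.05, 40)
    p <- runif(J)
    counts <- rpois(J, lambda * p)
    K <- max(counts) + sample(40:100, 1)
    expect_equal(site_log_likelihood(counts, lambda, p, K),
                 brute_force_site_loglik(counts, lambda, p, K),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to survey order within a site", {
  set.seed(5)
  for (i in 1:20) {
    counts <- rpois(3, 4)
    p <- runif(3)
    perm <- sample(3)
    expect_equal(site_log_likelihood(counts, 6, p),
                 site_log_likelihood(counts[perm], 6, p[perm]),
                 tolerance = 1e-12)
  }
})

test_that("increasing K beyond convergence leaves the likelihood stable", {
  counts <- c(4, 2)
  p <- c(0.3, 0.5)
  base <- site_log_likelihood(counts, 8, p, K = 120)
  for (K in c(150, 300, 1000))
    expect_equal(site_log_likelihood(counts, 8, p, K = K), base,
                 tolerance = 1e-10)
  # adaptive choice agrees with a generously truncated sum
  expect_equal(site_log_likelihood(counts, 8, p), base, tolerance = 1e-10)
})

test_that("likelihood input validation catches domain violations", {
  expect_error(site_log_likelihood(c(3, 1), 4, c(0.5, 0.4), K = 2),
               "max\\(counts\\)")
  expect_error(site_log_likelihood(c(3, 1), -1, c(0.5, 0.4)), "positive")
  expect_error(site_log_likelihood(c(3, 1), 4, c(0.5, 1.4)), "\\[0, 1\\]")
  expect_error(site_log_likelihood(c(-1, 1), 4, c(0.5, 0.4)),
               "non-negative")
})

test_that("log prior has the stated closed form and support", {
  spec <- nmix_model_spec("m", random_effect = FALSE)
  params <- list(alpha = c(0, 0), beta = c(0, 0, 0))
  expect_equal(log_prior(params, spec), 5 * dnorm(0, 0, 10, log = TRUE),
               tolerance = 1e-12)
  # moving any coefficient away from 0 cannot raise the prior
  p2 <- params; p2$beta[1] <- 2
  expect_lt(log_prior(p2, spec), log_prior(params, spec))
  spec_re <- nmix_model_spec("m2", random_effect = TRUE)
  pr <- list(alpha = 0, beta = 0, sigma_eps = -1, eps = c(0, 0))
  expect_identical(log_prior(pr, spec_re), -Inf)
  pr$sigma_eps <- 0.5
  expect_equal(log_prior(pr, spec_re),
               2 * dnorm(0, 0, 10, log = TRUE) +
                 dnorm(0.5, 0, 2.5, log = TRUE) + log(2) +
                 2 * dnorm(0, 0, 0.5, log = TRUE),
               tolerance = 1e-12)
})

test_that("link predictions apply log and logit links", {
  X <- cbind(Intercept = rep(1, 3), x = c(-1, 0, 1))
  W <- cbind(Intercept = rep(1, 6), y = rep(c(-1, 1), 3))
  d <- list(X = X, W = W)
  out <- link_predictions(list(alpha = c(0, 0), beta = c(0, 0)), d)
  expect_equal(out$lambda, rep(1, 3))
  expect_equal(as.vector(out$p), rep(0.5, 6))
  # negative slope: p strictly decreasing in the covariate
  out2 <- link_predictions(list(alpha = c(0, -1), beta = c(0, 0)), d)
  expect_true(all(out2$p[, 1] > out2$p[, 2]))
  expect_error(link_predictions(list(alpha = c(0, 0, 0), beta = c(0, 0)),
                                d), "match")
})

test_that("identical seeds reproduce the MCMC draws exactly", {
  tf1 <- toy_fit(seed = 7)
  tf2 <- toy_fit(seed = 7)
  expect_identical(tf1$fit$chains, tf2$fit$chains)
  tf3 <- toy_fit(seed = 8)
  expect_false(identical(tf1$fit$chains, tf3$fit$chains))
})

test_that("posterior matches 1-D quadrature on an intercept-only toy", {
  # single site, single survey, p fixed and known: the marginal count is
  # Poisson(lambda * p), so the exact posterior of beta0 is available by
  # quadrature against the Normal(0, 10) prior
  cnt <- matrix(4L, 1, 1)
  spec <- nmix_model_spec("toy", random_effect = FALSE)
  data <- list(counts = cnt,
               X = matrix(1, 1, 1, dimnames = list(NULL, "Intercept")),
               W = matrix(1, 1, 1, dimnames = list(NULL, "Intercept")))
  fit <- fit_mcmc(spec, data,
                  mcmc_config(chains = 2, iterations = 20000,
                              burnin = 4000, thin = 2),
                  seed = 3, fixed_alpha = qlogis(0.5))
  lam_mcmc <- mean(exp(pooled_draws(fit)[, "beta_Intercept"]))
  b <- seq(-12, 12, length.out = 40001)
  post <- dpois(4, exp(b) * 0.5) * dnorm(b, 0, 10)
  lam_quad <- sum(exp(b) * post) / sum(post)
  expect_equal(lam_mcmc, lam_quad, tolerance = 0.02)
})

test_that("posterior matches dense grid integration with known detection", {
  # p = 1 (alpha fixed at a huge logit), two sites, intercept + slope:
  # compare against 2-D grid integration of the exact posterior
  cnt <- matrix(c(3L, 7L), 2, 1)
  spec <- nmix_model_spec("toy", random_effect = FALSE)
  X <- cbind(Intercept = c(1, 1), x = c(-1, 1))
  data <- list(counts = cnt, X = X,
               W = matrix(1, 2, 1, dimnames = list(NULL, "Intercept")))
  fit <- fit_mcmc(spec, data,
                  mcmc_config(chains = 2, iterations = 20000,
                              burnin = 4000, thin = 2),
                  seed = 4, fixed_alpha = 20)
  dr <- pooled_draws(fit)
  g <- seq(-4, 4, length.out = 801)
  grid <- expand.grid(b0 = g, b1 = g)
  lp <- dpois(3, exp(grid$b0 - grid$b1), log = TRUE) +
    dpois(7, exp(grid$b0 + grid$b1), log = TRUE) +
    dnorm(grid$b0, 0, 10, log = TRUE) + dnorm(grid$b1, 0, 10, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  expect_equal(mean(dr[, "beta_Intercept"]), sum(grid$b0 * w),
               tolerance = 0.03)
  expect_equal(mean(dr[, "beta_x"]), sum(grid$b1 * w), tolerance = 0.03)
  expect_equal(sd(dr[, "beta_Intercept"]),
               sqrt(sum(grid$b0^2 * w) - sum(grid$b0 * w)^2),
               tolerance = 0.05)
})

test_that("posterior lambda concentrates near mean(count)/p at many sites", {
  set.seed(30)
  n <- 400
  p_true <- 0.6
  N <- rpois(n, 9)
  cnt <- matrix(rbinom(n, N, p_true), n, 1)
  spec <- nmix_model_spec("suff", random_effect = FALSE)
  data <- list(counts = cnt,
               X = matrix(1, n, 1, dimnames = list(NULL, "Intercept")),
               W = matrix(1, n, 1, dimnames = list(NULL, "Intercept")))
  fit <- fit_mcmc(spec, data,
                  mcmc_config(chains = 2, iterations = 3000,
                              burnin = 1000, thin = 2),
                  seed = 31, fixed_alpha = qlogis(p_true))
  lam_hat <- mean(exp(pooled_draws(fit)[, "beta_Intercept"]))
  expect_equal(lam_hat, mean(cnt) / p_true, tolerance = 0.05)
})

test_that("fit validation rejects malformed inputs", {
  tf <- toy_fit()
  bad <- tf$data
  bad$counts <- matrix(c(-1L, 1L, 1L, 1L), 2, 2)
  spec <- nmix_model_spec("m", random_effect = FALSE)
  expect_error(fit_mcmc(spec, bad, mcmc_config(2, 100, 50, 1)),
               "non-negative")
  bad2 <- tf$data
  bad2$X <- matrix(c(1, NA), 2, 1)
  expect_error(fit_mcmc(spec, bad2, mcmc_config(2, 100, 50, 1)), "finite")
  expect_error(mcmc_config(chains = 2, iterations = 100, burnin = 200),
               "burnin")
})
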