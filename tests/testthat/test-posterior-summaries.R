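test_that("gelman_rubin matches the closed form for identical chains", {
  x <- rnorm(100)
  expect_equal(gelman_rubin(list(x, x)), sqrt(99 / 100), tolerance = 1e-12)
  n <- 500
  y <- rnorm(n)
  expect_equal(gelman_rubin(list(y, y, y)), sqrt((n - 1) / n),
               tolerance = 1e-12)
})

test_that("gelman_rubin is near 1 for same-distribution chains and large
           for separated chains", {
  set.seed(60)
  chains <- replicate(3, rnorm(10000), simplify = FALSE)
  expect_lt(gelman_rubin(chains), 1.01)
  far <- list(rnorm(100, 0), rnorm(100, 100))
  expect_gt(gelman_rubin(far), 10)
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "10")
})

test_that("f statistic reports the dominant-sign posterior share", {
  expect_equal(f_statistic(c(1, 2, 3, 4)), 100)
  expect_equal(f_statistic(c(-1, -1, 1, 1)), 50)
  expect_equal(f_statistic(c(rep(-1, 9), 1)), 90)
  expect_equal(f_statistic(c(0, 0, 1, 1)), 75) # zeros split evenly
  expect_error(f_statistic(numeric(0)), "empty")
})

test_that("summary matches the normal-quantile oracle in the DEPTH regime", {
  set.seed(61)
  draws <- rnorm(100000, -0.604, 0.16)
  q <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_equal(q[1], -0.604 - 1.959964 * 0.16, tolerance = 0.02)
  expect_equal(q[2], -0.604 + 1.959964 * 0.16, tolerance = 0.02)
  expect_equal(f_statistic(draws), 100, tolerance = 0.05)
})

test_that("importance flag covers all four (BCI x f) combinations", {
  flag <- function(lo, hi, f) (lo > 0 || hi < 0) || f > 90
  expect_true(flag(0.2, 0.9, 100))   # excludes zero, high f
  expect_true(flag(-0.1, 0.9, 95))   # overlaps zero, f escape hatch
  expect_true(flag(0.05, 0.9, 80))   # excludes zero, modest f
  expect_false(flag(-0.4, 0.4, 60))  # neither
  # and end-to-end: symmetric posterior is not important
  tf <- toy_fit(chains = 2, iterations = 2000, burnin = 500)
  summ <- summarize_posterior(tf$fit, "beta_Intercept")
  expect_identical(names(summ),
                   c("parameter", "mean", "sd", "q2.5", "q97.5", "f",
                     "important"))
  expect_true(summ$q2.5 <= summ$q97.5)
})

test_that("pooling chains equals summarizing concatenated draws", {
  tf <- toy_fit(chains = 3, iterations = 800, burnin = 400)
  summ <- summarize_posterior(tf$fit, "beta_Intercept")
  all_draws <- do.call(rbind, tf$fit$chains)[, "beta_Intercept"]
  expect_equal(summ$mean, mean(all_draws), tolerance = 1e-12)
  expect_equal(summ$sd, sd(all_draws), tolerance = 1e-12)
  expect_equal(summ$q2.5, quantile(all_draws, 0.025, names = FALSE),
               tolerance = 1e-12)
  expect_equal(summ$f, f_statistic(all_draws), tolerance = 1e-12)
  expect_error(summarize_posterior(tf$fit, "nope"), "unknown")
})

test_that("response curves span the observed range and track the slope", {
  scen <- newt_scenario(n_sites = 60, seed = 62)
  sim <- simulate_newt_survey(scen)
  prep <- prepare_covariates(sim$sites, sim$surveys)
  spec <- nmix_model_spec("wet", detection_covariate = "DEPTH",
                          abundance_covariates = c("WATERBODY", "NNDIST",
                                                   "WETLAND500"))
  d <- build_design(spec, prep)
  fit <- fit_mcmc(spec, list(counts = sim$counts, X = d$X, W = d$W),
                  mcmc_config(chains = 2, iterations = 2000, burnin = 800,
                              thin = 2), seed = 63)
  obs <- sim$sites$WETLAND500
  curve <- response_curve(fit, "WETLAND500", prep$site_record, obs,
                          n_grid = 21)
  expect_equal(curve$x[1], min(obs))             # no extrapolation
  expect_equal(curve$x[nrow(curve)], max(obs))
  expect_true(all(curve$lo <= curve$hi))
  # slope direction: positive wetland effect means an increasing curve
  if (mean(pooled_draws(fit)[, "beta_WETLAND500"]) > 0)
    expect_gt(curve$mean[nrow(curve)], curve$mean[1])
  expect_error(response_curve(fit, "URBAN250", prep$site_record, obs),
               "not in the fitted model")
})

test_that("a point-mass posterior yields a flat zero-width curve", {
  # hand-built degenerate posterior: beta0 = log(10), zero focal slope
  m <- matrix(rep(c(log(10), 0), each = 50), 50, 2,
              dimnames = list(NULL, c("beta_Intercept", "beta_X")))
  fit <- structure(list(chains = list(m), loglik = list(),
                        par_names = colnames(m), n_sites = 1,
                        spec = nmix_model_spec("flat",
                                               abundance_covariates = "X",
                                               random_effect = FALSE),
                        config = NULL, seed = 1, fixed_alpha = NULL),
                   class = "nmix_fit")
  rec <- structure(list(mean = c(X = 0), sd = c(X = 1),
                        log = c(X = FALSE)),
                   class = "standardization_record")
  curve <- response_curve(fit, "X", rec, observed = c(-2, 3), n_grid = 5)
  expect_equal(curve$mean, rep(10, 5), tolerance = 1e-12)
  expect_equal(curve$lo, rep(10, 5), tolerance = 1e-12)
  expect_equal(curve$hi, rep(10, 5), tolerance = 1e-12)
  expect_equal(curve$x, seq(-2, 3, length.out = 5))
})

test_that("curve at the covariate mean matches exp(beta0) integral", {
  scen <- newt_scenario(n_sites = 80, seed = 64)
  sim <- simulate_newt_survey(scen)
  prep <- prepare_covariates(sim$sites, sim$surveys)
  spec <- nmix_model_spec("wet", detection_covariate = "DEPTH",
                          abundance_covariates = "WETLAND500")
  d <- build_design(spec, prep)
  fit <- fit_mcmc(spec, list(counts = sim$counts, X = d$X, W = d$W),
                  mcmc_config(chains = 2, iterations = 2000, burnin = 800,
                              thin = 2), seed = 65)
  rec <- prep$site_record
  m <- rec$mean[["WETLAND500"]]
  curve <- response_curve(fit, "WETLAND500", rec, c(m - 1e-9, m + 1e-9),
                          n_grid = 3, re_draws = 200)
  dr <- pooled_draws(fit)
  expected <- mean(exp(dr[, "beta_Intercept"]) *
                     exp(dr[, "sigma_eps"]^2 / 2))
  expect_equal(curve$mean[2], expected, tolerance = 0.1)
})
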