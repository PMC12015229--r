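test_that("site covariate generation is seeded, bounded and compositional", {
  a <- generate_site_covariates(32, seed = 1)
  b <- generate_site_covariates(32, seed = 1)
  expect_identical(a, b)
  c2 <- generate_site_covariates(32, seed = 2)
  expect_false(identical(a, c2))

  covers <- paste0(rep(c("URBAN", "CROPLAND", "WETLAND", "TERRSITES"),
                       each = 3), rep(c(250, 500, 1000), 4))
  expect_true(all(as.matrix(a[covers]) >= 0 & as.matrix(a[covers]) <= 100))
  for (r in c(250, 500, 1000)) {
    tot <- rowSums(a[paste0(c("URBAN", "CROPLAND", "WETLAND", "TERRSITES"),
                            r)])
    expect_true(all(tot <= 100))
  }
  expect_true(all(a$WATERBODY > 0) && all(a$NNDIST > 0) &&
                all(a$DISTROAD > 0) && all(a$DISTRAILWAY > 0))
  expect_error(generate_site_covariates(0), "positive")
})

test_that("same land-cover class is correlated across adjacent scales", {
  s <- generate_site_covariates(10000, seed = 3)
  for (cls in c("URBAN", "CROPLAND", "WETLAND", "TERRSITES")) {
    expect_gt(cor(s[[paste0(cls, 250)]], s[[paste0(cls, 500)]]), 0.5)
    expect_gt(cor(s[[paste0(cls, 500)]], s[[paste0(cls, 1000)]]), 0.5)
  }
})

test_that("trap allocation follows the area rule with the 18-trap cap", {
  expect_identical(traps_for_area(0), 4L)
  expect_identical(traps_for_area(0.02), 6L)
  expect_identical(traps_for_area(2.0), 18L)
  expect_identical(traps_for_area(0.019), 4L) # floor, not round
  expect_identical(traps_for_area(0.14), 18L) # cap binds below 1 km^2 too
  expect_true(all(traps_for_area(seq(1.0001, 10, by = 0.5)) == 18L))
  expect_error(traps_for_area(-0.1), "non-negative")
})

test_that("survey covariates match the field regime and are seeded", {
  sites <- generate_site_covariates(5000, seed = 4)
  sv <- generate_survey_covariates(sites, 2, seed = 5)
  sv2 <- generate_survey_covariates(sites, 2, seed = 5)
  expect_identical(sv, sv2)
  expect_equal(mean(sv$DEPTH), 34.14, tolerance = 1 / 34.14)
  expect_equal(sd(sv$DEPTH), 15.30, tolerance = 0.05)
  expect_true(all(sv$DEPTH > 0))
  expect_true(all(sv$VEG >= 0 & sv$VEG <= 100))
  expect_true(all(sv$DATE[sv$survey == 1] %in% 94:101))
  expect_true(all(sv$DATE[sv$survey == 2] %in% 103:110))
  expect_identical(sv$TRAPS,
                   rep(traps_for_area(sites$WATERBODY), each = 2))
  expect_error(generate_survey_covariates(sites, 0), ">= 1")
})

test_that("counts follow the binomial-Poisson hierarchy", {
  sites <- generate_site_covariates(200, seed = 6)
  sv <- generate_survey_covariates(sites, 2, seed = 7)
  scen <- newt_scenario(n_sites = 200, n_surveys = 2, seed = 8)
  sim <- generate_counts(sites, sv, scen)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  # binomial thinning can never exceed the latent total
  expect_true(all(sim$counts <= sim$truth$N))
  expect_true(all(sim$truth$lambda > 0))
})

test_that("perfect detection with no random effect reproduces N exactly", {
  sites <- generate_site_covariates(50, seed = 9)
  sv <- generate_survey_covariates(sites, 2, seed = 10)
  scen <- newt_scenario(n_sites = 50, n_surveys = 2,
                        true_alpha = c(50, 0), sigma_eps = 0, seed = 11)
  sim <- generate_counts(sites, sv, scen)
  expect_identical(sim$counts[, 1], sim$truth$N)
  expect_identical(sim$counts[, 2], sim$truth$N)
})

test_that("intercept-only abundance matches the Poisson mean at large n", {
  n <- 20000
  sites <- generate_site_covariates(n, seed = 12)
  sv <- generate_survey_covariates(sites, 1, seed = 13)
  scen <- newt_scenario(n_sites = n, n_surveys = 1,
                        true_alpha = c(50, 0), true_beta = log(5),
                        sigma_eps = 0, abundance_covariates = character(),
                        seed = 14)
  sim <- generate_counts(sites, sv, scen)
  expect_equal(mean(sim$truth$N), 5, tolerance = 0.1 / 5)
})

test_that("Poisson thinning moments hold: E[C] = Var[C] = lambda p", {
  n <- 20000
  sites <- generate_site_covariates(n, seed = 15)
  sv <- generate_survey_covariates(sites, 1, seed = 16)
  scen <- newt_scenario(n_sites = n, n_surveys = 1,
                        true_alpha = c(qlogis(0.4), 0), true_beta = log(6),
                        sigma_eps = 0, abundance_covariates = character(),
                        seed = 17)
  sim <- generate_counts(sites, sv, scen)
  expect_equal(mean(sim$counts), 6 * 0.4, tolerance = 0.03)
  expect_equal(var(as.vector(sim$counts)), 6 * 0.4, tolerance = 0.05)
})

test_that("counts rise with the driving covariate (study-like truth)", {
  scen <- newt_scenario(n_sites = 500, n_surveys = 2,
                        true_alpha = c(-1.6, -0.6),
                        true_beta = c(2.4, 0.73), sigma_eps = 0.3,
                        abundance_covariates = "WETLAND500", seed = 18)
  sim <- simulate_newt_survey(scen)
  site_mean <- rowMeans(sim$counts)
  expect_gt(cor(site_mean, sim$sites$WETLAND500, method = "spearman"), 0.2)
})

test_that("scenario validation rejects malformed configurations", {
  expect_error(newt_scenario(n_sites = 0), "n_sites")
  expect_error(newt_scenario(sigma_eps = -1), "sigma_eps")
  expect_error(newt_scenario(abundance_covariates = "NOPE",
                             true_beta = c(1, 1)), "unknown covariate")
  expect_error(newt_scenario(true_beta = c(1, 2)), "slope per")
})
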