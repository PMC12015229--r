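#' Scenario configuration for the synthetic survey generator
#'
#' Bundles the true generative parameters for a simulated trap-count study:
#' detection coefficients on the logit scale, abundance coefficients on the
#' log scale, the SD of the site random effect, and which covariates the
#' coefficients act on. Defaults mirror the posterior means of the
#' best-supported wetland model of the motivating 32-site smooth-newt study,
#' so that default simulations resemble that data regime (counts mostly
#' below ~40, detection probability roughly 0.1--0.3).
#'
#' @param n_sites number of sites (waterbodies).
#' @param n_surveys number of repeat surveys per site.
#' @param true_alpha detection intercept and slope `c(alpha0, alpha1)`
#'   (logit scale, slope on the standardized detection covariate).
#' @param true_beta abundance intercept and slopes (log scale, slopes on the
#'   standardized abundance covariates, in the order of
#'   `abundance_covariates`).
#' @param sigma_eps SD of the site-level random effect (>= 0; 0 switches the
#'   random effect off).
#' @param detection_covariate name of the survey covariate driving detection.
#' @param abundance_covariates names of the site covariates driving
#'   abundance, matching `true_beta[-1]`.
#' @param seed integer seed; every draw the generator makes descends from it.
#' @return A list of class `newt_scenario`.
#' @export
newt_scenario <- function(n_sites = 32L, n_surveys = 2L,
                          true_alpha = c(-1.621, -0.648),
                          true_beta = c(2.417, 0.222, -0.176, 0.727),
                          sigma_eps = 0.5,
                          detection_covariate = "DEPTH",
                          abundance_covariates = c("WATERBODY", "NNDIST",
                                                   "WETLAND500"),
                          seed = 1L) {
  if (n_sites < 1L) stop("`n_sites` must be >= 1", call. = FALSE)
  if (n_surveys < 1L) stop("`n_surveys` must be >= 1", call. = FALSE)
  if (sigma_eps < 0) stop("`sigma_eps` must be >= 0", call. = FALSE)
  if (length(true_beta) != length(abundance_covariates) + 1L)
    stop("`true_beta` must have one slope per abundance covariate plus ",
         "an intercept", call. = FALSE)
  if (length(true_alpha) != 2L)
    stop("`true_alpha` must be c(intercept, slope)", call. = FALSE)
  known <- c(site_covariate_names(), survey_covariate_names())
  bad <- setdiff(c(detection_covariate, abundance_covariates), known)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n_sites = as.integer(n_sites),
                 n_surveys = as.integer(n_surveys),
                 true_alpha = true_alpha, true_beta = true_beta,
                 sigma_eps = sigma_eps,
                 detection_covariate = detection_covariate,
                 abundance_covariates = abundance_covariates,
                 seed = as.integer(seed)),
            class = "newt_scenario")
}

site_covariate_names <- function() {
  c(paste0(rep(c("URBAN", "CROPLAND", "WETLAND", "TERRSITES"), each = 3),
           rep(c(250, 500, 1000), 4)),
    "WATERBODY", "NNDIST", "DISTROAD", "DISTRAILWAY")
}

survey_covariate_names <- function() c("DEPTH", "WTEMP", "VEG", "DATE", "TRAPS")

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate per-site landscape covariates at three buffer scales
#'
#' Draws, for each site, percent cover of urban land, cropland, wetland and
#' terrestrial habitat within 250, 500 and 1000 m buffers, plus waterbody
#' area and distances to the nearest neighbouring site, major road and
#' railway. Covers at one radius are drawn jointly from a Dirichlet over
#' five classes (the fifth, unreported "other" class absorbs the remainder)
#' whose concentration is a shared site-level latent composition, so the
#' same class at adjacent radii is positively correlated -- the property the
#' buffer-scale selection stage relies on. Areas and distances are
#' log-normal: strictly positive and right-skewed, which is why the analysis
#' log-transforms them.
#'
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed.
#' @return data.frame with `site_id`, the twelve `<CLASS><RADIUS>` percent
#'   covers, `WATERBODY` (km^2), `NNDIST`, `DISTROAD`, `DISTRAILWAY` (km).
#' @export
generate_site_covariates <- function(n_sites, seed = 1L) {
  if (length(n_sites) != 1L || is.na(n_sites) || n_sites < 1L)
    stop("`n_sites` must be a positive integer", call. = FALSE)
  n_sites <- as.integer(n_sites)
  set.seed(seed)
  base_conc <- c(URBAN = 2, CROPLAND = 3, WETLAND = 2, TERRSITES = 4,
                 OTHER = 3)
  kappa <- 40 # tightness of per-radius draws around the site composition
  classes <- names(base_conc)[1:4]
  radii <- c(250, 500, 1000)
  cover <- matrix(NA_real_, n_sites, 12,
                  dimnames = list(NULL, paste0(rep(classes, each = 3),
                                               rep(radii, 4))))
  for (i in seq_len(n_sites)) {
    m <- rdirichlet1(base_conc)
    for (r in radii) {
      comp <- rdirichlet1(kappa * m)
      cover[i, paste0(classes, r)] <- 100 * comp[1:4]
    }
  }
  data.frame(site_id = seq_len(n_sites), cover,
             WATERBODY = rlnorm(n_sites, meanlog = log(0.02), sdlog = 1.3),
             NNDIST = rlnorm(n_sites, meanlog = log(1.2), sdlog = 0.7),
             DISTROAD = rlnorm(n_sites, meanlog = log(0.6), sdlog = 0.9),
             DISTRAILWAY = rlnorm(n_sites, meanlog = log(1.8), sdlog = 1.0))
}

#' Number of funnel traps deployed for a waterbody of given area
#'
#' Trap effort follows the field protocol: a minimum of 4 traps, plus 2
#' additional traps for every 0.02 km^2 of surface area, with waterbodies
#' larger than 1 km^2 sampled with 18 traps. The per-0.02-km^2 increments
#' use `floor`, and the 18-trap cap applies throughout.
#'
#' @param area_km2 waterbody surface area in km^2 (>= 0); vectorized.
#' @return integer trap counts.
#' @export
traps_for_area <- function(area_km2) {
  if (any(is.na(area_km2)) || any(area_km2 < 0))
    stop("`area_km2` must be non-negative", call. = FALSE)
  n <- 4L + 2L * as.integer(floor(area_km2 / 0.02))
  pmin(n, 18L)
}

#' Generate survey-level covariates for each site x survey
#'
#' Emulates the field measurements taken at each trap deployment: water
#' depth (gamma with mean 34.14 and SD 15.30 cm, matching the study's
#' summary), water temperature (spring regime, about 12 +/- 3 C), percent
#' emergent vegetation (beta-scaled to 0--100), Julian date drawn inside
#' consecutive early/mid-April windows (survey 1: day 94--101, survey 2:
#' 103--110, continuing in 9-day steps for further surveys), and trap count
#' from [traps_for_area()] (constant across surveys at a site).
#'
#' @param site_table output of [generate_site_covariates()].
#' @param n_surveys number of surveys per site (>= 1).
#' @param seed integer seed.
#' @return data.frame with `site_id`, `survey`, `DEPTH`, `WTEMP`, `VEG`,
#'   `DATE`, `TRAPS`; one row per site x survey, survey-major within site.
#' @export
generate_survey_covariates <- function(site_table, n_surveys = 2L, seed = 1L) {
  if (n_surveys < 1L) stop("`n_surveys` must be >= 1", call. = FALSE)
  n_surveys <- as.integer(n_surveys)
  n <- nrow(site_table)
  set.seed(seed)
  depth_mean <- 34.14; depth_sd <- 15.30
  shape <- (depth_mean / depth_sd)^2
  out <- do.call(rbind, lapply(seq_len(n_surveys), function(j) {
    start <- 94L + 9L * (j - 1L)
    data.frame(site_id = site_table$site_id, survey = j,
               DEPTH = rgamma(n, shape = shape, rate = shape / depth_mean),
               WTEMP = rnorm(n, mean = 12, sd = 3),
               VEG = 100 * stats::rbeta(n, 2, 2),
               DATE = start + sample.int(8L, n, replace = TRUE) - 1L,
               TRAPS = traps_for_area(site_table$WATERBODY))
  }))
  out <- out[order(out$site_id, out$survey), ]
  rownames(out) <- NULL
  out
}

#' Generate repeated trap counts and the latent truth
#'
#' Applies the hierarchical generative model the analysis assumes. Raw
#' covariates are first transformed exactly as [prepare_covariates()] does
#' (log then standardize), so the true coefficients act on the same scale
#' the fitted model sees. Then, per site i and survey j:
#' lambda_i = exp(beta0 + sum_k beta_k x_ik + eps_i) with
#' eps_i ~ Normal(0, sigma_eps); N_i ~ Poisson(lambda_i);
#' p_ij = plogis(alpha0 + alpha1 y_ij); C_ij ~ Binomial(N_i, p_ij).
#'
#' @param site_table site covariates, as from [generate_site_covariates()].
#' @param survey_covs survey covariates, as from
#'   [generate_survey_covariates()].
#' @param scenario a [newt_scenario()]; its `seed` drives the draws.
#' @return list with `counts` (sites x surveys integer matrix), `truth`
#'   (data.frame: site_id, lambda, N, eps) and `p` (sites x surveys matrix
#'   of detection probabilities).
#' @export
generate_counts <- function(site_table, survey_covs, scenario) {
  stopifnot(inherits(scenario, "newt_scenario"))
  miss_s <- setdiff(intersect(scenario$abundance_covariates,
                              site_covariate_names()),
                    names(site_table))
  if (length(miss_s) ||
      !scenario$detection_covariate %in% names(survey_covs))
    stop("scenario names covariates absent from the tables: ",
         paste(c(miss_s,
                 setdiff(scenario$detection_covariate, names(survey_covs))),
               collapse = ", "), call. = FALSE)
  prep <- prepare_covariates(site_table, survey_covs)
  n <- nrow(site_table); J <- scenario$n_surveys
  if (nrow(survey_covs) != n * J)
    stop("`survey_covs` must have n_sites x n_surveys rows", call. = FALSE)
  set.seed(scenario$seed)
  X <- as.matrix(cbind(1, prep$sites[scenario$abundance_covariates]))
  eps <- if (scenario$sigma_eps > 0) rnorm(n, 0, scenario$sigma_eps) else
    rep(0, n)
  lambda <- exp(drop(X %*% scenario$true_beta) + eps)
  N <- rpois(n, lambda)
  idx <- order(survey_covs$site_id, survey_covs$survey)
  y <- matrix(prep$surveys[[scenario$detection_covariate]][idx], nrow = n,
              byrow = TRUE) # rows ordered by site, columns by survey
  p <- plogis(scenario$true_alpha[1] + scenario$true_alpha[2] * y)
  counts <- matrix(rbinom(n * J, size = rep(N, J), prob = as.vector(p)),
                   nrow = n)
  list(counts = counts,
       truth = data.frame(site_id = site_table$site_id, lambda = lambda,
                          N = N, eps = eps),
       p = p)
}

#' Simulate a complete synthetic trap-count survey
#'
#' Convenience wrapper chaining [generate_site_covariates()],
#' [generate_survey_covariates()] and [generate_counts()], with sub-seeds
#' derived deterministically from the scenario seed.
#'
#' @param scenario a [newt_scenario()].
#' @return list with `sites`, `surveys` (the surveys table gains a `count`
#'   column), `counts`, `truth`, `p` and the `scenario`.
#' @export
simulate_newt_survey <- function(scenario = newt_scenario()) {
  stopifnot(inherits(scenario, "newt_scenario"))
  sites <- generate_site_covariates(scenario$n_sites,
                                    seed = scenario$seed)
  surveys <- generate_survey_covariates(sites, scenario$n_surveys,
                                        seed = scenario$seed + 1000L)
  sim <- generate_counts(sites, surveys, scenario)
  # surveys is ordered by (site_id, survey); counts is sites x surveys
  surveys$count <- as.integer(t(sim$counts))
  list(sites = sites, surveys = surveys, counts = sim$counts,
       truth = sim$truth, p = sim$p, scenario = scenario)
}
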