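#' Parameter-recovery experiment
#'
#' Repeatedly simulates surveys at known detection and abundance
#' coefficients, refits the model, and reports per-replicate posterior
#' means, absolute errors and 95% credible-interval coverage for the four
#' target parameters (detection intercept and slope, abundance intercept
#' and focal slope). The generator and the fitted model share the same
#' structure; with `sigma_eps = 0` the random effect is dropped from both.
#'
#' @param n_reps replicates.
#' @param n_sites,n_surveys design size per replicate.
#' @param true_alpha,true_beta truth: `c(alpha0, alpha1)` on DEPTH and
#'   `c(beta0, beta1)` on one site covariate.
#' @param focal site covariate carrying the abundance effect.
#' @param sigma_eps random-effect SD in the generator (0 = off).
#' @param config a [mcmc_config()].
#' @param seed base seed; replicate r uses `seed + r`.
#' @return data.frame, one row per replicate x parameter: `rep`,
#'   `parameter`, `truth`, `mean`, `abs_error`, `covered`.
#' @export
recovery_experiment <- function(n_reps = 50, n_sites = 200, n_surveys = 3,
                                true_alpha = c(-1.5, -0.6),
                                true_beta = c(2.4, 0.7),
                                focal = "WETLAND500", sigma_eps = 0,
                                config = mcmc_config(chains = 2,
                                                     iterations = 12000,
                                                     burnin = 5000,
                                                     thin = 3),
                                seed = 1L) {
  spec <- nmix_model_spec("recovery", detection_covariate = "DEPTH",
                          abundance_covariates = focal,
                          random_effect = sigma_eps > 0)
  target <- c("alpha_Intercept", "alpha_DEPTH", "beta_Intercept",
              paste0("beta_", focal))
  truths <- setNames(c(true_alpha, true_beta), target)
  rows <- list()
  for (r in seq_len(n_reps)) {
    scen <- newt_scenario(n_sites = n_sites, n_surveys = n_surveys,
                          true_alpha = true_alpha, true_beta = true_beta,
                          sigma_eps = sigma_eps,
                          detection_covariate = "DEPTH",
                          abundance_covariates = focal,
                          seed = seed + r)
    sim <- simulate_newt_survey(scen)
    prep <- prepare_covariates(sim$sites, sim$surveys)
    design <- build_design(spec, prep)
    data <- list(counts = sim$counts, X = design$X, W = design$W)
    fit <- fit_mcmc(spec, data, config, seed = seed + 7919L * r)
    summ <- summarize_posterior(fit, target)
    rows[[r]] <- data.frame(
      rep = r, parameter = summ$parameter,
      truth = unname(truths[summ$parameter]), mean = summ$mean,
      abs_error = abs(summ$mean - truths[summ$parameter]),
      covered = truths[summ$parameter] >= summ$q2.5 &
        truths[summ$parameter] <= summ$q97.5)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Buffer-scale recovery experiment
#'
#' Simulates abundance driven by one landscape covariate at one scale and
#' checks how often the scale stage selects that scale for that covariate.
#'
#' @param n_reps replicates.
#' @param n_sites sites per replicate.
#' @param true_focal the driving covariate column (e.g. `"WETLAND500"`).
#' @param effect its abundance slope (standardized scale).
#' @param landscape_covariates which classes to scan (scanning only the
#'   focal class keeps the experiment cheap; the full four-class scan is
#'   the study design).
#' @param config a [mcmc_config()].
#' @param seed base seed.
#' @return data.frame: `rep`, `selected`, `correct`.
#' @export
scale_selection_experiment <- function(n_reps = 20, n_sites = 100,
                                       true_focal = "WETLAND500",
                                       effect = 0.7,
                                       landscape_covariates = "WETLAND",
                                       config = mcmc_config(chains = 2,
                                                            iterations = 3000,
                                                            burnin = 1000,
                                                            thin = 2),
                                       seed = 1L) {
  cls <- sub("(250|500|1000)$", "", true_focal)
  rows <- list()
  for (r in seq_len(n_reps)) {
    scen <- newt_scenario(n_sites = n_sites, n_surveys = 2,
                          true_alpha = c(-1.0, -0.6),
                          true_beta = c(2.0, 0.2, -0.2, effect),
                          sigma_eps = 0.3,
                          detection_covariate = "DEPTH",
                          abundance_covariates = c("WATERBODY", "NNDIST",
                                                   true_focal),
                          seed = seed + r)
    sim <- simulate_newt_survey(scen)
    res <- run_scale_stage(sim$sites, sim$surveys,
                           landscape_covariates = landscape_covariates,
                           detection_covariate = "DEPTH", config = config,
                           seed = seed + 104729L * r)
    sel <- res$winners[[cls]]
    rows[[r]] <- data.frame(rep = r, selected = sel,
                            correct = identical(sel, true_focal))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection-covariate recovery experiment
#'
#' Simulates detection driven by a single survey covariate and checks how
#' often the detection stage ranks that covariate's model first.
#'
#' @param n_reps replicates.
#' @param n_sites sites per replicate.
#' @param true_covariate driving detection covariate.
#' @param alpha1 its logit-scale slope.
#' @param config a [mcmc_config()].
#' @param seed base seed.
#' @return data.frame: `rep`, `winner`, `correct`.
#' @export
detection_selection_experiment <- function(n_reps = 20, n_sites = 100,
                                           true_covariate = "DEPTH",
                                           alpha1 = -0.6,
                                           config = mcmc_config(
                                             chains = 2,
                                             iterations = 3000,
                                             burnin = 1000, thin = 2),
                                           seed = 1L) {
  rows <- list()
  for (r in seq_len(n_reps)) {
    scen <- newt_scenario(n_sites = n_sites, n_surveys = 2,
                          true_alpha = c(-1.0, alpha1),
                          true_beta = c(2.0),
                          sigma_eps = 0.3,
                          detection_covariate = true_covariate,
                          abundance_covariates = character(),
                          seed = seed + r)
    sim <- simulate_newt_survey(scen)
    res <- run_detection_stage(sim$sites, sim$surveys, config = config,
                               seed = seed + 224737L * r)
    rows[[r]] <- data.frame(rep = r, winner = res$winner,
                            correct = identical(res$winner, true_covariate))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
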