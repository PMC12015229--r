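# newtmix

Bayesian N-mixture models for estimating smooth-newt abundance from
repeated funnel-trap counts under imperfect detection, with the full
staged model-selection workflow that goes with a multi-scale landscape
study: detection-covariate selection, buffer-scale selection
(250/500/1000 m), a final landscape/infrastructure model set, posterior
summary tables, and abundance response curves. A synthetic-data generator
emulating the 32-site, two-survey study design makes the entire workflow
testable without field data.

## Who this is for

Ecologists and biostatisticians analysing repeated count surveys where
not every individual present is detected — pond amphibians in funnel
traps being the motivating case — and who want a reproducible,
simulation-validated version of the common JAGS-style hierarchical
workflow as plain R functions.

## The model

Latent abundance at site *i* is Poisson with a log-linear regression and
a site random effect:

    N_i ~ Poisson(lambda_i)
    log(lambda_i) = beta_0 + sum_k beta_k * x_ik + eps_i,   eps_i ~ Normal(0, sigma_eps)

Counts are binomial thinnings with logit-linear detection in one survey
covariate:

    C_ij ~ Binomial(N_i, p_ij)
    logit(p_ij) = alpha_0 + alpha_1 * y_ij

The latent `N_i` is marginalized out of the likelihood (a truncated
Poisson-binomial sum evaluated exactly in C++), so the sampler — an
adaptive Metropolis-within-Gibbs with a jointly adapted coefficient
block — works in a small parameter space and the likelihood can be
verified against brute-force enumeration. Model comparison uses WAIC
with the site as the pointwise unit and a Delta-WAIC < 2 support rule;
summaries report posterior mean, SD, the 95% credible interval
(2.5th/97.5th percentiles), and the f-statistic (percent of posterior
mass on the dominant sign, important when the interval excludes zero or
f > 90). Convergence is monitored with the Brooks–Gelman–Rubin R-hat
(< 1.1).

## Worked example

Simulate a study-like dataset (32 sites, 2 surveys, detection driven by
water depth, abundance by waterbody area, neighbour distance and wetland
cover at 500 m), fit the wetland model, and summarize:

```r
library(newtmix)

scen <- newt_scenario(seed = 1)          # study-like defaults
sim  <- simulate_newt_survey(scen)
sum(sim$counts)                          # 231 captures in this realization

prep <- prepare_covariates(sim$sites, sim$surveys)   # log + standardize
spec <- nmix_model_spec("wetland", detection_covariate = "DEPTH",
                        abundance_covariates = c("WATERBODY", "NNDIST",
                                                 "WETLAND500"))
d   <- build_design(spec, prep)
fit <- fit_mcmc(spec, list(counts = sim$counts, X = d$X, W = d$W),
                mcmc_config(chains = 3, iterations = 12000,
                            burnin = 4000, thin = 4), seed = 2)
summarize_posterior(fit)
```

```
        parameter   mean    sd    q2.5  q97.5     f important
1 alpha_Intercept -0.701 0.692 -2.4123  0.305  88.1     FALSE
2     alpha_DEPTH -0.775 0.203 -1.1969 -0.415 100.0      TRUE
3  beta_Intercept  1.821 0.483  1.2051  3.117 100.0      TRUE
4  beta_WATERBODY  0.285 0.127  0.0249  0.535  98.4      TRUE
5     beta_NNDIST -0.286 0.128 -0.5327 -0.036  98.2      TRUE
6 beta_WETLAND500  0.825 0.119  0.5885  1.062 100.0      TRUE
7       sigma_eps  0.394 0.177  0.1034  0.753 100.0      TRUE
```

Detection falls with water depth (`alpha_DEPTH` −0.78, f = 100: newts
are easier to trap in shallow water), abundance rises with wetland cover
(`beta_WETLAND500` 0.83 with a credible interval well above zero) — both
recovering the simulation's truth (−0.648 and 0.727) within posterior
uncertainty. `waic(fit)` returns the model's WAIC (228.7 here);
`rhat(fit)` confirms convergence (all below 1.03).

## The full analysis workflow

The numbered scripts under `analysis/` run the complete study pipeline on
a synthetic dataset and narrate what they find; each writes its tables
under `results/`:

```sh
Rscript analysis/01_simulate.R              # sites.csv, surveys.csv, truth.csv
Rscript analysis/02_prepare_covariates.R    # standardization + collinearity screen
Rscript analysis/03_detection_stage.R       # 5 detection models, WAIC-ranked
Rscript analysis/04_scale_stage.R           # 12 buffer-scale models
Rscript analysis/05_final_stage.R           # 6 final models + summaries
Rscript analysis/06_response_curves.R       # abundance curves, 95% bands
Rscript analysis/07_operating_characteristics.R  # recovery & selection rates
```

The same staged workflow is available as one call:
`run_pipeline(run_config(scenario = newt_scenario(seed = 1), seed = 1,
out_dir = "results/run"))`, which writes every selection table, summary,
draws file and a reproducibility manifest.

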