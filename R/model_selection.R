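#' Pointwise log-likelihood matrix from a fitted model
#'
#' Recomputes, for every retained draw, the marginalized log-likelihood of
#' each site's full count vector conditional on that draw's random effect
#' (conditional WAIC unit = site). The sampler also stores this matrix
#' during the run; this function recomputes it from the draws and is used
#' to cross-check the stored copy.
#'
#' @param fit an `nmix_fit`.
#' @param data the data list the model was fitted to.
#' @return draws x sites matrix.
#' @export
pointwise_loglik <- function(fit, data) {
  stopifnot(inherits(fit, "nmix_fit"))
  draws <- pooled_draws(fit)
  counts <- data$counts
  X <- as.matrix(data$X); W <- as.matrix(data$W)
  n <- nrow(counts); J <- ncol(counts)
  offset <- if (is.null(data$offset)) rep(0, n) else data$offset
  qdet <- ncol(W); pab <- ncol(X)
  a_idx <- seq_len(qdet)
  b_idx <- qdet + seq_len(pab)
  e_idx <- qdet + pab + 1 + seq_len(n)
  out <- matrix(NA_real_, nrow(draws), n)
  for (s in seq_len(nrow(draws))) {
    alpha <- draws[s, a_idx]; beta <- draws[s, b_idx]
    eps <- if (fit$spec$random_effect) draws[s, e_idx] else rep(0, n)
    lam <- exp(drop(X %*% beta) + offset + eps)
    pv <- plogis(drop(W %*% alpha))
    for (i in seq_len(n)) {
      out[s, i] <- nmix_site_loglik_cpp(
        counts[i, ], lam[i], pv[(i - 1) * J + seq_len(J)], -1L)
    }
  }
  out
}

#' Stored pointwise log-likelihood (fast path)
#' @param fit an `nmix_fit`.
#' @return draws x sites matrix recorded during sampling.
#' @export
stored_loglik <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  do.call(rbind, fit$loglik)
}

#' Watanabe-Akaike information criterion
#'
#' waic = -2 (lppd - p_waic) with lppd = sum_i log mean_s exp(ll_si)
#' (log-sum-exp stabilized) and p_waic = sum_i var_s(ll_si) (sample
#' variance, n - 1 denominator). Lower is better.
#'
#' @param pointwise draws x sites matrix of pointwise log-likelihoods (>= 2
#'   draws), or an `nmix_fit` (its stored matrix is used).
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(pointwise) {
  if (inherits(pointwise, "nmix_fit")) pointwise <- stored_loglik(pointwise)
  S <- nrow(pointwise)
  if (is.null(S) || S < 2)
    stop("need at least 2 draws for the WAIC variance term", call. = FALSE)
  m <- apply(pointwise, 2, max)
  lppd <- sum(m + log(colMeans(exp(sweep(pointwise, 2, m)))))
  p_waic <- sum(apply(pointwise, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Rank models by WAIC
#'
#' Sorts ascending, computes Delta-WAIC relative to the minimum, and flags
#' support at Delta-WAIC < 2. Ties keep input order.
#'
#' @param models data.frame with at least `label` and `waic` columns
#'   (extra columns, e.g. `covariates`, are carried through), or a named
#'   numeric vector of WAICs.
#' @return `selection_table` data.frame: the input columns plus
#'   `delta_waic` and `supported`, sorted by WAIC.
#' @export
rank_models <- function(models) {
  if (is.numeric(models))
    models <- data.frame(label = names(models), waic = as.numeric(models))
  if (!nrow(models)) stop("empty model list", call. = FALSE)
  if (any(!is.finite(models$waic)))
    stop("non-finite WAIC", call. = FALSE)
  ord <- order(models$waic) # stable: ties keep input order
  out <- models[ord, , drop = FALSE]
  out$delta_waic <- out$waic - min(out$waic)
  out$supported <- out$delta_waic < 2
  rownames(out) <- NULL
  class(out) <- c("selection_table", "data.frame")
  out
}

fit_and_waic <- function(spec, prepared, raw_sites, counts, config, seed) {
  design <- build_design(spec, prepared, raw_site_table = raw_sites)
  data <- list(counts = counts, X = design$X, W = design$W,
               offset = design$offset)
  fit <- fit_mcmc(spec, data, config, seed = seed)
  list(fit = fit, data = data, waic = waic(fit)$waic)
}

#' Detection-covariate selection stage
#'
#' Fits one model per candidate survey covariate (default the study's five:
#' DEPTH, DATE, TRAPS, WTEMP, VEG), each with logit-linear detection in
#' that single covariate and an intercept + random-effect abundance
#' sub-model, and ranks them by WAIC. The winner's covariate is carried to
#' the later stages.
#'
#' @param sites raw site table.
#' @param surveys raw survey table including a `count` column.
#' @param candidates detection covariates to compare.
#' @param config a [mcmc_config()].
#' @param seed integer seed (each model uses an offset of it).
#' @return list with `table` (a `selection_table`), `winner` (covariate
#'   name) and `fits` (named list of `nmix_fit`s).
#' @export
run_detection_stage <- function(sites, surveys,
                                candidates = c("DEPTH", "DATE", "TRAPS",
                                               "WTEMP", "VEG"),
                                config = mcmc_config(), seed = 1L) {
  miss <- setdiff(candidates, names(surveys))
  if (length(miss))
    stop("candidate covariate(s) missing from survey table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  prepared <- prepare_covariates(sites, surveys)
  counts <- counts_matrix(surveys)
  rows <- list(); fits <- list()
  for (k in seq_along(candidates)) {
    cand <- candidates[k]
    spec <- nmix_model_spec(label = cand, detection_covariate = cand,
                            abundance_covariates = character(),
                            random_effect = TRUE)
    res <- fit_and_waic(spec, prepared, sites, counts, config,
                        seed + 101L * k)
    rows[[k]] <- data.frame(label = cand,
                            covariates = paste("Intercept", cand),
                            waic = res$waic)
    fits[[cand]] <- res$fit
  }
  table <- rank_models(do.call(rbind, rows))
  list(table = table, winner = table$label[1], fits = fits)
}

#' Buffer-scale selection stage
#'
#' For each landscape covariate, fits one model per buffer scale with
#' abundance sub-model intercept + WATERBODY + NNDIST + covariate-at-scale
#' and the chosen detection covariate, then picks the scale with minimum
#' WAIC. Twelve models in the default full design (4 covariates x 3
#' scales).
#'
#' @inheritParams run_detection_stage
#' @param landscape_covariates landscape classes to scan.
#' @param scales buffer radii (m).
#' @param detection_covariate the detection covariate selected upstream.
#' @return list with `tables` (one `selection_table` per covariate) and
#'   `winners` (named character: covariate -> best column name, e.g.
#'   `WETLAND500`).
#' @export
run_scale_stage <- function(sites, surveys,
                            landscape_covariates = c("URBAN", "CROPLAND",
                                                     "WETLAND", "TERRSITES"),
                            scales = c(250, 500, 1000),
                            detection_covariate = "DEPTH",
                            config = mcmc_config(), seed = 1L) {
  cols <- as.vector(outer(landscape_covariates, scales, paste0))
  miss <- setdiff(cols, names(sites))
  if (length(miss))
    stop("site table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  prepared <- prepare_covariates(sites, surveys)
  counts <- counts_matrix(surveys)
  tables <- list(); winners <- character()
  mi <- 0L
  for (lc in landscape_covariates) {
    rows <- list()
    for (k in seq_along(scales)) {
      mi <- mi + 1L
      focal <- paste0(lc, scales[k])
      spec <- nmix_model_spec(label = focal,
                              detection_covariate = detection_covariate,
                              abundance_covariates = c("WATERBODY",
                                                       "NNDIST", focal))
      res <- fit_and_waic(spec, prepared, sites, counts, config,
                          seed + 211L * mi)
      rows[[k]] <- data.frame(
        label = focal,
        covariates = paste("Intercept WATERBODY NNDIST", focal),
        waic = res$waic)
    }
    tables[[lc]] <- rank_models(do.call(rbind, rows))
    winners[lc] <- tables[[lc]]$label[1]
  }
  list(tables = tables, winners = winners)
}

#' Final model-selection stage
#'
#' Fits the six final abundance models -- the four landscape covariates at
#' their selected scales plus the two infrastructure distances -- each as
#' intercept + WATERBODY + NNDIST + focal covariate with the chosen
#' detection covariate, and ranks them with the Delta-WAIC < 2 support
#' flag.
#'
#' @inheritParams run_scale_stage
#' @param winners named character mapping each landscape covariate to its
#'   selected column (as returned by [run_scale_stage()]).
#' @param distance_covariates infrastructure distance covariates.
#' @return list with `table` (a `selection_table`), `fits` (named list,
#'   all six), and `supported` (labels with Delta-WAIC < 2).
#' @export
run_final_stage <- function(sites, surveys, winners,
                            distance_covariates = c("DISTROAD",
                                                    "DISTRAILWAY"),
                            detection_covariate = "DEPTH",
                            config = mcmc_config(), seed = 1L) {
  expected <- c("URBAN", "CROPLAND", "WETLAND", "TERRSITES")
  if (!all(expected %in% names(winners)))
    stop("`winners` must map each of ",
         paste(expected, collapse = ", "), call. = FALSE)
  focals <- c(unname(winners[expected]), distance_covariates)
  prepared <- prepare_covariates(sites, surveys)
  counts <- counts_matrix(surveys)
  rows <- list(); fits <- list()
  for (k in seq_along(focals)) {
    focal <- focals[k]
    spec <- nmix_model_spec(label = focal,
                            detection_covariate = detection_covariate,
                            abundance_covariates = c("WATERBODY", "NNDIST",
                                                     focal))
    res <- fit_and_waic(spec, prepared, sites, counts, config,
                        seed + 307L * k)
    rows[[k]] <- data.frame(
      label = focal,
      covariates = paste("Intercept WATERBODY NNDIST", focal),
      waic = res$waic)
    fits[[focal]] <- res$fit
  }
  table <- rank_models(do.call(rbind, rows))
  list(table = table, fits = fits,
       supported = table$label[table$supported])
}

#' Reshape a survey table into a sites x surveys count matrix
#' @param surveys survey table with `site_id`, `survey`, `count`.
#' @return integer matrix, rows ordered by site_id, columns by survey.
#' @export
counts_matrix <- function(surveys) {
  if (!"count" %in% names(surveys))
    stop("survey table has no `count` column", call. = FALSE)
  idx <- order(surveys$site_id, surveys$survey)
  sv <- surveys[idx, ]
  J <- length(unique(sv$survey))
  matrix(as.integer(sv$count), ncol = J, byrow = TRUE)
}
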