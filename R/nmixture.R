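#' Specify an N-mixture model structure
#'
#' An N-mixture model here couples a Poisson abundance layer,
#' log(lambda_i) = beta0 + sum_k beta_k x_ik (+ eps_i), with a Binomial
#' detection layer, logit(p_ij) = alpha0 + alpha1 y_ij, the latent site
#' abundance N_i marginalized out of the likelihood. Abundance sub-models
#' are limited to three covariates beyond the intercept (a ten-sites-per-
#' parameter rule of thumb at 32 sites).
#'
#' @param label short model label used in selection tables.
#' @param detection_covariate survey covariate for the detection layer, or
#'   `NA` for intercept-only detection.
#' @param abundance_covariates character vector (possibly empty) of site
#'   covariates, at most 3.
#' @param random_effect include the site-level Normal(0, sigma_eps) random
#'   effect in log(lambda)?
#' @param waterbody_offset enter log waterbody area as a fixed offset
#'   (coefficient 1) instead of an estimated slope. Off by default: the
#'   default reading estimates a WATERBODY slope.
#' @return object of class `nmix_model_spec`.
#' @export
nmix_model_spec <- function(label, detection_covariate = NA_character_,
                            abundance_covariates = character(),
                            random_effect = TRUE,
                            waterbody_offset = FALSE) {
  if (length(abundance_covariates) > 3)
    stop("abundance sub-models are limited to 3 covariates, got ",
         length(abundance_covariates), call. = FALSE)
  structure(list(label = label,
                 detection_covariate = detection_covariate,
                 abundance_covariates = abundance_covariates,
                 random_effect = isTRUE(random_effect),
                 waterbody_offset = isTRUE(waterbody_offset)),
            class = "nmix_model_spec")
}

#' Marginalized site log-likelihood
#'
#' Computes log sum_{N = max(c)}^{K} Poisson(N | lambda) prod_j
#' Binomial(c_j | N, p_j) in log space (online log-sum-exp). With
#' `K = NULL` the truncation point is chosen adaptively so the neglected
#' Poisson tail mass is below ~1e-8.
#'
#' @param counts integer vector of counts at one site (one per survey).
#' @param lambda expected abundance (> 0).
#' @param p detection probabilities, one per survey, in \[0, 1\].
#' @param K truncation point for the latent-abundance sum, or `NULL` for
#'   adaptive choice. Must be >= max(counts).
#' @return the site log-likelihood (scalar).
#' @export
site_log_likelihood <- function(counts, lambda, p, K = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!is.finite(lambda) || lambda <= 0)
    stop("`lambda` must be positive", call. = FALSE)
  if (length(p) != length(counts))
    stop("`p` must have one entry per survey", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  if (is.null(K)) K <- -1L
  else if (K < max(counts))
    stop("`K` must be at least max(counts)", call. = FALSE)
  nmix_site_loglik_cpp(as.integer(counts), lambda, as.numeric(p),
                       as.integer(K))
}

#' Joint log-prior density
#'
#' Independent Normal(0, 10) priors on all detection and abundance
#' coefficients, Half-Normal(2.5) on sigma_eps, and Normal(0, sigma_eps)
#' on each site random effect. A non-positive sigma_eps with the random
#' effect on has zero prior mass (returns -Inf).
#'
#' @param params list with `alpha`, `beta`, and (when the spec has a
#'   random effect) `sigma_eps` and `eps`.
#' @param spec a [nmix_model_spec()].
#' @return log prior density (scalar; may be `-Inf`).
#' @export
log_prior <- function(params, spec) {
  stopifnot(inherits(spec, "nmix_model_spec"))
  lp <- sum(dnorm(c(params$alpha, params$beta), 0, 10, log = TRUE))
  if (spec$random_effect) {
    s <- params$sigma_eps
    if (is.null(s) || !is.finite(s) || s <= 0) return(-Inf)
    # Half-Normal(2.5): folded normal density on (0, Inf)
    lp <- lp + dnorm(s, 0, 2.5, log = TRUE) + log(2)
    lp <- lp + sum(dnorm(params$eps, 0, s, log = TRUE))
  }
  lp
}

#' MCMC configuration
#'
#' @param chains number of chains (>= 2 for convergence assessment).
#' @param iterations iterations per chain (including burn-in).
#' @param burnin burn-in iterations discarded per chain (adaptation happens
#'   here only).
#' @param thin retain every `thin`-th post-burn-in draw.
#' @return list of class `nmix_mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, iterations = 20000L, burnin = 5000L,
                        thin = 5L) {
  if (burnin >= iterations)
    stop("`burnin` must be smaller than `iterations`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  if (chains < 1L) stop("`chains` must be >= 1", call. = FALSE)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin)),
            class = "nmix_mcmc_config")
}

#' Fit an N-mixture model by adaptive Metropolis-within-Gibbs
#'
#' Samples the exact posterior of the marginalized Binomial-Poisson
#' N-mixture model: the latent N_i are never sampled but summed out of the
#' likelihood, which keeps the state space small. Updates are blocked as
#' (all coefficients jointly) | (each site random effect) | (log
#' sigma_eps), with the coefficient block using a Haario-style adaptive
#' covariance proposal tuned toward a 0.2--0.5 acceptance rate during
#' burn-in and frozen afterward (preserving detailed balance in the
#' retained draws). Each retained draw carries the per-site pointwise
#' log-likelihood (conditional on that draw's random effects), the unit
#' WAIC needs.
#'
#' @param spec a [nmix_model_spec()].
#' @param data list with `counts` (sites x surveys integer matrix), `X`
#'   (abundance design), `W` (detection design, site-major rows), and
#'   optional `offset` (length sites); see [build_design()].
#' @param config a [mcmc_config()].
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param fixed_alpha optional numeric: fix the detection coefficients at
#'   these values instead of sampling them (used e.g. when p is known).
#' @return object of class `nmix_fit`: per-chain draw matrices, per-chain
#'   pointwise log-likelihood matrices, parameter names, spec, config.
#' @export
fit_mcmc <- function(spec, data, config = mcmc_config(), seed = 1L,
                     fixed_alpha = NULL) {
  stopifnot(inherits(spec, "nmix_model_spec"),
            inherits(config, "nmix_mcmc_config"))
  counts <- data$counts
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  X <- as.matrix(data$X); W <- as.matrix(data$W)
  if (!all(is.finite(X)) || !all(is.finite(W)))
    stop("design matrices must be finite", call. = FALSE)
  n <- nrow(counts)
  offset <- if (is.null(data$offset)) rep(0, n) else data$offset
  if (nrow(X) != n || nrow(W) != n * ncol(counts))
    stop("design matrix rows do not match the count matrix", call. = FALSE)
  qdet <- ncol(W); pab <- ncol(X)
  fix_alpha <- !is.null(fixed_alpha)
  if (fix_alpha && length(fixed_alpha) != qdet)
    stop("`fixed_alpha` must match the detection design columns",
         call. = FALSE)

  par_names <- c(paste0("alpha_", colnames(W)),
                 paste0("beta_", colnames(X)),
                 "sigma_eps", paste0("eps_", seq_len(n)))
  chains <- vector("list", config$chains)
  lls <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(seed + ch - 1L)
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      a0 <- if (fix_alpha) as.numeric(fixed_alpha) else
        rnorm(qdet, 0, 0.3 * attempt / 10)
      # start the abundance intercept near the naive log mean count
      b0 <- rnorm(pab, 0, 0.3 * attempt / 10)
      b0[1] <- log(mean(counts) + 0.5) + rnorm(1, 0, 0.3)
      s0 <- 0.5
      e0 <- rep(0, n)
      init_ll <- sum(vapply(seq_len(n), function(i) {
        pv <- plogis(drop(W[(i - 1) * ncol(counts) + seq_len(ncol(counts)),
                            , drop = FALSE] %*% a0))
        nmix_site_loglik_cpp(counts[i, ], exp(offset[i] +
          drop(X[i, , drop = FALSE] %*% b0)), pv, -1L)
      }, numeric(1)))
      if (is.finite(init_ll)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not find finite starting values after 100 re-draws",
           call. = FALSE)
    res <- nmix_mcmc_cpp(counts, X, W, offset, spec$random_effect,
                         a0, b0, s0, e0, fix_alpha,
                         config$iterations, config$burnin, config$thin,
                         10, 2.5)
    dr <- res$draws[seq_len(res$kept), , drop = FALSE]
    colnames(dr) <- par_names
    chains[[ch]] <- dr
    lls[[ch]] <- res$loglik[seq_len(res$kept), , drop = FALSE]
    if (anyNA(lls[[ch]]))
      stop("NaN in likelihood during sampling", call. = FALSE)
  }
  structure(list(chains = chains, loglik = lls, par_names = par_names,
                 n_sites = n, spec = spec, config = config, seed = seed,
                 fixed_alpha = fixed_alpha),
            class = "nmix_fit")
}

#' Pool retained draws across chains
#' @param fit an `nmix_fit`.
#' @return matrix (all retained draws) x parameters.
#' @export
pooled_draws <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  do.call(rbind, fit$chains)
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat("N-mixture fit:", x$spec$label, "\n")
  cat(sprintf("  %d chain(s) x %d retained draws, %d sites\n",
              length(x$chains), nrow(x$chains[[1]]), x$n_sites))
  invisible(x)
}

#' Abundance and detection predictions from parameters
#'
#' Applies the model's link functions: lambda = exp(X beta + offset + eps)
#' and p = plogis(W alpha).
#'
#' @param params list with `alpha`, `beta`, optional `eps` (default 0).
#' @param designs list with `X`, `W`, optional `offset`, and `n_surveys`.
#' @return list with `lambda` (per site) and `p` (site x survey matrix).
#' @export
link_predictions <- function(params, designs) {
  X <- as.matrix(designs$X); W <- as.matrix(designs$W)
  if (ncol(X) != length(params$beta) || ncol(W) != length(params$alpha))
    stop("parameter lengths do not match design columns", call. = FALSE)
  n <- nrow(X)
  offset <- if (is.null(designs$offset)) rep(0, n) else designs$offset
  eps <- if (is.null(params$eps)) rep(0, n) else params$eps
  lambda <- exp(drop(X %*% params$beta) + offset + eps)
  J <- nrow(W) / n
  p <- matrix(plogis(drop(W %*% params$alpha)), nrow = n, byrow = TRUE)
  list(lambda = lambda, p = p)
}
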