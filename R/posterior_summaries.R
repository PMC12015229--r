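#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Classic R-hat: with m chains of length n, within-chain variance W (mean
#' of chain variances), between-chain variance B = n * var(chain means),
#' R-hat = sqrt(((n - 1)/n * W + B/n) / W). Values below 1.1 are taken as
#' satisfactory convergence.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths of
#'   at least 10), or a matrix with one column per chain.
#' @return R-hat (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 10)
    stop("chains must have equal lengths >= 10", call. = FALSE)
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' R-hat for every parameter of a fit
#' @param fit an `nmix_fit` with >= 2 chains.
#' @param parameters parameter names (default: all coefficients and
#'   sigma_eps; site random effects are excluded unless asked for).
#' @return named numeric vector of R-hat values.
#' @export
rhat <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (is.null(parameters))
    parameters <- grep("^eps_", fit$par_names, value = TRUE, invert = TRUE)
  if (!fit$spec$random_effect)
    parameters <- setdiff(parameters, "sigma_eps")
  if (!is.null(fit$fixed_alpha))
    parameters <- grep("^alpha_", parameters, value = TRUE, invert = TRUE)
  vapply(parameters, function(p)
    gelman_rubin(lapply(fit$chains, function(ch) ch[, p])), numeric(1))
}

#' Proportion of the posterior on the dominant sign (f-statistic)
#'
#' f = 100 * max(fraction of draws > 0, fraction of draws < 0), with draws
#' exactly at zero split evenly between the signs. Interpretable as the
#' percent probability that the effect is positive (or negative).
#'
#' @param draws numeric vector of posterior draws (>= 1).
#' @return f in percent (0--100).
#' @export
f_statistic <- function(draws) {
  if (!length(draws)) stop("empty draws", call. = FALSE)
  pos <- sum(draws > 0) + sum(draws == 0) / 2
  neg <- sum(draws < 0) + sum(draws == 0) / 2
  100 * max(pos, neg) / length(draws)
}

#' Posterior summary table
#'
#' Pools the retained draws across chains and reports, per parameter, the
#' posterior mean, SD, 2.5th and 97.5th percentiles (95% credible
#' interval, linear-interpolation quantiles), the f-statistic, and an
#' importance flag: important when the credible interval excludes zero or
#' f > 90. A warning is attached if any requested parameter has
#' R-hat >= 1.1.
#'
#' @param fit an `nmix_fit`.
#' @param parameters parameter names (default: coefficients + sigma_eps).
#' @return data.frame: parameter, mean, sd, q2.5, q97.5, f, important.
#' @export
summarize_posterior <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (is.null(parameters)) {
    parameters <- grep("^eps_", fit$par_names, value = TRUE, invert = TRUE)
    if (!fit$spec$random_effect)
      parameters <- setdiff(parameters, "sigma_eps")
    if (!is.null(fit$fixed_alpha))
      parameters <- grep("^alpha_", parameters, value = TRUE, invert = TRUE)
  }
  bad <- setdiff(parameters, fit$par_names)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(fit$chains) >= 2) {
    rh <- rhat(fit, intersect(parameters,
                              grep("^eps_", parameters, value = TRUE,
                                   invert = TRUE)))
    if (any(rh >= 1.1))
      warning("R-hat >= 1.1 for: ",
              paste(names(rh)[rh >= 1.1], collapse = ", "),
              "; summaries may be unreliable", call. = FALSE)
  }
  draws <- pooled_draws(fit)
  rows <- lapply(parameters, function(p) {
    x <- draws[, p]
    q <- quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    f <- f_statistic(x)
    data.frame(parameter = p, mean = mean(x), sd = sd(x),
               q2.5 = q[1], q97.5 = q[2], f = f,
               important = (q[1] > 0 || q[2] < 0) || f > 90)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Abundance response curve for a focal covariate
#'
#' Predicts mean abundance across the focal covariate's observed range
#' (original scale, back-transformed through any log; never extrapolating
#' beyond observed min/max), holding all other covariates at their sample
#' means (standardized 0). For each posterior draw, lambda(x) = exp(beta0 +
#' beta_focal * x_std), and the site random effect is integrated out by
#' Monte-Carlo averaging exp(eps) over eps ~ Normal(0, sigma_eps) at that
#' draw's sigma (setting eps = 0 instead would bias the mean curve low,
#' since exp is convex). The curve is the posterior mean and 2.5/97.5
#' percentiles of lambda at each grid point.
#'
#' @param fit an `nmix_fit` whose model contains the focal covariate.
#' @param focal_covariate covariate name.
#' @param record the site `standardization_record`.
#' @param observed numeric vector of the covariate's observed values on
#'   the original scale (defines the grid range).
#' @param n_grid grid size.
#' @param integrate_re integrate over the random effect (default TRUE when
#'   the model has one)?
#' @param re_draws Monte-Carlo draws for the random-effect integral.
#' @return data.frame: x (original scale), mean, lo, hi.
#' @export
response_curve <- function(fit, focal_covariate, record, observed,
                           n_grid = 50, integrate_re = NULL,
                           re_draws = 40) {
  stopifnot(inherits(fit, "nmix_fit"))
  bcol <- paste0("beta_", focal_covariate)
  if (!bcol %in% fit$par_names)
    stop("covariate ", focal_covariate, " is not in the fitted model",
         call. = FALSE)
  if (is.null(integrate_re)) integrate_re <- fit$spec$random_effect
  draws <- pooled_draws(fit)
  b0 <- draws[, "beta_Intercept"]
  bf <- draws[, bcol]
  xs <- seq(min(observed), max(observed), length.out = n_grid)
  zs <- apply_standardization(record, xs, focal_covariate)
  re_factor <- if (integrate_re && fit$spec$random_effect) {
    sig <- draws[, "sigma_eps"]
    vapply(sig, function(s) mean(exp(rnorm(re_draws, 0, s))), numeric(1))
  } else rep(1, nrow(draws))
  out <- data.frame(x = xs, mean = NA_real_, lo = NA_real_, hi = NA_real_)
  for (g in seq_len(n_grid)) {
    lam <- exp(b0 + bf * zs[g]) * re_factor
    q <- quantile(lam, c(0.025, 0.975), names = FALSE)
    out$mean[g] <- mean(lam); out$lo[g] <- q[1]; out$hi[g] <- q[2]
  }
  out
}
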