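#' Read and validate a site table
#'
#' Expects a CSV with one row per site: `site_id`, the twelve
#' `<CLASS><RADIUS>` percent covers, `WATERBODY`, `NNDIST`, `DISTROAD`,
#' `DISTRAILWAY`. A `DISTMAINROAD` header is accepted as an alias for
#' `DISTROAD`. All violations are collected and reported together.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_sites <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if ("DISTMAINROAD" %in% names(tab) && !"DISTROAD" %in% names(tab))
    names(tab)[names(tab) == "DISTMAINROAD"] <- "DISTROAD"
  problems <- character()
  need <- c("site_id", site_covariate_names())
  miss <- setdiff(need, names(tab))
  if (length(miss))
    problems <- c(problems,
                  paste("missing column(s):", paste(miss, collapse = ", ")))
  if ("site_id" %in% names(tab) && anyDuplicated(tab$site_id))
    problems <- c(problems, "duplicate site_id values")
  covers <- grep("^(URBAN|CROPLAND|WETLAND|TERRSITES)", names(tab),
                 value = TRUE)
  for (nm in covers) {
    bad <- which(!is.finite(tab[[nm]]) | tab[[nm]] < 0 | tab[[nm]] > 100)
    if (length(bad))
      problems <- c(problems,
                    sprintf("%s outside [0, 100] at row(s) %s", nm,
                            paste(bad, collapse = ", ")))
  }
  for (nm in intersect(c("WATERBODY", "NNDIST", "DISTROAD", "DISTRAILWAY"),
                       names(tab))) {
    bad <- which(!is.finite(tab[[nm]]) | tab[[nm]] <= 0)
    if (length(bad))
      problems <- c(problems,
                    sprintf("%s must be > 0; bad row(s): %s", nm,
                            paste(bad, collapse = ", ")))
  }
  if (length(problems))
    stop("site table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  tab
}

#' Read and validate a survey table
#'
#' Expects a CSV with one row per site x survey: `site_id`, `survey`,
#' `count`, `DEPTH`, `WTEMP`, `VEG`, `DATE`, `TRAPS`. Counts must be
#' non-negative integers, every site must have the same number of surveys,
#' and covariates must be complete.
#'
#' @param path CSV path.
#' @return validated data.frame ordered by site and survey.
#' @export
read_surveys <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  problems <- character()
  need <- c("site_id", "survey", "count", survey_covariate_names())
  miss <- setdiff(need, names(tab))
  if (length(miss))
    problems <- c(problems,
                  paste("missing column(s):", paste(miss, collapse = ", ")))
  if ("count" %in% names(tab)) {
    bad <- which(!is.finite(tab$count) | tab$count < 0 |
                   tab$count != round(tab$count))
    if (length(bad))
      problems <- c(problems,
                    sprintf("count must be a non-negative integer; bad row(s): %s",
                            paste(bad, collapse = ", ")))
  }
  if (all(c("site_id", "survey") %in% names(tab))) {
    per_site <- table(tab$site_id)
    if (length(unique(per_site)) > 1)
      problems <- c(problems, "unbalanced design: sites differ in survey count")
  }
  covs <- intersect(survey_covariate_names(), names(tab))
  if (length(covs)) {
    bad <- which(!complete.cases(tab[covs]))
    if (length(bad))
      problems <- c(problems,
                    sprintf("missing covariate value(s) at row(s): %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(problems))
    stop("survey table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  tab <- tab[order(tab$site_id, tab$survey), ]
  rownames(tab) <- NULL
  tab
}

#' Write posterior draws to CSV plus a JSON meta sidecar
#'
#' The draws file is long-format columnar (`chain`, `iteration`,
#' `parameter`, `value`); the sidecar records the model label, chain
#' count, iterations, burn-in, thinning and seed so external diagnostics
#' tools can interpret the draws.
#'
#' @param fit an `nmix_fit`.
#' @param prefix path prefix; writes `<prefix>.csv` and
#'   `<prefix>_meta.json`.
#' @export
write_draws <- function(fit, prefix) {
  stopifnot(inherits(fit, "nmix_fit"))
  long <- do.call(rbind, lapply(seq_along(fit$chains), function(ch) {
    m <- fit$chains[[ch]]
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  write.csv(long, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(label = fit$spec$label, chains = length(fit$chains),
               iterations = fit$config$iterations,
               burnin = fit$config$burnin, thin = fit$config$thin,
               seed = fit$seed, parameters = fit$par_names)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a draws CSV back into per-chain matrices
#' @param prefix path prefix used by [write_draws()].
#' @return list with `chains` (list of matrices) and `meta`.
#' @export
read_draws <- function(prefix) {
  long <- read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  chains <- lapply(sort(unique(long$chain)), function(ch) {
    sub <- long[long$chain == ch, ]
    pars <- unique(sub$parameter)
    m <- sapply(pars, function(p) sub$value[sub$parameter == p])
    colnames(m) <- pars
    m
  })
  list(chains = chains, meta = meta)
}

#' Write / read a selection table
#' @param table a `selection_table`.
#' @param path CSV path.
#' @export
write_selection <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("selection_table", "data.frame")
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' @param scenario a [newt_scenario()] for simulation-driven runs, or NULL
#'   to read tables from `sites_path` / `surveys_path`.
#' @param sites_path,surveys_path CSV paths (ignored when `scenario` is
#'   given).
#' @param mcmc a [mcmc_config()].
#' @param seed integer seed; mandatory, for cross-machine reproducibility.
#' @param out_dir output directory.
#' @param detection_candidates,landscape_covariates,scales,distance_covariates
#'   stage plan.
#' @return list of class `newt_run_config`.
#' @export
run_config <- function(scenario = NULL, sites_path = NULL,
                       surveys_path = NULL, mcmc = mcmc_config(),
                       seed, out_dir,
                       detection_candidates = c("DEPTH", "DATE", "TRAPS",
                                                "WTEMP", "VEG"),
                       landscape_covariates = c("URBAN", "CROPLAND",
                                                "WETLAND", "TERRSITES"),
                       scales = c(250, 500, 1000),
                       distance_covariates = c("DISTROAD", "DISTRAILWAY")) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(inherits(mcmc, "nmix_mcmc_config"))
  if (mcmc$chains < 2)
    stop("pipeline runs need >= 2 chains for convergence assessment",
         call. = FALSE)
  if (is.null(scenario) && (is.null(sites_path) || is.null(surveys_path)))
    stop("give either a `scenario` or both table paths", call. = FALSE)
  structure(list(scenario = scenario, sites_path = sites_path,
                 surveys_path = surveys_path, mcmc = mcmc,
                 seed = as.integer(seed), out_dir = out_dir,
                 detection_candidates = detection_candidates,
                 landscape_covariates = landscape_covariates,
                 scales = scales,
                 distance_covariates = distance_covariates),
            class = "newt_run_config")
}

#' Run the full staged workflow
#'
#' simulate (or read) -> prepare -> detection stage (5 models) -> scale
#' stage (12) -> final stage (6) -> posterior summaries, R-hat report and
#' response curves for every supported final model. Writes every selection
#' table, summary CSV, draws file, the curves, and a machine-readable
#' `manifest.json` (config, seed, stage timings and model counts) under
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "newt_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_line(sprintf("stage %s done in %.1fs", name,
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if (!is.null(config$scenario)) {
    sim <- stage("simulate", simulate_newt_survey(config$scenario))
    sites <- sim$sites; surveys <- sim$surveys
    write.csv(sites, file.path(config$out_dir, "sites.csv"),
              row.names = FALSE)
    write.csv(surveys, file.path(config$out_dir, "surveys.csv"),
              row.names = FALSE)
    write.csv(sim$truth, file.path(config$out_dir, "truth.csv"),
              row.names = FALSE)
  } else {
    sites <- read_sites(config$sites_path)
    surveys <- read_surveys(config$surveys_path)
    if (!setequal(surveys$site_id, sites$site_id))
      stop("site ids in the survey table do not match the site table",
           call. = FALSE)
  }

  prep <- prepare_covariates(sites, surveys)
  write_standardization(prep$site_record,
                        file.path(config$out_dir, "site_record.json"))
  scr <- collinearity_screen(sites, intersect(site_covariate_names(),
                                              names(sites)))
  if (nrow(scr)) log_line("collinearity warning: ", nrow(scr), " pair(s)")

  det <- stage("detection", run_detection_stage(
    sites, surveys, config$detection_candidates, config$mcmc,
    seed = config$seed))
  write_selection(det$table,
                  file.path(config$out_dir, "selection_detection.csv"))
  log_line("detection stage: ", nrow(det$table), " models; winner ",
           det$winner)

  scl <- stage("scale", run_scale_stage(
    sites, surveys, config$landscape_covariates, config$scales,
    detection_covariate = det$winner, config$mcmc,
    seed = config$seed + 10000L))
  for (lc in names(scl$tables))
    write_selection(scl$tables[[lc]],
                    file.path(config$out_dir,
                              sprintf("selection_scale_%s.csv", lc)))
  log_line("scale stage: ", sum(vapply(scl$tables, nrow, integer(1))),
           " models")

  fin <- stage("final", run_final_stage(
    sites, surveys, scl$winners, config$distance_covariates,
    detection_covariate = det$winner, config$mcmc,
    seed = config$seed + 20000L))
  write_selection(fin$table,
                  file.path(config$out_dir, "selection_final.csv"))
  log_line("final stage: ", nrow(fin$table), " models; supported: ",
           paste(fin$supported, collapse = ", "))

  rhat_rows <- list()
  for (lab in fin$supported) {
    fit <- fin$fits[[lab]]
    write_draws(fit, file.path(config$out_dir, paste0("draws_", lab)))
    summ <- suppressWarnings(summarize_posterior(fit))
    write.csv(summ, file.path(config$out_dir,
                              paste0("summary_", lab, ".csv")),
              row.names = FALSE)
    rh <- rhat(fit)
    rhat_rows[[lab]] <- data.frame(model = lab, parameter = names(rh),
                                   rhat = unname(rh))
    focal <- setdiff(fit$spec$abundance_covariates,
                     c("WATERBODY", "NNDIST"))
    for (fc in focal) {
      obs <- if (prep$site_record$log[[fc]]) exp(prep$sites[[fc]] *
        prep$site_record$sd[[fc]] + prep$site_record$mean[[fc]]) else
        prep$sites[[fc]] * prep$site_record$sd[[fc]] +
          prep$site_record$mean[[fc]]
      curve <- response_curve(fit, fc, prep$site_record, obs)
      write.csv(curve, file.path(config$out_dir,
                                 sprintf("curve_%s_%s.csv", lab, fc)),
                row.names = FALSE)
    }
  }
  if (length(rhat_rows))
    write.csv(do.call(rbind, rhat_rows),
              file.path(config$out_dir, "rhat_report.csv"),
              row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    mcmc = unclass(config$mcmc),
    scenario = if (!is.null(config$scenario)) unclass(config$scenario),
    n_models = list(detection = nrow(det$table),
                    scale = sum(vapply(scl$tables, nrow, integer(1))),
                    final = nrow(fin$table)),
    detection_winner = det$winner,
    scale_winners = as.list(scl$winners),
    supported_final = fin$supported,
    package_version = as.character(utils::packageVersion("newtmix")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line("pipeline complete: ",
           manifest$n_models$detection + manifest$n_models$scale +
             manifest$n_models$final, " models fitted")
  invisible(config$out_dir)
}
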