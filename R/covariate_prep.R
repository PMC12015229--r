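#' Natural-log transform of strictly positive covariates
#'
#' @param table data.frame.
#' @param covariate_names columns to replace by their natural log.
#' @return the table with the named columns log-transformed.
#' @export
log_transform <- function(table, covariate_names) {
  miss <- setdiff(covariate_names, names(table))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in covariate_names) {
    bad <- which(!is.finite(table[[nm]]) | table[[nm]] <= 0)
    if (length(bad))
      stop(sprintf(
        "non-positive value in column %s at row(s) %s: log undefined",
        nm, paste(bad, collapse = ", ")), call. = FALSE)
    table[[nm]] <- log(table[[nm]])
  }
  table
}

#' Standardize covariates to mean 0, SD 1
#'
#' Centers and scales each named column using the sample SD (n - 1
#' denominator) and records the constants so the mapping can be inverted
#' and reapplied at prediction time.
#'
#' @param table data.frame.
#' @param covariate_names columns to standardize (must be non-constant).
#' @param log_flags optional named logical: which covariates were
#'   log-transformed upstream (kept in the record for back-transformation).
#' @return list with `table` (standardized) and `record`
#'   (a `standardization_record`).
#' @export
standardize <- function(table, covariate_names, log_flags = NULL) {
  miss <- setdiff(covariate_names, names(table))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  mu <- s <- setNames(numeric(length(covariate_names)), covariate_names)
  for (nm in covariate_names) {
    x <- table[[nm]]
    mu[nm] <- mean(x)
    s[nm] <- sd(x)
    if (!is.finite(s[nm]) || s[nm] <= 0)
      stop("column ", nm, " is constant; cannot standardize", call. = FALSE)
    table[[nm]] <- (x - mu[nm]) / s[nm]
  }
  lf <- setNames(rep(FALSE, length(covariate_names)), covariate_names)
  if (!is.null(log_flags)) lf[names(log_flags)] <- log_flags
  record <- structure(list(mean = mu, sd = s, log = lf),
                      class = "standardization_record")
  list(table = table, record = record)
}

#' Apply a stored standardization to new values
#'
#' @param record a `standardization_record`.
#' @param x numeric values on the original (pre-log) scale.
#' @param covariate which covariate's constants to use.
#' @return standardized values.
#' @export
apply_standardization <- function(record, x, covariate) {
  stopifnot(inherits(record, "standardization_record"))
  if (!covariate %in% names(record$mean))
    stop("covariate ", covariate, " not in record", call. = FALSE)
  if (record$log[[covariate]]) x <- log(x)
  (x - record$mean[[covariate]]) / record$sd[[covariate]]
}

#' Invert a stored standardization
#'
#' @inheritParams apply_standardization
#' @param z standardized values.
#' @return values on the original (pre-log) scale.
#' @export
inverse_standardization <- function(record, z, covariate) {
  stopifnot(inherits(record, "standardization_record"))
  if (!covariate %in% names(record$mean))
    stop("covariate ", covariate, " not in record", call. = FALSE)
  x <- z * record$sd[[covariate]] + record$mean[[covariate]]
  if (record$log[[covariate]]) x <- exp(x)
  x
}

#' Save / load a standardization record as JSON
#' @param record a `standardization_record`.
#' @param path file path.
#' @export
write_standardization <- function(record, path) {
  stopifnot(inherits(record, "standardization_record"))
  jsonlite::write_json(lapply(unclass(record), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(list(mean = unlist(raw$mean), sd = unlist(raw$sd),
                 log = unlist(raw$log)),
            class = "standardization_record")
}

#' Screen covariate pairs for collinearity
#'
#' Flags every pair whose absolute Pearson correlation reaches the cutoff.
#' The screen is advisory: it warns rather than stops, since it is meant
#' for covariate vetting, not automated exclusion.
#'
#' @param table data.frame with >= 3 rows.
#' @param covariate_names columns to screen.
#' @param cutoff absolute Pearson R at or above which a pair is flagged.
#' @return data.frame (`var1`, `var2`, `r`), zero rows if the table passes.
#' @export
collinearity_screen <- function(table, covariate_names, cutoff = 0.7) {
  if (nrow(table) < 3)
    stop("need at least 3 rows to estimate correlations", call. = FALSE)
  miss <- setdiff(covariate_names, names(table))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  R <- cor(table[covariate_names])
  out <- data.frame(var1 = character(), var2 = character(), r = numeric())
  nms <- covariate_names
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j > i && abs(R[i, j]) >= cutoff)
      out <- rbind(out, data.frame(var1 = nms[i], var2 = nms[j],
                                   r = R[i, j]))
  }
  if (nrow(out))
    warning(sprintf("%d covariate pair(s) at |R| >= %.2f", nrow(out),
                    cutoff), call. = FALSE)
  out
}

#' Prepare raw site and survey tables for modelling
#'
#' Applies the analysis's covariate recipe in one step: WATERBODY, NNDIST,
#' DISTROAD and DISTRAILWAY are log-transformed, then every site covariate
#' is standardized over sites and every survey covariate over all
#' site x survey rows jointly.
#'
#' @param site_table raw site table (see [generate_site_covariates()]).
#' @param survey_covs raw survey table (see
#'   [generate_survey_covariates()]).
#' @return list with standardized `sites`, `surveys`, and the two
#'   `standardization_record`s (`site_record`, `survey_record`).
#' @export
prepare_covariates <- function(site_table, survey_covs) {
  log_vars <- intersect(c("WATERBODY", "NNDIST", "DISTROAD", "DISTRAILWAY"),
                        names(site_table))
  site_vars <- intersect(site_covariate_names(), names(site_table))
  surv_vars <- intersect(survey_covariate_names(), names(survey_covs))
  sites <- log_transform(site_table, log_vars)
  st <- standardize(sites, site_vars,
                    log_flags = setNames(site_vars %in% log_vars, site_vars))
  sv <- standardize(survey_covs, surv_vars)
  list(sites = st$table, surveys = sv$table,
       site_record = st$record, survey_record = sv$record)
}

#' Assemble model design matrices from a model specification
#'
#' Builds the abundance design matrix (intercept followed by the spec's
#' abundance covariates, in order) from the standardized site table, and
#' the detection design matrix (intercept plus the spec's detection
#' covariate, if any) from the standardized survey table. Detection rows
#' are ordered site-major: all surveys of site 1, then site 2, and so on.
#' When the spec requests the waterbody-offset variant, log(WATERBODY)
#' (unstandardized) enters as a fixed offset instead of an estimated slope.
#'
#' @param spec a [nmix_model_spec()].
#' @param prepared output of [prepare_covariates()].
#' @param raw_site_table the raw site table; required only for the offset
#'   variant, to recover unstandardized log areas.
#' @return list with `X` (sites x coefficients), `W`
#'   ((sites*surveys) x coefficients), `offset` (length sites),
#'   `counts_order` (site ids in row order).
#' @export
build_design <- function(spec, prepared, raw_site_table = NULL) {
  stopifnot(inherits(spec, "nmix_model_spec"))
  sites <- prepared$sites
  surveys <- prepared$surveys
  ab <- spec$abundance_covariates
  miss <- setdiff(ab, names(sites))
  if (length(miss))
    stop("abundance covariate(s) not in site table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind(Intercept = rep(1, nrow(sites)))
  if (length(ab)) X <- cbind(X, as.matrix(sites[ab]))
  colnames(X) <- c("Intercept", ab)
  offset <- rep(0, nrow(sites))
  if (isTRUE(spec$waterbody_offset)) {
    if (is.null(raw_site_table))
      stop("waterbody offset requested but `raw_site_table` not given",
           call. = FALSE)
    offset <- log(raw_site_table$WATERBODY)
  }
  idx <- order(surveys$site_id, surveys$survey)
  sv <- surveys[idx, , drop = FALSE]
  W <- cbind(Intercept = rep(1, nrow(sv)))
  if (!is.na(spec$detection_covariate)) {
    if (!spec$detection_covariate %in% names(sv))
      stop("detection covariate not in survey table: ",
           spec$detection_covariate, call. = FALSE)
    W <- cbind(W, sv[[spec$detection_covariate]])
    colnames(W) <- c("Intercept", spec$detection_covariate)
  }
  list(X = X, W = W, offset = offset, counts_order = unique(sv$site_id))
}
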