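#' Read index-trial individual patient data from CSV
#'
#' @param path CSV file with a header row.
#' @param covariates,treatment,outcome Column declarations; all must be
#'   present, numeric, and free of missing values, and treatment must be
#'   coded 0/1 with both arms present.
#'
#' @return A validated tibble.
#' @export
read_ipd <- function(path, covariates, treatment = "treatment",
                     outcome = "outcome") {
  data <- as_tibble(read.csv(path))
  needed <- c(covariates, treatment, outcome)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_shape(sprintf("IPD file '%s' lacks column(s): %s",
                       path, paste(missing_cols, collapse = ", ")))
  }
  for (col in needed) {
    bad <- which(is.na(data[[col]]))
    if (length(bad) > 0) {
      stop_shape(sprintf("missing value in column '%s', row %d of '%s'",
                         col, bad[1], path))
    }
  }
  check_treatment(data[[treatment]])
  data
}

#' Read competitor-trial aggregate data from JSON or CSV
#'
#' JSON files hold an object with fields `covariate_means` (named),
#' `effect_estimate`, `effect_variance` and optionally `sample_size`.
#' CSV files hold two columns `name,value` where covariate rows are named
#' after the covariates they summarize.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return A [competitor_ald()].
#' @export
read_ald <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$covariate_means) || is.null(obj$effect_estimate) ||
        is.null(obj$effect_variance)) {
      stop_shape(sprintf(
        "ALD file '%s' must provide covariate_means, effect_estimate, effect_variance",
        path
      ))
    }
    competitor_ald(unlist(obj$covariate_means), obj$effect_estimate,
                   obj$effect_variance, obj$sample_size)
  } else {
    kv <- read.csv(path)
    if (!all(c("name", "value") %in% names(kv))) {
      stop_shape(sprintf("ALD CSV '%s' needs columns 'name' and 'value'", path))
    }
    vals <- setNames(as.numeric(kv$value), kv$name)
    reserved <- c("effect_estimate", "effect_variance", "sample_size")
    if (!all(c("effect_estimate", "effect_variance") %in% names(vals))) {
      stop_shape(sprintf(
        "ALD CSV '%s' must provide effect_estimate and effect_variance rows", path
      ))
    }
    competitor_ald(
      vals[setdiff(names(vals), reserved)],
      vals[["effect_estimate"]], vals[["effect_variance"]],
      if ("sample_size" %in% names(vals)) vals[["sample_size"]] else NULL
    )
  }
}

#' Write a per-subject weight table to CSV
#'
#' @param path Output CSV path.
#' @param trial_fit A `trial_weight_fit`.
#' @param propensity_fit Optional `propensity_fit`.
#' @param combined,truncated Optional `weight_set`s to include.
#' @return The written tibble, invisibly.
#' @export
write_weight_table <- function(path, trial_fit, propensity_fit = NULL,
                               combined = NULL, truncated = NULL) {
  out <- tibble(
    subject_index = seq_len(trial_fit$n),
    trial_weight = trial_fit$weights,
    propensity = if (is.null(propensity_fit)) NA_real_ else propensity_fit$scores,
    combined_weight = if (is.null(combined)) NA_real_ else combined$values,
    truncated_weight = if (is.null(truncated)) NA_real_ else truncated$values
  )
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
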