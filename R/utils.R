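# classed conditions used across the package -------------------------------

stop_separation <- function(covariates) {
  abort(
    paste0(
      "No feasible weight solution: every observed value of ",
      paste0("'", covariates, "'", collapse = ", "),
      " lies strictly on one side of its target mean."
    ),
    class = "maic2s_separation",
    covariates = covariates
  )
}

stop_shape <- function(msg) abort(msg, class = "maic2s_shape")
stop_domain <- function(msg) abort(msg, class = "maic2s_domain")

stop_convergence <- function(grad_norm, iterations) {
  abort(
    sprintf(
      "Weight solver did not converge after %d iterations (relative gradient norm %.3g).",
      iterations, grad_norm
    ),
    class = "maic2s_convergence",
    grad_norm = grad_norm,
    iterations = iterations
  )
}

# deterministic child seeds ----------------------------------------------
# One stream per (base seed, scenario, replicate).  The multipliers keep
# distinct (scenario, replicate) pairs distinct for replicate ids below
# 10007, and the result stays inside the 32-bit integer range set.seed()
# accepts.  All arithmetic is exact in doubles (< 2^53).
child_seed <- function(base_seed, scenario_id = 0L, replicate_id = 0L) {
  v <- (as.double(base_seed) %% 1e6) * 1000003 +
    as.double(scenario_id) * 10007 + as.double(replicate_id)
  as.integer(v %% 2147483646) + 1L
}

# column extraction with a helpful error
pull_columns <- function(data, cols, what = "covariate") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_shape(sprintf(
      "%s column(s) not found in data: %s",
      what, paste(missing_cols, collapse = ", ")
    ))
  }
  m <- as.matrix(data[cols])
  if (!is.numeric(m)) stop_shape(sprintf("%s columns must be numeric", what))
  if (anyNA(m)) stop_shape(sprintf("missing values in %s columns", what))
  m
}

check_treatment <- function(t) {
  if (anyNA(t) || !all(t %in% c(0, 1))) {
    stop_shape("treatment must be coded 0/1 with no missing values")
  }
  if (length(unique(t)) < 2) {
    stop_shape("both treatment arms must be present")
  }
  as.numeric(t)
}
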