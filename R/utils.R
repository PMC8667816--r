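# internal validation helpers

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    rlang::abort(sprintf("`%s` must be a finite numeric value.", name),
                 class = "mitoquant_parameter_error")
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper)) {
    rlang::abort(sprintf(
      "`%s` must be %s %s%s.", name,
      if (strict_lower) "greater than" else "at least", lower,
      if (is.finite(upper)) sprintf(" and at most %s", upper) else ""),
      class = "mitoquant_parameter_error")
  }
  invisible(x)
}

check_positive <- function(x, name) check_number(x, name, lower = 0, strict_lower = TRUE)
check_nonneg <- function(x, name) check_number(x, name, lower = 0)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min) {
    rlang::abort(sprintf("`%s` must be an integer >= %d.", name, min),
                 class = "mitoquant_parameter_error")
  }
  invisible(as.integer(x))
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s is missing required column(s): %s.",
                         what, paste(missing, collapse = ", ")),
                 class = "mitoquant_data_error")
  }
  invisible(df)
}

# set the RNG for the duration of the calling function, restoring state on exit
local_sim_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    check_count(seed, "seed", min = 0L)
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
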