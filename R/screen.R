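#' Property pre-filter for a docking score matrix
#'
#' Removes compounds with molecular weight above `max_mw` Dalton and, when
#' requested, compounds carrying a nitro group. Both filters reproduce the
#' pre-docking library triage used in structure-based screens: the boundary
#' weight itself is kept (only weights strictly greater than `max_mw` are
#' excluded).
#'
#' @param matrix A score matrix tibble with a `compound_id` column; an `mw`
#'   column (Dalton) is required when `max_mw` is finite and a logical
#'   `has_nitro` column when `exclude_nitro = TRUE`.
#' @param max_mw Molecular-weight cutoff in Dalton (`Inf` disables).
#' @param exclude_nitro Drop compounds with `has_nitro == TRUE`.
#'
#' @return The filtered tibble. The number of removed rows is reported via
#'   `message()` and stored in attribute `"n_removed"`.
#' @export
prefilter <- function(matrix, max_mw = 500, exclude_nitro = TRUE) {
  check_cols(matrix, "compound_id", "score matrix")
  keep <- rep(TRUE, nrow(matrix))
  if (is.finite(max_mw)) {
    if (!"mw" %in% names(matrix)) {
      rlang::abort("Molecular-weight filtering requires an `mw` column.",
                   class = "mitoquant_config_error")
    }
    keep <- keep & matrix$mw <= max_mw
  }
  if (isTRUE(exclude_nitro)) {
    if (!"has_nitro" %in% names(matrix)) {
      rlang::abort("Nitro filtering requires a `has_nitro` column.",
                   class = "mitoquant_config_error")
    }
    keep <- keep & !matrix$has_nitro
  }
  out <- matrix[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  message(sprintf("prefilter: removed %d of %d compounds", n_removed,
                  nrow(matrix)))
  attr(out, "n_removed") <- n_removed
  out
}

score_columns <- function(matrix, score_cols = NULL) {
  if (is.null(score_cols)) {
    num <- vapply(matrix, is.numeric, logical(1))
    score_cols <- setdiff(names(matrix)[num], c("mw"))
  }
  check_cols(matrix, score_cols, "score matrix")
  score_cols
}

#' Z-score normalisation of docking scores per scoring function
#'
#' Standardises every scoring-function column by subtracting its mean and
#' dividing by its sample standard deviation (n - 1 denominator), computed
#' over the compounds present in `matrix` (i.e. after any property
#' pre-filtering). Missing scores are left missing and excluded from the
#' column statistics. An optional sign map flips functions whose convention
#' is "higher = better" so that all Z columns share the "lower = better"
#' orientation.
#'
#' @param matrix Score matrix tibble (see [gen_score_matrix()]).
#' @param score_cols Names of the scoring-function columns; default: every
#'   numeric column except `mw`.
#' @param sign_map Optional named vector of +1/-1 multipliers applied to raw
#'   scores before standardisation.
#'
#' @return A tibble of the same shape with Z-scores in the score columns; the
#'   per-column means and SDs used are stored in attributes `"center"` and
#'   `"scale"`, the column names in `"score_cols"`.
#' @export
zscore_matrix <- function(matrix, score_cols = NULL, sign_map = NULL) {
  score_cols <- score_columns(matrix, score_cols)
  out <- matrix
  center <- scale <- stats::setNames(numeric(length(score_cols)), score_cols)
  for (col in score_cols) {
    s <- matrix[[col]]
    if (!is.null(sign_map) && col %in% names(sign_map)) {
      s <- s * sign_map[[col]]
    }
    finite <- is.finite(s)
    if (sum(finite) < 2) {
      rlang::abort(sprintf(
        "Scoring function `%s` has fewer than 2 finite scores.", col),
        class = "mitoquant_data_error")
    }
    m <- mean(s[finite])
    sd <- stats::sd(s[finite])
    if (sd == 0) {
      rlang::abort(sprintf(
        "Scoring function `%s` is degenerate (zero standard deviation).", col),
        class = "mitoquant_data_error")
    }
    center[col] <- m
    scale[col] <- sd
    out[[col]] <- (s - m) / sd
  }
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  attr(out, "score_cols") <- score_cols
  out
}

#' Select consensus hits by Z-score voting
#'
#' A compound is nominated when its Z-score is strictly smaller than
#' `z_threshold` in at least `min_functions` scoring functions. Missing
#' Z-scores never count as passing. Hits are ranked deterministically by the
#' number of passing functions (descending) and, within ties, by the sum of
#' the passing Z-scores (ascending, i.e. most negative consensus first) —
#' a reproducible stand-in for the manual pose inspection that usually
#' follows.
#'
#' @param z A Z-score tibble from [zscore_matrix()].
#' @param z_threshold Voting threshold on the Z scale (default -3).
#' @param min_functions Minimum number of passing functions (default 3).
#' @param score_cols Score column names; default: those recorded by
#'   [zscore_matrix()], else every numeric column except `mw`.
#'
#' @return A tibble `compound_id, n_functions_passing, sum_passing_z` plus one
#'   logical `pass_<function>` column per scoring function, ordered by the
#'   rank key.
#' @export
select_hits <- function(z, z_threshold = -3, min_functions = 3,
                        score_cols = NULL) {
  score_cols <- score_cols %||% attr(z, "score_cols")
  score_cols <- score_columns(z, score_cols)
  if (!is.finite(z_threshold)) {
    rlang::abort("`z_threshold` must be finite.",
                 class = "mitoquant_parameter_error")
  }
  min_functions <- check_count(min_functions, "min_functions")
  if (min_functions > length(score_cols)) {
    rlang::abort("`min_functions` cannot exceed the number of scoring functions.",
                 class = "mitoquant_parameter_error")
  }
  zm <- as.matrix(z[, score_cols, drop = FALSE])
  pass <- !is.na(zm) & zm < z_threshold
  n_pass <- rowSums(pass)
  sum_pass <- rowSums(ifelse(pass, zm, 0))
  hits <- tibble::tibble(compound_id = z$compound_id,
                         n_functions_passing = as.integer(n_pass),
                         sum_passing_z = sum_pass)
  flags <- tibble::as_tibble(as.data.frame(pass))
  names(flags) <- paste0("pass_", score_cols)
  hits <- dplyr::bind_cols(hits, flags)
  hits <- hits[n_pass >= min_functions, , drop = FALSE]
  hits <- hits[order(-hits$n_functions_passing, hits$sum_passing_z), ,
               drop = FALSE]
  attr(hits, "z_threshold") <- z_threshold
  attr(hits, "min_functions") <- min_functions
  hits
}
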