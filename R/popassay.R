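FATE_LEVELS <- c("death_in_mitosis", "division", "slippage_failed_cytokinesis")

#' Fate fractions and arrest-duration summary of a per-cell fate table
#'
#' Tabulates the fates of individually followed cells (death in mitosis,
#' division, mitotic exit with failed cytokinesis) as percentages over the
#' non-censored cells, and summarises the arrest duration
#' (`exit_h - entry_h`) as mean +/- sample SD.
#'
#' @param table A fate tibble `cell_id, entry_h, exit_h, fate, condition`
#'   (see [gen_fate_table()]); `fate == "censored"` marks cells still
#'   arrested at film end.
#' @return A list with `fractions` (tibble `fate, n, pct`, percentages
#'   summing to 100 over non-censored cells), `duration_mean_h`,
#'   `duration_sd_h`, `n` (non-censored) and `n_censored`.
#' @export
fate_fractions <- function(table) {
  check_cols(table, c("cell_id", "entry_h", "exit_h", "fate"), "fate table")
  if (any(table$exit_h < table$entry_h, na.rm = TRUE)) {
    rlang::abort("Exit times must not precede entry times.",
                 class = "mitoquant_data_error")
  }
  obs <- table[table$fate != "censored", , drop = FALSE]
  if (nrow(obs) == 0) {
    rlang::abort("All cells are censored; no fates to tabulate.",
                 class = "mitoquant_data_error")
  }
  counts <- table(factor(obs$fate, levels = FATE_LEVELS))
  dur <- obs$exit_h - obs$entry_h
  list(
    fractions = tibble::tibble(fate = FATE_LEVELS,
                               n = as.integer(counts),
                               pct = 100 * as.numeric(counts) / nrow(obs)),
    duration_mean_h = mean(dur),
    duration_sd_h = stats::sd(dur),
    n = nrow(obs),
    n_censored = nrow(table) - nrow(obs))
}

#' Mitotic and cell-death index time courses
#'
#' At each scoring time the mitotic index is the percentage of cells that
#' have entered but not exited mitosis (instantaneous definition; censored
#' cells remain in mitosis up to the film end), and the death index is the
#' percentage of cells that have died in mitosis by that time. The death
#' index is monotone nondecreasing by construction.
#'
#' @inheritParams fate_fractions
#' @param times Scoring times (hours).
#' @param cumulative Use the cumulative mitotic index (% of cells that have
#'   entered mitosis by each time) instead of the instantaneous one.
#' @return A tibble `time_h, mitotic_pct, death_pct, n_scored`.
#' @export
index_timecourse <- function(table, times, cumulative = FALSE) {
  check_cols(table, c("cell_id", "entry_h", "exit_h", "fate"), "fate table")
  check_nonneg(times, "times")
  n <- nrow(table)
  exit_eff <- ifelse(table$fate == "censored", Inf, table$exit_h)
  mitotic <- vapply(times, function(t) {
    if (cumulative) sum(table$entry_h <= t)
    else sum(table$entry_h <= t & t < exit_eff)
  }, numeric(1))
  dead <- vapply(times, function(t) {
    sum(table$fate == "death_in_mitosis" & table$exit_h <= t)
  }, numeric(1))
  tibble::tibble(time_h = times, mitotic_pct = 100 * mitotic / n,
                 death_pct = 100 * dead / n, n_scored = n)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares of
#' `response = bottom + (top - bottom) / (1 + (c / EC50)^hill)` with the
#' concentration handled on the log10 scale (the fit parameter is
#' `log10(EC50)`, keeping the optimisation well conditioned across decades of
#' concentration); the hill slope and top asymptote are free and
#' unconstrained. By default the lower asymptote is fixed at 0, appropriate
#' for background-corrected viability signals: when the tested range ends
#' near the EC50 the lower plateau is never observed and a free bottom makes
#' the curve unidentifiable (see the methods vignette). Pass
#' `fix_bottom = NULL` for the fully free four-parameter fit. The EC50
#' standard error is delta-method transformed back to the concentration
#' scale. The fit is flagged non-converged when the optimiser fails, the
#' Jacobian is rank-deficient, or `log10(EC50)` is determined to worse than
#' +/- 2 decades (an unidentifiable, e.g. flat, curve).
#'
#' @param dose A tibble `conc_um, response` (replicates as extra rows); at
#'   least 4 distinct concentrations.
#' @param init Optional named list overriding starting values
#'   (`top`, `bottom`, `log10_ec50`, `hill`).
#' @param fix_bottom Value at which the lower asymptote is fixed (default 0);
#'   `NULL` leaves it free.
#' @return An object of class `ec50_fit`: list with `ec50`, `hill`, `top`,
#'   `bottom`, `se` (named, including `ec50` and `log10_ec50`), `rss`, `n`
#'   and `converged`.
#' @export
fit_ec50 <- function(dose, init = NULL, fix_bottom = 0) {
  check_cols(dose, c("conc_um", "response"), "dose-response table")
  check_positive(dose$conc_um, "conc_um")
  if (length(unique(dose$conc_um)) < 4) {
    rlang::abort("Fitting requires at least 4 distinct concentrations.",
                 class = "mitoquant_data_error")
  }
  free_bottom <- is.null(fix_bottom)
  start <- list(top = max(dose$response),
                log10_ec50 = stats::median(log10(dose$conc_um)), hill = 1)
  if (free_bottom) start$bottom <- min(dose$response)
  start[names(init)] <- init
  form <- if (free_bottom) {
    response ~ bottom + (top - bottom) /
      (1 + 10^(hill * (log10(conc_um) - log10_ec50)))
  } else {
    dose$.bottom <- fix_bottom
    response ~ .bottom + (top - .bottom) /
      (1 + 10^(hill * (log10(conc_um) - log10_ec50)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dose, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, se = NULL, rss = NA_real_,
                          n = nrow(dose), converged = FALSE),
                     class = "ec50_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(stats::coef(summary(fit))[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_,
                                                         length(cf)),
                                                     names(cf)))
  ec50 <- 10^unname(cf["log10_ec50"])
  se_log <- unname(se["log10_ec50"])
  converged <- isTRUE(fit$convInfo$isConv) && all(is.finite(se)) &&
    is.finite(se_log) && se_log < 2
  structure(list(
    ec50 = ec50, hill = unname(cf["hill"]), top = unname(cf["top"]),
    bottom = if (free_bottom) unname(cf["bottom"]) else fix_bottom,
    se = c(ec50 = log(10) * ec50 * se_log, log10_ec50 = se_log,
           hill = unname(se["hill"]), top = unname(se["top"]),
           bottom = if (free_bottom) unname(se["bottom"]) else NA_real_),
    rss = sum(stats::resid(fit)^2), n = nrow(dose),
    converged = converged), class = "ec50_fit")
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  EC50 = %.4g +/- %.4g uM, hill = %.3g\n",
              x$ec50, if (is.null(x$se)) NA else x$se["ec50"], x$hill))
  cat(sprintf("  top = %.4g, bottom = %.4g, n = %d, converged = %s\n",
              x$top, x$bottom, x$n, x$converged))
  invisible(x)
}

#' Excess over additivity for a drug combination
#'
#' Compares an observed combination index time course against an additivity
#' null built from the monotherapy courses. The default null is Bliss
#' independence, `E = A + B - A * B / 100` (indices as percentages); a plain
#' additive null `min(A + B, 100)` is available. When replicate wells are
#' supplied, a nonparametric bootstrap over wells gives a confidence interval
#' on the excess at each time point.
#'
#' @param mono_a,mono_b,combo Index values (%) on a shared time grid; either
#'   numeric vectors or tibbles from [index_timecourse()] (the
#'   `mitotic_pct` column is used).
#' @param mode `"bliss"` (default) or `"additive"`.
#' @param reps_a,reps_b,reps_combo Optional matrices (time x replicate well)
#'   for the bootstrap.
#' @param n_boot Bootstrap draws (default 1000).
#' @param conf_level Bootstrap interval coverage (default 0.95).
#' @return A tibble `expected, observed, excess` (one row per time point),
#'   plus `lower, upper` when replicates were given.
#' @export
combination_excess <- function(mono_a, mono_b, combo, mode = c("bliss",
                                                               "additive"),
                               reps_a = NULL, reps_b = NULL,
                               reps_combo = NULL, n_boot = 1000,
                               conf_level = 0.95) {
  mode <- match.arg(mode)
  pick <- function(x) {
    if (is.data.frame(x)) {
      check_cols(x, "mitotic_pct", "index time course")
      x$mitotic_pct
    } else as.numeric(x)
  }
  a <- pick(mono_a); b <- pick(mono_b); ab <- pick(combo)
  if (length(a) != length(b) || length(a) != length(ab)) {
    rlang::abort("Index time courses must share the same time grid.",
                 class = "mitoquant_data_error")
  }
  if (is.data.frame(mono_a) && is.data.frame(combo) &&
      !isTRUE(all.equal(mono_a$time_h, combo$time_h))) {
    rlang::abort("Index time courses must share the same time grid.",
                 class = "mitoquant_data_error")
  }
  expected_fun <- function(a, b) {
    if (mode == "bliss") a + b - a * b / 100 else pmin(a + b, 100)
  }
  out <- tibble::tibble(expected = expected_fun(a, b), observed = ab,
                        excess = ab - expected_fun(a, b))
  if (!is.null(reps_a) && !is.null(reps_b) && !is.null(reps_combo)) {
    boots <- replicate(n_boot, {
      ra <- rowMeans(reps_a[, sample(ncol(reps_a), replace = TRUE),
                            drop = FALSE])
      rb <- rowMeans(reps_b[, sample(ncol(reps_b), replace = TRUE),
                            drop = FALSE])
      rc <- rowMeans(reps_combo[, sample(ncol(reps_combo), replace = TRUE),
                                drop = FALSE])
      rc - expected_fun(ra, rb)
    })
    alpha <- (1 - conf_level) / 2
    qs <- apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha))
    out$lower <- qs[1, ]
    out$upper <- qs[2, ]
  }
  out
}
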