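#' Extract dwell times from a single-molecule event table
#'
#' For each binding event the dwell is `last frame time - first frame time +
#' one frame interval`, so that a single-frame event contributes one full
#' frame of residence. Events with dwell below `t_min` are discarded (their
#' count is recorded); right-censoring flags are propagated.
#'
#' @param events A `tirf_sim` object from [gen_tirf_events()] or a long event
#'   tibble with columns `event_id, t_s` and optionally `censored`.
#' @param t_min Minimum dwell retained (seconds); defaults to one frame
#'   interval, the detection limit of frame-based imaging.
#' @param frame_interval Frame interval (seconds); inferred from the time
#'   stamps when omitted. Each event must be sampled at this constant
#'   interval, otherwise a data error naming the event is raised.
#'
#' @return A tibble `event_id, dwell_s, censored` with attributes
#'   `n_discarded`, `t_min` and `frame_interval`.
#' @export
dwell_times <- function(events, t_min = NULL, frame_interval = NULL) {
  if (inherits(events, "tirf_sim")) {
    frame_interval <- frame_interval %||% events$params$frame_interval
    events <- events$events
  }
  check_cols(events, c("event_id", "t_s"), "event table")
  if (!"censored" %in% names(events)) events$censored <- FALSE

  ord <- order(events$event_id, events$t_s)
  ev <- events[ord, , drop = FALSE]
  by_ev <- split(ev$t_s, ev$event_id)
  if (is.null(frame_interval)) {
    all_d <- unlist(lapply(by_ev, diff), use.names = FALSE)
    if (length(all_d) == 0) {
      rlang::abort("Cannot infer `frame_interval` from single-frame events.",
                   class = "mitoquant_data_error")
    }
    frame_interval <- min(all_d)
  }
  for (id in names(by_ev)) {
    d <- diff(by_ev[[id]])
    if (length(d) > 0 && any(abs(d - frame_interval) > 1e-6 * frame_interval)) {
      rlang::abort(sprintf(
        "Event %s is not sampled at a constant interval of %g s.",
        id, frame_interval), class = "mitoquant_data_error")
    }
  }
  t_min <- t_min %||% frame_interval
  check_nonneg(t_min, "t_min")

  dw <- vapply(by_ev, function(t) max(t) - min(t), numeric(1)) + frame_interval
  cens <- vapply(split(ev$censored, ev$event_id), function(x) x[1], logical(1))
  keep <- dw >= t_min
  out <- tibble::tibble(event_id = names(by_ev)[keep],
                        dwell_s = unname(dw[keep]),
                        censored = unname(cens[keep]))
  attr(out, "n_discarded") <- sum(!keep)
  attr(out, "t_min") <- t_min
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Fit a single-exponential off-rate to dwell times
#'
#' Maximum-likelihood fit of a left-truncated exponential to unbinned dwell
#' times, the model behind a single-exponential fit to a residence-time
#' distribution. Two censoring policies are available:
#' \describe{
#'   \item{`drop`}{censored events are removed and the closed-form truncated
#'     MLE `k = 1 / (mean(t) - t0)` is used.}
#'   \item{`mle`}{censored events contribute survival terms
#'     `exp(-k (t - t0))` to the likelihood, which is maximised numerically
#'     (root of the score equation).}
#' }
#' Here `t0` is the truncation point: `t_min` as given, or
#' `t_min - frame_interval / 2` when the frame interval is supplied, a
#' midpoint correction for dwells quantised to the camera frame grid (see the
#' methods vignette). Standard errors come from the observed Fisher
#' information. The empirical survival curve (Kaplan-Meier under censoring) is
#' attached for plotting against the fit.
#'
#' @param dwells Output of [dwell_times()], or a numeric vector of dwell
#'   times (then assumed uncensored).
#' @param t_min Truncation point of the observed dwell distribution; default:
#'   the value recorded by [dwell_times()], else the minimum dwell.
#' @param censoring `"mle"` (default) or `"drop"`.
#' @param frame_interval Frame interval (seconds) enabling the half-frame
#'   correction; default: taken from `dwells` when present, none for plain
#'   numeric input.
#' @param min_events Warn when fewer usable events remain (default 50).
#'
#' @return An object of class `dwell_fit`: list with `k_off`, `se`,
#'   `n_events`, `n_censored`, `t_min`, `t0`, `censoring`, `loglik`,
#'   `survival` (tibble `time, surv`) and `converged`.
#' @export
fit_koff <- function(dwells, t_min = NULL, censoring = c("mle", "drop"),
                     frame_interval = NULL, min_events = 50) {
  censoring <- match.arg(censoring)
  if (is.numeric(dwells)) {
    dwells <- tibble::tibble(event_id = as.character(seq_along(dwells)),
                             dwell_s = dwells, censored = FALSE)
  }
  check_cols(dwells, c("dwell_s", "censored"), "dwell table")
  t_min <- t_min %||% attr(dwells, "t_min") %||% min(dwells$dwell_s)
  frame_interval <- frame_interval %||% attr(dwells, "frame_interval")
  t0 <- if (!is.null(frame_interval)) t_min - frame_interval / 2 else t_min

  d <- dwells[dwells$dwell_s >= t_min, , drop = FALSE]
  if (censoring == "drop") d <- d[!d$censored, , drop = FALSE]
  n_unc <- sum(!d$censored)
  if (n_unc == 0) {
    rlang::abort("No usable (uncensored) events to fit.",
                 class = "mitoquant_data_error")
  }
  if (nrow(d) < min_events) {
    rlang::warn(sprintf("Only %d usable events (minimum recommended: %d).",
                        nrow(d), min_events))
  }
  excess <- d$dwell_s - t0
  if (censoring == "drop") {
    k <- 1 / mean(excess)
  } else {
    # score: n_unc / k - sum(excess) = 0, solved numerically
    total <- sum(excess)
    score <- function(k) n_unc / k - total
    k <- stats::uniroot(score, lower = 1e-10, upper = 1e6,
                        tol = .Machine$double.eps^0.75)$root
  }
  se <- k / sqrt(n_unc)  # observed Fisher information n_unc / k^2
  unc <- !d$censored
  loglik <- n_unc * log(k) - k * sum(excess)

  km <- survival::survfit(survival::Surv(d$dwell_s, unc) ~ 1)
  structure(list(
    k_off = k, se = se, n_events = nrow(d), n_censored = sum(d$censored),
    t_min = t_min, t0 = t0, censoring = censoring, loglik = loglik,
    survival = tibble::tibble(time = km$time, surv = km$surv),
    converged = TRUE), class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat("Single-exponential dwell-time fit\n")
  cat(sprintf("  k_off = %.4g +/- %.4g s^-1 (mean residence %.3g s)\n",
              x$k_off, x$se, 1 / x$k_off))
  cat(sprintf("  n = %d events (%d censored), policy = %s, t_min = %g s\n",
              x$n_events, x$n_censored, x$censoring, x$t_min))
  invisible(x)
}

#' Binned least-squares exponential fit to a dwell histogram
#'
#' Cross-check for [fit_koff()]: bins the uncensored dwell times, and fits a
#' straight line to the log survival counts. Less efficient than the MLE but
#' mirrors how residence-time histograms are often fitted.
#'
#' @inheritParams fit_koff
#' @param bin_width Histogram bin width (seconds); default one frame interval
#'   when known, else a tenth of the dwell range.
#' @return A list with `k_off` and the fitted line's `intercept`.
#' @export
fit_koff_binned <- function(dwells, t_min = NULL, bin_width = NULL) {
  if (is.numeric(dwells)) {
    dwells <- tibble::tibble(dwell_s = dwells, censored = FALSE)
  }
  t_min <- t_min %||% attr(dwells, "t_min") %||% min(dwells$dwell_s)
  bin_width <- bin_width %||% attr(dwells, "frame_interval") %||%
    (diff(range(dwells$dwell_s)) / 10)
  d <- dwells$dwell_s[!dwells$censored & dwells$dwell_s >= t_min]
  breaks <- seq(t_min, max(d) + bin_width, by = bin_width)
  surv <- vapply(breaks, function(b) sum(d >= b), numeric(1))
  ok <- surv > 0
  fit <- stats::lm(log(surv[ok]) ~ breaks[ok])
  list(k_off = -unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Compare two fitted off-rates
#'
#' Two-sided Gaussian z-test on the difference of two independent rate
#' estimates: `z = (k_b - k_a) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param fit_a,fit_b `dwell_fit` objects (or lists with `k_off` and `se`).
#' @return A list with `z`, `p_value` and the rate difference `delta`.
#' @export
compare_koff <- function(fit_a, fit_b) {
  for (f in list(fit_a, fit_b)) {
    if (is.null(f$k_off) || is.null(f$se) || !is.finite(f$se)) {
      rlang::abort("Both fits must carry a finite `k_off` and `se`.",
                   class = "mitoquant_data_error")
    }
  }
  delta <- fit_b$k_off - fit_a$k_off
  z <- delta / sqrt(fit_a$se^2 + fit_b$se^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), delta = delta)
}

#' Mean-squared displacement versus time lag
#'
#' Pools squared displacements over all events and all start frames
#' (overlapping windows) for each lag `tau = m * frame_interval`. The curve
#' reports the mean, the SEM over pooled displacement pairs and the pair
#' count per lag; the lag range is limited to a fraction of the longest
#' event's duration.
#'
#' @param events A `tirf_sim` object or long event tibble
#'   (`event_id, t_s, x_um`).
#' @param max_lag_fraction Largest lag as a fraction of the longest event's
#'   span (default 0.25; short lags keep censoring-induced curvature out of
#'   the fit range).
#' @param frame_interval Frame interval (seconds); inferred when omitted.
#'
#' @return An object of class `msd_curve`: tibble
#'   `lag_s, msd, sem, n_pairs` with the frame interval in an attribute.
#' @export
msd <- function(events, max_lag_fraction = 0.25, frame_interval = NULL) {
  if (inherits(events, "tirf_sim")) {
    frame_interval <- frame_interval %||% events$params$frame_interval
    events <- events$events
  }
  check_cols(events, c("event_id", "t_s", "x_um"), "event table")
  check_number(max_lag_fraction, "max_lag_fraction", lower = 0,
               strict_lower = TRUE, upper = 1)
  ord <- order(events$event_id, events$t_s)
  ev <- events[ord, , drop = FALSE]
  xs <- split(ev$x_um, ev$event_id)
  n_i <- lengths(xs)
  if (max(n_i) < 2) {
    rlang::abort("MSD requires at least one event with 2 or more frames.",
                 class = "mitoquant_data_error")
  }
  if (is.null(frame_interval)) {
    frame_interval <- min(unlist(lapply(split(ev$t_s, ev$event_id), diff),
                                 use.names = FALSE))
  }
  max_m <- max(1L, floor((max(n_i) - 1L) * max_lag_fraction))
  xs <- xs[n_i >= 2]
  rows <- lapply(seq_len(max_m), function(m) {
    sq <- unlist(lapply(xs, function(x) {
      if (length(x) > m) diff(x, lag = m)^2 else numeric(0)
    }), use.names = FALSE)
    if (length(sq) == 0) return(NULL)
    c(lag_s = m * frame_interval, msd = mean(sq),
      sem = stats::sd(sq) / sqrt(length(sq)), n_pairs = length(sq))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    rlang::abort("No displacement pairs available.",
                 class = "mitoquant_data_error")
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  out$n_pairs <- as.integer(out$n_pairs)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit a line to the MSD curve to estimate the diffusion constant
#'
#' Weighted least squares of `MSD(tau) = 2 D tau + c` over the first
#' `n_fit_lags` lags (weights `1 / SEM^2`), the one-dimensional convention
#' for motion parameterised along the filament axis. The intercept `c`
#' estimates twice the localisation-noise variance. A negative fitted slope
#' is truncated to `D = 0` and flagged; degenerate weights trigger a logged
#' fallback to an unweighted fit.
#'
#' @param curve An `msd_curve` from [msd()].
#' @param n_fit_lags Number of leading lags in the fit (default 5).
#'
#' @return An object of class `msd_fit`: list with `D` (um^2/s), `se_D`,
#'   `intercept`, `se_intercept`, `lags_used`, `curve`, `weighted` and
#'   `truncated` flags.
#' @export
fit_diffusion <- function(curve, n_fit_lags = 5) {
  check_cols(curve, c("lag_s", "msd", "sem"), "MSD curve")
  n_fit_lags <- check_count(n_fit_lags, "n_fit_lags", min = 2L)
  use <- curve[seq_len(min(n_fit_lags, nrow(curve))), , drop = FALSE]
  if (nrow(use) < 2) {
    rlang::abort("Diffusion fitting requires at least 2 lags.",
                 class = "mitoquant_data_error")
  }
  w <- 1 / use$sem^2
  weighted <- all(is.finite(w)) && all(w > 0)
  if (!weighted) {
    rlang::warn("Degenerate SEM weights; falling back to an unweighted fit.")
    fit <- stats::lm(msd ~ lag_s, data = use)
  } else {
    fit <- stats::lm(msd ~ lag_s, data = use, weights = w)
  }
  cf <- stats::coef(fit)
  se <- stats::coef(summary(fit))[, "Std. Error"]
  slope <- unname(cf["lag_s"])
  truncated <- slope < 0
  if (truncated) {
    rlang::warn("Negative MSD slope; reporting D = 0.")
  }
  structure(list(
    D = max(slope, 0) / 2, se_D = unname(se["lag_s"]) / 2,
    intercept = unname(cf["(Intercept)"]),
    se_intercept = unname(se["(Intercept)"]),
    lags_used = use$lag_s, curve = curve, weighted = weighted,
    truncated = truncated), class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("Linear MSD fit (1D: slope = 2 D)\n")
  cat(sprintf("  D = %.4g +/- %.4g um^2/s, intercept = %.3g um^2\n",
              x$D, x$se_D, x$intercept))
  cat(sprintf("  fitted over %d lags up to %g s\n",
              length(x$lags_used), max(x$lags_used)))
  invisible(x)
}
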