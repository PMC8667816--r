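test_that("dwell extraction follows the frame-span-plus-one convention", {
  ev <- tibble::tibble(event_id = 1, t_s = seq(0, 0.9, by = 0.1), x_um = 0,
                       censored = FALSE)
  d <- dwell_times(ev, frame_interval = 0.1)
  expect_equal(d$dwell_s, 1.0)

  # single-frame event below t_min is discarded and counted
  ev2 <- tibble::tibble(event_id = c(1, 2, 2), t_s = c(0.5, 0, 0.1),
                        x_um = 0, censored = FALSE)
  d2 <- dwell_times(ev2, t_min = 0.2, frame_interval = 0.1)
  expect_identical(d2$event_id, "2")
  expect_identical(attr(d2, "n_discarded"), 1L)

  # known dwell list round-trips exactly
  dw <- c(0.5, 1.0, 2.3)
  d3 <- dwell_times(events_from_dwells(dw, dt = 0.1), frame_interval = 0.1)
  expect_equal(d3$dwell_s, dw)

  # non-uniform sampling is a data error naming the event
  bad <- tibble::tibble(event_id = 7, t_s = c(0, 0.1, 0.35), x_um = 0)
  expect_error(dwell_times(bad, frame_interval = 0.1), "7",
               class = "mitoquant_data_error")
})

test_that("off-rate MLE matches its closed forms", {
  fit <- fit_koff(c(1.2, 2.2, 3.2), t_min = 0.2, censoring = "drop",
                  min_events = 1)
  expect_equal(fit$k_off, 0.5)  # 1 / (2.2 - 0.2)

  fit2 <- fit_koff(rep(2, 60), t_min = 0)
  expect_equal(fit2$k_off, 0.5, tolerance = 1e-8)

  # numeric optimiser vs closed form with censored survival terms
  set.seed(1)
  dw <- tibble::tibble(event_id = as.character(1:200),
                       dwell_s = rexp(200, 0.7) + 0.1,
                       censored = runif(200) < 0.2)
  m <- fit_koff(dw, t_min = 0.1, censoring = "mle", min_events = 1)
  closed <- sum(!dw$censored) / sum(dw$dwell_s - 0.1)
  expect_equal(m$k_off, closed, tolerance = 1e-8)
  expect_equal(m$se, closed / sqrt(sum(!dw$censored)), tolerance = 1e-6)
  expect_identical(m$n_censored, sum(dw$censored))

  # binned least-squares histogram fit agrees as a cross-check oracle
  set.seed(2)
  big <- rexp(20000, 0.47)
  binned <- fit_koff_binned(big, t_min = 0, bin_width = 0.1)
  expect_equal(binned$k_off, 0.47, tolerance = 0.05)

  expect_error(fit_koff(tibble::tibble(dwell_s = 2, censored = TRUE),
                        t_min = 0.1, min_events = 1),
               class = "mitoquant_data_error")
})

test_that("censoring-aware MLE beats dropping under heavy censoring", {
  est <- vapply(1:30, function(s) {
    sim <- gen_tirf_events(k_off = 0.47, n_events = 400, movie_length = 3,
                           seed = s)
    d <- dwell_times(sim)
    c(mle = fit_koff(d, censoring = "mle")$k_off,
      drop = suppressWarnings(fit_koff(d, censoring = "drop"))$k_off)
  }, numeric(2))
  bias_mle <- abs(mean(est["mle", ]) - 0.47)
  bias_drop <- abs(mean(est["drop", ]) - 0.47)
  expect_lt(bias_mle, bias_drop)
})

test_that("reported standard errors calibrate against seed-to-seed scatter", {
  fits <- lapply(1:60, function(s) {
    fit_koff(dwell_times(gen_tirf_events(k_off = 0.47, n_events = 400,
                                         seed = s + 300)))
  })
  ks <- vapply(fits, `[[`, numeric(1), "k_off")
  ses <- vapply(fits, `[[`, numeric(1), "se")
  expect_gt(sd(ks) / mean(ses), 0.7)
  expect_lt(sd(ks) / mean(ses), 1.4)
})

test_that("off-rate comparison z-test matches hand arithmetic", {
  a <- list(k_off = 1.0, se = 0.1)
  same <- compare_koff(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  toy <- compare_koff(a, list(k_off = 1.3, se = 0.1))
  expect_equal(toy$z, 0.3 / sqrt(0.02), tolerance = 1e-4)  # ~2.121

  paper_scale <- compare_koff(list(k_off = 0.47, se = 0.02),
                              list(k_off = 0.79, se = 0.04))
  expect_lt(paper_scale$p_value, 0.001)

  expect_error(compare_koff(a, list(k_off = 1, se = NA_real_)),
               class = "mitoquant_data_error")
})

test_that("MSD pools overlapping displacement pairs by hand-checkable rules", {
  ev <- tibble::tibble(event_id = 1, t_s = 0:3, x_um = c(0, 1, 0, 1))
  curve <- msd(ev, max_lag_fraction = 1, frame_interval = 1)
  expect_equal(curve$msd[1:2], c(1, 0))
  expect_identical(curve$n_pairs[1:2], c(3L, 2L))

  # constant positions: MSD identically zero
  flat <- tibble::tibble(event_id = 1, t_s = 0:5, x_um = 2)
  expect_true(all(msd(flat, max_lag_fraction = 1)$msd == 0))

  # pure drift: MSD(tau) = (v tau)^2, the negative control for linearity
  drift <- tibble::tibble(event_id = 1, t_s = 0:3, x_um = c(0, 1, 2, 3))
  expect_equal(msd(drift, max_lag_fraction = 1)$msd, c(1, 4, 9))
})

test_that("diffusion fitting recovers slope and intercept from exact lines", {
  curve <- tibble::tibble(lag_s = (1:6) * 0.1, msd = 2 * 0.016 * (1:6) * 0.1,
                          sem = 0.001, n_pairs = 100L)
  class(curve) <- c("msd_curve", class(curve))
  fit <- fit_diffusion(curve, n_fit_lags = 5)
  expect_equal(fit$D, 0.016, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  curve$msd <- curve$msd + 0.002
  fit2 <- fit_diffusion(curve, n_fit_lags = 5)
  expect_equal(fit2$D, 0.016, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0.002, tolerance = 1e-12)

  # negative slope is truncated to zero with a warning flag
  curve$msd <- rev(curve$msd)
  expect_warning(fit3 <- fit_diffusion(curve, n_fit_lags = 5), "Negative")
  expect_identical(fit3$D, 0)
  expect_true(fit3$truncated)

  # degenerate weights fall back to an unweighted fit
  curve2 <- tibble::tibble(lag_s = (1:5) * 0.1, msd = 2 * 0.01 * (1:5) * 0.1,
                           sem = 0, n_pairs = 10L)
  class(curve2) <- c("msd_curve", class(curve2))
  w <- capture_warnings(fit4 <- fit_diffusion(curve2))
  expect_match(w, "weights", all = FALSE)
  expect_false(fit4$weighted)
  expect_equal(fit4$D, 0.01, tolerance = 1e-12)
})

test_that("MSD of simulated pure diffusion is linear with unbiased slope", {
  sim <- gen_tirf_events(k_off = 0.47, D = 0.016, n_events = 1e4,
                         loc_noise_sd = 0, movie_length = 1e4,
                         filament_length = 100, seed = 12)
  curve <- msd(sim)
  fit <- fit_diffusion(curve, n_fit_lags = 5)
  used <- curve[1:5, ]
  r2 <- summary(lm(msd ~ lag_s, data = used))$r.squared
  expect_gt(r2, 0.99)
  expect_lt(abs(fit$D - 0.016), 3 * fit$se_D + 0.001)
})
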