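test_that("generators are pure functions of their seed", {
  expect_identical(gen_tirf_events(n_events = 50, seed = 11),
                   gen_tirf_events(n_events = 50, seed = 11))
  expect_identical(gen_anisotropy(seed = 11), gen_anisotropy(seed = 11))
  expect_identical(gen_sister_tracks(n_pairs = 5, seed = 11),
                   gen_sister_tracks(n_pairs = 5, seed = 11))
  expect_identical(gen_score_matrix(100, seed = 11),
                   gen_score_matrix(100, seed = 11))
  expect_identical(gen_fate_table(seed = 11), gen_fate_table(seed = 11))
  expect_identical(gen_dose_response(seed = 11), gen_dose_response(seed = 11))
  # different seeds differ
  expect_false(identical(gen_fate_table(seed = 1), gen_fate_table(seed = 2)))
})

test_that("generator parameter validation rejects non-physical inputs", {
  expect_error(gen_tirf_events(k_off = 0), class = "mitoquant_parameter_error")
  expect_error(gen_tirf_events(frame_interval = 400, movie_length = 300),
               class = "mitoquant_parameter_error")
  expect_error(gen_anisotropy(P_grid = numeric(0)),
               class = "mitoquant_parameter_error")
  expect_error(gen_anisotropy(r_free = 0.1, r_bound = 0.1),
               class = "mitoquant_parameter_error")
  expect_error(gen_sister_tracks(rest_distance = 0),
               class = "mitoquant_parameter_error")
  expect_error(gen_score_matrix(10, n_planted_hits = 20),
               class = "mitoquant_parameter_error")
  expect_error(gen_fate_table(fate_probs = c(0.5, 0.5, 0.5)),
               class = "mitoquant_parameter_error")
  expect_error(gen_dose_response(ec50 = -1),
               class = "mitoquant_parameter_error")
})

test_that("TIRF generator reproduces dwell and displacement moments", {
  # law of large numbers on the raw (pre-frame-sampling) dwells
  sim <- gen_tirf_events(k_off = 1, D = 0.01, n_events = 1e5,
                         movie_length = 1e6, seed = 7)
  expect_lt(abs(mean(sim$truth$dwell_true_s) - 1), 0.01)
  # censoring is negligible with a 1e6 s movie
  expect_lt(mean(sim$truth$censored), 1e-3)

  # step-displacement variance = 2 D dt + 2 sigma_loc^2 (large filament so
  # reflection never engages)
  sim2 <- gen_tirf_events(k_off = 0.2, D = 0.016, n_events = 2e4,
                          frame_interval = 0.1, movie_length = 1e5,
                          filament_length = 1000, loc_noise_sd = 0.02,
                          seed = 8)
  steps <- unlist(lapply(split(sim2$events$x_um, sim2$events$event_id), diff),
                  use.names = FALSE)
  steps <- steps[seq_len(min(length(steps), 1e5))]
  v_expect <- 2 * 0.016 * 0.1 + 2 * 0.02^2
  se_var <- v_expect * sqrt(2 / length(steps))
  expect_lt(abs(var(steps) - v_expect), 3 * se_var)
})

test_that("TIRF generator handles degenerate and censored events", {
  # zero diffusion, zero noise: positions constant within each event
  sim <- gen_tirf_events(k_off = 0.5, D = 0, loc_noise_sd = 0,
                         n_events = 100, seed = 3)
  spread <- vapply(split(sim$events$x_um, sim$events$event_id),
                   function(x) diff(range(x)), numeric(1))
  expect_true(all(spread == 0))

  # events extending past the movie end are right-censored
  sim2 <- gen_tirf_events(k_off = 0.05, n_events = 200, movie_length = 30,
                          seed = 4)
  with_truth <- sim2$truth
  expect_identical(with_truth$censored,
                   with_truth$landing_s + with_truth$dwell_true_s > 30)
  expect_gt(sum(with_truth$censored), 0)

  # sub-frame events are flagged with zero frames and absent from the table
  sim3 <- gen_tirf_events(k_off = 20, n_events = 500, seed = 5)
  zf <- sim3$truth$event_id[sim3$truth$zero_frames]
  expect_gt(length(zf), 0)
  expect_false(any(zf %in% sim3$events$event_id))
})

test_that("anisotropy generator follows the depletion isotherm", {
  tit <- gen_anisotropy(K_d = 2.07, r_free = 0.05, r_bound = 0.25,
                        L_total = 5, P_grid = 1:15, noise_sd = 0.003,
                        replicates = 3, seed = 3)
  means <- tapply(tit$anisotropy, tit$p_total_um, mean)
  expect_true(all(diff(means) > 0))  # monotone increasing mean anisotropy

  # noise-free with P = 0 appended: anisotropy exactly r_free at P = 0
  tit0 <- gen_anisotropy(K_d = 2.07, r_free = 0.05, r_bound = 0.25,
                         P_grid = c(0, 1:15), noise_sd = 0, replicates = 1,
                         seed = 1)
  expect_identical(tit0$anisotropy[tit0$p_total_um == 0], 0.05)

  # noise-free inversion: fit recovers K_d to at least 6 significant digits
  fit <- fit_kd(gen_anisotropy(K_d = 2.07, noise_sd = 0, replicates = 1,
                               seed = 2))
  expect_lt(abs(fit$kd - 2.07) / 2.07, 1e-6)
})

test_that("sister-track generator honours its geometric contracts", {
  quiet <- gen_sister_tracks(n_pairs = 6, amplitude = 0, noise_sd = 0,
                             seed = 1)
  expect_true(all(kt_oscillation(quiet)$amplitude_um < 1e-12))

  rest <- gen_sister_tracks(n_pairs = 6, rest_distance = 1.0, noise_sd = 0,
                            seed = 2)
  expect_equal(kt_distance(rest)$mean_dist_um, rep(1.0, 6), tolerance = 1e-12)

  # oscillation SD recovers amplitude / sqrt(2) within 5%
  osc <- gen_sister_tracks(n_pairs = 85, amplitude = 0.5, period = 60,
                           noise_sd = 0.02, seed = 6)
  amp <- mean(kt_oscillation(osc)$amplitude_um)
  expect_lt(abs(amp - sinusoid_sd(0.5)) / sinusoid_sd(0.5), 0.05)
})

test_that("score-matrix generator plants recoverable hits", {
  m <- gen_score_matrix(500, n_functions = 6, n_planted_hits = 10,
                        hit_shift = 6, n_functions_hit = 6, seed = 1)
  expect_identical(sum(m$planted), 10L)
  hits <- select_hits(zscore_matrix(m))
  expect_true(all(m$compound_id[m$planted] %in% hits$compound_id))
})

test_that("fate-table generator matches its sampling contracts", {
  one <- gen_fate_table(n_cells = 40, fate_probs = c(1, 0, 0), seed = 1)
  fr <- fate_fractions(one)
  expect_equal(fr$fractions$pct, c(100, 0, 0))

  const <- gen_fate_table(n_cells = 20, arrest_mean = 11.5, arrest_sd = 0,
                          seed = 2)
  expect_equal(const$exit_h - const$entry_h, rep(11.5, 20))

  # paper-scale conditions: recovered duration and fractions within
  # sampling error
  tab <- gen_fate_table(n_cells = 75, arrest_mean = 11.5, arrest_sd = 5.5,
                        fate_probs = c(0.84, 0.08, 0.08), seed = 3)
  fr2 <- fate_fractions(tab)
  expect_lt(abs(fr2$duration_mean_h - 11.5), 3 * 5.5 / sqrt(75))
  expect_lt(abs(fr2$fractions$pct[1] - 84), 3 * 100 * sqrt(0.84 * 0.16 / 75))
})

test_that("dose-response generator obeys the 4PL midpoint and inverts", {
  d <- gen_dose_response(ec50 = 6.5, hill = 1.2, top = 90, bottom = 10,
                         conc_grid = c(1, 6.5, 20), noise_sd = 0,
                         replicates = 1, seed = 1)
  expect_equal(d$response[d$conc_um == 6.5], (90 + 10) / 2)

  fit <- fit_ec50(gen_dose_response(ec50 = 6.5, noise_sd = 0, seed = 2))
  expect_lt(abs(fit$ec50 - 6.5) / 6.5, 1e-6)
})

test_that("simulated tables round-trip through disk with a sidecar", {
  dir <- withr::local_tempdir()
  sim <- gen_tirf_events(n_events = 20, seed = 1)
  path <- file.path(dir, "events.csv")
  write_sim(sim, path)
  back <- read_events(path)
  expect_equal(back$x_um, sim$events$x_um)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 1)
  expect_equal(side$k_off, 0.47)

  tit <- gen_anisotropy(seed = 2)
  p2 <- file.path(dir, "titration.csv")
  write_sim(tit, p2)
  expect_equal(read_titration(p2)$anisotropy, tit$anisotropy)
})
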