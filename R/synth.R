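#' Simulate single-molecule TIRF binding events on a microtubule
#'
#' Generates a table of single-molecule binding events as observed in a TIRF
#' assay of GFP-tagged kinetochore complexes on immobilised, Taxol-stabilised
#' microtubules. Each event lands at a uniform random time during the movie,
#' stays bound for an exponentially distributed dwell (rate `k_off`), and
#' diffuses in one dimension along the filament with diffusion constant `D`
#' (step variance `2 * D * dt`), reflecting at the filament ends. Positions are
#' sampled on the camera frame grid and perturbed by Gaussian localisation
#' noise. Events still bound when the movie ends are flagged right-censored;
#' events too short to span a single frame are kept in the ground-truth table
#' with zero observed frames.
#'
#' @param k_off Unbinding rate constant (per second, > 0).
#' @param D Diffusion constant along the filament (um^2/s, >= 0).
#' @param n_events Number of binding events to simulate.
#' @param frame_interval Camera frame interval (seconds).
#' @param movie_length Movie duration (seconds); must exceed `frame_interval`.
#' @param filament_length Length of the microtubule (um); diffusing particles
#'   reflect at 0 and at this length.
#' @param loc_noise_sd Standard deviation of Gaussian localisation noise (um).
#' @param condition Condition label carried into the event table.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#'
#' @return An object of class `tirf_sim`: a list with
#'   \describe{
#'     \item{events}{tibble with one row per observed frame:
#'       `event_id, t_s, x_um, censored, condition`.}
#'     \item{truth}{tibble with one row per simulated event: landing time,
#'       true dwell, censoring flag, number of observed frames and a
#'       `zero_frames` flag for events shorter than one frame.}
#'     \item{params}{the generating parameters, including the seed.}
#'   }
#' @seealso [dwell_times()], [fit_koff()], [msd()]
#' @export
gen_tirf_events <- function(k_off = 0.47, D = 0.016, n_events = 581,
                            frame_interval = 0.1, movie_length = 300,
                            filament_length = 15, loc_noise_sd = 0.02,
                            condition = "control", seed = NULL) {
  check_positive(k_off, "k_off")
  check_nonneg(D, "D")
  n_events <- check_count(n_events, "n_events")
  check_positive(frame_interval, "frame_interval")
  check_positive(movie_length, "movie_length")
  check_positive(filament_length, "filament_length")
  check_nonneg(loc_noise_sd, "loc_noise_sd")
  if (frame_interval >= movie_length) {
    rlang::abort("`frame_interval` must be smaller than `movie_length`.",
                 class = "mitoquant_parameter_error")
  }
  local_sim_seed(seed)

  dwell_true <- stats::rexp(n_events, rate = k_off)
  landing <- stats::runif(n_events, 0, movie_length)
  depart <- landing + dwell_true
  censored <- depart > movie_length
  depart_obs <- pmin(depart, movie_length)

  first_idx <- ceiling(landing / frame_interval)
  last_idx <- floor(depart_obs / frame_interval)
  n_frames <- pmax(0L, as.integer(last_idx - first_idx + 1L))
  x0 <- stats::runif(n_events, 0, filament_length)

  keep <- n_frames > 0L
  id <- rep(seq_len(n_events)[keep], n_frames[keep])
  frame_no <- sequence(n_frames[keep])
  t_s <- (rep(first_idx[keep], n_frames[keep]) + frame_no - 1L) * frame_interval
  # first increment covers landing -> first frame; later ones a full frame
  step_dt <- ifelse(frame_no == 1L, t_s - rep(landing[keep], n_frames[keep]),
                    frame_interval)
  inc <- stats::rnorm(length(t_s), 0, sqrt(2 * D * step_dt))
  x_true <- rep(x0[keep], n_frames[keep]) +
    stats::ave(inc, id, FUN = cumsum)
  # reflecting boundaries via triangle-wave folding into [0, L]
  x_fold <- x_true %% (2 * filament_length)
  x_fold <- ifelse(x_fold > filament_length, 2 * filament_length - x_fold, x_fold)
  x_obs <- x_fold + stats::rnorm(length(t_s), 0, loc_noise_sd)
  x_obs <- pmin(pmax(x_obs, 0), filament_length)

  events <- tibble::tibble(
    event_id = id,
    t_s = t_s,
    x_um = x_obs,
    censored = rep(censored[keep], n_frames[keep]),
    condition = condition
  )
  truth <- tibble::tibble(
    event_id = seq_len(n_events),
    landing_s = landing,
    dwell_true_s = dwell_true,
    censored = censored,
    n_frames = n_frames,
    zero_frames = n_frames == 0L
  )
  structure(list(
    events = events, truth = truth,
    params = list(k_off = k_off, D = D, n_events = n_events,
                  frame_interval = frame_interval, movie_length = movie_length,
                  filament_length = filament_length,
                  loc_noise_sd = loc_noise_sd, condition = condition,
                  seed = seed)
  ), class = "tirf_sim")
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Generates anisotropy readings for a fixed total ligand concentration
#' titrated with increasing protein, following the one-site binding isotherm
#' with ligand depletion ([fb()]) plus i.i.d. Gaussian noise. Defaults mirror a
#' small-fluorophore ligand at 5 uM titrated with 1-15 uM protein.
#'
#' @param K_d Dissociation constant (uM, >= 0).
#' @param r_free,r_bound Anisotropy of free and bound ligand (must differ).
#' @param L_total Total ligand concentration (uM, > 0).
#' @param P_grid Protein concentrations (uM, non-empty).
#' @param noise_sd Gaussian noise SD on anisotropy.
#' @param replicates Number of replicate readings per concentration.
#' @param seed Integer seed.
#'
#' @return A tibble `p_total_um, l_total_um, anisotropy, replicate` with the
#'   generating parameters stored in the `"params"` attribute.
#' @seealso [fit_kd()], [predict_anisotropy()]
#' @export
gen_anisotropy <- function(K_d = 2.07, r_free = 0.05, r_bound = 0.25,
                           L_total = 5, P_grid = 1:15, noise_sd = 0.003,
                           replicates = 3, seed = NULL) {
  check_nonneg(K_d, "K_d")
  check_positive(L_total, "L_total")
  check_nonneg(noise_sd, "noise_sd")
  replicates <- check_count(replicates, "replicates")
  if (length(P_grid) == 0) {
    rlang::abort("`P_grid` must contain at least one protein concentration.",
                 class = "mitoquant_parameter_error")
  }
  check_nonneg(P_grid, "P_grid")
  if (r_bound == r_free) {
    rlang::abort("`r_bound` must differ from `r_free`.",
                 class = "mitoquant_parameter_error")
  }
  local_sim_seed(seed)

  p <- rep(P_grid, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(P_grid))
  r <- predict_anisotropy(p, L_total, K_d, r_free, r_bound) +
    stats::rnorm(length(p), 0, noise_sd)
  out <- tibble::tibble(p_total_um = p, l_total_um = L_total,
                        anisotropy = r, replicate = rep_id)
  attr(out, "params") <- list(K_d = K_d, r_free = r_free, r_bound = r_bound,
                              L_total = L_total, P_grid = P_grid,
                              noise_sd = noise_sd, replicates = replicates,
                              seed = seed)
  out
}

#' Simulate sister-kinetochore tracks
#'
#' Generates 2D tracks of sister-kinetochore pairs as seen in a single focal
#' plane of a metaphase cell expressing a fluorescent kinetochore marker. Each
#' pair's centroid sits on the spindle axis of its cell and oscillates
#' sinusoidally along that axis with a random phase; sisters are placed at
#' centroid +/- `rest_distance / 2` along the axis. An optional constant drift
#' along the axis models the rapid, directed movements of laterally attached
#' kinetochores in early mitosis. Isotropic Gaussian positional noise is added
#' per sister and frame, and each cell carries its own pole coordinate.
#'
#' @param n_pairs Number of sister pairs.
#' @param amplitude Oscillation amplitude (um, >= 0).
#' @param period Oscillation period (seconds, > 0).
#' @param rest_distance Sister separation at rest (um, > 0).
#' @param frame_interval Sampling interval (seconds; 5 s is typical for
#'   kinetochore tracking).
#' @param duration Track duration (seconds).
#' @param noise_sd Positional noise SD per coordinate (um).
#' @param drift_speed Directed speed of the pair centroid along the spindle
#'   axis (um/min, >= 0).
#' @param n_cells Number of cells the pairs are distributed over.
#' @param condition Condition label.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `cell_id, pair_id, sister, t_s, x_um, y_um,
#'   pole_x_um, pole_y_um, condition`; generating parameters and per-pair
#'   ground truth (phase, base pole distance) in attributes `"params"` and
#'   `"truth"`.
#' @seealso [kt_oscillation()], [kt_distance()], [kt_rapid_speeds()]
#' @export
gen_sister_tracks <- function(n_pairs = 85, amplitude = 0.5, period = 60,
                              rest_distance = 1.0, frame_interval = 5,
                              duration = 300, noise_sd = 0.02,
                              drift_speed = 0, n_cells = 7,
                              condition = "control", seed = NULL) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  check_nonneg(amplitude, "amplitude")
  check_positive(period, "period")
  check_positive(rest_distance, "rest_distance")
  check_positive(frame_interval, "frame_interval")
  check_positive(duration, "duration")
  check_nonneg(noise_sd, "noise_sd")
  check_nonneg(drift_speed, "drift_speed")
  n_cells <- check_count(n_cells, "n_cells")
  local_sim_seed(seed)

  times <- seq(0, duration, by = frame_interval)
  n_t <- length(times)
  cell_of_pair <- sort(rep_len(seq_len(n_cells), n_pairs))
  pole <- matrix(stats::runif(2 * n_cells, 0, 20), ncol = 2)
  axis_angle <- stats::runif(n_cells, 0, 2 * pi)
  phase <- stats::runif(n_pairs, 0, 2 * pi)
  base_dist <- stats::runif(n_pairs, 3, 6)

  rows <- vector("list", n_pairs)
  drift_um_s <- drift_speed / 60
  for (p in seq_len(n_pairs)) {
    cell <- cell_of_pair[p]
    u <- c(cos(axis_angle[cell]), sin(axis_angle[cell]))
    centroid <- base_dist[p] + drift_um_s * times +
      amplitude * sin(2 * pi * times / period + phase[p])
    for (s in c("a", "b")) {
      pos_axis <- centroid + (if (s == "a") -1 else 1) * rest_distance / 2
      x <- pole[cell, 1] + u[1] * pos_axis + stats::rnorm(n_t, 0, noise_sd)
      y <- pole[cell, 2] + u[2] * pos_axis + stats::rnorm(n_t, 0, noise_sd)
      rows[[p]] <- rbind(rows[[p]], data.frame(
        cell_id = cell, pair_id = p, sister = s, t_s = times,
        x_um = x, y_um = y,
        pole_x_um = pole[cell, 1], pole_y_um = pole[cell, 2],
        condition = condition))
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "params") <- list(n_pairs = n_pairs, amplitude = amplitude,
                              period = period, rest_distance = rest_distance,
                              frame_interval = frame_interval,
                              duration = duration, noise_sd = noise_sd,
                              drift_speed = drift_speed, n_cells = n_cells,
                              condition = condition, seed = seed)
  attr(out, "truth") <- tibble::tibble(pair_id = seq_len(n_pairs),
                                       cell_id = cell_of_pair,
                                       phase = phase, base_dist_um = base_dist)
  out
}

#' Simulate a multi-scoring-function docking score matrix
#'
#' Generates raw docking scores for `n_compounds` compounds under
#' `n_functions` scoring functions. Background scores are i.i.d. Gaussian per
#' function, with function-specific means and spreads so that per-function
#' normalisation is exercised. A set of planted binders is shifted downwards
#' (lower = better, the convention of exhaustive rigid-docking scores) by
#' `hit_shift` function SDs in a random subset of at least `min_functions_hit`
#' functions; plant assignments are recorded as ground truth.
#'
#' @param n_compounds Number of compounds.
#' @param n_functions Number of scoring functions (>= 3); the first six get
#'   the conventional names native, shapegauss, plp, chemgauss3, chemscore,
#'   screenscore.
#' @param n_planted_hits Number of planted binders (<= `n_compounds`).
#' @param hit_shift Plant shift in units of the function SD (> 0).
#' @param n_functions_hit Number of functions in which each plant is shifted;
#'   `NULL` draws a size between `min_functions_hit` and `n_functions` per
#'   plant.
#' @param min_functions_hit Lower bound for the random subset size.
#' @param with_properties Add `mw` (Dalton) and `has_nitro` columns so the
#'   property pre-filter can be exercised.
#' @param seed Integer seed.
#'
#' @return A tibble with `compound_id`, optional `mw`/`has_nitro`, a logical
#'   `planted` column, and one numeric score column per function.
#' @seealso [prefilter()], [zscore_matrix()], [select_hits()]
#' @export
gen_score_matrix <- function(n_compounds = 1000, n_functions = 6,
                             n_planted_hits = 0, hit_shift = 6,
                             n_functions_hit = NULL, min_functions_hit = 3,
                             with_properties = FALSE, seed = NULL) {
  n_compounds <- check_count(n_compounds, "n_compounds")
  n_functions <- check_count(n_functions, "n_functions", min = 3L)
  n_planted_hits <- check_count(n_planted_hits, "n_planted_hits", min = 0L)
  check_positive(hit_shift, "hit_shift")
  if (n_planted_hits > n_compounds) {
    rlang::abort("`n_planted_hits` cannot exceed `n_compounds`.",
                 class = "mitoquant_parameter_error")
  }
  if (!is.null(n_functions_hit)) {
    n_functions_hit <- check_count(n_functions_hit, "n_functions_hit",
                                   min = as.integer(min_functions_hit))
    if (n_functions_hit > n_functions) {
      rlang::abort("`n_functions_hit` cannot exceed `n_functions`.",
                   class = "mitoquant_parameter_error")
    }
  }
  local_sim_seed(seed)

  fn_names <- c("native", "shapegauss", "plp", "chemgauss3", "chemscore",
                "screenscore")
  if (n_functions > length(fn_names)) {
    fn_names <- c(fn_names, paste0("fn", seq_len(n_functions - length(fn_names))))
  }
  fn_names <- fn_names[seq_len(n_functions)]
  mu <- stats::runif(n_functions, -60, -20)
  sd <- stats::runif(n_functions, 2, 8)
  scores <- matrix(stats::rnorm(n_compounds * n_functions), n_compounds)
  scores <- sweep(sweep(scores, 2, sd, `*`), 2, mu, `+`)

  planted <- rep(FALSE, n_compounds)
  if (n_planted_hits > 0) {
    plant_idx <- sample.int(n_compounds, n_planted_hits)
    planted[plant_idx] <- TRUE
    for (i in plant_idx) {
      k <- n_functions_hit %||%
        sample(seq(min_functions_hit, n_functions), 1)
      cols <- sample.int(n_functions, k)
      scores[i, cols] <- scores[i, cols] - hit_shift * sd[cols]
    }
  }
  out <- tibble::tibble(compound_id = sprintf("CPD%05d", seq_len(n_compounds)),
                        planted = planted)
  if (with_properties) {
    out$mw <- stats::runif(n_compounds, 150, 550)
    out$has_nitro <- stats::runif(n_compounds) < 0.05
  }
  score_df <- tibble::as_tibble(as.data.frame(scores))
  names(score_df) <- fn_names
  out <- dplyr::bind_cols(out, score_df)
  attr(out, "params") <- list(n_compounds = n_compounds,
                              n_functions = n_functions,
                              n_planted_hits = n_planted_hits,
                              hit_shift = hit_shift, seed = seed)
  out
}

#' Simulate a per-cell fate table from a live-cell imaging experiment
#'
#' Generates one record per filmed cell: mitotic entry time, arrest duration
#' drawn from a Gaussian truncated at zero, and a fate drawn multinomially
#' over death in mitosis, division and slippage (mitotic exit with failed
#' cytokinesis). Cells whose exit would fall beyond the film end are marked
#' censored. Defaults mirror a 75-cell experiment with an 11.5 +/- 5.5 h
#' arrest and fate split 84/8/8%.
#'
#' @param n_cells Number of cells.
#' @param arrest_mean,arrest_sd Mean and SD (hours) of the arrest duration
#'   before truncation at zero; `arrest_sd = 0` gives identical durations.
#' @param fate_probs Probabilities over
#'   `c(death_in_mitosis, division, slippage_failed_cytokinesis)`; must sum
#'   to 1.
#' @param fate_counts Optional exact fate counts (same order, summing to
#'   `n_cells`); overrides multinomial sampling and is shuffled over cells.
#' @param entry_window_h Mitotic entries are uniform over `[0, entry_window_h]`.
#' @param film_length_h Film duration; exits beyond it are censored.
#'   Default `Inf` (no censoring).
#' @param condition Condition label.
#' @param seed Integer seed.
#'
#' @return A tibble `cell_id, entry_h, exit_h, fate, condition` with the
#'   true (pre-censoring) durations in attribute `"truth"`.
#' @seealso [fate_fractions()], [index_timecourse()]
#' @export
gen_fate_table <- function(n_cells = 75, arrest_mean = 11.5, arrest_sd = 5.5,
                           fate_probs = c(0.84, 0.08, 0.08),
                           fate_counts = NULL, entry_window_h = 6,
                           film_length_h = Inf, condition = "treated",
                           seed = NULL) {
  n_cells <- check_count(n_cells, "n_cells")
  check_positive(arrest_mean, "arrest_mean")
  check_nonneg(arrest_sd, "arrest_sd")
  check_nonneg(entry_window_h, "entry_window_h")
  fates <- c("death_in_mitosis", "division", "slippage_failed_cytokinesis")
  if (length(fate_probs) != 3 || any(fate_probs < 0) ||
      abs(sum(fate_probs) - 1) > 1e-8) {
    rlang::abort("`fate_probs` must be 3 nonnegative probabilities summing to 1.",
                 class = "mitoquant_parameter_error")
  }
  if (!is.null(fate_counts)) {
    if (length(fate_counts) != 3 || any(fate_counts < 0) ||
        sum(fate_counts) != n_cells) {
      rlang::abort("`fate_counts` must be 3 counts summing to `n_cells`.",
                   class = "mitoquant_parameter_error")
    }
  }
  local_sim_seed(seed)

  entry <- if (entry_window_h > 0) stats::runif(n_cells, 0, entry_window_h)
           else rep(0, n_cells)
  # truncated-at-zero Gaussian by rejection
  dur <- stats::rnorm(n_cells, arrest_mean, arrest_sd)
  while (any(bad <- dur <= 0)) {
    dur[bad] <- stats::rnorm(sum(bad), arrest_mean, arrest_sd)
  }
  fate <- if (is.null(fate_counts)) {
    sample(fates, n_cells, replace = TRUE, prob = fate_probs)
  } else {
    sample(rep(fates, times = fate_counts))
  }
  exit <- entry + dur
  censored <- exit > film_length_h
  fate[censored] <- "censored"
  exit[censored] <- film_length_h
  out <- tibble::tibble(cell_id = seq_len(n_cells), entry_h = entry,
                        exit_h = exit, fate = fate, condition = condition)
  attr(out, "truth") <- tibble::tibble(cell_id = seq_len(n_cells),
                                       duration_true_h = dur,
                                       censored = censored)
  attr(out, "params") <- list(n_cells = n_cells, arrest_mean = arrest_mean,
                              arrest_sd = arrest_sd, fate_probs = fate_probs,
                              entry_window_h = entry_window_h,
                              film_length_h = film_length_h, seed = seed)
  out
}

#' Simulate a dose-response viability table
#'
#' Generates viability readings on a concentration grid following the
#' four-parameter logistic (4PL) curve
#' `bottom + (top - bottom) / (1 + (c / ec50)^hill)` plus Gaussian noise.
#' Defaults mirror a viability assay read in 6 replicate wells at 7
#' concentrations between 1 nM and 20 uM.
#'
#' @param ec50 Half-maximal concentration (uM, > 0).
#' @param hill Hill slope.
#' @param top,bottom Upper and lower response asymptotes.
#' @param conc_grid Concentrations (uM, > 0).
#' @param noise_sd Gaussian noise SD on the response.
#' @param replicates Replicate wells per concentration.
#' @param seed Integer seed.
#'
#' @return A tibble `conc_um, response, replicate` with generating parameters
#'   in attribute `"params"`.
#' @seealso [fit_ec50()]
#' @export
gen_dose_response <- function(ec50 = 6.5, hill = 1, top = 100, bottom = 0,
                              conc_grid = 10^seq(log10(0.001), log10(20),
                                                 length.out = 7),
                              noise_sd = 5, replicates = 6, seed = NULL) {
  check_positive(ec50, "ec50")
  check_positive(conc_grid, "conc_grid")
  check_nonneg(noise_sd, "noise_sd")
  replicates <- check_count(replicates, "replicates")
  local_sim_seed(seed)

  conc <- rep(conc_grid, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(conc_grid))
  resp <- bottom + (top - bottom) / (1 + (conc / ec50)^hill) +
    stats::rnorm(length(conc), 0, noise_sd)
  out <- tibble::tibble(conc_um = conc, response = resp, replicate = rep_id)
  attr(out, "params") <- list(ec50 = ec50, hill = hill, top = top,
                              bottom = bottom, conc_grid = conc_grid,
                              noise_sd = noise_sd, replicates = replicates,
                              seed = seed)
  out
}
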