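#' Project kinetochore coordinates onto the pole axis
#'
#' Kinetochore movements are tracked relative to one spindle pole: the
#' projected position is the scalar Euclidean distance from the pole at each
#' frame, which is invariant under rigid translation and rotation of the
#' cell.
#'
#' @param x,y Kinetochore coordinates (um), equal-length vectors.
#' @param pole_x,pole_y Pole coordinates (um); scalar or per-frame.
#' @return Nonnegative distances from the pole (um).
#' @export
project_to_pole_axis <- function(x, y, pole_x, pole_y) {
  if (anyNA(c(pole_x, pole_y))) {
    rlang::abort("Pole coordinates are missing.",
                 class = "mitoquant_data_error")
  }
  sqrt((x - pole_x)^2 + (y - pole_y)^2)
}

#' Mean speed of rapid kinetochore movements
#'
#' Per-step speeds `|delta position| / delta t` (converted to um/min) are
#' computed from the pole-projected 1D position; steps slower than
#' `threshold` are excluded and the mean of the surviving steps is returned
#' (`NA` if none survive). The exclusion isolates the rapid, directed
#' movements of laterally sliding kinetochores from slow positional jitter.
#'
#' @param positions Pole-projected positions (um) at a constant interval.
#' @param frame_interval Sampling interval (seconds).
#' @param threshold Exclusion threshold (um/min); speeds strictly below it
#'   are dropped.
#' @return A list with `mean_speed` (um/min, `NA` when no step survives),
#'   `n_used` and `n_total` step counts.
#' @export
rapid_speeds <- function(positions, frame_interval, threshold = 10) {
  check_positive(frame_interval, "frame_interval")
  check_nonneg(threshold, "threshold")
  if (length(positions) < 2) {
    rlang::abort("At least 2 frames are needed to compute speeds.",
                 class = "mitoquant_data_error")
  }
  speeds <- abs(diff(positions)) / frame_interval * 60
  used <- speeds[speeds >= threshold]
  list(mean_speed = if (length(used)) mean(used) else NA_real_,
       n_used = length(used), n_total = length(speeds))
}

#' Oscillation amplitude as deviation from average position
#'
#' The deviation of a kinetochore from its average position is summarised as
#' the sample standard deviation (n - 1) of its pole-projected position over
#' the track. For a pure sinusoid of amplitude A this converges to A / sqrt(2).
#'
#' @param positions Pole-projected positions (um); at least 3 frames.
#' @return The sample SD of the positions (um).
#' @export
oscillation_amplitude <- function(positions) {
  if (length(positions) < 3) {
    rlang::abort("At least 3 frames are needed for the oscillation amplitude.",
                 class = "mitoquant_data_error")
  }
  stats::sd(positions)
}

#' Mean inter-kinetochore distance of a sister pair
#'
#' Euclidean distance between the sisters on every frame where both are
#' present, averaged over frames.
#'
#' @param xa,ya,xb,yb Coordinates (um) of sisters a and b on common frames.
#' @return Mean distance (um).
#' @export
inter_kt_distance <- function(xa, ya, xb, yb) {
  n <- length(xa)
  if (n == 0 || length(ya) != n || length(xb) != n || length(yb) != n) {
    rlang::abort("Sisters share no common frames.",
                 class = "mitoquant_data_error")
  }
  mean(sqrt((xa - xb)^2 + (ya - yb)^2))
}

kt_check <- function(tracks) {
  check_cols(tracks, c("cell_id", "pair_id", "sister", "t_s", "x_um", "y_um",
                       "pole_x_um", "pole_y_um", "condition"), "track table")
  tracks
}

#' Per-kinetochore mean rapid speeds from a track table
#'
#' Applies [rapid_speeds()] to every kinetochore (cell, pair, sister) in a
#' sister-track table, using the pole-projected position.
#'
#' @param tracks Track tibble with columns `cell_id, pair_id, sister, t_s,
#'   x_um, y_um, pole_x_um, pole_y_um, condition` (see
#'   [gen_sister_tracks()]).
#' @param threshold Exclusion threshold (um/min), default 10.
#' @return A tibble with one row per kinetochore: identifiers, condition,
#'   `mean_rapid_speed`, `n_used`, `n_total`.
#' @export
kt_rapid_speeds <- function(tracks, threshold = 10) {
  kt_check(tracks)
  tracks |>
    dplyr::arrange(.data$cell_id, .data$pair_id, .data$sister, .data$t_s) |>
    dplyr::group_by(.data$cell_id, .data$pair_id, .data$sister,
                    .data$condition) |>
    dplyr::summarise({
      r <- project_to_pole_axis(.data$x_um, .data$y_um,
                                .data$pole_x_um, .data$pole_y_um)
      dt <- diff(.data$t_s)
      res <- rapid_speeds(r, dt[1], threshold)
      tibble::tibble(mean_rapid_speed = res$mean_speed,
                     n_used = res$n_used, n_total = res$n_total)
    }, .groups = "drop")
}

#' Per-kinetochore oscillation amplitudes from a track table
#'
#' @inheritParams kt_rapid_speeds
#' @return A tibble with one row per kinetochore: identifiers, condition,
#'   `amplitude_um` (sample SD of the pole-projected position) and the frame
#'   count `n_frames`.
#' @export
kt_oscillation <- function(tracks) {
  kt_check(tracks)
  tracks |>
    dplyr::arrange(.data$cell_id, .data$pair_id, .data$sister, .data$t_s) |>
    dplyr::group_by(.data$cell_id, .data$pair_id, .data$sister,
                    .data$condition) |>
    dplyr::summarise(
      amplitude_um = oscillation_amplitude(project_to_pole_axis(
        .data$x_um, .data$y_um, .data$pole_x_um, .data$pole_y_um)),
      n_frames = dplyr::n(), .groups = "drop")
}

#' Per-pair mean inter-kinetochore distances from a track table
#'
#' Frames where only one sister is visible contribute to amplitude metrics
#' but are skipped here.
#'
#' @inheritParams kt_rapid_speeds
#' @return A tibble with one row per pair: identifiers, condition,
#'   `mean_dist_um` and the number of common frames `n_frames`.
#' @export
kt_distance <- function(tracks) {
  kt_check(tracks)
  a <- tracks[tracks$sister == "a", c("cell_id", "pair_id", "condition",
                                      "t_s", "x_um", "y_um")]
  b <- tracks[tracks$sister == "b", c("cell_id", "pair_id", "t_s",
                                      "x_um", "y_um")]
  m <- dplyr::inner_join(a, b, by = c("cell_id", "pair_id", "t_s"),
                         suffix = c("_a", "_b"))
  if (nrow(m) == 0) {
    rlang::abort("Sisters share no common frames.",
                 class = "mitoquant_data_error")
  }
  m |>
    dplyr::group_by(.data$cell_id, .data$pair_id, .data$condition) |>
    dplyr::summarise(
      mean_dist_um = inter_kt_distance(.data$x_um_a, .data$y_um_a,
                                       .data$x_um_b, .data$y_um_b),
      n_frames = dplyr::n(), .groups = "drop")
}

#' Condition-level summary with pairwise Welch tests
#'
#' Summarises a per-kinetochore (or per-pair) metric by condition as
#' mean +/- SD with n, and compares every pair of conditions with Welch's
#' two-sample t-test. Conditions with a single observation are summarised but
#' excluded from testing, with a warning.
#'
#' @param metrics A tibble holding the metric and a `condition` column.
#' @param value Name of the metric column (string).
#' @return A list with `summary` (tibble `condition, mean, sd, n`) and
#'   `tests` (tibble `condition_a, condition_b, t, df, p_value`; zero rows
#'   when no pair is testable).
#' @export
condition_summary <- function(metrics, value) {
  check_cols(metrics, c(value, "condition"), "metric table")
  v <- metrics[[value]]
  ok <- is.finite(v)
  metrics <- metrics[ok, , drop = FALSE]
  v <- v[ok]
  summ <- metrics |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean = mean(.data[[value]]),
                     sd = stats::sd(.data[[value]]),
                     n = dplyr::n(), .groups = "drop")
  testable <- summ$condition[summ$n >= 2]
  if (length(testable) < nrow(summ)) {
    rlang::warn("Conditions with a single observation were not tested.")
  }
  tests <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(sort(testable), 2)
    tests <- lapply(seq_len(ncol(pairs)), function(i) {
      ga <- v[metrics$condition == pairs[1, i]]
      gb <- v[metrics$condition == pairs[2, i]]
      tt <- stats::t.test(ga, gb)
      tibble::tibble(condition_a = pairs[1, i], condition_b = pairs[2, i],
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value)
    })
    tests <- dplyr::bind_rows(tests)
  } else {
    tests <- tibble::tibble(condition_a = character(), condition_b = character(),
                            t = numeric(), df = numeric(), p_value = numeric())
  }
  list(summary = summ, tests = tests)
}
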