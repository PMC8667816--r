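# Independent oracles used to cross-check the implementation.

# Exhaustive double-loop evaluation of the Z-score voting rule.
brute_force_hits <- function(z, score_cols, z_threshold = -3,
                             min_functions = 3) {
  hits <- character(0)
  for (i in seq_len(nrow(z))) {
    votes <- 0
    for (col in score_cols) {
      v <- z[[col]][i]
      if (!is.na(v) && v < z_threshold) votes <- votes + 1
    }
    if (votes >= min_functions) hits <- c(hits, z$compound_id[i])
  }
  hits
}

# Bound fraction by numeric root-finding on the free-ligand mass-action
# equation (independent of the closed-form quadratic).
fb_numeric <- function(P, L, Kd) {
  if (P == 0) return(0)
  if (Kd == 0) return(min(P, L) / L)
  g <- function(Lf) Lf * (1 + P / (Kd + Lf)) - L
  Lf <- uniroot(g, c(0, L), tol = 1e-12)$root
  # Newton polish to machine precision
  for (i in 1:5) {
    Lf <- Lf - g(Lf) / (1 + P * Kd / (Kd + Lf)^2)
  }
  1 - Lf / L
}

# Brute-force interval-membership counts for the index time course.
index_oracle <- function(table, times) {
  n <- nrow(table)
  res <- data.frame(time_h = times, mitotic_pct = NA_real_,
                    death_pct = NA_real_)
  for (j in seq_along(times)) {
    t <- times[j]
    mit <- 0
    dead <- 0
    for (i in seq_len(n)) {
      in_mitosis <- table$entry_h[i] <= t &&
        (table$fate[i] == "censored" || t < table$exit_h[i])
      if (in_mitosis) mit <- mit + 1
      if (table$fate[i] == "death_in_mitosis" && table$exit_h[i] <= t) {
        dead <- dead + 1
      }
    }
    res$mitotic_pct[j] <- 100 * mit / n
    res$death_pct[j] <- 100 * dead / n
  }
  res
}

# SD of a densely sampled noiseless sinusoid of amplitude A.
sinusoid_sd <- function(A, n = 1e5) {
  sd(A * sin(seq(0, 200 * pi, length.out = n)))
}

# Build a long event table from explicit dwell times (frames at dt spacing).
events_from_dwells <- function(dwells, dt = 0.1, censored = NULL) {
  censored <- censored %||% rep(FALSE, length(dwells))
  rows <- lapply(seq_along(dwells), function(i) {
    n_frames <- round(dwells[i] / dt)
    tibble::tibble(event_id = i, t_s = (seq_len(n_frames) - 1) * dt,
                   x_um = 0, censored = censored[i], condition = "test")
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
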