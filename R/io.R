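#' Write a simulated table with a parameter sidecar
#'
#' Writes a generated table as a delimiter-separated file with a one-line
#' header, and the generating parameters (including the seed) as a JSON
#' sidecar at `<path>.json`, so any simulation on disk is reproducible.
#'
#' @param data A generated tibble, or a `tirf_sim` object (its `events` table
#'   is written).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @param params Parameter list for the sidecar; default: the object's
#'   recorded parameters.
#' @return `path`, invisibly.
#' @export
write_sim <- function(data, path, delim = ",", params = NULL) {
  if (inherits(data, "tirf_sim")) {
    params <- params %||% data$params
    data <- data$events
  }
  params <- params %||% attr(data, "params")
  readr::write_delim(data, path, delim = delim)
  if (!is.null(params)) {
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

read_checked <- function(path, required, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  check_cols(df, required, basename(path))
  df
}

#' Read assay tables from delimited files
#'
#' Thin readers for the pipeline's table formats, validating that the
#' required columns are present: single-molecule event tables
#' (`event_id, t_s, x_um`), anisotropy titrations
#' (`p_total_um, l_total_um, anisotropy`), sister-kinetochore tracks
#' (`cell_id, pair_id, sister, t_s, x_um, y_um, pole_x_um, pole_y_um,
#' condition`), per-cell fate tables (`cell_id, entry_h, exit_h, fate`) and
#' dose-response tables (`conc_um, response`).
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return A tibble with the validated columns.
#' @name readers
NULL

#' @rdname readers
#' @export
read_events <- function(path, delim = ",") {
  read_checked(path, c("event_id", "t_s", "x_um"), delim)
}

#' @rdname readers
#' @export
read_titration <- function(path, delim = ",") {
  read_checked(path, c("p_total_um", "l_total_um", "anisotropy"), delim)
}

#' @rdname readers
#' @export
read_tracks <- function(path, delim = ",") {
  read_checked(path, c("cell_id", "pair_id", "sister", "t_s", "x_um", "y_um",
                       "pole_x_um", "pole_y_um", "condition"), delim)
}

#' @rdname readers
#' @export
read_fate_table <- function(path, delim = ",") {
  read_checked(path, c("cell_id", "entry_h", "exit_h", "fate"), delim)
}

#' @rdname readers
#' @export
read_dose_table <- function(path, delim = ",") {
  read_checked(path, c("conc_um", "response"), delim)
}
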