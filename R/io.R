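#' Read and validate pipeline input tables
#'
#' Plain-text, diff-able formats: TSV for time series and events, CSV for
#' AQ responses. Schemas are checked column by column; timestamps must be
#' strictly increasing within subject and trial (duplicates are an error
#' naming the row); pupil values that look like raw pixels (median over 10)
#' raise a unit-sanity warning.
#'
#' @param path File path.
#' @return A validated tibble.
#' @name readers
NULL

check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

check_monotone_time <- function(df, path) {
  key <- paste(df$subject, df$trial)
  for (k in unique(key)) {
    t <- df$t_s[key == k]
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0) {
      stop("non-increasing t_s in ", path, " (subject/trial ", k,
           ", row ", bad[1] + 1, " of that trial)", call. = FALSE)
    }
  }
  invisible(df)
}

#' @rdname readers
#' @export
read_samples <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_integer(), trial = readr::col_integer(),
    t_s = readr::col_double(), pupil_mm = readr::col_double(),
    gaze_x_deg = readr::col_double(), gaze_y_deg = readr::col_double()))
  check_columns(df, c("subject", "trial", "t_s", "pupil_mm"), path)
  check_monotone_time(df, path)
  med <- stats::median(df$pupil_mm, na.rm = TRUE)
  if (is.finite(med) && med > 10) {
    warning("median pupil_mm is ", round(med, 1),
            ": values look like pixels, not millimetres", call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_percepts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_integer(), trial = readr::col_integer(),
    t_s = readr::col_double(), key_state = readr::col_character()))
  check_columns(df, c("subject", "trial", "t_s", "key_state"), path)
  check_monotone_time(df, path)
  df
}

#' @rdname readers
#' @export
read_events <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_integer(), trial = readr::col_integer(),
    t_s = readr::col_double(), dot_color = readr::col_character(),
    kind = readr::col_character()))
  check_columns(df, c("subject", "trial", "t_s", "dot_color"), path)
  check_monotone_time(df, path)
  df
}

#' @rdname readers
#' @export
read_presses <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_integer(), trial = readr::col_integer(),
    t_s = readr::col_double()))
  check_columns(df, c("subject", "trial", "t_s"), path)
  df
}

#' @rdname readers
#' @export
read_aq_responses <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_integer()))
  check_columns(df, c("subject", sprintf("item_%02d", 1:50)), path)
  df
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes `samples.tsv`, `percepts.tsv`, `aq_responses.csv`, optional
#' `events.tsv` / `presses.tsv`, the ground truth (`ground_truth.csv`,
#' synthetic quantities the pipeline should recover) and a `manifest.json`
#' recording every generator parameter, so the dataset is reconstructible
#' from the manifest alone.
#'
#' @param cohort A `synthetic_cohort` from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create ", dir, call. = FALSE)
  with_subject <- function(field) {
    dplyr::bind_rows(lapply(seq_along(cohort$data), function(s) {
      df <- cohort$data[[s]][[field]]
      if (is.null(df) || nrow(df) == 0) return(NULL)
      dplyr::bind_cols(tibble::tibble(subject = s), df)
    }))
  }
  samples <- with_subject("samples")
  readr::write_tsv(samples, file.path(dir, "samples.tsv"))
  phases <- with_subject("phases")
  percepts <- dplyr::transmute(phases, subject = subject,
                               trial = trial, t_s = start_s,
                               key_state = label)
  readr::write_tsv(percepts, file.path(dir, "percepts.tsv"))
  readr::write_csv(cohort$aq_responses, file.path(dir, "aq_responses.csv"))
  if (!is.null(cohort$data[[1]]$events)) {
    ev <- with_subject("events")
    ev$kind <- "increment"
    readr::write_tsv(ev[, c("subject", "trial", "t_s", "dot_color", "kind")],
                     file.path(dir, "events.tsv"))
    readr::write_tsv(with_subject("presses"), file.path(dir, "presses.tsv"))
  }
  readr::write_csv(cohort$subjects, file.path(dir, "ground_truth.csv"))
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Analysis configuration
#'
#' All thresholds and windows of the pipeline, with the study's values as
#' defaults. `load_config()` reads a YAML file (unknown keys are rejected);
#' the shipped defaults live at
#' `system.file("extdata", "paper_defaults.yaml", package = "pupilstyle")`.
#'
#' @param ... Overrides of the default fields.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    experiment = "main",
    min_pupil_mm = 1, max_pupil_mm = 7,
    min_phase_s = 1, max_phase_s = 15, min_usable_phases = 10,
    trial_duration_s = 59, gap_tolerance_s = 0.2,
    analysis_rate_hz = 60, baseline_s = 0.15,
    epoch_window_s = c(-1, 1), pre_window_s = c(-1, 0),
    post_window_s = c(0, 1), index_mode = "pre_post",
    onset_window_s = c(0, 6), attention_window_s = c(1, 3),
    detection_window_s = 2,
    ci_level = 0.95, bf_prior_scale = jzs_default_scale,
    alpha = 0.05
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$experiment %in% c("main", "swapped", "feature_attention",
                          "double_task", "instruction"),
    cfg$min_pupil_mm < cfg$max_pupil_mm,
    cfg$min_phase_s < cfg$max_phase_s, cfg$min_usable_phases >= 0,
    cfg$trial_duration_s > 0, cfg$analysis_rate_hz > 0,
    cfg$baseline_s > 0, length(cfg$epoch_window_s) == 2,
    cfg$index_mode %in% c("pre_post", "post_only"),
    cfg$detection_window_s > 0, cfg$ci_level > 0, cfg$ci_level < 1)
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(analysis_config, cfg)
}
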