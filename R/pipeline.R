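#' Run a full experiment analysis on a data directory
#'
#' End-to-end orchestration: read the input tables, segment and filter each
#' subject's percept phases, mask pupil samples, extract switch-locked (or
#' onset-locked) epochs, compute the per-subject indices, score the
#' detection task when present, and run the inferential layer (correlation
#' of the luminance-modulation index with AQ). Excluded subjects are
#' reported with their QC, never silently dropped.
#'
#' @param data_dir Directory containing `samples.tsv`, `percepts.tsv`,
#'   `aq_responses.csv` and, depending on the experiment, `events.tsv`,
#'   `presses.tsv` or `onsets.tsv`.
#' @param config An [analysis_config()].
#' @return List with `subjects` (per-subject summary tibble: indices,
#'   switch rate, QC, exclusion flags), `stats` (correlation results), and
#'   `traces` (figure-ready across-subject mean traces).
#' @export
run_experiment <- function(data_dir, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  samples_all <- read_samples(file.path(data_dir, "samples.tsv"))
  aq <- score_aq(read_aq_responses(file.path(data_dir, "aq_responses.csv")))
  if (config$experiment == "feature_attention") {
    onset_path <- file.path(data_dir, "onsets.tsv")
    if (!file.exists(onset_path)) {
      stop("feature_attention analysis needs onsets.tsv with a cue column",
           call. = FALSE)
    }
    onsets_all <- readr::read_tsv(onset_path, col_types = readr::cols(
      subject = readr::col_integer(), trial = readr::col_integer(),
      t_s = readr::col_double(), cue = readr::col_character()))
    check_columns(onsets_all, c("subject", "trial", "t_s", "cue"),
                  onset_path)
    return(run_attention(samples_all, onsets_all, aq, config))
  }
  percepts_all <- read_percepts(file.path(data_dir, "percepts.tsv"))
  has_detection <- file.exists(file.path(data_dir, "events.tsv"))
  if (config$experiment == "double_task" && !has_detection) {
    stop("double_task analysis needs events.tsv and presses.tsv",
         call. = FALSE)
  }
  events_all <- if (has_detection) {
    read_events(file.path(data_dir, "events.tsv"))
  }
  presses_all <- if (has_detection) {
    read_presses(file.path(data_dir, "presses.tsv"))
  }
  subjects <- sort(unique(samples_all$subject))
  rows <- vector("list", length(subjects))
  epochs_kept <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    samples <- samples_all[samples_all$subject == s, ]
    percepts <- percepts_all[percepts_all$subject == s, ]
    seg <- segment_phases(percepts, config$trial_duration_s,
                          config$gap_tolerance_s)
    flt <- filter_phases(seg, config$min_phase_s, config$max_phase_s,
                         config$min_usable_phases, config$trial_duration_s)
    sq <- sample_qc(samples, config$min_pupil_mm, config$max_pupil_mm)
    row <- dplyr::bind_cols(
      tibble::tibble(subject = s,
                     aq_total = aq$total[match(s, aq$subject)]),
      flt$qc, sq)
    row$switch_rate <- switch_rate(flt$phases)
    row$foreground_share <- tryCatch(foreground_time_share(flt$phases),
                                     error = function(e) NA_real_)
    if (!flt$qc$subject_excluded) {
      ep <- extract_switch_epochs(
        samples, flt$phases, config$epoch_window_s, config$analysis_rate_hz,
        config$baseline_s, config$min_pupil_mm, config$max_pupil_mm)
      row$luminance_modulation <- tryCatch(
        luminance_modulation(ep, config$index_mode, config$pre_window_s,
                             config$post_window_s),
        error = function(e) NA_real_)
      row$general_dilation <- tryCatch(general_dilation(ep,
                                                        config$post_window_s),
                                       error = function(e) NA_real_)
      sig <- per_subject_significance(ep, config$post_window_s, config$alpha)
      row$modulation_positive <- sig$significant
      epochs_kept[[as.character(s)]] <- ep
    } else {
      row$luminance_modulation <- NA_real_
      row$general_dilation <- NA_real_
      row$modulation_positive <- NA
    }
    if (has_detection) {
      det <- score_detection(
        events_all[events_all$subject == s, ],
        presses_all[presses_all$subject == s, ],
        flt$phases, config$trial_duration_s, config$detection_window_s)
      row$dprime_front <- det$dprime[det$surface == "front"]
      row$dprime_rear <- det$dprime[det$surface == "rear"]
      row$dprime_overall <- det$dprime[det$surface == "overall"]
    }
    rows[[i]] <- row
  }
  subjects_tbl <- dplyr::bind_rows(rows)
  kept <- !subjects_tbl$subject_excluded &
    is.finite(subjects_tbl$luminance_modulation)
  stats <- list()
  if (sum(kept) >= 4) {
    stats$modulation_vs_aq <- pearson_full(
      subjects_tbl$luminance_modulation[kept], subjects_tbl$aq_total[kept],
      config$ci_level, config$bf_prior_scale)
    stats$dilation_vs_aq <- pearson_full(
      subjects_tbl$general_dilation[kept], subjects_tbl$aq_total[kept],
      config$ci_level, config$bf_prior_scale)
    stats$switch_rate_vs_aq <- pearson_full(
      subjects_tbl$switch_rate[kept], subjects_tbl$aq_total[kept],
      config$ci_level, config$bf_prior_scale)
    if (has_detection) {
      ok <- kept & is.finite(subjects_tbl$dprime_front) &
        is.finite(subjects_tbl$dprime_rear)
      stats$dprime_front_vs_rear <- paired_t(
        subjects_tbl$dprime_front[ok], subjects_tbl$dprime_rear[ok])
    }
    stats$n_modulation_positive <-
      sum(subjects_tbl$modulation_positive[kept], na.rm = TRUE)
  }
  traces <- if (length(epochs_kept) > 0) mean_traces(epochs_kept) else NULL
  list(subjects = subjects_tbl, stats = stats, traces = traces)
}

run_attention <- function(samples_all, onsets_all, aq, config) {
  subjects <- sort(unique(samples_all$subject))
  rows <- vector("list", length(subjects))
  epochs_kept <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    ep <- extract_onset_epochs(
      samples_all[samples_all$subject == s, ],
      onsets_all[onsets_all$subject == s, ],
      config$onset_window_s, config$analysis_rate_hz, config$baseline_s,
      config$min_pupil_mm, config$max_pupil_mm)
    rows[[i]] <- tibble::tibble(
      subject = s, aq_total = aq$total[match(s, aq$subject)],
      attention_modulation = tryCatch(
        attention_modulation(ep, config$attention_window_s),
        error = function(e) NA_real_),
      n_epochs = nrow(ep$mat))
    epochs_kept[[as.character(s)]] <- ep
  }
  subjects_tbl <- dplyr::bind_rows(rows)
  kept <- is.finite(subjects_tbl$attention_modulation)
  stats <- list()
  if (sum(kept) >= 4) {
    stats$attention_vs_aq <- pearson_full(
      subjects_tbl$attention_modulation[kept], subjects_tbl$aq_total[kept],
      config$ci_level, config$bf_prior_scale)
  }
  list(subjects = subjects_tbl, stats = stats,
       traces = mean_traces(epochs_kept))
}
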