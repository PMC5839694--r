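#' Mask unrealistic pupil samples
#'
#' A sample is invalid iff pupil < `min_mm` (blinks) or > `max_mm` (eyelash
#' interference) — strict inequalities, so samples exactly at a bound are
#' kept — or non-finite.
#'
#' @param samples Tibble with a `pupil_mm` column (or a numeric vector).
#' @param min_mm,max_mm Validity bounds, mm.
#' @return Logical vector, `TRUE` = valid, one element per sample.
#' @export
mask_pupil_samples <- function(samples, min_mm = 1, max_mm = 7) {
  p <- if (is.data.frame(samples)) samples$pupil_mm else samples
  is.finite(p) & p >= min_mm & p <= max_mm
}

#' Apply a validity mask to a recording
#'
#' Sets invalid samples' `pupil_mm` to `NA` so that downstream interpolation
#' propagates missingness instead of bridging artifacts.
#'
#' @param samples Sample tibble.
#' @param mask Logical mask from [mask_pupil_samples()].
#' @return The tibble with invalid `pupil_mm` replaced by `NA`.
#' @export
apply_mask <- function(samples, mask = mask_pupil_samples(samples)) {
  samples$pupil_mm[!mask] <- NA_real_
  samples
}

#' Segment a percept-report stream into phases
#'
#' The stream is a per-trial sequence of state changes (`black_front`,
#' `white_front`, or `none` when no key is held). Maximal constant-label
#' runs become phases; `none` gaps shorter than `gap_tolerance` are absorbed
#' into the preceding phase, longer gaps end it. The stream is assumed to
#' cover each trial up to `trial_duration`.
#'
#' @param percepts Tibble with `trial`, `t_s`, `key_state` (state-change
#'   rows, `t_s` increasing within trial). A `subject` column, if present,
#'   is carried through (one subject per call).
#' @param trial_duration Trial duration, s.
#' @param gap_tolerance Maximum `none` gap absorbed into the preceding
#'   phase, s.
#' @return Tibble with `trial`, `start_s`, `end_s`, `label`, ordered and
#'   non-overlapping within trial.
#' @export
segment_phases <- function(percepts, trial_duration = 59,
                           gap_tolerance = 0.2) {
  stopifnot(all(c("trial", "t_s", "key_state") %in% names(percepts)))
  bad <- !(percepts$key_state %in% c("black_front", "white_front", "none"))
  if (any(bad)) {
    stop("unknown key_state: ", percepts$key_state[which(bad)[1]],
         call. = FALSE)
  }
  out <- lapply(unique(percepts$trial), function(tr) {
    st <- percepts[percepts$trial == tr, ]
    st <- st[order(st$t_s), ]
    if (any(diff(st$t_s) <= 0)) {
      stop("non-increasing report timestamps in trial ", tr, call. = FALSE)
    }
    times <- c(st$t_s, trial_duration)
    states <- st$key_state
    # absorb short "none" gaps into the preceding keyed state
    for (i in seq_along(states)) {
      if (states[i] == "none" && i > 1 &&
          (times[i + 1] - times[i]) < gap_tolerance) {
        states[i] <- states[i - 1]
      }
    }
    keep <- c(TRUE, states[-1] != states[-length(states)])
    states <- states[keep]
    starts <- times[-length(times)][keep]
    ends <- c(starts[-1], trial_duration)
    keyed <- states != "none"
    if (!any(keyed)) return(NULL)
    tibble::tibble(trial = tr, start_s = starts[keyed], end_s = ends[keyed],
                   label = states[keyed])
  })
  dplyr::bind_rows(out)
}

#' Flag usable phases and build a QC report
#'
#' A phase is usable iff its duration lies in \[`min_s`, `max_s`\]
#' (inclusive: the exclusion rules are strictly "less than 1 s" and "longer
#' than 15 s") and it is not truncated by the trial end (duration censored).
#' A subject with fewer than `min_usable` usable phases is excluded.
#'
#' @param phases Phase tibble (from [segment_phases()] or the generator).
#' @param min_s,max_s Duration bounds, s.
#' @param min_usable Minimum usable phases for a subject to be retained.
#' @param trial_duration Trial duration, s (to detect end-truncated phases).
#' @return List with `phases` (input plus `usable`, `exclusion_reason`) and
#'   `qc` (single-row tibble: `n_phases`, `n_usable`, `fraction_excluded`,
#'   `subject_excluded`).
#' @export
filter_phases <- function(phases, min_s = 1, max_s = 15, min_usable = 10,
                          trial_duration = 59) {
  dur <- phases$end_s - phases$start_s
  boundary <- phases$end_s >= trial_duration - 1e-9
  reason <- dplyr::case_when(
    boundary ~ "trial_boundary",
    dur < min_s ~ "too_short",
    dur > max_s ~ "too_long",
    TRUE ~ "none"
  )
  phases$usable <- reason == "none"
  phases$exclusion_reason <- reason
  n_usable <- sum(phases$usable)
  qc <- tibble::tibble(
    n_phases = nrow(phases),
    n_usable = n_usable,
    fraction_excluded = if (nrow(phases) > 0) 1 - n_usable / nrow(phases)
    else NA_real_,
    subject_excluded = n_usable < min_usable
  )
  list(phases = phases, qc = qc)
}

#' Fraction of usable reporting time spent in the black-front percept
#'
#' @param phases Phase tibble with `usable` flags (see [filter_phases()]).
#' @return Scalar in \[0, 1\].
#' @export
foreground_time_share <- function(phases) {
  ph <- phases[phases$usable, ]
  tot <- sum(ph$end_s - ph$start_s)
  if (!is.finite(tot) || tot <= 0) {
    stop("no usable reporting time", call. = FALSE)
  }
  sum((ph$end_s - ph$start_s)[ph$label == "black_front"]) / tot
}

#' Sample-level QC summary
#'
#' @param samples Sample tibble.
#' @param min_mm,max_mm Validity bounds, mm.
#' @return Single-row tibble with `n_samples`, `fraction_samples_excluded`.
#' @export
sample_qc <- function(samples, min_mm = 1, max_mm = 7) {
  mask <- mask_pupil_samples(samples, min_mm, max_mm)
  tibble::tibble(n_samples = length(mask),
                 fraction_samples_excluded = mean(!mask))
}
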