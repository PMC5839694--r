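# Linear interpolation that propagates missing samples: a grid point is NA
# unless both bracketing samples exist and are valid.
interp_na <- function(t, p, tout) {
  idx <- findInterval(tout, t)
  ok <- idx >= 1 & idx < length(t)
  out <- rep(NA_real_, length(tout))
  i <- idx[ok]
  w <- (tout[ok] - t[i]) / (t[i + 1] - t[i])
  out[ok] <- (1 - w) * p[i] + w * p[i + 1]
  # exact hit on the last sample
  last <- tout == t[length(t)]
  out[last] <- p[length(t)]
  out
}

opposite_label <- function(label) {
  ifelse(label == "black_front", "white_front", "black_front")
}

#' Extract switch-locked pupil epochs
#'
#' For every perceptual switch (boundary between two contiguous phases of a
#' trial), the pupil trace is resampled onto the analysis grid over
#' `window` around the switch by linear interpolation (invalid samples
#' propagate as missing), and each side is baseline-corrected by its own
#' 150-ms window adjacent to the switch. The post side is labeled by the
#' destination percept; the pre side belongs to the ending percept (always
#' the opposite, since percepts alternate). A side is kept only if its
#' flanking phase is usable and its baseline window has at least
#' `min_baseline_frac` valid samples.
#'
#' @param samples One subject's sample tibble (`trial`, `t_s`, `pupil_mm`).
#'   Sample validity bounds are applied internally.
#' @param phases Phase tibble with `usable` flags (see [filter_phases()]).
#' @param window Epoch window around the switch, s.
#' @param analysis_rate Analysis grid rate, Hz (1000-Hz input is downsampled
#'   by the interpolation onto this grid).
#' @param baseline_s Baseline window length, s.
#' @param min_mm,max_mm Sample validity bounds, mm.
#' @param min_baseline_frac Minimum fraction of valid baseline samples.
#' @return An object of class `pupil_epochs`: list with `time` (grid),
#'   `mat` (epochs x time, baseline-corrected, `NA` where a side is
#'   dropped), `dest` (destination percept), `pre_ok`, `post_ok`, `trial`,
#'   `t_switch`, `type = "switch"`.
#' @export
extract_switch_epochs <- function(samples, phases, window = c(-1, 1),
                                  analysis_rate = 60, baseline_s = 0.15,
                                  min_mm = 1, max_mm = 7,
                                  min_baseline_frac = 0.5) {
  stopifnot(window[1] < 0, window[2] > 0)
  samples <- apply_mask(samples, mask_pupil_samples(samples, min_mm, max_mm))
  tt <- seq(window[1], window[2], by = 1 / analysis_rate)
  pre_i <- tt < 0
  post_i <- tt >= 0
  pre_base <- tt >= -baseline_s & tt < 0
  post_base <- tt >= 0 & tt <= baseline_s
  rows <- list(); dest <- character(0); pre_ok <- logical(0)
  post_ok <- logical(0); trial <- integer(0); t_switch <- numeric(0)
  for (tr in unique(phases$trial)) {
    ph <- phases[phases$trial == tr, ]
    ph <- ph[order(ph$start_s), ]
    sm <- samples[samples$trial == tr, ]
    if (nrow(ph) < 2 || nrow(sm) < 2) next
    for (k in seq_len(nrow(ph) - 1)) {
      if (abs(ph$end_s[k] - ph$start_s[k + 1]) > 1e-6) next  # gap: no switch
      ts <- ph$end_s[k]
      trace <- interp_na(sm$t_s, sm$pupil_mm, ts + tt)
      p_ok <- ph$usable[k]
      q_ok <- ph$usable[k + 1]
      if (p_ok) {
        b <- trace[pre_base]
        if (mean(is.finite(b)) >= min_baseline_frac) {
          trace[pre_i] <- trace[pre_i] - mean(b, na.rm = TRUE)
        } else p_ok <- FALSE
      }
      if (!p_ok) trace[pre_i] <- NA_real_
      if (q_ok) {
        b <- trace[post_base]
        if (mean(is.finite(b)) >= min_baseline_frac) {
          trace[post_i] <- trace[post_i] - mean(b, na.rm = TRUE)
        } else q_ok <- FALSE
      }
      if (!q_ok) trace[post_i] <- NA_real_
      if (!p_ok && !q_ok) next
      rows[[length(rows) + 1]] <- trace
      dest <- c(dest, ph$label[k + 1]); pre_ok <- c(pre_ok, p_ok)
      post_ok <- c(post_ok, q_ok); trial <- c(trial, tr)
      t_switch <- c(t_switch, ts)
    }
  }
  structure(list(time = tt,
                 mat = if (length(rows)) do.call(rbind, rows)
                 else matrix(numeric(0), 0, length(tt)),
                 dest = dest, pre_ok = pre_ok, post_ok = post_ok,
                 trial = trial, t_switch = t_switch, type = "switch"),
            class = "pupil_epochs")
}

#' Extract onset-locked pupil epochs
#'
#' Traces are aligned to stimulus onset, resampled onto the analysis grid
#' over `window`, and corrected by the mean pupil size in the 150 ms
#' preceding the onset. Labels (attention cues) are carried 1:1.
#'
#' @param samples One subject's sample tibble.
#' @param onsets Tibble with `trial`, `t_s` (onset time), `cue`
#'   (`"black_cued"`/`"white_cued"`).
#' @inheritParams extract_switch_epochs
#' @return A `pupil_epochs` object with `label` instead of `dest`,
#'   `type = "onset"`.
#' @export
extract_onset_epochs <- function(samples, onsets, window = c(0, 6),
                                 analysis_rate = 60, baseline_s = 0.15,
                                 min_mm = 1, max_mm = 7,
                                 min_baseline_frac = 0.5) {
  samples <- apply_mask(samples, mask_pupil_samples(samples, min_mm, max_mm))
  tt <- seq(window[1], window[2], by = 1 / analysis_rate)
  tb <- seq(-baseline_s, -1e-9, by = 1 / analysis_rate)
  rows <- list(); label <- character(0); trial <- integer(0)
  onset_t <- numeric(0)
  for (j in seq_len(nrow(onsets))) {
    sm <- samples[samples$trial == onsets$trial[j], ]
    if (nrow(sm) < 2) next
    base <- interp_na(sm$t_s, sm$pupil_mm, onsets$t_s[j] + tb)
    if (mean(is.finite(base)) < min_baseline_frac) next
    trace <- interp_na(sm$t_s, sm$pupil_mm, onsets$t_s[j] + tt) -
      mean(base, na.rm = TRUE)
    rows[[length(rows) + 1]] <- trace
    label <- c(label, onsets$cue[j]); trial <- c(trial, onsets$trial[j])
    onset_t <- c(onset_t, onsets$t_s[j])
  }
  structure(list(time = tt,
                 mat = if (length(rows)) do.call(rbind, rows)
                 else matrix(numeric(0), 0, length(tt)),
                 label = label, trial = trial, t_onset = onset_t,
                 type = "onset"),
            class = "pupil_epochs")
}

#' Per-label mean trace for one subject
#'
#' For switch epochs, the black-front trace combines the post side of
#' switches *to* black with the pre side of switches *away from* black (the
#' phase that is ending); for onset epochs, labels are used directly.
#'
#' @param epochs A `pupil_epochs` object.
#' @param label Percept or cue label.
#' @return Numeric vector over `epochs$time` (pointwise mean, `NA` where no
#'   epoch contributes).
#' @export
label_trace <- function(epochs, label) {
  tt <- epochs$time
  out <- rep(NA_real_, length(tt))
  if (epochs$type == "onset") {
    sel <- epochs$label == label
    if (any(sel)) out <- colMeans(epochs$mat[sel, , drop = FALSE],
                                  na.rm = TRUE)
    return(ifelse(is.nan(out), NA_real_, out))
  }
  pre_i <- tt < 0; post_i <- tt >= 0
  pre_sel <- epochs$dest == opposite_label(label) & epochs$pre_ok
  post_sel <- epochs$dest == label & epochs$post_ok
  if (any(pre_sel)) {
    out[pre_i] <- colMeans(epochs$mat[pre_sel, pre_i, drop = FALSE],
                           na.rm = TRUE)
  }
  if (any(post_sel)) {
    out[post_i] <- colMeans(epochs$mat[post_sel, post_i, drop = FALSE],
                            na.rm = TRUE)
  }
  ifelse(is.nan(out), NA_real_, out)
}

#' Across-subject mean traces with s.e.m.
#'
#' Within-subject label means are computed first, then averaged across
#' subjects; the s.e.m. is across subjects (reported as `NA` for a single
#' subject). Missing grid points are ignored pointwise with count tracking.
#'
#' @param epoch_list A `pupil_epochs` object or a list of them (one per
#'   subject).
#' @param labels Labels to summarise (default: those present).
#' @return Tibble with `time`, `label`, `mean`, `sem`, `n`.
#' @export
mean_traces <- function(epoch_list, labels = NULL) {
  if (inherits(epoch_list, "pupil_epochs")) epoch_list <- list(epoch_list)
  present <- unique(unlist(lapply(epoch_list, function(e) {
    if (e$type == "onset") unique(e$label) else unique(e$dest)
  })))
  if (is.null(labels)) labels <- sort(present)
  missing <- setdiff(labels, present)
  if (length(missing) > 0) {
    stop("label(s) absent: ", paste(missing, collapse = ", "),
         "; present: ", paste(present, collapse = ", "), call. = FALSE)
  }
  tt <- epoch_list[[1]]$time
  out <- lapply(labels, function(lb) {
    m <- do.call(rbind, lapply(epoch_list, label_trace, label = lb))
    n <- colSums(is.finite(m))
    mu <- colMeans(m, na.rm = TRUE)
    sem <- apply(m, 2, function(col) {
      col <- col[is.finite(col)]
      if (length(col) > 1) stats::sd(col) / sqrt(length(col)) else NA_real_
    })
    tibble::tibble(time = tt, label = lb,
                   mean = ifelse(is.nan(mu), NA_real_, mu), sem = sem, n = n)
  })
  dplyr::bind_rows(out)
}

window_mean <- function(tt, trace, window, closed_left = TRUE) {
  sel <- if (closed_left) tt >= window[1] & tt <= window[2]
  else tt > window[1] & tt <= window[2]
  mean(trace[sel], na.rm = TRUE)
}

#' Luminance-dependent pupil-modulation index
#'
#' The difference between the subject's black-front and white-front mean
#' traces, averaged over the index windows: the post-switch window \[0, 1\] s
#' and (in the default `"pre_post"` mode) also the pre-switch window
#' \[-1, 0) s, the two window means being averaged. Positive = more dilated
#' when the black surface is perceived in front.
#'
#' @param epochs A subject's switch `pupil_epochs`.
#' @param mode `"pre_post"` (default) or `"post_only"`.
#' @param pre_window,post_window Index windows, s.
#' @return Index in mm.
#' @export
luminance_modulation <- function(epochs, mode = c("pre_post", "post_only"),
                                 pre_window = c(-1, 0),
                                 post_window = c(0, 1)) {
  mode <- match.arg(mode)
  b <- label_trace(epochs, "black_front")
  w <- label_trace(epochs, "white_front")
  d <- b - w
  tt <- epochs$time
  post <- window_mean(tt, d, post_window)
  if (!is.finite(post)) {
    stop("a percept label is missing from the post-switch epochs",
         call. = FALSE)
  }
  if (mode == "post_only") return(post)
  pre_sel <- tt >= pre_window[1] & tt < pre_window[2]
  pre <- mean(d[pre_sel], na.rm = TRUE)
  if (!is.finite(pre)) {
    stop("a percept label is missing from the pre-switch epochs",
         call. = FALSE)
  }
  (pre + post) / 2
}

#' General post-switch pupil dilation
#'
#' Mean over \[0, 1\] s of the baseline-corrected post-switch trace pooled
#' across both percept labels.
#'
#' @param epochs A subject's switch `pupil_epochs`.
#' @param window Averaging window, s.
#' @return Dilation in mm.
#' @export
general_dilation <- function(epochs, window = c(0, 1)) {
  sel <- epochs$post_ok
  if (!any(sel)) stop("no post-switch epochs", call. = FALSE)
  tt <- epochs$time
  cols <- tt >= window[1] & tt <= window[2]
  mu <- colMeans(epochs$mat[sel, cols, drop = FALSE], na.rm = TRUE)
  mean(mu, na.rm = TRUE)
}

#' Feature-based attention modulation
#'
#' Difference between the black-cued and white-cued onset-locked traces,
#' averaged over \[1, 3\] s from stimulus onset (where the feature-based
#' attention effect peaks).
#'
#' @param epochs A subject's onset `pupil_epochs`.
#' @param window Averaging window, s.
#' @return Modulation in mm.
#' @export
attention_modulation <- function(epochs, window = c(1, 3)) {
  b <- label_trace(epochs, "black_cued")
  w <- label_trace(epochs, "white_cued")
  out <- window_mean(epochs$time, b - w, window)
  if (!is.finite(out)) stop("a cue label is missing", call. = FALSE)
  out
}

#' Perceptual switch rate
#'
#' Number of within-trial switches divided by total in-trial reporting
#' time.
#'
#' @param phases Phase tibble.
#' @param total_time Reporting time, s (default: summed per-trial span).
#' @return Switches per second.
#' @export
switch_rate <- function(phases, total_time = NULL) {
  n_switch <- 0L
  span <- 0
  for (tr in unique(phases$trial)) {
    ph <- phases[phases$trial == tr, ]
    ph <- ph[order(ph$start_s), ]
    if (nrow(ph) > 1) {
      n_switch <- n_switch +
        sum(abs(ph$end_s[-nrow(ph)] - ph$start_s[-1]) < 1e-6)
    }
    span <- span + max(ph$end_s) - min(ph$start_s)
  }
  if (is.null(total_time)) total_time <- span
  if (total_time <= 0) stop("zero reporting time", call. = FALSE)
  n_switch / total_time
}

#' Is a subject's modulation significantly positive?
#'
#' Per-epoch post-window means are compared between destination percepts
#' with a one-sided Welch t-test (black > white) at level `alpha`. The
#' paper does not state its per-subject test; Welch is this package's
#' documented choice.
#'
#' @param epochs A subject's switch `pupil_epochs`.
#' @param window Post-switch window, s.
#' @param alpha Significance level.
#' @return List with `significant`, `p_value`, `n_black`, `n_white`
#'   (`significant = NA` with a `reason` when either group has < 2 epochs).
#' @export
per_subject_significance <- function(epochs, window = c(0, 1),
                                     alpha = 0.05) {
  tt <- epochs$time
  cols <- tt >= window[1] & tt <= window[2]
  sel <- epochs$post_ok
  vals <- rowMeans(epochs$mat[sel, cols, drop = FALSE], na.rm = TRUE)
  grp <- epochs$dest[sel]
  b <- vals[grp == "black_front" & is.finite(vals)]
  w <- vals[grp == "white_front" & is.finite(vals)]
  if (length(b) < 2 || length(w) < 2) {
    return(list(significant = NA, p_value = NA_real_, n_black = length(b),
                n_white = length(w), reason = "insufficient epochs"))
  }
  tst <- stats::t.test(b, w, alternative = "greater")
  list(significant = tst$p.value < alpha, p_value = tst$p.value,
       n_black = length(b), n_white = length(w))
}
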