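#' Classify key presses as hits or false alarms
#'
#' A press is a hit for the most recent event no more than `window` seconds
#' before it; each event is credited at most one hit (the earliest press in
#' its window; surplus presses inside a credited window are ignored). When
#' a press falls inside the windows of two events, it is attributed to the
#' later (closer) one. A press more than `window` seconds away from every
#' event (in either direction) is a false alarm; a press that precedes a
#' nearby event (within `window`, but answering nothing) is neither and is
#' dropped. Times are compared within trial.
#'
#' @param events Event tibble with `trial`, `t_s` (sorted within trial).
#' @param presses Press tibble with `trial`, `t_s`.
#' @param window Hit window, s.
#' @return List with `events` (input plus `hit`, `press_t`), `false_alarms`
#'   (press tibble), `n_ignored` (surplus/ambiguous presses).
#' @export
classify_presses <- function(events, presses, window = 2) {
  stopifnot(window > 0)
  events$hit <- FALSE
  events$press_t <- NA_real_
  fa <- list(); n_ignored <- 0L
  for (tr in unique(c(events$trial, presses$trial))) {
    ei <- which(events$trial == tr)
    et <- events$t_s[ei]
    stopifnot(!is.unsorted(et))
    pt <- sort(presses$t_s[presses$trial == tr])
    for (p in pt) {
      # most recent event at or before the press, within the window
      cand <- which(et <= p & p - et <= window)
      if (length(cand) > 0) {
        k <- max(cand)  # later = closer event
        if (!events$hit[ei[k]]) {
          events$hit[ei[k]] <- TRUE
          events$press_t[ei[k]] <- p
        } else {
          n_ignored <- n_ignored + 1L
        }
      } else if (length(et) == 0 || all(abs(p - et) > window)) {
        fa[[length(fa) + 1]] <- tibble::tibble(trial = tr, t_s = p)
      } else {
        n_ignored <- n_ignored + 1L  # early press just before an event
      }
    }
  }
  list(events = events,
       false_alarms = if (length(fa)) dplyr::bind_rows(fa)
       else tibble::tibble(trial = integer(0), t_s = numeric(0)),
       n_ignored = n_ignored)
}

#' Perceived surface of a speed-increment event
#'
#' An event on the black or white dots is on the front surface iff its dot
#' colour matches the perceived foreground at the event time. Events during
#' unusable (or unreported) phases are excluded (`NA`).
#'
#' @param events Event tibble with `trial`, `t_s`, `dot_color`.
#' @param phases Phase tibble with `usable` flags (ground-truth phases from
#'   the generator carry no flags and are treated as all usable).
#' @return The events tibble with a `surface` column
#'   (`"front"`/`"rear"`/`NA`).
#' @export
surface_of_event <- function(events, phases) {
  if (!"usable" %in% names(phases)) phases$usable <- TRUE
  surface <- rep(NA_character_, nrow(events))
  for (j in seq_len(nrow(events))) {
    ph <- phases[phases$trial == events$trial[j] &
                   phases$start_s <= events$t_s[j] &
                   phases$end_s > events$t_s[j], ]
    if (nrow(ph) == 1 && ph$usable) {
      front_color <- if (ph$label == "black_front") "black" else "white"
      surface[j] <- if (events$dot_color[j] == front_color) "front" else "rear"
    }
  }
  events$surface <- surface
  events
}

#' False-alarm opportunities
#'
#' The paper never defines the false-alarm denominator; this package uses
#' the number of non-overlapping `window`-sized bins of reporting time that
#' contain no event, so hit and false-alarm rates are commensurate
#' proportions.
#'
#' @param events Event tibble with `trial`, `t_s`.
#' @param trial_duration Trial duration, s.
#' @param trials Trials to count over (default: those in `events`).
#' @param window Bin length, s.
#' @return Integer count of event-free bins.
#' @export
fa_opportunities <- function(events, trial_duration = 59, trials = NULL,
                             window = 2) {
  if (is.null(trials)) trials <- unique(events$trial)
  n <- 0L
  for (tr in trials) {
    et <- events$t_s[events$trial == tr]
    edges <- seq(0, trial_duration, by = window)
    if (length(edges) < 2) next
    for (b in seq_len(length(edges) - 1)) {
      if (!any(et >= edges[b] & et < edges[b + 1])) n <- n + 1L
    }
  }
  n
}

#' Signal-detection sensitivity (d-prime)
#'
#' `d' = z(H) - z(F)` with the standard-normal quantile `z`; rates of 0 or
#' 1 are corrected to `1/(2N)` and `1 - 1/(2N)`.
#'
#' @param n_hits,n_events Hit count and number of events.
#' @param n_fas,n_fa_opportunities False-alarm count and number of
#'   opportunities (see [fa_opportunities()]).
#' @return List with `hit_rate`, `fa_rate` (corrected), `dprime`, and the
#'   raw counts.
#' @export
dprime <- function(n_hits, n_events, n_fas, n_fa_opportunities) {
  if (n_events < 1) stop("need at least one event", call. = FALSE)
  if (n_fa_opportunities < 1) stop("zero false-alarm opportunities",
                                   call. = FALSE)
  correct <- function(k, n) {
    r <- k / n
    if (r <= 0) 1 / (2 * n) else if (r >= 1) 1 - 1 / (2 * n) else r
  }
  H <- correct(n_hits, n_events)
  F_ <- correct(n_fas, n_fa_opportunities)
  list(hit_rate = H, fa_rate = F_, dprime = stats::qnorm(H) - stats::qnorm(F_),
       n_hits = n_hits, n_events = n_events, n_fas = n_fas,
       n_fa_opportunities = n_fa_opportunities)
}

#' Score a subject's detection data by perceived surface
#'
#' Combines press classification, event-surface resolution and d-prime,
#' separately for events on the front and rear surface (events in unusable
#' phases are dropped with a count).
#'
#' @param events Event tibble (`trial`, `t_s`, `dot_color`).
#' @param presses Press tibble (`trial`, `t_s`).
#' @param phases Phase tibble with `usable` flags.
#' @param trial_duration Trial duration, s.
#' @param window Hit window, s.
#' @return Tibble with one row per surface (`front`, `rear`, `overall`) and
#'   columns `hit_rate`, `fa_rate`, `dprime`, `n_events`, `n_hits`,
#'   `n_fas`, `n_dropped_events`.
#' @export
score_detection <- function(events, presses, phases, trial_duration = 59,
                            window = 2) {
  cls <- classify_presses(events, presses, window)
  ev <- surface_of_event(cls$events, phases)
  n_fas <- nrow(cls$false_alarms)
  n_opp <- fa_opportunities(events, trial_duration, window = window)
  dropped <- sum(is.na(ev$surface))
  one <- function(sel, name) {
    if (sum(sel) < 1) {
      return(tibble::tibble(surface = name, hit_rate = NA_real_,
                            fa_rate = NA_real_, dprime = NA_real_,
                            n_events = 0L, n_hits = 0L, n_fas = n_fas,
                            n_dropped_events = dropped))
    }
    d <- dprime(sum(ev$hit[sel]), sum(sel), n_fas, n_opp)
    tibble::tibble(surface = name, hit_rate = d$hit_rate,
                   fa_rate = d$fa_rate, dprime = d$dprime,
                   n_events = sum(sel), n_hits = sum(ev$hit[sel]),
                   n_fas = n_fas, n_dropped_events = dropped)
  }
  keep <- !is.na(ev$surface)
  dplyr::bind_rows(one(keep & ev$surface == "front", "front"),
                   one(keep & ev$surface == "rear", "rear"),
                   one(keep, "overall"))
}

#' Score the cued counting task
#'
#' Percent correct is the exact-match fraction of reported vs true counts
#' (0-3 per trial). The d-prime collapses counts to per-opportunity
#' detections: hits = sum of `min(reported, true)` over trials out of the
#' true events; false alarms = sum of `max(reported - true, 0)` out of the
#' unfilled opportunity slots (`max_count - true`). This collapsing
#' convention is this package's documented choice; the paper does not
#' define one.
#'
#' @param reported,true Integer vectors of per-trial counts, in 0..`max_count`.
#' @param max_count Maximum possible count per trial.
#' @return List with `percent_correct`, `dprime`, and the collapsed counts.
#' @export
score_counting_task <- function(reported, true, max_count = 3) {
  stopifnot(length(reported) == length(true))
  if (any(reported < 0 | reported > max_count | true < 0 |
          true > max_count)) {
    stop("counts must lie in 0..", max_count, call. = FALSE)
  }
  pc <- 100 * mean(reported == true)
  n_hits <- sum(pmin(reported, true))
  n_sig <- sum(true)
  n_fas <- sum(pmax(reported - true, 0))
  n_opp <- sum(max_count - true)
  d <- if (n_sig >= 1 && n_opp >= 1) {
    dprime(n_hits, n_sig, n_fas, n_opp)$dprime
  } else NA_real_
  list(percent_correct = pc, dprime = d, n_hits = n_hits, n_signals = n_sig,
       n_fas = n_fas, n_fa_opportunities = n_opp)
}
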