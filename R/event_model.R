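#' Protocol specification for a conditioning group
#'
#' A protocol is defined by the mean CS-US interval `T_mean` (CS durations
#' vary uniformly from trial to trial between `T_min` and `T_max`, reinforced
#' at CS termination), the mean US-US interval `C`, the minimum inter-trial
#' interval, and the session structure. The pre-CS observation window is the
#' stretch of ITI immediately before CS onset during which baseline pokes are
#' recorded; it defaults to 10 s but is a field because some designs use
#' longer windows.
#'
#' @param group_id Label for the group.
#' @param T_mean Mean CS-US interval in seconds.
#' @param C Mean US-US interval in seconds; must exceed `T_mean`.
#' @param trials_per_session Trials per session (positive integer).
#' @param n_sessions Number of sessions.
#' @param iti_min Minimum inter-trial interval in seconds (>= 15 by design).
#' @param pre_cs_window Pre-CS observation window in seconds.
#' @param T_min,T_max Range of CS durations; defaults are the uniform
#'   mean-centred rule `[2, 2*T_mean - 2]`.
#' @return An object of class `"protocol_spec"`.
#' @examples
#' protocol_spec("g1", T_mean = 42, C = 63, trials_per_session = 10,
#'               n_sessions = 42)
#' @export
protocol_spec <- function(group_id, T_mean, C, trials_per_session,
                          n_sessions, iti_min = 15, pre_cs_window = 10,
                          T_min = 2, T_max = 2 * T_mean - 2) {
  stopifnot(T_mean > 0, C > T_mean, T_min >= 2, T_max >= T_min,
            iti_min > 0, trials_per_session >= 1, n_sessions >= 1,
            pre_cs_window > 0)
  out <- list(group_id = as.character(group_id), T_mean = T_mean,
              T_min = T_min, T_max = T_max, C = C, iti_min = iti_min,
              trials_per_session = as.integer(trials_per_session),
              n_sessions = as.integer(n_sessions),
              pre_cs_window = pre_cs_window)
  class(out) <- "protocol_spec"
  out
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf(
    "Protocol %s: T = %g s [%g-%g], C = %g s, C/T = %.3g, %d trials x %d sessions\n",
    x$group_id, x$T_mean, x$T_min, x$T_max, x$C, x$C / x$T_mean,
    x$trials_per_session, x$n_sessions))
  invisible(x)
}

#' The 14-group informativeness design
#'
#' The standard design spanning informativeness ratios (C/T) from 1.5 to 300:
#' 14 groups differing in mean CS-US interval `T` and mean US-US interval
#' `C`, with 10 trials per session for the first 11 groups and 3 for the
#' last three, 42 daily sessions, minimum ITI 15 s, and a 10 s pre-CS
#' observation window.
#'
#' @return A data frame with columns `group`, `T_mean`, `C`,
#'   `trials_per_session`, `n_sessions` and `iota` (= C/T).
#' @examples
#' head(default_protocols())
#' @export
default_protocols <- function() {
  d <- data.frame(
    group = 1:14,
    T_mean = c(42, 48, 21, 12, 6, 62, 30, 18, 36, 26, 8, 16, 10, 14),
    C = c(63, 144, 94.5, 72, 54, 930, 600, 486, 1296, 1404, 576,
          1760, 1800, 4200),
    trials_per_session = c(rep(10L, 11), rep(3L, 3)),
    n_sessions = 42L
  )
  d$iota <- d$C / d$T_mean
  d
}

#' @rdname default_protocols
#' @param group Row of [default_protocols()] to convert (1-14).
#' @param n_sessions Optionally override the number of sessions.
#' @export
default_protocol_spec <- function(group, n_sessions = NULL) {
  d <- default_protocols()
  stopifnot(group %in% d$group)
  r <- d[d$group == group, ]
  protocol_spec(group_id = as.character(r$group), T_mean = r$T_mean, C = r$C,
                trials_per_session = r$trials_per_session,
                n_sessions = if (is.null(n_sessions)) r$n_sessions else n_sessions)
}

#' Construct and validate a poke stream
#'
#' A poke stream is the timestamped record of magazine entries for one
#' subject: one row per photo-beam interruption, with entry and exit times
#' in seconds from session start (millisecond precision) and a session
#' index. Events must be strictly ordered within session, non-overlapping,
#' with `exit >= entry`.
#'
#' @param subject_id Subject label.
#' @param session Session index per event (integer).
#' @param entry,exit Entry and exit times in seconds from session start.
#' @return A data frame of class `"poke_stream"` with columns `subject_id`,
#'   `session`, `entry`, `exit`.
#' @export
poke_stream <- function(subject_id, session, entry, exit) {
  stopifnot(length(session) == length(entry), length(entry) == length(exit))
  d <- data.frame(subject_id = rep(as.character(subject_id), length(entry)),
                  session = as.integer(session),
                  entry = round(as.numeric(entry), 3),
                  exit = round(as.numeric(exit), 3))
  d <- d[order(d$session, d$entry), , drop = FALSE]
  rownames(d) <- NULL
  validate_poke_stream(d)
  class(d) <- c("poke_stream", "data.frame")
  d
}

validate_poke_stream <- function(d) {
  if (any(d$exit < d$entry)) {
    stop("poke stream invalid: exit before entry at row ",
         which(d$exit < d$entry)[1])
  }
  by_sess <- split(seq_len(nrow(d)), d$session)
  for (idx in by_sess) {
    if (length(idx) > 1) {
      ent <- d$entry[idx]; ext <- d$exit[idx]
      if (any(diff(ent) <= 0)) {
        stop("poke stream invalid: events not strictly ordered in session ",
             d$session[idx[1]])
      }
      if (any(ent[-1] < ext[-length(ext)])) {
        stop("poke stream invalid: overlapping pokes in session ",
             d$session[idx[1]])
      }
    }
  }
  invisible(d)
}

#' Read and write poke-event and trial tables
#'
#' The events CSV dialect has columns `subject_id`, `session`,
#' `poke_start_s`, `poke_end_s`; the trials CSV has `subject_id`, `session`,
#' `trial`, `cs_onset_s`, `cs_duration_s`, `reinforced`. Malformed rows
#' raise a parse error naming the offending line; overlapping pokes raise a
#' validation error.
#'
#' @param path File path.
#' @return `read_events()` returns a `"poke_stream"`; `read_trials()` a
#'   trial-schedule data frame with columns `trial`, `session`, `cs_onset`,
#'   `cs_duration`, `reinforced`.
#' @export
read_events <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "poke_start_s", "poke_end_s")
  if (!all(need %in% names(d))) {
    stop("events file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  d$poke_start_s <- suppressWarnings(as.numeric(d$poke_start_s))
  d$poke_end_s <- suppressWarnings(as.numeric(d$poke_end_s))
  bad <- which(!is.finite(d$poke_start_s) | !is.finite(d$poke_end_s))
  if (length(bad)) {
    stop("malformed events row at line ", bad[1] + 1L)
  }
  poke_stream(d$subject_id[1], d$session, d$poke_start_s, d$poke_end_s)
}

#' @rdname read_events
#' @param stream A `"poke_stream"`.
#' @export
write_events <- function(stream, path) {
  d <- data.frame(subject_id = stream$subject_id, session = stream$session,
                  poke_start_s = sprintf("%.3f", stream$entry),
                  poke_end_s = sprintf("%.3f", stream$exit))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_events
#' @export
read_trials <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "trial", "cs_onset_s", "cs_duration_s")
  if (!all(need %in% names(d))) {
    stop("trials file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  d$cs_onset_s <- suppressWarnings(as.numeric(d$cs_onset_s))
  d$cs_duration_s <- suppressWarnings(as.numeric(d$cs_duration_s))
  bad <- which(!is.finite(d$cs_onset_s) | !is.finite(d$cs_duration_s) |
                 d$cs_duration_s < 2)
  if (length(bad)) {
    stop("malformed trials row at line ", bad[1] + 1L)
  }
  out <- data.frame(trial = as.integer(d$trial), session = as.integer(d$session),
                    cs_onset = d$cs_onset_s, cs_duration = d$cs_duration_s,
                    reinforced = if ("reinforced" %in% names(d))
                      as.integer(d$reinforced) else 1L)
  out[order(out$trial), , drop = FALSE]
}

#' @rdname read_events
#' @param schedule A trial schedule as returned by [read_trials()] or
#'   [generate_protocol()].
#' @param subject_id Subject label written into the file.
#' @export
write_trials <- function(schedule, path, subject_id = "s1") {
  d <- data.frame(subject_id = subject_id, session = schedule$session,
                  trial = schedule$trial,
                  cs_onset_s = sprintf("%.3f", schedule$cs_onset),
                  cs_duration_s = sprintf("%.3f", schedule$cs_duration),
                  reinforced = if ("reinforced" %in% names(schedule))
                    schedule$reinforced else 1L)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event/trial table pair into a stream plus trial summaries
#'
#' Convenience reader combining [read_events()], [read_trials()] and
#' [summarize_trials()].
#'
#' @param events_path,trials_path CSV paths in the documented dialects.
#' @param pre_cs_window Pre-CS observation window in seconds.
#' @return A list with elements `stream`, `schedule` and `trials` (the
#'   per-trial summaries).
#' @export
read_event_table <- function(events_path, trials_path, pre_cs_window = 10) {
  stream <- read_events(events_path)
  schedule <- read_trials(trials_path)
  list(stream = stream, schedule = schedule,
       trials = summarize_trials(stream, schedule, pre_cs_window))
}

#' Per-trial counts, exposures and latencies
#'
#' For each trial the CS window is `[cs_onset, cs_onset + cs_duration)` and
#' the pre-CS window is the `pre_cs_window` seconds ending at CS onset
#' (truncated at the session start). A poke belongs to the context in which
#' it begins, which keeps counts additive across contexts; in-magazine time
#' within a window is clipped at the window end.
#'
#' @param stream A `"poke_stream"`.
#' @param schedule Trial schedule: data frame with `trial`, `session`,
#'   `cs_onset`, `cs_duration`.
#' @param pre_cs_window Pre-CS observation window in seconds.
#' @return A data frame with one row per trial: `trial`, `session`,
#'   `cs_onset`, `cs_duration`, `n_cs_pokes`, `cs_first_poke_latency` (`NA`
#'   when no CS poke), `cs_in_magazine_time`, `n_pre_pokes`, `pre_exposure`,
#'   `pre_in_magazine_time`.
#' @examples
#' s <- poke_stream("r1", c(1, 1), c(12, 14), c(12.4, 14.5))
#' sched <- data.frame(trial = 1, session = 1, cs_onset = 10, cs_duration = 20)
#' summarize_trials(s, sched)
#' @export
summarize_trials <- function(stream, schedule, pre_cs_window = 10) {
  stopifnot(nrow(schedule) >= 1)
  schedule <- schedule[order(schedule$trial), , drop = FALSE]
  if (any(duplicated(schedule$trial))) stop("duplicate trial indices")
  # non-overlap of trials within each session
  for (sch in split(schedule, schedule$session)) {
    if (nrow(sch) > 1) {
      sch <- sch[order(sch$cs_onset), , drop = FALSE]
      if (any(sch$cs_onset[-1] < (sch$cs_onset + sch$cs_duration)[-nrow(sch)])) {
        stop("trial schedule overlaps within session ", sch$session[1])
      }
    }
  }
  n <- nrow(schedule)
  out <- data.frame(
    trial = schedule$trial, session = schedule$session,
    cs_onset = schedule$cs_onset, cs_duration = schedule$cs_duration,
    n_cs_pokes = 0L, cs_first_poke_latency = NA_real_,
    cs_in_magazine_time = 0, n_pre_pokes = 0L,
    pre_exposure = 0, pre_in_magazine_time = 0
  )
  by_sess <- split(stream[, c("entry", "exit")], stream$session)
  for (i in seq_len(n)) {
    sess <- as.character(schedule$session[i])
    on <- schedule$cs_onset[i]; dur <- schedule$cs_duration[i]
    pre_start <- max(0, on - pre_cs_window)
    out$pre_exposure[i] <- on - pre_start
    ev <- by_sess[[sess]]
    if (is.null(ev) || nrow(ev) == 0) next
    in_cs <- ev$entry >= on & ev$entry < on + dur
    in_pre <- ev$entry >= pre_start & ev$entry < on
    out$n_cs_pokes[i] <- sum(in_cs)
    if (any(in_cs)) {
      out$cs_first_poke_latency[i] <- min(ev$entry[in_cs]) - on
      out$cs_in_magazine_time[i] <-
        sum(pmin(ev$exit[in_cs], on + dur) - ev$entry[in_cs])
    }
    out$n_pre_pokes[i] <- sum(in_pre)
    if (any(in_pre)) {
      out$pre_in_magazine_time[i] <-
        sum(pmin(ev$exit[in_pre], on) - ev$entry[in_pre])
    }
  }
  out
}
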