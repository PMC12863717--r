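#' Build the CS inter-poke interval vector
#'
#' Constructs the vector of head-out inter-poke intervals used for CS rate
#' parsing. Within each CS, the first poke is excluded from the count (first
#' poke latencies come from a different distribution than subsequent
#' inter-poke intervals) and each remaining poke contributes the head-out
#' gap that preceded it (previous poke's exit to this poke's entry). CSs
#' with fewer than two pokes contribute nothing: with no poke there is no
#' latency to exclude, and with a single poke there is no countable poke
#' after the first. The resulting rate - countable pokes over summed gaps -
#' is the corrected (head-out) CS rate.
#'
#' @param stream A `"poke_stream"`.
#' @param schedule Trial schedule (`trial`, `session`, `cs_onset`,
#'   `cs_duration`).
#' @return An object of class `"interval_vector"`: list with `intervals`
#'   (positive seconds), `trial` (origin trial per interval) and `context =
#'   "CS"`.
#' @export
build_cs_intervals <- function(stream, schedule) {
  ivs <- list(); trs <- list()
  for (i in seq_len(nrow(schedule))) {
    sess <- schedule$session[i]
    on <- schedule$cs_onset[i]; dur <- schedule$cs_duration[i]
    ev <- stream[stream$session == sess &
                   stream$entry >= on & stream$entry < on + dur, , drop = FALSE]
    k <- nrow(ev)
    if (k >= 2) {
      gaps <- ev$entry[-1] - ev$exit[-k]
      gaps[gaps <= 0] <- 1e-3  # beam re-entry at recording resolution
      ivs[[length(ivs) + 1L]] <- gaps
      trs[[length(trs) + 1L]] <- rep(schedule$trial[i], k - 1L)
    }
  }
  out <- list(intervals = unlist(ivs) %||% numeric(0),
              trial = unlist(trs) %||% integer(0),
              context = "CS")
  class(out) <- "interval_vector"
  out
}

#' Build the pre-CS (ITI) inter-poke interval vector
#'
#' Pre-CS rate estimates use raw counts and durations (no first-poke
#' exclusion). The pre-CS observation windows are concatenated into one
#' continuous timeline; each poke contributes the interval since the
#' previous poke on that timeline (the first poke measures time from the
#' start of observation). Time after the final poke is right-censored and
#' not included.
#'
#' @inheritParams build_cs_intervals
#' @param trials Per-trial summaries from [summarize_trials()]; used for the
#'   window geometry.
#' @return An `"interval_vector"` with `context = "ITI"`.
#' @export
build_pre_intervals <- function(stream, trials) {
  pos <- numeric(0); tr <- integer(0)
  offset <- 0
  for (i in seq_len(nrow(trials))) {
    sess <- trials$session[i]
    on <- trials$cs_onset[i]
    w <- trials$pre_exposure[i]
    start <- on - w
    ev <- stream[stream$session == sess &
                   stream$entry >= start & stream$entry < on, , drop = FALSE]
    if (nrow(ev)) {
      pos <- c(pos, offset + (ev$entry - start))
      tr <- c(tr, rep(trials$trial[i], nrow(ev)))
    }
    offset <- offset + w
  }
  iv <- diff(c(0, pos))
  iv[iv <= 0] <- 1e-3
  out <- list(intervals = iv, trial = tr, context = "ITI")
  class(out) <- "interval_vector"
  out
}

#' @export
print.interval_vector <- function(x, ...) {
  cat(sprintf("%s interval vector: %d intervals over trials %s-%s\n",
              x$context, length(x$intervals),
              if (length(x$trial)) min(x$trial) else "-",
              if (length(x$trial)) max(x$trial) else "-"))
  invisible(x)
}

## Change-point profile over candidate split points of an interval vector.
## "segments": G(s) = s*DKL(rate_1:s || rate_full) +
##                    (n-s)*DKL(rate_s+1:n || rate_full),
## the count-weighted divergence of the two complementary sub-sequences from
## the full-sequence rate (half the likelihood-ratio deviance, Gamma(0.5,1)
## under the null). "prefix": n_e(s, n)*DKL(rate_1:s || rate_full), the
## one-sided prefix profile.
split_profile <- function(x, comparison = c("segments", "prefix")) {
  comparison <- match.arg(comparison)
  n <- length(x)
  if (n < 2) return(numeric(0))
  cs <- cumsum(x)
  s <- seq_len(n - 1L)
  l_pre <- s / cs[s]
  l_full <- n / cs[n]
  if (comparison == "segments") {
    l_post <- (n - s) / (cs[n] - cs[s])
    s * dkl_exp(l_pre, l_full) + (n - s) * dkl_exp(l_post, l_full)
  } else {
    ndkl_stat(s, l_pre, n, l_full)
  }
}

#' Parse an interval vector into constant-rate segments
#'
#' Recursive change-point segmentation of a vector of inter-event intervals.
#' At each stage the divergence profile over candidate truncation points is
#' computed; whenever its maximum exceeds the decision criterion `c` (in
#' nats) the vector is truncated at the location of the maximum (ties broken
#' toward the earliest index) and the algorithm recurses on the
#' post-truncation remainder, until no sub-sequence is significant. The
#' default statistic is the count-weighted divergence of the two
#' complementary sub-sequences from the full-sequence rate, which is
#' distributed Gamma(0.5, 1) under the single-rate null, so `c = 6` nats is
#' exceeded by chance about once in 1800 tests. `comparison = "prefix"`
#' instead profiles only the prefix against the full sequence.
#'
#' Each segment's rate is its event count divided by its summed intervals.
#' A vector of fewer than two intervals is returned as a single segment.
#'
#' @param x An `"interval_vector"` or a bare numeric vector of positive
#'   intervals (seconds).
#' @param c Decision criterion in nats (> 0; conventionally 2, 4 or 6, with
#'   6 preferred because parsing makes many comparisons).
#' @param comparison Split statistic; see Details.
#' @return An object of class `"parse_segmentation"`: a data frame-bearing
#'   list with `segments` (columns `start`, `end`, `n`, `duration`,
#'   `rate`), `criterion`, `comparison`, and the origin-trial mapping when
#'   available.
#' @examples
#' set.seed(1)
#' v <- c(rexp(30, 0.1), rexp(30, 1))
#' parse_intervals(v, c = 6)
#' @export
parse_intervals <- function(x, c = 6, comparison = c("segments", "prefix")) {
  comparison <- match.arg(comparison)
  stopifnot(c > 0)
  iv <- if (inherits(x, "interval_vector")) x$intervals else as.numeric(x)
  trial <- if (inherits(x, "interval_vector")) x$trial else NULL
  stopifnot(all(iv > 0))
  n <- length(iv)
  bounds <- integer(0)  # last index of each closed segment
  lo <- 1L
  while (lo <= n) {
    seg <- iv[lo:n]
    prof <- split_profile(seg, comparison)
    if (length(prof) == 0 || max(prof) <= c) break
    cut <- which.max(prof)  # which.max takes the earliest maximum
    bounds <- c(bounds, lo + cut - 1L)
    lo <- lo + cut
  }
  ends <- c(bounds, n)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (n == 0) {
    segments <- data.frame(start = integer(0), end = integer(0),
                           n = integer(0), duration = numeric(0),
                           rate = numeric(0))
  } else {
    segments <- data.frame(
      start = starts, end = ends,
      n = ends - starts + 1L,
      duration = vapply(seq_along(starts),
                        function(i) sum(iv[starts[i]:ends[i]]), numeric(1))
    )
    segments$rate <- segments$n / segments$duration
  }
  out <- list(segments = segments, criterion = c, comparison = comparison,
              intervals = iv, trial = trial)
  class(out) <- "parse_segmentation"
  out
}

#' @export
print.parse_segmentation <- function(x, ...) {
  cat(sprintf("Parse (c = %g nats, %s statistic): %d segment(s)\n",
              x$criterion, x$comparison, nrow(x$segments)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Per-trial rates implied by a parse
#'
#' Expresses a segmentation on the trial axis. Each segment covers the
#' trials of its member intervals; the first segment extends back to trial 1
#' (the initial rate estimate extends to the start of observation) and the
#' last extends forward to `n_trials`. Trials falling between segments take
#' the rate of the segment that began most recently.
#'
#' @param seg A `"parse_segmentation"` built from an `"interval_vector"`
#'   (the origin-trial mapping is required).
#' @param n_trials Total number of trials on the axis.
#' @return Numeric vector of length `n_trials`: the parsed rate per trial
#'   (`NA` if the parse contains no intervals at all).
#' @export
parsed_trial_rates <- function(seg, n_trials) {
  stopifnot(inherits(seg, "parse_segmentation"))
  if (is.null(seg$trial)) stop("segmentation lacks an origin-trial mapping")
  if (length(seg$intervals) == 0) return(rep(NA_real_, n_trials))
  rates <- rep(NA_real_, n_trials)
  sg <- seg$segments
  for (i in seq_len(nrow(sg))) {
    from <- if (i == 1) 1L else seg$trial[sg$start[i]]
    to <- if (i == nrow(sg)) n_trials else seg$trial[sg$end[i]]
    if (to >= from) rates[from:to] <- sg$rate[i]
  }
  # forward-fill trials between segment boundaries
  for (t in seq_len(n_trials)[-1]) {
    if (is.na(rates[t])) rates[t] <- rates[t - 1L]
  }
  if (is.na(rates[1])) rates[1] <- rates[which(!is.na(rates))[1]]
  rates
}

#' Parse-based acquisition criterion
#'
#' The onset of conditioned responding according to the parsed rates: the
#' smallest trial `t` (0 meaning "from the start") such that over the trials
#' after `t` the parsed CS rate is strictly greater than the parsed ITI rate
#' on at least `prop` of trials.
#'
#' @param cs_rates,iti_rates Per-trial parsed rates (equal length), e.g.
#'   from [parsed_trial_rates()].
#' @param prop Required proportion of post-`t` trials with CS rate above ITI
#'   rate (default 0.95).
#' @return Integer trial boundary (0 when the criterion holds from the
#'   start) or `NA_integer_` when never satisfied.
#' @export
parse_based_acquisition <- function(cs_rates, iti_rates, prop = 0.95) {
  stopifnot(length(cs_rates) == length(iti_rates), prop > 0, prop <= 1)
  n <- length(cs_rates)
  greater <- cs_rates > iti_rates
  greater[is.na(greater)] <- FALSE
  for (t in 0:(n - 1L)) {
    idx <- (t + 1L):n
    if (mean(greater[idx]) >= prop) return(t)
  }
  NA_integer_
}

`%||%` <- function(a, b) if (is.null(a)) b else a
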