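#' Cumulative CS and contextual response-rate series
#'
#' At each trial the cumulative CS rate is the cumulative number of CS pokes
#' divided by cumulative CS time, and the cumulative contextual rate pools
#' the CS and pre-CS observation windows (the context includes the CS, so
#' the contextual count includes the CS pokes). The signed nDKL compares the
#' two cumulative rates with counts `n_x` = cumulative CS pokes and `n_y` =
#' cumulative contextual pokes, carrying a negative sign on trials where the
#' CS rate is below the contextual rate. Entries are `NA` (undefined) until
#' both rates are computable.
#'
#' @param trials Per-trial summaries from [summarize_trials()].
#' @return A data frame with one row per trial: `trial`, `cum_cs_count`,
#'   `cum_cs_time`, `cum_cs_rate`, `cum_ctx_count`, `cum_ctx_time`,
#'   `cum_ctx_rate`, `ndkl_signed`.
#' @export
cumulative_rate_series <- function(trials) {
  stopifnot(nrow(trials) >= 1)
  trials <- trials[order(trials$trial), , drop = FALSE]
  cs_n <- cumsum(trials$n_cs_pokes)
  cs_t <- cumsum(trials$cs_duration)
  ctx_n <- cumsum(trials$n_cs_pokes + trials$n_pre_pokes)
  ctx_t <- cumsum(trials$cs_duration + trials$pre_exposure)
  cs_rate <- ifelse(cs_t > 0, cs_n / cs_t, NA_real_)
  ctx_rate <- ifelse(ctx_t > 0, ctx_n / ctx_t, NA_real_)
  mag <- ndkl_stat(cs_n, cs_rate, ctx_n, ctx_rate)
  sgn <- ifelse(cs_rate >= ctx_rate, 1, -1)
  data.frame(trial = trials$trial,
             cum_cs_count = cs_n, cum_cs_time = cs_t, cum_cs_rate = cs_rate,
             cum_ctx_count = ctx_n, cum_ctx_time = ctx_t,
             cum_ctx_rate = ctx_rate,
             ndkl_signed = sgn * mag)
}

#' First index from which a series is permanently positive
#'
#' Returns the smallest index `t*` such that every defined value at indices
#' `>= t*` is strictly positive (exact zeros count as not-positive), with the
#' value at `t*` itself defined and positive. Undefined (`NA`) entries are
#' skipped when testing permanence: they neither establish nor break it.
#' Permanence is evaluated within the observed record; nothing is
#' extrapolated beyond the final trial. Returns `NA` when the series never
#' ends positive. The number of reinforcements to acquisition under this
#' criterion is `t* - 1` (the trial before the difference became permanently
#' positive).
#'
#' @param x Numeric series (e.g. the signed nDKL or a cumulative rate
#'   difference), possibly containing `NA`.
#' @return Integer index into `x`, or `NA_integer_`.
#' @examples
#' permanent_exceedance(c(-1, 0.5, -0.2, 0.3, 0.4))  # 4
#' permanent_exceedance(c(0.1, 0.2, 0.3))            # 1
#' @export
permanent_exceedance <- function(x) {
  if (length(x) == 0) stop("empty series")
  defined <- which(!is.na(x))
  if (length(defined) == 0) return(NA_integer_)
  neg <- defined[x[defined] <= 0]
  if (length(neg) == 0) return(defined[1])
  last_neg <- max(neg)
  after <- defined[defined > last_neg]
  if (length(after) == 0) return(NA_integer_)
  after[1]
}

#' Trials to a statistical acquisition criterion with the restart rule
#'
#' Recomputes the cumulative rates and the nDKL using only trials from
#' `start` onward (discarding the pre-acquisition record, which would dilute
#' the evidence) and returns the first trial at which the signed nDKL
#' permanently exceeds `threshold` within the record.
#'
#' @param trials Per-trial summaries from [summarize_trials()].
#' @param start Trial index at which to restart the cumulative record
#'   (normally the permanent-exceedance trial). `NA` gives `NA`.
#' @param threshold Criterion in nats (e.g. `odds_to_threshold(4)`).
#' @return Trial index (on the original trial numbering) or `NA_integer_`.
#' @export
trials_to_criterion <- function(trials, start, threshold) {
  stopifnot(threshold > 0)
  if (is.na(start)) return(NA_integer_)
  sub <- trials[trials$trial >= start, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_integer_)
  ser <- cumulative_rate_series(sub)
  idx <- permanent_exceedance(ser$ndkl_signed - threshold)
  if (is.na(idx)) NA_integer_ else ser$trial[idx]
}

#' Trials-to-acquisition profile for one subject
#'
#' Combines the acquisition indices for a single subject: the trial from
#' which the cumulative CS rate permanently exceeds the cumulative
#' contextual rate (`t_exceed`, with `reinforcements_to_acquisition =
#' t_exceed - 1`), the trials at which the restarted nDKL permanently
#' exceeds each statistical threshold, and the trial of the minimum signed
#' nDKL (reported as a descriptive marker only; it can mislocalise
#' acquisition and is never used as the default criterion).
#'
#' Two formulations of `t_exceed` are available. The default compares the
#' from-trial-1 cumulative rates. The `"fixed_point"` mode instead searches
#' for the smallest trial `t` such that the cumulative records restarted at
#' `t + 1` stay permanently positive.
#'
#' @param trials Per-trial summaries from [summarize_trials()].
#' @param thresholds Named vector of criteria in nats; defaults to odds 4:1
#'   plus p < .05, .01, .001.
#' @param mode `"cumulative"` (default) or `"fixed_point"`.
#' @return An object of class `"acquisition_profile"`: a list with
#'   `t_exceed`, `reinforcements_to_acquisition`, `t_by_threshold` (named
#'   integer vector), `t_min_ndkl` and the series used.
#' @export
acquisition_profile <- function(trials,
                                thresholds = c(odds4 = odds_to_threshold(4),
                                               p05 = odds_to_threshold(19),
                                               p01 = odds_to_threshold(99),
                                               p001 = odds_to_threshold(999)),
                                mode = c("cumulative", "fixed_point")) {
  mode <- match.arg(mode)
  ser <- cumulative_rate_series(trials)
  t_exceed <- if (mode == "cumulative") {
    idx <- permanent_exceedance(ser$ndkl_signed)
    if (is.na(idx)) NA_integer_ else ser$trial[idx]
  } else {
    fixed_point_exceedance(trials)
  }
  t_thr <- vapply(thresholds, function(th)
    trials_to_criterion(trials, t_exceed, th), integer(1))
  t_min <- if (all(is.na(ser$ndkl_signed))) NA_integer_ else
    ser$trial[which.min(ser$ndkl_signed)]
  out <- list(t_exceed = t_exceed,
              reinforcements_to_acquisition =
                if (is.na(t_exceed)) NA_integer_ else t_exceed - 1L,
              t_by_threshold = t_thr,
              t_min_ndkl = t_min,
              series = ser, mode = mode)
  class(out) <- "acquisition_profile"
  out
}

## Fixed-point variant: smallest t such that the cumulative CS rate computed
## from trial t+1 onward is permanently greater than the contextual rate
## computed over the same restarted record.
fixed_point_exceedance <- function(trials) {
  trials <- trials[order(trials$trial), , drop = FALSE]
  for (i in seq_len(nrow(trials) - 1L)) {
    sub <- trials[(i + 1L):nrow(trials), , drop = FALSE]
    ser <- cumulative_rate_series(sub)
    idx <- permanent_exceedance(ser$ndkl_signed)
    if (!is.na(idx) && idx == which(!is.na(ser$ndkl_signed))[1]) {
      return(trials$trial[i])
    }
  }
  NA_integer_
}

#' @export
print.acquisition_profile <- function(x, ...) {
  cat("Acquisition profile (", x$mode, " mode)\n", sep = "")
  cat("  permanent exceedance at trial:", x$t_exceed,
      "(reinforcements to acquisition:", x$reinforcements_to_acquisition, ")\n")
  for (nm in names(x$t_by_threshold)) {
    cat(sprintf("  criterion %s: trial %s\n", nm, x$t_by_threshold[[nm]]))
  }
  cat("  minimum signed nDKL at trial:", x$t_min_ndkl, "\n")
  invisible(x)
}

#' Acquisition table for a cohort
#'
#' Applies [acquisition_profile()] to each subject of a simulated or loaded
#' cohort and returns one row per subject.
#'
#' @param cohort A list of subjects as returned by [generate_cohort()]; each
#'   element needs `subject_id`, `group`, `iota` and `trials`.
#' @param ... Passed to [acquisition_profile()].
#' @return Data frame: `subject_id`, `group`, `iota`, `t_exceed`,
#'   `reinf_to_acq`, one column per threshold, `t_min_ndkl`.
#' @export
cohort_acquisition <- function(cohort, ...) {
  rows <- lapply(cohort, function(s) {
    pr <- acquisition_profile(s$trials, ...)
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     iota = s$iota, t_exceed = pr$t_exceed,
                     reinf_to_acq = pr$reinforcements_to_acquisition,
                     t_min_ndkl = pr$t_min_ndkl),
          as.data.frame(as.list(pr$t_by_threshold)))
  })
  do.call(rbind, rows)
}
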