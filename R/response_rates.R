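#' Corrected response-rate estimator
#'
#' Response rates computed as count over elapsed time underestimate high
#' poke rates because time spent with the head in the magazine (mean poke
#' duration about 0.5 s) is unavailable for initiating another poke, and
#' because the latency to the first poke of a CS comes from a different
#' distribution than the later inter-poke intervals. The corrected
#' estimator divides an adjusted count by the observation time minus the
#' excluded latencies and minus in-magazine time. When
#' `zero_count = "half"` and the count is zero, the numerator is set to 0.5
#' - an unbiased stand-in for a true rate known only to lie between 0 and
#' 1 per total exposure - so the log rate remains defined.
#'
#' @param count Number of pokes observed.
#' @param exposure Observation time in seconds.
#' @param n_excluded Pokes excluded from the numerator (e.g. one first poke
#'   per CS).
#' @param excluded_time Time excluded from the denominator (e.g. summed
#'   first-poke latencies), seconds.
#' @param in_magazine_time Summed poke durations to subtract from the
#'   denominator, seconds.
#' @param zero_count `"half"` applies the 0.5-count convention when the
#'   adjusted count is zero; `"none"` leaves it at zero.
#' @return Rate in events/second.
#' @examples
#' corrected_rate(10, 60, n_excluded = 3, excluded_time = 6,
#'                in_magazine_time = 3.5)        # 7/50.5
#' corrected_rate(0, 2100, zero_count = "half")  # 0.5/2100
#' @export
corrected_rate <- function(count, exposure, n_excluded = 0,
                           excluded_time = 0, in_magazine_time = 0,
                           zero_count = c("none", "half")) {
  zero_count <- match.arg(zero_count)
  denom <- exposure - excluded_time - in_magazine_time
  if (any(denom <= 0)) stop("non-positive adjusted exposure")
  num <- count - n_excluded
  if (any(num < 0)) stop("more excluded pokes than observed")
  if (zero_count == "half") num <- ifelse(num == 0, 0.5, num)
  num / denom
}

#' Terminal response rates over the final training sessions
#'
#' Pools the last `final_sessions` sessions of a subject's per-trial record
#' into one corrected CS rate and one pre-CS (ITI) rate. The CS rate counts
#' pokes after the first poke of each CS and divides by the remaining CS
#' time with the head out of the magazine (CSs with no pokes are excluded
#' entirely). The ITI rate uses raw counts - no first-poke exclusion - over
#' head-out pre-CS time, with the 0.5-count convention when the subject
#' never poked in the pre-CS windows. Reinforcement rates 1/T and 1/C come
#' from the protocol.
#'
#' @param trials Per-trial summaries from [summarize_trials()].
#' @param protocol A `"protocol_spec"`.
#' @param final_sessions Number of final sessions to pool (5 by default;
#'   10 gives very similar results on well-trained subjects).
#' @return One-row data frame: `cs_rate`, `iti_rate`, `cs_reinf_rate`
#'   (= 1/T), `ctx_reinf_rate` (= 1/C), `n_trials_used`.
#' @export
terminal_rates <- function(trials, protocol, final_sessions = 5) {
  stopifnot(inherits(protocol, "protocol_spec"), final_sessions >= 1)
  keep <- trials$session > max(trials$session) - final_sessions
  tr <- trials[keep, , drop = FALSE]
  with_poke <- tr$n_cs_pokes >= 1
  cs_rate <- if (!any(with_poke)) NA_real_ else corrected_rate(
    sum(tr$n_cs_pokes[with_poke]),
    sum(tr$cs_duration[with_poke]),
    n_excluded = sum(with_poke),
    excluded_time = sum(tr$cs_first_poke_latency[with_poke]),
    in_magazine_time = sum(tr$cs_in_magazine_time[with_poke]),
    zero_count = "none"
  )
  iti_rate <- corrected_rate(
    sum(tr$n_pre_pokes), sum(tr$pre_exposure),
    in_magazine_time = sum(tr$pre_in_magazine_time),
    zero_count = "half"
  )
  data.frame(cs_rate = cs_rate, iti_rate = iti_rate,
             cs_reinf_rate = 1 / protocol$T_mean,
             ctx_reinf_rate = 1 / protocol$C,
             n_trials_used = nrow(tr))
}

## BIC from residual sum of squares: n*ln(RSS/n) + p*ln(n).
bic_rss <- function(rss, n, p) n * log(rss / n) + p * log(n)

#' Log-log scalar regression of response rate on reinforcement rate
#'
#' Fits `log10(response rate) = intercept + slope * log10(reinforcement
#' rate)` by least squares, either with a free slope or with the slope
#' fixed at 1. A slope of 1 means the non-log relation is a straight line
#' through the origin: response rate is a fixed multiple (the scalar) of
#' reinforcement rate. The regression is computed in the log domain because
#' the variability about the scalar relation is multiplicative.
#'
#' @param x,y Reinforcement and response rates in log10 units (finite,
#'   length >= 2).
#' @param variant `"free"` (slope and intercept) or `"slope1"` (intercept
#'   only).
#' @return An object of class `"scalar_fit"`: `slope`, `intercept_log10`,
#'   `scalar` (= 10^intercept), `r_squared`, `rss`, `bic`, `n`, `p`,
#'   `variant`.
#' @examples
#' x <- log10(c(0.01, 0.05, 0.1)); y <- log10(21.8) + x
#' fit_scalar_regression(x, y, "slope1")$scalar  # 21.8
#' @export
fit_scalar_regression <- function(x, y, variant = c("free", "slope1")) {
  variant <- match.arg(variant)
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  if (variant == "free") {
    if (stats::sd(x) == 0) stop("degenerate x-spread with a free slope")
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    res <- stats::residuals(fit)
    p <- 2L
  } else {
    slope <- 1
    intercept <- mean(y - x)
    res <- y - x - intercept
    p <- 1L
  }
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  out <- list(slope = slope, intercept_log10 = intercept,
              scalar = 10^intercept,
              r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
              rss = rss, bic = bic_rss(rss, length(y), p),
              n = length(y), p = p, variant = variant)
  class(out) <- "scalar_fit"
  out
}

#' @export
print.scalar_fit <- function(x, ...) {
  cat(sprintf(
    "Scalar fit (%s): slope %.3f, intercept %.3f log10 (scalar %.3g), R^2 = %.3f, BIC = %.1f\n",
    x$variant, x$slope, x$intercept_log10, x$scalar, x$r_squared, x$bic))
  if (!is.null(x$shift_log10)) {
    cat(sprintf("  ITI shift: %.3f log10 units (factor %.3g)\n",
                x$shift_log10, x$shift_factor))
  }
  invisible(x)
}

#' Shared-scalar model with a uniform ITI reinforcement-rate shift
#'
#' Fits the slope-1 model in which a single scaling factor relates response
#' rate to reinforcement rate during both the CS and the ITI, but the
#' reinforcement rate effective during the ITI is the overall rate 1/C
#' shifted down by a constant factor (the CS overshadows what is learned
#' about the context). In log10 units the model is
#' `y_cs = a + x_cs` and `y_iti = a + (x_iti - shift)`; `a` and `shift` are
#' the two free parameters, and the least-squares solution makes `shift`
#' the difference between the x-intercepts of separate slope-1 fits to the
#' CS and ITI points.
#'
#' @param cs_x,cs_y CS reinforcement (1/T) and response rates, log10 units.
#' @param iti_x,iti_y ITI reinforcement (1/C) and response rates, log10
#'   units.
#' @return A `"scalar_fit"` (variant `"shifted-shared"`) with additional
#'   fields `shift_log10` and `shift_factor` (= 10^shift).
#' @export
fit_shifted_shared <- function(cs_x, cs_y, iti_x, iti_y) {
  stopifnot(length(cs_x) == length(cs_y), length(iti_x) == length(iti_y),
            length(cs_x) >= 1, length(iti_x) >= 1)
  d_cs <- cs_y - cs_x
  d_iti <- iti_y - iti_x
  a <- mean(d_cs)
  shift <- a - mean(d_iti)
  res <- c(d_cs - a, d_iti - (a - shift))
  y <- c(cs_y, iti_y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  out <- list(slope = 1, intercept_log10 = a, scalar = 10^a,
              r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
              rss = rss, bic = bic_rss(rss, n, 2L), n = n, p = 2L,
              variant = "shifted-shared",
              shift_log10 = shift, shift_factor = 10^shift)
  class(out) <- "scalar_fit"
  out
}

#' Correlations and partial correlations of acquisition speed with protocol
#'
#' Product-moment correlations of log10 group medians of
#' trials-to-acquisition with log10(C/T), log10(C) and log10(T), plus the
#' partial correlations of each of log(C/T) and log(C) controlling for the
#' other (computed from the residuals of the two controlling regressions).
#' Columns with no variance yield `NA` with a warning rather than an error.
#'
#' @param group_stats Data frame with columns `median_trials`, `C`,
#'   `T_mean` (one row per group, at least 3 groups).
#' @return A list with `correlations` (named vector), `partials` (named
#'   vector) and `n_groups`.
#' @export
group_correlates <- function(group_stats) {
  stopifnot(all(c("median_trials", "C", "T_mean") %in% names(group_stats)))
  if (nrow(group_stats) < 3) stop("need at least 3 groups")
  y <- log10(group_stats$median_trials)
  lct <- log10(group_stats$C / group_stats$T_mean)
  lc <- log10(group_stats$C)
  lt <- log10(group_stats$T_mean)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant column; correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  partial <- function(a, b, z) {
    ra <- stats::residuals(stats::lm(a ~ z))
    rb <- stats::residuals(stats::lm(b ~ z))
    safe_cor(ra, rb)
  }
  list(
    correlations = c(log_CT = safe_cor(y, lct), log_C = safe_cor(y, lc),
                     log_T = safe_cor(y, lt)),
    partials = c(log_CT_given_C = partial(y, lct, lc),
                 log_C_given_CT = partial(y, lc, lct)),
    n_groups = nrow(group_stats)
  )
}
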