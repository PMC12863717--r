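#' Informativeness of a conditioning protocol
#'
#' The informativeness iota is the ratio of the CS reinforcement rate (1/T)
#' to the contextual reinforcement rate (1/C), i.e. `C/T`; its natural log
#' is the mutual information CS onset transmits about the wait to the next
#' reinforcement. A detection delay `delay` (e.g. the time taken to find
#' the first pellets when subjects are not magazine-trained) adds to both
#' intervals, giving the effective informativeness `(C + delay)/(T +
#' delay)` - a reduction that hits highly informative protocols much harder
#' than weakly informative ones.
#'
#' @param C Mean US-US interval, seconds.
#' @param T_mean Mean CS-US interval, seconds; must satisfy `C > T_mean > 0`.
#' @param delay US-detection delay in seconds (>= 0).
#' @return List with `iota`, `effective_iota`, `mutual_info_nats`,
#'   `mutual_info_bits`.
#' @examples
#' informativeness(63, 42)$iota                       # 1.5
#' informativeness(4200, 14, delay = 39)$effective_iota  # 80.0
#' @export
informativeness <- function(C, T_mean, delay = 0) {
  if (any(T_mean <= 0) || any(C <= T_mean)) stop("need C > T > 0")
  if (any(delay < 0)) stop("delay must be non-negative")
  iota <- C / T_mean
  list(iota = iota,
       effective_iota = (C + delay) / (T_mean + delay),
       mutual_info_nats = log(iota),
       mutual_info_bits = nats_to_bits(log(iota)))
}

#' Learning-rate regression on informativeness
#'
#' Fits the scalar learning-rate law `trials-to-acquisition =
#' ((iota - 1)/k')^s` by least squares of log trials on log(iota - 1).
#' The model is parameterised so that the x-intercept - the informativeness
#' at which the median subject acquires in one trial - remains `k' + 1`
#' whatever the slope (for slope -1 it reduces to the familiar
#' `k * (iota - 1)^s` form with `k = 1/k'`).
#'
#' @param medians Per-group median trials to acquisition (> 0).
#' @param iota Per-group informativeness; all must exceed 1.
#' @param conf_level Confidence level for the slope interval.
#' @return List with `s` (slope), `s_ci`, `intercept` (log of trials at
#'   `iota - 1 = 1`), `k_prime` (the `iota - 1` value giving one-trial
#'   acquisition), `x_intercept_iota` (= `k_prime + 1`), `r_squared` and
#'   the fitted `lm` object.
#' @examples
#' iota <- c(4.5, 9, 36, 300)
#' fit_learning_rate(297 / (iota - 1), iota)$s  # -1
#' @export
fit_learning_rate <- function(medians, iota, conf_level = 0.95) {
  stopifnot(length(medians) == length(iota))
  if (length(iota) < 3) stop("need at least 3 groups")
  if (any(iota <= 1)) stop("all informativeness values must exceed 1")
  if (any(medians <= 0)) stop("medians must be positive")
  x <- log(iota - 1); y <- log(medians)
  fit <- stats::lm(y ~ x)
  s <- unname(stats::coef(fit)[2])
  b0 <- unname(stats::coef(fit)[1])
  ci <- stats::confint(fit, "x", level = conf_level)
  k_prime <- exp(-b0 / s)
  list(s = s, s_ci = unname(ci[1, ]), intercept = b0, k_prime = k_prime,
       x_intercept_iota = k_prime + 1,
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Generative response-probability model
#'
#' In the one-parameter generative model, the probability that a subject
#' starts responding after any given reinforced trial is
#' `p = 1 - exp(-k * (iota - 1))`: an exponential function of the
#' informativeness in excess of 1, with rate constant `k` (default 1/297,
#' the value implied by the pigeon meta-analytic regression). Trials are
#' independent, so the cumulative probability of having responded by trial
#' `n` is `1 - (1 - p)^n`, and the median subject responds on the smallest
#' `n` for which that reaches one half.
#'
#' @param iota Informativeness (>= 1).
#' @param k Rate constant per unit informativeness.
#' @param n_trials Number of trials for the cumulative curve.
#' @return List with `p_per_trial`, `cumulative` (length `n_trials`),
#'   `median_trials` (`Inf` when `p = 0`).
#' @examples
#' response_probability(300)$median_trials  # 1
#' response_probability(3)$median_trials    # 103
#' @export
response_probability <- function(iota, k = 1 / 297, n_trials = 1000) {
  stopifnot(length(iota) == 1, n_trials >= 1, k > 0)
  if (iota < 1) stop("informativeness must be >= 1")
  p <- 1 - exp(-k * (iota - 1))
  cum <- 1 - (1 - p)^seq_len(n_trials)
  med <- if (p <= 0) Inf else ceiling(log(0.5) / log(1 - p))
  list(p_per_trial = p, cumulative = cum, median_trials = med)
}

#' Rate-estimation credit assignment for a one-CS protocol
#'
#' Solves the rate-estimation matrix equation ascribing the observed
#' reinforcement rates to the context alone and to the CS. With
#' informativeness `iota`, the observed vector (contextual rate; rate when
#' the CS is present) equals `[1, 1/iota; 1, 1]` times the ascribed vector
#' (context-without-CS; CS), so the ascription is the exact linear solve.
#' Ascribed rates can be negative and are reported raw.
#'
#' @param iota Informativeness; `iota = 1` makes the matrix singular.
#' @param observed Numeric length-2 vector: observed contextual
#'   reinforcement rate and observed rate in the presence of the CS.
#' @return List with `ascribed` (named: `context`, `cs`), `observed`,
#'   `iota` and the `matrix` used.
#' @examples
#' ret_solve(2, c(1, 3))$ascribed  # context -1, cs 4
#' @export
ret_solve <- function(iota, observed) {
  stopifnot(length(observed) == 2, all(is.finite(observed)))
  if (iota == 1) stop("matrix singular at informativeness 1")
  M <- matrix(c(1, 1, 1 / iota, 1), nrow = 2)
  asc <- solve(M, as.numeric(observed))
  list(ascribed = c(context = asc[1], cs = asc[2]),
       observed = as.numeric(observed), iota = iota, matrix = M)
}

#' Prospective and retrospective mutual information between event streams
#'
#' The prospective mutual information an x-stream carries about a y-stream
#' is the log ratio of the unconditional expected wait between y events to
#' the expected wait from an x event to the next y. The retrospective
#' variant is identical in form, looking back from each y to the most
#' recent x. Negative values (conditional wait longer than unconditional)
#' indicate an inhibitory cue and are returned as-is.
#'
#' @param wait_unconditional Expected wait between target events, seconds.
#' @param wait_conditional Expected wait conditional on the cue, seconds.
#' @return Mutual information in nats.
#' @examples
#' mutual_info_waits(100, 2)  # log(50) = 3.912
#' @export
mutual_info_waits <- function(wait_unconditional, wait_conditional) {
  if (any(wait_unconditional <= 0) || any(wait_conditional <= 0)) {
    stop("waits must be positive")
  }
  log(wait_unconditional / wait_conditional)
}
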