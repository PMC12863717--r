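#' Peak response rate by moving average over sessions
#'
#' The peak rate is the maximum of a centred moving average of the
#' per-session response rates (window width 3 sessions by default); ties
#' are broken toward the earliest window. The returned index is the last
#' session of the maximising window, marking the end of the growth segment.
#'
#' @param session_rates Per-session response rates (length >= `window`).
#' @param window Moving-average window width in sessions (odd).
#' @return List with `session_end` (last session of the maximising window)
#'   and `Rmax` (the maximal moving average).
#' @export
find_peak <- function(session_rates, window = 3) {
  n <- length(session_rates)
  if (n < window) stop("need at least ", window, " sessions")
  half <- (window - 1) / 2
  ma <- stats::filter(session_rates, rep(1 / window, window), sides = 2)
  ma <- as.numeric(ma)
  centre <- which.max(ma)  # earliest maximum
  list(session_end = min(centre + half, n), Rmax = ma[centre])
}

#' Trials to each decile of the response-rate increase
#'
#' Locates, for each decile `q` of the total rate increase `delta_R = Rmax -
#' R1`, the trial at which the slope of the cumulative response record first
#' sustainedly exceeded `R1 + q * delta_R`. The reference record
#' `cumR'_t = (R1 + q * delta_R) * cumT_t` is what the cumulative count
#' would be at constant rate `R1 + q * delta_R`; the trial maximising
#' `cumR'_t - cumR_t` (earliest tie) is where the observed slope overtook
#' that level. Records with `delta_R < 0.1` events/s are too flat for the
#' decile geometry and should be excluded upstream.
#'
#' @param cum_counts Cumulative response counts per trial (corrected
#'   counts, i.e. excluding each CS's first poke, when used on CS data).
#' @param cum_exposure Cumulative response opportunity per trial (seconds).
#' @param R1 Response rate at the start of the growth segment (events/s).
#' @param Rmax Peak response rate (events/s).
#' @param deciles Quantiles of `delta_R` to locate.
#' @return Integer vector of trial indices, one per decile.
#' @export
trials_to_deciles <- function(cum_counts, cum_exposure, R1, Rmax,
                              deciles = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(cum_counts) == length(cum_exposure), Rmax > R1)
  vapply(deciles, function(q) {
    ref <- (R1 + q * (Rmax - R1)) * cum_exposure
    which.max(ref - cum_counts)
  }, integer(1))
}

#' Growth-decile record for one subject
#'
#' Builds the decile record from a per-trial record of corrected CS counts
#' and exposures: finds the peak by moving session average, takes `R1` as
#' the corrected rate over the first session of the growth segment, and
#' extracts the trials to each decile. Subjects with `delta_R < min_delta`
#' are excluded (`NULL` is returned).
#'
#' @param trials Per-trial summaries from [summarize_trials()].
#' @param t1 First trial of the growth segment (e.g. the odds-4:1 criterion
#'   trial from [acquisition_profile()]).
#' @param window Moving-average window (sessions) for the peak.
#' @param min_delta Minimum `Rmax - R1` (events/s) for a usable record.
#' @return List with `t1`, `session_end`, `R1`, `Rmax`, `delta_R`,
#'   `trials_at_decile`; or `NULL` when the record is excluded.
#' @export
growth_decile_record <- function(trials, t1, window = 3, min_delta = 0.1) {
  if (is.na(t1)) return(NULL)
  tr <- trials[trials$trial >= t1, , drop = FALSE]
  if (nrow(tr) < 2) return(NULL)
  # corrected per-trial counts/exposures (first poke and head-in excluded)
  cnt <- pmax(tr$n_cs_pokes - 1, 0)
  expo <- ifelse(tr$n_cs_pokes >= 1,
                 tr$cs_duration - ifelse(is.na(tr$cs_first_poke_latency), 0,
                                         tr$cs_first_poke_latency) -
                   tr$cs_in_magazine_time,
                 0)
  expo[expo < 0] <- 0
  sess <- tr$session
  by_sess <- split(seq_len(nrow(tr)), sess)
  srate <- vapply(by_sess, function(i) {
    e <- sum(expo[i]); if (e > 0) sum(cnt[i]) / e else 0
  }, numeric(1))
  if (length(srate) < window) return(NULL)
  pk <- find_peak(srate, window)
  R1 <- srate[1]
  delta <- pk$Rmax - R1
  if (!is.finite(delta) || delta < min_delta) return(NULL)
  last_sess <- as.integer(names(srate))[pk$session_end]
  upto <- tr$session <= last_sess
  cum_counts <- cumsum(cnt[upto])
  cum_expo <- cumsum(expo[upto])
  keep <- cum_expo > 0
  dec <- trials_to_deciles(cum_counts[keep], cum_expo[keep], R1, pk$Rmax)
  list(t1 = t1, session_end = last_sess, R1 = R1, Rmax = pk$Rmax,
       delta_R = delta, trials_at_decile = dec)
}

inv_erf_gauss <- function(d, m, s, c) s * stats::qnorm(m * d + 0.5) + c

#' Fit four growth-curve forms to a decile record
#'
#' Least-squares fits of trials-to-criterion `t_c` against response decile
#' `d` for four candidate forms, compared by
#' `BIC = n * ln(RSS/n) + p * ln(n)` with `n` the number of deciles:
#' \describe{
#'   \item{line}{`t_c = m*d + c` (p = 2); uniform growth in rate.}
#'   \item{exponential}{`t_c = c*exp(m*d)` (p = 2); slope rises across
#'     deciles.}
#'   \item{inverse-cumulative-gaussian}{`t_c = s*sqrt(2)*erfinv(2*(m*d +
#'     0.5) - 1) + c` (p = 3); a step governed by a noisy decision
#'     threshold. The probability argument `m*d + 0.5` must stay inside
#'     (0, 1); fits violating the domain are flagged, not clipped.}
#'   \item{log}{`t_c = -ln(1 - d)/k + c` (p = 2); the inverse cumulative
#'     exponential implied by error-correction updating.}
#' }
#' Nonlinear forms are fitted from a deterministic coarse grid of starting
#' values (no randomness); a form that fails to converge is flagged and the
#' others are still reported. A BIC difference above 4.6 corresponds to
#' odds of about 10:1 in favour of the lower-BIC form.
#'
#' @param t_c Trials to each decile (length = `length(d)`).
#' @param d Deciles (default 0.1 to 0.9).
#' @return An object of class `"growth_fits"`: list of per-form fits
#'   (`params`, `rss`, `bic`, `converged`), plus `best` (name of the
#'   lowest-BIC converged form) and `n`.
#' @export
fit_growth_models <- function(t_c, d = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(t_c) == length(d), all(is.finite(t_c)))
  n <- length(d)
  fits <- list()

  lf <- stats::lm(t_c ~ d)
  fits$line <- list(params = c(m = unname(stats::coef(lf)[2]),
                               c = unname(stats::coef(lf)[1])),
                    rss = sum(stats::residuals(lf)^2), converged = TRUE)

  fits$exponential <- fit_nls_grid(
    t_c, d, function(p) p[2] * exp(p[1] * d),
    starts = {
      g <- expand.grid(m = c(0.5, 1, 2, 3, 5), c0 = NA)
      if (all(t_c > 0)) {
        ll <- stats::lm(log(t_c) ~ d)
        g <- rbind(c(unname(stats::coef(ll)[2]), exp(unname(stats::coef(ll)[1]))), g)
      }
      g$c0[is.na(g$c0)] <- max(min(t_c), 1e-3)
      as.matrix(g)
    },
    names = c("m", "c"))

  fits$inv_gauss <- fit_invgauss(t_c, d)

  z <- -log(1 - d)
  lg <- stats::lm(t_c ~ z)
  kinv <- unname(stats::coef(lg)[2])
  fits$log <- list(params = c(k = 1 / kinv, c = unname(stats::coef(lg)[1])),
                   rss = sum(stats::residuals(lg)^2), converged = TRUE)

  pfree <- c(line = 2L, exponential = 2L, inv_gauss = 3L, log = 2L)
  for (nm in names(fits)) {
    fits[[nm]]$p <- pfree[[nm]]
    fits[[nm]]$bic <- if (isTRUE(fits[[nm]]$converged))
      bic_rss(max(fits[[nm]]$rss, .Machine$double.eps), n, pfree[[nm]])
    else NA_real_
  }
  bics <- vapply(fits, function(f) f$bic %||% NA_real_, numeric(1))
  out <- list(fits = fits, n = n,
              best = if (all(is.na(bics))) NA_character_ else
                names(fits)[which.min(bics)])
  class(out) <- "growth_fits"
  out
}

## Gauss-Newton from a deterministic grid of starts; returns best fit.
fit_nls_grid <- function(y, d, fn, starts, names) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    res <- try(stats::optim(p0, function(p) sum((y - fn(p))^2),
                            method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(list(params = stats::setNames(rep(NA_real_, length(names)), names),
                rss = NA_real_, converged = FALSE))
  }
  list(params = stats::setNames(best$par, names), rss = best$value,
       converged = TRUE)
}

## Inverse-cumulative-Gaussian fit: for fixed m the model is linear in
## (s, c), so profile a deterministic m grid and refine by optimise.
fit_invgauss <- function(t_c, d) {
  dmax <- max(d)
  m_hi <- (1 - 1e-6 - 0.5) / dmax  # keep m*d + 0.5 < 1
  prof <- function(m) {
    q <- stats::qnorm(m * d + 0.5)
    f <- stats::lm(t_c ~ q)
    sum(stats::residuals(f)^2)
  }
  grid <- seq(0.01, m_hi * 0.999, length.out = 120)
  rss_g <- vapply(grid, prof, numeric(1))
  i <- which.min(rss_g)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimise(prof, c(lo, hi))
  m <- opt$minimum
  q <- stats::qnorm(m * d + 0.5)
  f <- stats::lm(t_c ~ q)
  list(params = c(m = m, s = unname(stats::coef(f)[2]),
                  c = unname(stats::coef(f)[1])),
       rss = sum(stats::residuals(f)^2),
       converged = is.finite(opt$objective))
}

#' @export
print.growth_fits <- function(x, ...) {
  cat("Growth-curve fits (n =", x$n, "deciles):\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-22s rss = %-10.4g BIC = %-8.2f %s\n", nm,
                f$rss, f$bic, if (!isTRUE(f$converged)) "[not converged]" else ""))
  }
  cat("  best form:", x$best, "\n")
  invisible(x)
}
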