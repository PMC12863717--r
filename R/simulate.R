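#' Behavioural parameters for the synthetic-cohort generator
#'
#' Defaults encode the study conditions the generator emulates: terminal
#' CS response rates that are `beta` (default 22) times the CS
#' reinforcement rate 1/T; ITI response rates scaled by the same factor but
#' against the contextual rate 1/C reduced by `iti_factor` (default 1.9,
#' the overshadowing of the context by the CS); poke durations with mean
#' 0.5 s; first-poke latencies floored at 2 s; multiplicative
#' between-subject spread of `noise_factor` (default 2.5, i.e. a residual
#' standard deviation of log10(2.5) = 0.39 log10 units); and an
#' acquisition trial drawn from the generative response-probability model
#' with rate constant `k` (default 1/297).
#'
#' @param beta Scalar relating terminal response rate to reinforcement
#'   rate.
#' @param iti_factor Divisor applied to 1/C for the terminal ITI rate.
#' @param k Rate constant of the generative acquisition model.
#' @param acquisition_trial If non-`NULL`, a fixed acquisition trial for
#'   every subject (e.g. 1 for a cohort studied at asymptote), bypassing
#'   the generative draw.
#' @param step_fraction Fraction of the baseline-to-peak rate difference
#'   taken in the initial step at acquisition.
#' @param ramp_fraction Fraction of the record over which the CS rate then
#'   ramps linearly to its peak.
#' @param poke_duration_mean Mean poke (head-in) duration, seconds.
#' @param poke_duration_floor Minimum poke duration, seconds.
#' @param first_poke_floor Minimum latency to the first CS poke, seconds.
#' @param noise_factor Multiplicative between-subject spread of terminal
#'   rates.
#' @return An object of class `"behavior_params"`.
#' @export
behavior_params <- function(beta = 22, iti_factor = 1.9, k = 1 / 297,
                            acquisition_trial = NULL, step_fraction = 0.25,
                            ramp_fraction = 1 / 3,
                            poke_duration_mean = 0.5,
                            poke_duration_floor = 0.1,
                            first_poke_floor = 2, noise_factor = 2.5) {
  stopifnot(beta > 0, iti_factor > 0, k > 0, step_fraction >= 0,
            step_fraction <= 1, ramp_fraction > 0,
            poke_duration_mean > poke_duration_floor,
            poke_duration_floor > 0, first_poke_floor >= 0,
            noise_factor >= 1)
  out <- as.list(environment())
  class(out) <- "behavior_params"
  out
}

#' Generate a trial schedule for a protocol
#'
#' Draws per-trial CS durations uniformly on `[T_min, T_max]` (the
#' mean-centred rule `[2, 2T - 2]` by default) and inter-trial intervals
#' uniformly with minimum `iti_min` and mean `C - T` (so the maximum is
#' `2(C - T) - iti_min`, mirroring the mean-centred bracketed ITI ranges of
#' the 14-group design). Reinforcement coincides with CS termination.
#' Times are seconds from the start of each session.
#'
#' @param protocol A `"protocol_spec"`.
#' @param seed Optional integer seed for a reproducible schedule.
#' @return Data frame with `trial`, `session`, `cs_onset`, `cs_duration`,
#'   `reinforced` (all 1).
#' @export
generate_protocol <- function(protocol, seed = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"))
  iti_mean <- protocol$C - protocol$T_mean
  iti_max <- 2 * iti_mean - protocol$iti_min
  if (iti_max < protocol$iti_min) {
    stop("infeasible protocol: C - T below the minimum ITI")
  }
  if (!is.null(seed)) set.seed(seed)
  n_per <- protocol$trials_per_session
  n_tot <- n_per * protocol$n_sessions
  dur <- stats::runif(n_tot, protocol$T_min, protocol$T_max)
  iti <- stats::runif(n_tot, protocol$iti_min, iti_max)
  session <- rep(seq_len(protocol$n_sessions), each = n_per)
  onset <- numeric(n_tot)
  t <- 0
  for (i in seq_len(n_tot)) {
    if (i > 1 && session[i] != session[i - 1]) t <- 0
    onset[i] <- t + iti[i]
    t <- onset[i] + dur[i]
  }
  data.frame(trial = seq_len(n_tot), session = session,
             cs_onset = round(onset, 3), cs_duration = round(dur, 3),
             reinforced = 1L)
}

## Alternating renewal pokes inside one observation window [0, len):
## head-out gaps ~ Exp(rate), head-in durations = floor + Exp(mean - floor),
## optional extra floor on the first gap (first-poke latency). Entry times
## strictly inside the window; exits clipped at the window end.
sim_window <- function(len, rate, behavior, first_floor = 0) {
  if (rate <= 0 || len <= 0) {
    return(data.frame(entry = numeric(0), exit = numeric(0)))
  }
  dmean <- behavior$poke_duration_mean - behavior$poke_duration_floor
  entries <- numeric(0); exits <- numeric(0)
  t <- first_floor
  m <- max(8L, ceiling(len * rate) + 8L)
  repeat {
    gaps <- stats::rexp(m, rate)
    durs <- behavior$poke_duration_floor + stats::rexp(m, 1 / dmean)
    for (j in seq_len(m)) {
      e <- t + gaps[j]
      if (e >= len) return(data.frame(entry = entries, exit = exits))
      entries <- c(entries, e)
      exits <- c(exits, min(e + durs[j], len))
      t <- e + durs[j]
      if (t >= len) return(data.frame(entry = entries, exit = exits))
    }
  }
}

#' Simulate one subject's poke stream with known ground truth
#'
#' Before the acquisition trial, pokes during the CS and the pre-CS window
#' arise from a common baseline renewal process at the subject's terminal
#' ITI rate (exponential head-out gaps; poke durations with the stated
#' mean). The acquisition trial - the number of reinforcements before
#' conditioned responding appears - is drawn from the generative model
#' (geometric over trials with `p = 1 - exp(-k (iota - 1))`), so responding
#' changes from the following trial: the CS head-out rate steps up by
#' `step_fraction` of the distance to its peak `beta/T` and then ramps
#' linearly to the peak over `ramp_fraction` of the record. First CS pokes
#' are delayed by a floor plus an exponential wait. Terminal rates carry
#' log-normal between-subject noise with spread `noise_factor`.
#'
#' @param schedule Trial schedule from [generate_protocol()].
#' @param protocol The `"protocol_spec"` that produced it.
#' @param behavior A `"behavior_params"`.
#' @param seed Optional integer seed.
#' @param subject_id Subject label.
#' @return List with `stream` (a `"poke_stream"`), `trials` (per-trial
#'   summaries) and `truth` (list: `acquisition_trial`, `cs_rate_by_trial`,
#'   `iti_rate_by_trial`, `peak_cs_rate`, `iti_rate`).
#' @export
generate_rat <- function(schedule, protocol, behavior = behavior_params(),
                         seed = NULL, subject_id = "s1") {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(behavior, "behavior_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(schedule)
  iota <- protocol$C / protocol$T_mean
  sd10 <- log10(behavior$noise_factor)
  cs_mult <- 10^stats::rnorm(1, 0, sd10)
  iti_mult <- 10^stats::rnorm(1, 0, sd10)
  peak <- behavior$beta * cs_mult / protocol$T_mean
  lam_iti <- behavior$beta * iti_mult / (behavior$iti_factor * protocol$C)

  acq <- if (!is.null(behavior$acquisition_trial)) {
    behavior$acquisition_trial
  } else {
    p <- 1 - exp(-behavior$k * (iota - 1))
    if (p <= 0) Inf else 1 + stats::rgeom(1, p)
  }

  ramp_trials <- max(1L, ceiling(behavior$ramp_fraction * n))
  r1 <- lam_iti + behavior$step_fraction * (peak - lam_iti)
  cs_rate <- rep(lam_iti, n)
  post <- which(seq_len(n) > acq)
  if (length(post)) {
    frac <- pmin(1, (seq_along(post) - 1) / ramp_trials)
    cs_rate[post] <- r1 + frac * (peak - r1)
  }

  pre_w <- protocol$pre_cs_window
  ent <- vector("list", 2L * n); ext <- vector("list", 2L * n)
  sess <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    on <- schedule$cs_onset[i]
    pre <- sim_window(min(pre_w, on), lam_iti, behavior)
    cs <- sim_window(schedule$cs_duration[i], cs_rate[i], behavior,
                     first_floor = behavior$first_poke_floor)
    w0 <- on - min(pre_w, on)
    ent[[2 * i - 1]] <- w0 + pre$entry
    ext[[2 * i - 1]] <- w0 + pmin(pre$exit, on - w0)
    ent[[2 * i]] <- on + cs$entry
    ext[[2 * i]] <- on + cs$exit
    sess[[2 * i - 1]] <- rep(schedule$session[i], nrow(pre))
    sess[[2 * i]] <- rep(schedule$session[i], nrow(cs))
  }
  stream <- poke_stream(subject_id, unlist(sess), unlist(ent), unlist(ext))
  trials <- summarize_trials(stream, schedule, pre_cs_window = pre_w)
  list(stream = stream, trials = trials,
       truth = list(acquisition_trial = acq,
                    cs_rate_by_trial = cs_rate,
                    iti_rate_by_trial = rep(lam_iti, n),
                    peak_cs_rate = peak, iti_rate = lam_iti))
}

#' Simulate a multi-group cohort
#'
#' Generates independent subjects for each protocol row, with per-subject
#' seeds derived from one master seed so the whole cohort is reproducible
#' bit-for-bit.
#'
#' @param protocols Data frame in the format of [default_protocols()].
#' @param n_per_group Subjects per group.
#' @param behavior A `"behavior_params"`.
#' @param seed Master seed (integer).
#' @param n_sessions Optional override of the session count for every
#'   group (smaller cohorts for quick studies).
#' @return A list of subjects; each element has `subject_id`, `group`,
#'   `iota`, `protocol`, `schedule`, `stream`, `trials`, `truth`.
#' @export
generate_cohort <- function(protocols = default_protocols(), n_per_group = 12,
                            behavior = behavior_params(), seed = 1,
                            n_sessions = NULL) {
  set.seed(seed)
  total <- nrow(protocols) * n_per_group
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * total)
  cohort <- vector("list", total)
  idx <- 0L
  for (g in seq_len(nrow(protocols))) {
    r <- protocols[g, ]
    spec <- protocol_spec(group_id = as.character(r$group), T_mean = r$T_mean,
                          C = r$C,
                          trials_per_session = r$trials_per_session,
                          n_sessions = if (is.null(n_sessions))
                            r$n_sessions else n_sessions)
    for (s in seq_len(n_per_group)) {
      idx <- idx + 1L
      sched <- generate_protocol(spec, seed = seeds[2L * idx - 1L])
      sid <- sprintf("g%s_r%02d", r$group, s)
      rat <- generate_rat(sched, spec, behavior, seed = seeds[2L * idx],
                          subject_id = sid)
      cohort[[idx]] <- c(list(subject_id = sid, group = r$group,
                              iota = r$C / r$T_mean, protocol = spec,
                              schedule = sched), rat)
    }
  }
  cohort
}
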