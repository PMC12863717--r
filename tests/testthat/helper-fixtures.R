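# Shared fixture builders; everything is generated in code.

# A stream from explicit poke times in one session.
fix_stream <- function(entry, exit, session = 1, id = "r1") {
  poke_stream(id, rep(session, length(entry)), entry, exit)
}

# A single-trial schedule.
fix_schedule <- function(cs_onset, cs_duration, session = 1,
                         trial = seq_along(cs_onset)) {
  data.frame(trial = trial, session = session, cs_onset = cs_onset,
             cs_duration = cs_duration, reinforced = 1L)
}

# Hand-built per-trial summaries (the acquisition module's input contract).
fix_trials <- function(n_cs, cs_dur, n_pre, pre_exp, session = 1) {
  n <- length(n_cs)
  data.frame(trial = seq_len(n), session = session,
             cs_onset = cumsum(rep(100, n)), cs_duration = cs_dur,
             n_cs_pokes = n_cs, cs_first_poke_latency = ifelse(n_cs > 0, 1, NA),
             cs_in_magazine_time = 0, n_pre_pokes = n_pre,
             pre_exposure = pre_exp, pre_in_magazine_time = 0)
}

# Exhaustive single-split oracle: the best split of an interval vector by
# the count-weighted two-segment divergence, recomputed from first
# principles (independent of split_profile()).
oracle_best_split <- function(x) {
  n <- length(x)
  g <- sapply(1:(n - 1), function(s) {
    l1 <- s / sum(x[1:s]); l2 <- (n - s) / sum(x[(s + 1):n])
    lf <- n / sum(x)
    s * (log(l1 / lf) + lf / l1 - 1) + (n - s) * (log(l2 / lf) + lf / l2 - 1)
  })
  list(s = which.max(g), g = max(g))
}
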