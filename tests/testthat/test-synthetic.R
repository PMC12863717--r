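test_that("protocol schedules respect the uniform duration and ITI rules", {
  spec <- default_protocol_spec(1)  # T = 42, C = 63
  sched <- generate_protocol(spec, seed = 51)
  expect_equal(nrow(sched), 420)
  expect_true(all(sched$cs_duration >= 2 & sched$cs_duration <= 82))
  expect_equal(mean(sched$cs_duration), 42, tolerance = 0.05)
  # ITIs: gap from previous CS offset (or session start) to next onset
  itis <- unlist(lapply(split(sched, sched$session), function(d) {
    offs <- c(0, head(d$cs_onset + d$cs_duration, -1))
    d$cs_onset - offs
  }))
  expect_true(all(itis >= 15 - 1e-3))
  expect_true(all(itis <= 2 * 21 - 15 + 1e-3))
  expect_equal(mean(itis), 21, tolerance = 0.05)
})

test_that("a boundary protocol gives constant 2-s CSs and infeasibility errors", {
  spec <- protocol_spec("b", T_mean = 2, C = 30, trials_per_session = 3,
                        n_sessions = 2)
  sched <- generate_protocol(spec, seed = 52)
  expect_true(all(sched$cs_duration == 2))
  bad <- protocol_spec("x", T_mean = 50, C = 60, trials_per_session = 3,
                       n_sessions = 2)
  expect_error(generate_protocol(bad), "infeasible")
})

test_that("generation is reproducible bit-for-bit under a fixed seed", {
  spec <- default_protocol_spec(7, n_sessions = 3)
  s1 <- generate_protocol(spec, seed = 53)
  s2 <- generate_protocol(spec, seed = 53)
  expect_identical(s1, s2)
  r1 <- generate_rat(s1, spec, seed = 54)
  r2 <- generate_rat(s2, spec, seed = 54)
  expect_identical(r1$stream, r2$stream)
  expect_identical(r1$truth, r2$truth)
  c1 <- generate_cohort(default_protocols()[c(3, 9), ], n_per_group = 2,
                        seed = 55, n_sessions = 2)
  c2 <- generate_cohort(default_protocols()[c(3, 9), ], n_per_group = 2,
                        seed = 55, n_sessions = 2)
  expect_identical(lapply(c1, `[[`, "stream"), lapply(c2, `[[`, "stream"))
})

test_that("at maximal informativeness most subjects acquire on trial 1", {
  spec <- default_protocol_spec(14, n_sessions = 1)  # iota = 300
  sched <- generate_protocol(spec, seed = 56)
  acq <- sapply(1:200, function(i)
    generate_rat(sched, spec, seed = 500 + i)$truth$acquisition_trial)
  # per-trial probability 1 - exp(-299/297) = 0.635
  expect_gt(mean(acq == 1), 0.55)
  expect_lt(mean(acq == 1), 0.72)
})

test_that("a never-acquiring subject stays at baseline with no criterion", {
  spec <- default_protocol_spec(5, n_sessions = 8)
  sched <- generate_protocol(spec, seed = 57)
  rat <- generate_rat(sched, spec, behavior_params(acquisition_trial = Inf),
                      seed = 58)
  expect_true(all(rat$truth$cs_rate_by_trial == rat$truth$iti_rate))
  pr <- acquisition_profile(rat$trials)
  expect_true(is.na(pr$t_by_threshold[["p05"]]))
})

test_that("terminal estimators recover the generating rates", {
  spec <- default_protocol_spec(4, n_sessions = 8)  # T = 12
  sched <- generate_protocol(spec, seed = 59)
  rat <- generate_rat(sched, spec, behavior_params(acquisition_trial = 1),
                      seed = 60)
  out <- terminal_rates(rat$trials, spec, final_sessions = 5)
  expect_equal(out$cs_rate, rat$truth$peak_cs_rate, tolerance = 0.15)
  expect_equal(out$iti_rate, rat$truth$iti_rate, tolerance = 0.45)
})

test_that("generated head-out gaps follow the stated exponential", {
  spec <- protocol_spec("w", T_mean = 60, C = 600, trials_per_session = 10,
                        n_sessions = 4)
  sched <- generate_protocol(spec, seed = 63)
  rat <- generate_rat(sched, spec,
                      behavior_params(acquisition_trial = 0,
                                      step_fraction = 1),
                      seed = 64)
  iv <- build_cs_intervals(rat$stream, sched)
  expect_gt(length(iv$intervals), 100)
  lam <- unique(rat$truth$cs_rate_by_trial)
  expect_length(lam, 1)
  ks <- suppressWarnings(ks.test(iv$intervals, "pexp", lam))
  expect_gt(ks$p.value, 0.01)
})

test_that("median trials-to-acquisition decreases with informativeness", {
  groups <- default_protocols()[c(4, 7, 11, 14), ]
  coh <- generate_cohort(groups, n_per_group = 8, seed = 65, n_sessions = 6)
  truth_acq <- vapply(coh, function(s) s$truth$acquisition_trial, numeric(1))
  iota <- vapply(coh, function(s) s$iota, numeric(1))
  med <- tapply(truth_acq, iota, median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) <= 0))
})
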