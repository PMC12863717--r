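test_that("corrected rate arithmetic handles exclusions and conventions", {
  # 10 pokes over 3 CSs: first pokes excluded -> 7 countable; 60 s of CS
  # minus 6 s of latencies minus 3.5 s head-in = 50.5 s of opportunity
  expect_equal(corrected_rate(10, 60, n_excluded = 3, excluded_time = 6,
                              in_magazine_time = 3.5), 7 / 50.5)
  expect_equal(round(corrected_rate(10, 60, 3, 6, 3.5), 4), 0.1386)
  # zero pokes with the half-count convention
  expect_equal(corrected_rate(0, 2100, zero_count = "half"), 0.5 / 2100)
  expect_equal(corrected_rate(0, 2100, zero_count = "half"), 2.38e-4,
               tolerance = 0.01)
  # no exclusions reduces to the conventional estimator
  expect_equal(corrected_rate(12, 60), 0.2)
  expect_error(corrected_rate(5, 10, excluded_time = 11), "exposure")
  expect_error(corrected_rate(2, 10, n_excluded = 3), "excluded")
})

test_that("correction only raises the rate when time is removed", {
  set.seed(6)
  for (i in 1:10) {
    n <- rpois(1, 20) + 2; expo <- runif(1, 50, 100)
    inmag <- runif(1, 0, 10)
    expect_gte(corrected_rate(n, expo, in_magazine_time = inmag),
               corrected_rate(n, expo))
  }
})

test_that("slope-1 regression recovers an exact scalar law", {
  x <- log10(c(1 / 62, 1 / 30, 1 / 12, 1 / 6))
  y <- log10(21.8) + x
  f <- fit_scalar_regression(x, y, "slope1")
  expect_equal(f$slope, 1)
  expect_equal(f$intercept_log10, log10(21.8), tolerance = 1e-12)
  expect_equal(round(f$intercept_log10, 3), 1.338)
  expect_equal(f$scalar, 21.8, tolerance = 1e-9)
  expect_equal(f$r_squared, 1)
  f2 <- fit_scalar_regression(x, x, "slope1")
  expect_equal(f2$intercept_log10, 0)
  ff <- fit_scalar_regression(x, y, "free")
  expect_equal(ff$slope, 1, tolerance = 1e-9)
  expect_error(fit_scalar_regression(rep(1, 3), 1:3, "free"), "degenerate")
})

test_that("the slope-1 intercept is the least-squares optimum", {
  set.seed(8)
  x <- runif(30, -3, -1); y <- 1.3 + x + rnorm(30, 0, 0.3)
  f <- fit_scalar_regression(x, y, "slope1")
  grid <- seq(f$intercept_log10 - 0.5, f$intercept_log10 + 0.5, by = 0.01)
  rss_g <- sapply(grid, function(a) sum((y - x - a)^2))
  expect_lte(f$rss, min(rss_g) + 1e-12)
})

test_that("the shifted shared model recovers scaling and shift exactly", {
  cs_x <- log10(1 / c(42, 21, 12, 6)); cs_y <- log10(22) + cs_x
  iti_x <- log10(1 / c(63, 94.5, 600, 4200))
  iti_y <- log10(22) + iti_x - log10(1.9)
  f <- fit_shifted_shared(cs_x, cs_y, iti_x, iti_y)
  expect_equal(f$scalar, 22, tolerance = 1e-9)
  expect_equal(f$shift_log10, log10(1.9), tolerance = 1e-12)
  expect_equal(round(f$shift_log10, 2), 0.28)
  expect_equal(f$shift_factor, 1.9, tolerance = 1e-9)
  expect_equal(f$rss, 0, tolerance = 1e-18)
  # identical CS and ITI laws give zero shift
  f0 <- fit_shifted_shared(cs_x, cs_y, iti_x, log10(22) + iti_x)
  expect_equal(f0$shift_log10, 0, tolerance = 1e-12)
})

test_that("shift recovery holds across seeds under multiplicative noise", {
  shifts <- sapply(1:10, function(s) {
    set.seed(100 + s)
    cs_x <- rep(log10(1 / c(42, 21, 12, 6)), each = 12)
    iti_x <- rep(log10(1 / c(63, 94.5, 600, 4200)), each = 12)
    cs_y <- log10(22) + cs_x + rnorm(length(cs_x), 0, log10(2.5))
    iti_y <- log10(22 / 1.9) + iti_x + rnorm(length(iti_x), 0, log10(2.5))
    fit_shifted_shared(cs_x, cs_y, iti_x, iti_y)$shift_log10
  })
  expect_true(all(abs(shifts - log10(1.9)) < 0.25))
  expect_lt(abs(mean(shifts) - log10(1.9)), 0.08)
})

test_that("terminal rates pool the final sessions with the right corrections", {
  # two sessions of one trial each; only the last session should count
  sched <- rbind(fix_schedule(cs_onset = 20, cs_duration = 10, session = 1),
                 fix_schedule(cs_onset = 20, cs_duration = 10, session = 2,
                              trial = 2))
  s <- poke_stream("r1", c(1, 2, 2, 2), c(12, 22, 24, 26),
                   c(12.5, 22.5, 24.5, 26.5))
  tr <- summarize_trials(s, sched)
  spec <- protocol_spec("g", T_mean = 10, C = 60, trials_per_session = 1,
                        n_sessions = 2)
  out <- terminal_rates(tr, spec, final_sessions = 1)
  # session 2: 3 CS pokes, first excluded; latency 2 s; head-in 1.5 s
  expect_equal(out$cs_rate, 2 / (10 - 2 - 1.5))
  expect_equal(out$iti_rate, 0.5 / 10)  # no pre pokes: half-count
  expect_equal(out$cs_reinf_rate, 0.1)
  expect_equal(out$ctx_reinf_rate, 1 / 60)
})

test_that("group correlates match closed-form partial correlations", {
  d <- default_protocols()
  set.seed(12)
  stats_df <- data.frame(C = d$C, T_mean = d$T_mean,
                         median_trials = 300 / (d$iota - 1) *
                           10^rnorm(14, 0, 0.15))
  gc <- group_correlates(stats_df)
  y <- log10(stats_df$median_trials)
  a <- log10(d$iota); b <- log10(d$C)
  r_ya <- cor(y, a); r_yb <- cor(y, b); r_ab <- cor(a, b)
  oracle <- (r_ya - r_yb * r_ab) / sqrt((1 - r_yb^2) * (1 - r_ab^2))
  expect_equal(unname(gc$partials["log_CT_given_C"]), oracle,
               tolerance = 1e-10)
  # perfectly collinear medians give |r| = 1
  stats2 <- data.frame(C = d$C, T_mean = d$T_mean, median_trials = d$iota)
  gc2 <- group_correlates(stats2)
  expect_equal(unname(gc2$correlations["log_CT"]), 1, tolerance = 1e-12)
  # a constant column is flagged, not fatal
  stats3 <- data.frame(C = d$C, T_mean = d$T_mean, median_trials = 5)
  expect_warning(gc3 <- group_correlates(stats3), "constant")
  expect_true(is.na(gc3$correlations["log_CT"]))
  expect_error(group_correlates(stats_df[1:2, ]), "3 groups")
})
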