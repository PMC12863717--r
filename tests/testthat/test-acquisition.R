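test_that("cumulative series reproduces the 50:1 rate-ratio example", {
  # 5 CS pokes over 20 s of CS; 1000 s observed in total, no other pokes
  tr <- fix_trials(n_cs = c(3, 2), cs_dur = c(10, 10),
                   n_pre = c(0, 0), pre_exp = c(490, 490))
  ser <- cumulative_rate_series(tr)
  expect_equal(ser$cum_cs_rate[2], 0.25)
  expect_equal(ser$cum_ctx_rate[2], 0.005)
  expect_equal(ser$cum_cs_rate[2] / ser$cum_ctx_rate[2], 50)
  # context counts include the CS pokes, so both counts are 5
  expect_equal(ser$cum_ctx_count[2], 5)
  expect_equal(ser$ndkl_signed[2], 2.5 * dkl_exp(0.25, 0.005),
               tolerance = 1e-10)
})

test_that("cumulative series matches a brute-force prefix oracle", {
  set.seed(11)
  tr <- fix_trials(n_cs = c(rpois(19, 1), rpois(21, 6)),
                   cs_dur = runif(40, 5, 30),
                   n_pre = rpois(40, 1), pre_exp = rep(10, 40))
  ser <- cumulative_rate_series(tr)
  for (t in c(1, 7, 23, 40)) {
    cs_n <- sum(tr$n_cs_pokes[1:t]); cs_T <- sum(tr$cs_duration[1:t])
    cx_n <- cs_n + sum(tr$n_pre_pokes[1:t])
    cx_T <- cs_T + sum(tr$pre_exposure[1:t])
    expect_equal(ser$cum_cs_rate[t], cs_n / cs_T)
    expect_equal(ser$cum_ctx_rate[t], cx_n / cx_T)
    r <- ndkl(cs_n, cs_n / cs_T, cx_n, cx_n / cx_T, signed = TRUE)
    expect_equal(ser$ndkl_signed[t], r$ndkl, tolerance = 1e-12)
  }
})

test_that("near-equal CS and pre rates give a small nDKL and no exceedance", {
  tr <- fix_trials(n_cs = rep(2, 30), cs_dur = rep(10, 30),
                   n_pre = rep(2, 30), pre_exp = rep(10, 30))
  ser <- cumulative_rate_series(tr)
  expect_true(all(abs(ser$ndkl_signed) < 0.05))
  expect_true(is.na(trials_to_criterion(tr, 1, odds_to_threshold(4))))
})

test_that("permanent exceedance scans to the last non-positive value", {
  expect_equal(permanent_exceedance(c(0.1, 0.2, 0.3)), 1L)
  expect_equal(permanent_exceedance(c(-1, 0.5, -0.2, 0.3, 0.4)), 4L)
  expect_true(is.na(permanent_exceedance(c(-1, 1, -0.5))))
  expect_true(is.na(permanent_exceedance(c(-1, -2))))
  # exact ties are not-greater
  expect_equal(permanent_exceedance(c(0.5, 0, 0.3, 0.4)), 3L)
  # NA entries are skipped, neither establishing nor breaking permanence
  expect_equal(permanent_exceedance(c(NA, -1, NA, 2, NA, 3)), 4L)
  expect_true(is.na(permanent_exceedance(c(NA, NA))))
  expect_error(permanent_exceedance(numeric(0)), "empty")
  # agreement with a backward-scan oracle on random series
  set.seed(4)
  for (i in 1:20) {
    x <- round(rnorm(15), 2)
    ok <- which(sapply(seq_along(x), function(t) all(x[t:15] > 0)))
    expect_equal(permanent_exceedance(x),
                 if (length(ok)) min(ok) else NA_integer_)
  }
})

test_that("a strong step is detected near its true position", {
  tr <- fix_trials(n_cs = c(rep(1, 19), rep(25, 21)), cs_dur = rep(10, 40),
                   n_pre = rep(1, 40), pre_exp = rep(10, 40))
  ser <- cumulative_rate_series(tr)
  idx <- permanent_exceedance(ser$ndkl_signed)
  expect_true(idx >= 20 && idx <= 23)
  t4 <- trials_to_criterion(tr, idx, odds_to_threshold(4))
  expect_true(t4 >= idx)
})

test_that("the restart rule never lags the from-trial-1 criterion", {
  # early CS deficit dilutes evidence when accumulated from trial 1
  set.seed(9)
  tr <- fix_trials(n_cs = c(rep(0, 14), rep(1, 11), rep(8, 25)),
                   cs_dur = rep(10, 50),
                   n_pre = rep(1, 50), pre_exp = rep(10, 50))
  pr <- acquisition_profile(tr)
  for (nm in names(pr$t_by_threshold)) {
    th <- c(odds4 = odds_to_threshold(4), p05 = odds_to_threshold(19),
            p01 = odds_to_threshold(99), p001 = odds_to_threshold(999))[[nm]]
    from1 <- permanent_exceedance(pr$series$ndkl_signed - th)
    restarted <- pr$t_by_threshold[[nm]]
    if (!is.na(from1) && !is.na(restarted)) expect_lte(restarted, from1)
  }
  # criterion trials come at or after the exceedance trial
  ok <- !is.na(pr$t_by_threshold)
  expect_true(all(pr$t_by_threshold[ok] >= pr$t_exceed))
})

test_that("an infinite threshold is never met", {
  tr <- fix_trials(n_cs = rep(5, 20), cs_dur = rep(10, 20),
                   n_pre = rep(0, 20), pre_exp = rep(10, 20))
  expect_true(is.na(trials_to_criterion(tr, 1, Inf)))
  expect_true(is.na(trials_to_criterion(tr, NA, 1)))
})

test_that("the fixed-point formulation agrees on a clean step", {
  tr <- fix_trials(n_cs = c(rep(1, 10), rep(30, 30)), cs_dur = rep(10, 40),
                   n_pre = rep(1, 40), pre_exp = rep(10, 40))
  a <- acquisition_profile(tr, mode = "cumulative")
  b <- acquisition_profile(tr, mode = "fixed_point")
  expect_false(is.na(a$t_exceed))
  expect_false(is.na(b$t_exceed))
  expect_lte(abs(a$t_exceed - b$t_exceed), 2)
  expect_equal(a$reinforcements_to_acquisition, a$t_exceed - 1L)
})
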