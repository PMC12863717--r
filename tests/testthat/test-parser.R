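test_that("a homogeneous vector parses to one segment at the pooled rate", {
  v <- rep(2, 40)
  p <- parse_intervals(v, c = 6)
  expect_equal(nrow(p$segments), 1)
  expect_equal(p$segments$rate, 0.5)
  set.seed(2)
  v2 <- rexp(60, 0.3)
  p2 <- parse_intervals(v2, c = 6)
  expect_equal(p2$segments$rate[1],
               p2$segments$n[1] / sum(v2[1:p2$segments$end[1]]),
               tolerance = 1e-12)
})

test_that("each segment rate is count over summed intervals", {
  set.seed(21)
  v <- c(rexp(25, 0.1), rexp(25, 2))
  p <- parse_intervals(v, c = 4)
  for (i in seq_len(nrow(p$segments))) {
    idx <- p$segments$start[i]:p$segments$end[i]
    expect_equal(p$segments$rate[i], length(idx) / sum(v[idx]),
                 tolerance = 1e-12)
  }
  # segments partition the vector
  expect_equal(p$segments$start[1], 1L)
  expect_equal(p$segments$end[nrow(p$segments)], length(v))
  if (nrow(p$segments) > 1) {
    expect_equal(p$segments$start[-1], head(p$segments$end, -1) + 1L)
  }
})

test_that("the greedy first split equals the exhaustive single-split oracle", {
  set.seed(14)
  for (i in 1:10) {
    v <- c(rexp(30, 0.1), rexp(30, 1))
    p <- parse_intervals(v, c = 6)
    orc <- oracle_best_split(v)
    if (orc$g > 6) {
      expect_gte(nrow(p$segments), 2)
      expect_equal(p$segments$end[1], orc$s)
    } else {
      expect_equal(nrow(p$segments), 1)
    }
  }
})

test_that("a plausible long first interval does not trigger a split", {
  # 3 s is an unremarkable draw from Exp(1); the first-segment rate then
  # extends back to the start of observation
  v <- c(3, rep(1, 30))
  p <- parse_intervals(v, c = 6)
  expect_equal(nrow(p$segments), 1)
  iv <- structure(list(intervals = v, trial = c(2L, rep(3:17, each = 2), 18L),
                       context = "CS"), class = "interval_vector")
  seg <- parse_intervals(iv, c = 6)
  rates <- parsed_trial_rates(seg, 20)
  expect_equal(rates[1], rates[5])  # extends to trial 1
  expect_true(all(is.finite(rates)))
})

test_that("parsing is deterministic and coarsens monotonically in c", {
  set.seed(31)
  for (i in 1:8) {
    v <- c(rexp(20, 0.2), rexp(20, 1.5), rexp(20, 0.2))
    p1 <- parse_intervals(v, c = 2)
    p2 <- parse_intervals(v, c = 4)
    p3 <- parse_intervals(v, c = 6)
    expect_identical(parse_intervals(v, c = 2)$segments, p1$segments)
    expect_gte(nrow(p1$segments), nrow(p2$segments))
    expect_gte(nrow(p2$segments), nrow(p3$segments))
  }
})

test_that("spurious splits on single-rate data are rare at c = 6", {
  set.seed(41)
  n_vec <- 300; n_int <- 50
  n_split <- 0
  for (i in seq_len(n_vec)) {
    p <- parse_intervals(rexp(n_int, 1), c = 6)
    n_split <- n_split + (nrow(p$segments) - 1)
  }
  # one test per candidate split point; a 6-nat excess occurs about once
  # in 1800 tests under the null
  per_test <- n_split / (n_vec * (n_int - 1))
  expect_lt(per_test, 3 / 1800)
})

test_that("CS interval construction excludes first pokes and empty CSs", {
  # CS at 10 s, pokes at latencies 2, 3 and 3.2 s
  s <- fix_stream(entry = c(12, 13, 13.2), exit = c(12.4, 13.15, 13.6))
  sched <- fix_schedule(cs_onset = 10, cs_duration = 20)
  iv <- build_cs_intervals(s, sched)
  expect_equal(length(iv$intervals), 2)  # two countable pokes after the first
  # head-out gaps only: previous exit to next entry
  expect_equal(iv$intervals, c(13 - 12.4, 13.2 - 13.15), tolerance = 1e-9)
  # single-poke and empty CSs contribute nothing
  sched2 <- fix_schedule(cs_onset = c(10, 50, 90), cs_duration = rep(20, 3))
  s2 <- fix_stream(entry = 52, exit = 52.5)
  iv2 <- build_cs_intervals(s2, sched2)
  expect_equal(length(iv2$intervals), 0)
  p <- parse_intervals(iv2, c = 6)
  expect_equal(nrow(p$segments), 0)
})

test_that("pre-CS intervals use raw counts over a concatenated timeline", {
  # two 10-s pre windows; pokes 4 s into each window
  s <- fix_stream(entry = c(14, 54), exit = c(14.5, 54.5))
  sched <- fix_schedule(cs_onset = c(20, 60), cs_duration = c(10, 10))
  tr <- summarize_trials(s, sched)
  iv <- build_pre_intervals(s, tr)
  expect_equal(length(iv$intervals), 2)
  expect_equal(iv$intervals, c(4, 10))  # 6 s left in window 1 + 4 s into 2
  expect_equal(iv$trial, c(1L, 2L))
})

test_that("parse-based acquisition finds the 95 percent dominance boundary", {
  n <- 25
  cs <- c(rep(0.1, 12), rep(1, n - 12))
  iti <- rep(0.2, n)
  expect_equal(parse_based_acquisition(cs, iti), 12L)
  expect_equal(parse_based_acquisition(rep(2, n), rep(1, n)), 0L)
  alt <- rep(c(2, 0.5), length.out = 40)
  expect_true(is.na(parse_based_acquisition(alt, rep(1, 40))))
})
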