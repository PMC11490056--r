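test_that("interdaily stability hits its closed-form anchors", {
  profile <- 50 + 30 * sin(2 * pi * (0:23) / 24)
  expect_equal(interdailyStability(makeHourly(rep(profile, 7)))$value, 1)
  # each day a distinct constant level: slot means all equal the grand mean
  flat <- rep(1:7, each = 24)
  expect_equal(interdailyStability(makeHourly(flat))$value, 0)
  # insufficient coverage and zero variance produce reasons, not errors
  v <- rep(profile, 2); v[1] <- NA       # slot 0 observed once
  r <- interdailyStability(makeHourly(v))
  expect_true(is.na(r$value))
  expect_match(r$reason, "coverage")
  r2 <- interdailyStability(makeHourly(rep(5, 48)))
  expect_match(r2$reason, "constant")
})

test_that("mean IS of hourly white noise approaches 24/N", {
  set.seed(41)
  vals <- replicate(1000, interdailyStability(makeHourly(rnorm(168)))$value)
  # ratio-of-expectations value is (N/D - 1)/(N - 1) = 23/167,
  # approximated by p/N = 24/168 for large D
  expect_lt(abs(mean(vals) - 23 / 167), 0.005)
  expect_lt(abs(mean(vals) - 24 / 168), 0.01)
})

test_that("intradaily variability matches ramp and alternating closed forms", {
  # arithmetic ramp over N hours: IV = 12 / (N^2 - 1)
  N <- 49
  v <- c(seq_len(N), rep(NA, 72 - N))
  expect_equal(intradailyVariability(makeHourly(v))$value, 12 / (N^2 - 1))
  expect_equal(12 / (N^2 - 1), 0.005)
  # alternating series: maximal fragmentation, IV = 4
  expect_equal(intradailyVariability(makeHourly(rep(c(1, -1), 36)))$value, 4)
})

test_that("mean IV of hourly white noise approaches 2N/(N-1)", {
  set.seed(42)
  vals <- replicate(1000, intradailyVariability(makeHourly(rnorm(168)))$value)
  expect_lt(abs(mean(vals) - 2 * 168 / 167), 0.05)
})

test_that("IV difference pairs skip omitted hours instead of bridging them", {
  v <- rep(c(0, 10), 24)
  vGap <- v; vGap[10:12] <- NA
  r <- intradailyVariability(makeHourly(c(vGap, rep(NA, 24))))
  # all remaining adjacent pairs still differ by 10
  expect_equal(r$value, naiveIV(c(vGap, rep(NA, 24))))
})

test_that("IS and IV are invariant to affine changes of the signal", {
  set.seed(43)
  v <- rep(abs(rnorm(24, 50, 20)), 5) * rep(runif(5, .8, 1.2), each = 24)
  for (f in list(function(x) x + 100, function(x) 3 * x,
                 function(x) 2 * x - 5)) {
    expect_equal(interdailyStability(makeHourly(f(v)))$value,
                 interdailyStability(makeHourly(v))$value, tolerance = 1e-12)
    expect_equal(intradailyVariability(makeHourly(f(v)))$value,
                 intradailyVariability(makeHourly(v))$value, tolerance = 1e-12)
  }
})

test_that("IS and IV agree with naive double-loop references on random inputs", {
  set.seed(44)
  for (i in 1:50) {
    D <- sample(3:7, 1)
    v <- rnorm(D * 24, 50, 25)
    v[sample(length(v), rpois(1, 5))] <- NA
    h <- makeHourly(v)
    expect_equal(interdailyStability(h)$value, naiveIS(v), tolerance = 1e-10)
    expect_equal(intradailyVariability(h)$value, naiveIV(v), tolerance = 1e-10)
  }
})

test_that("bout extraction run-length-encodes states with boundary censoring", {
  b <- dayBinary(c(0, 0, 0, 1, 1, 0, 0, 0, 1, 1))
  bouts <- extractBouts(b)
  expect_equal(bouts$state, c(0L, 1L, 0L, 1L))
  expect_equal(bouts$length, c(3L, 2L, 3L, 2L))
  expect_equal(bouts$left_censored, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(bouts$right_censored, c(FALSE, FALSE, FALSE, TRUE))
  # fully unobserved period -> nothing
  expect_equal(nrow(extractBouts(dayBinary(rep(NA, 5), rep(FALSE, 5)))), 0)
  # single state all period: one bout censored on both sides
  one <- extractBouts(dayBinary(rep(1, 6)))
  expect_equal(nrow(one), 1)
  expect_true(one$left_censored && one$right_censored)
  # a gap censors the runs that touch it
  g <- dayBinary(c(0, 0, 1, NA, 1, 0), c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  bg <- extractBouts(g)
  expect_equal(bg$state, c(0L, 1L, 1L, 0L))
  expect_true(bg$right_censored[2])      # run before the gap
  expect_true(bg$left_censored[3])       # run after the gap
})

test_that("transition probabilities are reciprocals of mean uncensored bout durations", {
  tp <- transitionProbabilities(extractBouts(dayBinary(c(0,0,0,1,1,0,0,0,1,1))))
  expect_equal(tp$tp_ra_d$value, 1 / 3)
  expect_equal(tp$tp_ar_d$value, 1 / 2)
  expect_true(is.na(tp$tp_ws_n$value))   # no night bouts at all
  # all bouts of length one: TP = 1
  tp1 <- transitionProbabilities(extractBouts(dayBinary(rep(c(0, 1), 10))))
  expect_equal(tp1$tp_ra_d$value, 1)
  expect_equal(tp1$tp_ar_d$value, 1)
})

test_that("bout-based TPs recover Markov chain probabilities at large n", {
  set.seed(45)
  st <- actifrag:::markovStates(1e5, 0.2, 0.4)
  tp <- transitionProbabilities(extractBouts(dayBinary(st)))
  expect_equal(tp$tp_ra_d$value, 0.2, tolerance = 0.01 / 0.2)
  expect_equal(tp$tp_ar_d$value, 0.4, tolerance = 0.01 / 0.4)
})

test_that("TPs are invariant to the time origin and to pooling across days", {
  set.seed(46)
  st <- actifrag:::markovStates(2000, 0.3, 0.25)
  b1 <- dayBinary(st)
  b2 <- dayBinary(st)
  b2@timestamp <- b2@timestamp + 86400   # shifted clock
  expect_equal(transitionProbabilities(extractBouts(b1)),
               transitionProbabilities(extractBouts(b2)))
  # splitting the same epochs across two day instances pools bout sets
  b3 <- b1
  b3@dayIndex <- rep(c(1L, 2L), each = 1000)
  pooled <- extractBouts(b3)
  direct <- rbind(extractBouts(dayBinary(st[1:1000])),
                  extractBouts(dayBinary(st[1001:2000])))
  expect_equal(pooled$length, direct$length)
  expect_equal(pooled$left_censored, direct$left_censored)
})

test_that("activity balance index transforms alpha symmetrically around one", {
  expect_equal(activityBalanceIndex(1), 1)
  expect_equal(activityBalanceIndex(0.5), exp(-0.5 * exp(2)))
  expect_equal(activityBalanceIndex(0.5), 0.0249, tolerance = 1e-2)
  expect_equal(activityBalanceIndex(0.9), activityBalanceIndex(1.1))
  expect_true(activityBalanceIndex(1.2) < activityBalanceIndex(1.1))
  expect_true(is.na(activityBalanceIndex(NA)))
})

test_that("the full metric vector reports per-metric computability", {
  coh <- smallCohort(n = 1, days = 7, seed = 12)
  es <- cohortSeries(coh)[[1]]; part <- cohortPartitions(coh)[[1]]
  mv <- computeMetricVector(es, part, "omit")
  expect_named(mv$values, c("IS", "IV", "TP_ra_d", "TP_ar_d",
                            "TP_ws_n", "TP_sw_n", "alpha", "ABI"))
  expect_false(anyNA(mv$values))
  expect_true(all(is.na(mv$reasons)))
  expect_true(mv$values["IS"] >= 0 && mv$values["IS"] <= 1)
  expect_true(all(mv$values[3:6] > 0 & mv$values[3:6] <= 1))

  # two retained days with an hour slot observed once: IS missing, rest present
  m2 <- applyScenarioBatch(coh, 3, 2, seed = 5)
  es2 <- cohortSeries(m2)[[1]]
  part2 <- cohortPartitions(m2)[[1]]
  hr3 <- timestamps(es2) - wakeOnsets(part2)[1]   # mask hour 3 of day 1
  es2@wear[hr3 >= 3 * 3600 & hr3 < 4 * 3600] <- FALSE
  mv2 <- computeMetricVector(es2, part2, "omit")
  expect_true(is.na(mv2$values["IS"]))
  expect_match(mv2$reasons["IS"], "coverage")
  expect_false(anyNA(mv2$values[c("IV", "TP_ra_d", "alpha")]))

  # an all-rest day leaves the active TP missing but computes the rest TP
  nEp <- 1440
  es3 <- EpochSeries("R", seq(0, by = 60, length.out = nEp), rep(5, nEp),
                     state = rep(c("wake", "sleep"), times = c(960, 480)))
  part3 <- DayPartition(c(0, 1440 * 60), 960 * 60)
  es3 <- partitionPeriods(es3, part3)
  mv3 <- computeMetricVector(es3, part3, "omit")
  expect_true(is.na(mv3$values["TP_ar_d"]))
  expect_match(mv3$reasons["TP_ar_d"], "state 1")
})
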