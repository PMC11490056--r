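test_that("epoch CSV round trip preserves epoch data exactly", {
  coh <- smallCohort(n = 2, days = 3, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  writeEpochCSV(coh, path)
  back <- readEpochCSV(path)
  expect_setequal(names(cohortSeries(back)), names(cohortSeries(coh)))
  for (sid in names(cohortSeries(coh))) {
    a <- cohortSeries(coh)[[sid]]; b <- cohortSeries(back)[[sid]]
    expect_identical(timestamps(b), timestamps(a))
    expect_identical(wearFlag(b), wearFlag(a))
    expect_identical(epochState(b), epochState(a))
    expect_equal(accel(b), accel(a), tolerance = 1e-12)
    expect_equal(nDays(cohortPartitions(back)[[sid]]),
                 nDays(cohortPartitions(coh)[[sid]]))
  }
})

test_that("malformed epoch files are rejected with structural errors", {
  coh <- smallCohort(n = 1, days = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  writeEpochCSV(coh, path)
  df <- read.csv(path)

  gap <- df[-100, ]                      # a missing minute row
  p1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(gap, p1, row.names = FALSE)
  expect_error(readEpochCSV(p1), "grid")

  flat <- df; flat$state <- "wake"       # labels never change
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(flat, p2, row.names = FALSE)
  expect_warning(out <- readEpochCSV(p2), "skipped")
  expect_length(cohortSeries(out), 0)

  nohdr <- df; names(nohdr)[2] <- "time" # bad header
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(nohdr, p3, row.names = FALSE)
  expect_error(readEpochCSV(p3), "header")
})

test_that("partition tags follow half-open day/night conventions", {
  # 2 synthetic days: wake at 0 and 1440', sleep onsets at 960' and 2400'
  nEp <- 2880
  es <- EpochSeries("T", seq(0, by = 60, length.out = nEp), rep(10, nEp),
                    state = rep(rep(c("wake", "sleep"), times = c(960, 480)), 2))
  part <- DayPartition(c(0, 1440, 2880) * 60, c(960, 2400) * 60)
  tagged <- partitionPeriods(es, part)
  expect_identical(periodLabel(tagged)[1], "day")         # epoch at wake onset
  expect_identical(periodLabel(tagged)[961], "night")     # epoch at sleep onset
  expect_identical(periodLabel(tagged)[1440], "night")    # last epoch of day 1
  expect_identical(dayIndex(tagged)[1440], 1L)
  expect_identical(dayIndex(tagged)[1441], 2L)
  # cover: day + night epochs of day d partition the entire day
  for (d in 1:2) {
    inD <- dayIndex(tagged) == d
    expect_identical(sum(inD), 1440L)
    expect_identical(sum(inD & periodLabel(tagged) == "day"), 960L)
    expect_identical(sum(inD & periodLabel(tagged) == "night"), 480L)
  }
  # an epoch outside every day is a structural error
  es2 <- EpochSeries("T", seq(0, by = 60, length.out = nEp + 1),
                     rep(10, nEp + 1))
  expect_error(partitionPeriods(es2, part), "outside")
})

test_that("rest/active binarization uses a strict 40 mg rule by day and labels by night", {
  nEp <- 1440
  acc <- rep(10, nEp)
  acc[1:5] <- c(39.9, 40.0, 40.1, 0, 500)
  st <- rep(rep(c("wake", "sleep"), times = c(960, 480)), 1)
  acc[961] <- 100                        # sleeping epoch, high acceleration
  st[970] <- "wake"                      # waking night epoch, low acceleration
  es <- EpochSeries("T", seq(0, by = 60, length.out = nEp), acc, state = st)
  es <- partitionPeriods(es, DayPartition(c(0, 1440 * 60), 960 * 60))
  b <- binarizeRestActive(es)
  expect_identical(b@states[1:5], c(0L, 1L, 1L, 0L, 1L))  # 40.0 itself is active
  expect_identical(b@states[961], 0L)    # sleep label wins at night
  expect_identical(b@states[970], 1L)
  # observed mirrors wear
  es@wear[3] <- FALSE
  b2 <- binarizeRestActive(es)
  expect_true(is.na(b2@states[3]))
  expect_false(b2@observed[3])
})

test_that("hourly aggregation averages observed epochs per wake-anchored hour", {
  nEp <- 1440
  acc <- rep(10, nEp)
  acc[61:120] <- 20                      # hour 1 at 20 mg
  es <- EpochSeries("T", seq(0, by = 60, length.out = nEp), acc,
                    state = rep(c("wake", "sleep"), times = c(960, 480)))
  part <- DayPartition(c(0, 1440 * 60), 960 * 60)
  es <- partitionPeriods(es, part)
  h <- hourlyAggregate(es, part)
  expect_length(hourlyValues(h), 24)
  expect_identical(observedCount(h), rep(60L, 24))
  expect_equal(hourlyValues(h)[1], 10)
  expect_equal(hourlyValues(h)[2], 20)
  # wear-complete series: hourly mean equals the brute-force average
  expect_equal(hourlyValues(h),
               sapply(0:23, function(k) mean(acc[(k * 60 + 1):(k * 60 + 60)])))
  # partial and empty hours
  es@wear[61:90] <- FALSE                # half of hour 1 masked
  es@wear[121:180] <- FALSE              # all of hour 2 masked
  h2 <- hourlyAggregate(es, part)
  expect_identical(observedCount(h2)[2], 30L)
  expect_equal(hourlyValues(h2)[2], 20)
  expect_identical(observedCount(h2)[3], 0L)
  expect_true(is.na(hourlyValues(h2)[3]))
})

test_that("day partitions are derived from sustained wake runs", {
  # fragmented night: brief wake bouts must not open new days
  dayRun <- rep("wake", 960)
  night <- rep(c("sleep", "wake"), times = c(100, 5))
  st <- c(dayRun, rep_len(night, 480), dayRun, rep_len(night, 480))
  es <- EpochSeries("T", seq(0, by = 60, length.out = length(st)),
                    rep(10, length(st)), state = st)
  part <- derivePartition(es)
  expect_equal(nDays(part), 2)
  expect_equal(wakeOnsets(part), c(0, 1440, 2880) * 60)
  expect_equal(sleepOnsets(part), c(960, 2400) * 60)
})
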