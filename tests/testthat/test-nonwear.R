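test_that("block draws respect the scenario support bounds", {
  day0 <- 0; sOn <- 960 * 60; dEnd <- 1440 * 60
  set.seed(1)
  for (i in 1:2000) {
    b1 <- drawNonwearBlocks(day0, sOn, dEnd, scenario = 1)
    expect_true(b1$length >= 1 && b1$length <= 480)
    expect_true(b1$start >= day0 &&
                b1$start + b1$length * 60 <= dEnd)
    b2 <- drawNonwearBlocks(day0, sOn, dEnd, scenario = 2)
    expect_equal(b2$period, c("day", "night"))
    expect_true(b2$length[1] >= 1 && b2$length[1] <= 320)
    expect_true(b2$length[2] >= 1 && b2$length[2] <= 160)
    expect_true(b2$start[1] >= day0 && b2$start[1] + b2$length[1] * 60 <= sOn)
    expect_true(b2$start[2] >= sOn && b2$start[2] + b2$length[2] * 60 <= dEnd)
  }
  expect_error(drawNonwearBlocks(0, 60, 120, scenario = 1), "degenerate")
})

test_that("block lengths are uniform on their integer support", {
  set.seed(2)
  L <- replicate(1e5, drawNonwearBlocks(0, 960 * 60, 1440 * 60, 1)$length)
  tab <- tabulate(L, nbins = 480)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("mean artificial non-wear is about one sixth of the day", {
  set.seed(3)
  fr1 <- replicate(2e4, sum(drawNonwearBlocks(0, 960 * 60, 1440 * 60, 1)$length) / 1440)
  fr2 <- replicate(2e4, sum(drawNonwearBlocks(0, 960 * 60, 1440 * 60, 2)$length) / 1440)
  expect_equal(mean(fr1), 1 / 6, tolerance = 0.02)
  expect_equal(mean(fr2), 1 / 6, tolerance = 0.02)
})

test_that("the batch grid crosses scenarios and days minus the reference", {
  g <- batchGrid()
  expect_equal(nrow(g), 20)
  expect_false(any(g$scenario == 3 & g$n_days == 7))
  # batch ids are a bijection with (scenario, n_days)
  expect_equal(anyDuplicated(g$batch_id), 0)
  rt <- do.call(rbind, lapply(strsplit(sub("s", "", g$batch_id), "_d"),
                              as.integer))
  expect_equal(rt[, 1], g$scenario)
  expect_equal(rt[, 2], g$n_days)
})

test_that("scenario batches mask wear only and keep every retained day valid", {
  coh <- smallCohort(n = 3, days = 7, seed = 61)
  for (sc in 1:3) {
    m <- applyScenarioBatch(coh, sc, 5, seed = 62)
    for (sid in names(cohortSeries(m))) {
      es0 <- cohortSeries(coh)[[sid]]; es <- cohortSeries(m)[[sid]]
      n <- nEpochs(es)
      expect_equal(nDays(cohortPartitions(m)[[sid]]), 5)
      # values untouched; wear can only be switched off, never on
      expect_identical(accel(es), accel(es0)[seq_len(n)])
      expect_true(all(wearFlag(es0)[seq_len(n)] | !wearFlag(es)))
      if (sc == 3) expect_true(all(wearFlag(es)))
      for (d in 1:5) expect_true(checkValidDay(es, d, sc))
    }
  }
  # determinism of the masks
  m1 <- applyScenarioBatch(coh, 2, 4, seed = 63)
  m2 <- applyScenarioBatch(coh, 2, 4, seed = 63)
  expect_identical(lapply(cohortSeries(m1), wearFlag),
                   lapply(cohortSeries(m2), wearFlag))
  expect_error(applyScenarioBatch(coh, 1, 9, seed = 1), "config error")
})

test_that("valid-day thresholds follow the 2/3 wear rules", {
  nEp <- 1440
  es <- EpochSeries("T", seq(0, by = 60, length.out = nEp), rep(10, nEp),
                    state = rep(c("wake", "sleep"), times = c(960, 480)))
  part <- DayPartition(c(0, 1440 * 60), 960 * 60)
  es <- partitionPeriods(es, part)
  # 31% of the entire day masked: still valid under scenario 1
  es1 <- es; es1@wear[1:446] <- FALSE
  expect_true(checkValidDay(es1, 1, 1))
  expect_false(checkValidDay(es1, 1, 3))
  # 40% of the day period masked, night complete: invalid under scenario 2
  es2 <- es; es2@wear[1:384] <- FALSE
  expect_false(checkValidDay(es2, 1, 2))
  expect_true(checkValidDay(es2, 1, 1))
})

test_that("non-wear profiling counts blocks and percent distributions", {
  coh <- smallCohort(n = 3, days = 2, seed = 64)
  # subject 1: one block; subject 2: one block; subject 3: two blocks
  sers <- cohortSeries(coh)
  sers[[1]]@wear[10:20] <- FALSE
  sers[[2]]@wear[100:120] <- FALSE
  sers[[3]]@wear[c(10:20, 400:420)] <- FALSE
  coh2 <- EpochCohort(sers, cohortPartitions(coh))
  p <- profileNonwear(coh2)
  expect_equal(sort(p$blockCounts$n_blocks), c(1, 1, 2))
  # fully worn cohort: empty profile
  p0 <- profileNonwear(coh)
  expect_true(all(p0$blockCounts$n_blocks == 0))
  expect_equal(nrow(p0$percentNonwear), 0)
  # arithmetic of the percent table: 96 masked epochs in a 960-epoch day period
  es <- sers[[1]]
  es@wear <- rep(TRUE, nEpochs(es))
  dayIdx <- which(dayIndex(es) == 1 & periodLabel(es) == "day")
  es@wear[dayIdx[1:96]] <- FALSE
  nDayEp <- length(dayIdx)
  p1 <- profileNonwear(EpochCohort(stats::setNames(list(es), subjectId(es)),
                                   cohortPartitions(coh)[subjectId(es)]))
  row <- p1$percentNonwear[p1$percentNonwear$period == "day", ]
  expect_equal(row$pct, 100 * 96 / nDayEp)
})
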