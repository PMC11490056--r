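#' Draw artificial non-wear blocks for one entire day
#'
#' Implements the valid-day scenarios. Scenario 1 draws a single block
#' anywhere in the entire day: its length (in epochs) is uniform
#' between one epoch and one third of the day's wear time, and its
#' start is uniform between the first epoch of the day and the last
#' minus the block length. Scenario 2 draws one such block in the day
#' period and one, independently, in the night period, each bounded by
#' one third of that period's wear time. Scenario 3 draws nothing. A
#' day masked this way always still satisfies its own scenario's
#' valid-day criterion (wear of at least 2/3), because block lengths
#' are capped at 1/3 of wear.
#'
#' @param dayStart,sleepOnset,dayEnd timestamps bounding the entire
#'   day (`[dayStart, dayEnd)`) and its day/night split at
#'   `sleepOnset`.
#' @param scenario 1 or 2 (3 draws no blocks and is rejected here).
#' @param wearEpochs optional named numeric giving current wear epochs
#'   for `entire_day`, `day`, `night`; defaults to the full period
#'   sizes (the reference cohort wears the device throughout).
#' @param epochLength epoch duration in seconds.
#' @return a data.frame `period,start,length` (timestamp, epochs); one
#'   row for scenario 1, two for scenario 2.
#' @export
drawNonwearBlocks <- function(dayStart, sleepOnset, dayEnd, scenario,
                              wearEpochs = NULL, epochLength = 60) {
  stopifnot(scenario %in% c(1, 2))
  nDay <- (sleepOnset - dayStart) %/% epochLength
  nNight <- (dayEnd - sleepOnset) %/% epochLength
  if (is.null(wearEpochs))
    wearEpochs <- c(entire_day = nDay + nNight, day = nDay, night = nNight)
  one <- function(label, pStart, pLen, W) {
    maxL <- floor(W / 3)
    if (maxL < 1)
      stop("degenerate period: wear time shorter than 3 epochs")
    L <- sample.int(maxL, 1L)
    startIdx <- sample.int(pLen - L + 1L, 1L) - 1L
    data.frame(period = label, start = pStart + startIdx * epochLength,
               length = L)
  }
  if (scenario == 1) {
    one("entire_day", dayStart, nDay + nNight, wearEpochs[["entire_day"]])
  } else {
    rbind(one("day", dayStart, nDay, wearEpochs[["day"]]),
          one("night", sleepOnset, nNight, wearEpochs[["night"]]))
  }
}

# deterministic per-subject substream seed below 2^31
subjectSeed <- function(seed, sid, salt = 0L) {
  h <- 0
  for (c in utf8ToInt(sid)) h <- (h * 31 + c) %% 2147483647
  as.integer(((seed %% 2147483647) * 69069 + h * 7919 + salt) %% 2147483647)
}

#' The 20-batch simulation grid
#'
#' Crosses the three valid-day scenarios with 1--7 retained days and
#' removes the (scenario 3, max days) cell — complete wear over the
#' full window is the reference and never a batch.
#'
#' @param scenarios,nDaysGrid subsets of the full grid.
#' @return a data.frame `batch_id,scenario,n_days`.
#' @export
batchGrid <- function(scenarios = 1:3, nDaysGrid = 1:7) {
  g <- expand.grid(scenario = scenarios, n_days = nDaysGrid)
  g <- g[!(g$scenario == 3 & g$n_days == max(nDaysGrid)), , drop = FALSE]
  g <- g[order(g$scenario, g$n_days), , drop = FALSE]
  data.frame(batch_id = sprintf("s%d_d%d", g$scenario, g$n_days),
             scenario = g$scenario, n_days = g$n_days,
             row.names = NULL)
}

#' Apply one simulation batch to a cohort
#'
#' Retains the first `nDaysRetained` entire days of every subject and,
#' for scenarios 1 and 2, draws and applies artificial non-wear blocks
#' to every retained day (wear is set to `FALSE` inside the blocks;
#' acceleration values are untouched). Scenario 3 applies no blocks.
#' Each subject uses an RNG substream derived from `(seed,
#' subject_id)`, so masks are reproducible and independent of cohort
#' ordering.
#'
#' @param cohort a wear-complete [EpochCohort-class].
#' @param scenario 1, 2 or 3.
#' @param nDaysRetained number of entire days to retain (1--7).
#' @param seed batch seed.
#' @return the masked, truncated [EpochCohort-class].
#' @export
applyScenarioBatch <- function(cohort, scenario, nDaysRetained, seed) {
  sers <- cohortSeries(cohort); parts <- cohortPartitions(cohort)
  outS <- list(); outP <- list()
  for (sid in names(sers)) {
    es <- sers[[sid]]; part <- parts[[sid]]
    if (nDaysRetained > nDays(part))
      stop(sprintf("config error: %d days requested but subject '%s' has %d",
                   nDaysRetained, sid, nDays(part)))
    w <- wakeOnsets(part); s <- sleepOnsets(part)
    part2 <- DayPartition(w[seq_len(nDaysRetained + 1L)],
                          s[seq_len(nDaysRetained)])
    es2 <- es[timestamps(es) < w[nDaysRetained + 1L]]
    if (scenario %in% c(1, 2)) {
      set.seed(subjectSeed(seed, sid))
      ts <- timestamps(es2)
      wear <- wearFlag(es2)
      for (d in seq_len(nDaysRetained)) {
        blocks <- drawNonwearBlocks(w[d], s[d], w[d + 1L], scenario,
                                    epochLength = es2@epochLength)
        for (b in seq_len(nrow(blocks))) {
          lo <- blocks$start[b]
          hi <- lo + blocks$length[b] * es2@epochLength
          wear[ts >= lo & ts < hi] <- FALSE
        }
      }
      es2@wear <- wear
    }
    outS[[sid]] <- es2
    outP[[sid]] <- part2
  }
  EpochCohort(outS, outP, truth = cohortTruth(cohort),
              strata = cohortStrata(cohort))
}

#' Valid-day check under a scenario
#'
#' Scenario 1: wear covers at least 2/3 of the entire day's epochs.
#' Scenario 2: wear covers at least 2/3 of the day period AND 2/3 of
#' the night period. Scenario 3: complete wear.
#'
#' @param series a tagged [EpochSeries-class].
#' @param d entire-day index to check.
#' @param scenario 1, 2 or 3.
#' @return `TRUE` or `FALSE`.
#' @export
checkValidDay <- function(series, d, scenario) {
  inDay <- dayIndex(series) == d
  wear <- wearFlag(series)[inDay]
  per <- periodLabel(series)[inDay]
  switch(as.character(scenario),
    "1" = mean(wear) >= 2 / 3,
    "2" = mean(wear[per == "day"]) >= 2 / 3 &&
          mean(wear[per == "night"]) >= 2 / 3,
    "3" = all(wear),
    stop("scenario must be 1, 2 or 3"))
}

#' Profile non-wear patterns in a cohort
#'
#' Counts, per subject, the maximal non-wear runs over the whole
#' observation period, and tabulates the percent of non-wear among
#' person-periods (entire days, day periods, night periods) that have
#' at least one non-wear episode and less than one third non-wear.
#'
#' @param cohort an [EpochCohort-class].
#' @return a list with `blockCounts`
#'   (`subject_id,n_blocks`) and `percentNonwear`
#'   (`subject_id,day_index,period,pct`, percentages in \[0, 33.3)).
#' @export
profileNonwear <- function(cohort) {
  sers <- cohortSeries(cohort)
  counts <- lapply(names(sers), function(sid) {
    r <- rle(!wearFlag(sers[[sid]]))
    data.frame(subject_id = sid, n_blocks = sum(r$values))
  })
  pcts <- lapply(names(sers), function(sid) {
    es <- sers[[sid]]
    out <- list()
    for (d in unique(dayIndex(es))) {
      inD <- dayIndex(es) == d
      for (p in c("entire_day", "day", "night")) {
        sel <- if (p == "entire_day") inD else inD & periodLabel(es) == p
        nw <- mean(!wearFlag(es)[sel])
        if (nw > 0 && nw < 1 / 3)
          out[[length(out) + 1L]] <- data.frame(
            subject_id = sid, day_index = d, period = p, pct = 100 * nw)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  pcts <- pcts[!vapply(pcts, is.null, logical(1))]
  list(blockCounts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
       percentNonwear = if (length(pcts))
         do.call(rbind, c(pcts, list(make.row.names = FALSE)))
       else data.frame(subject_id = character(0), day_index = integer(0),
                       period = character(0), pct = numeric(0)))
}
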