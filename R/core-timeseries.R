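#' Read an epoch CSV into an EpochCohort
#'
#' Reads the plain epoch dialect
#' `subject_id,timestamp,accel_mg,wear,state` (optionally `imputed`),
#' one row per 60-s epoch, many subjects per file. Timestamps may be
#' integer seconds or ISO-8601; they are rebased to seconds since each
#' subject's series start. Day partitions are derived from the
#' sleep/wake label transitions: a wake onset is the first wake epoch
#' after a sleep run, a sleep onset the first sleep epoch after a wake
#' run. Subjects with fewer than one full wake-to-wake entire day are
#' skipped with a warning.
#'
#' @param path path to the CSV file.
#' @param epochLength epoch duration in seconds (default 60).
#' @return an [EpochCohort-class]; series are trimmed to whole entire
#'   days and tagged with day index and day/night period.
#' @export
readEpochCSV <- function(path, epochLength = 60) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "accel_mg", "wear", "state")
  if (!all(need %in% names(df)))
    stop("parse error: header must contain ", paste(need, collapse = ","))
  ts <- df$timestamp
  if (!is.numeric(ts)) {
    suppressWarnings(num <- as.numeric(ts))
    if (anyNA(num)) {
      parsed <- as.POSIXct(ts, tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
      if (anyNA(parsed)) {
        bad <- which(is.na(parsed))[1]
        stop(sprintf("parse error at data line %d: unparseable timestamp '%s'",
                     bad, ts[bad]))
      }
      num <- as.numeric(parsed)
    }
    ts <- num
  }
  if (anyNA(df$accel_mg) || !is.numeric(df$accel_mg)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$accel_mg))))[1]
    stop(sprintf("parse error at data line %d: bad accel_mg", bad))
  }
  if (!all(df$wear %in% c(0, 1)))
    stop("parse error: wear must be 0 or 1")
  if (!all(df$state %in% c("wake", "sleep")))
    stop("parse error: state must be 'wake' or 'sleep'")
  imput <- if ("imputed" %in% names(df)) df$imputed == 1 else rep(FALSE, nrow(df))

  series <- list(); partitions <- list()
  for (sid in unique(df$subject_id)) {
    i <- which(df$subject_id == sid)
    o <- order(ts[i]); i <- i[o]
    t0 <- ts[i] - ts[i][1]
    if (length(i) > 1 && any(diff(t0) != epochLength))
      stop(sprintf("structural error: subject '%s' has a gap or duplicate in the %gs epoch grid",
                   sid, epochLength))
    es <- EpochSeries(sid, t0, df$accel_mg[i],
                      wear = df$wear[i] == 1, state = df$state[i],
                      imputed = imput[i], epochLength = epochLength)
    part <- tryCatch(derivePartition(es), error = function(e) e)
    if (inherits(part, "error")) {
      warning(sprintf("subject '%s' skipped: %s", sid, conditionMessage(part)))
      next
    }
    es <- trimToPartition(es, part)
    es <- partitionPeriods(es, part)
    series[[sid]] <- es
    partitions[[sid]] <- part
  }
  EpochCohort(series, partitions)
}

#' Derive a wake-to-wake day partition from sleep/wake labels
#'
#' A wake onset is the start of a sustained wake run (at least
#' `minWakeRun` epochs — the day period), so that brief nocturnal
#' wake bouts do not open a new day; the matching sleep onset is the
#' first sleep epoch after that run. The final day is closed one
#' epoch past the series end (the series is expected to end during
#' the last night); a trailing day period without any night is
#' dropped as incomplete.
#'
#' @param series an [EpochSeries-class] with sleep/wake state labels.
#' @param minWakeRun minimum sustained wake run (epochs) that starts
#'   a day; default 120 (2 h on a 60-s grid).
#' @return a [DayPartition-class].
#' @export
derivePartition <- function(series, minWakeRun = 120) {
  st <- epochState(series); ts <- timestamps(series)
  n <- length(st)
  if (length(unique(st)) < 2L)
    stop("partition error: sleep/wake labels never change, no day boundaries")
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values == "wake" & r$lengths >= minWakeRun)
  if (!length(long))
    stop("partition error: no sustained wake run (day period) found")
  wake <- ts[starts[long]]
  sleepIdx <- ends[long] + 1L   # first sleep epoch after the day period
  D <- length(long)
  if (sleepIdx[D] > n) {        # ends right at end of a day period
    wake <- wake[-D]; sleepIdx <- sleepIdx[-D]; D <- D - 1L
  }
  if (D < 1L)
    stop("partition error: fewer than one full entire day")
  DayPartition(c(wake, ts[n] + series@epochLength), ts[sleepIdx])
}

trimToPartition <- function(series, part) {
  w <- wakeOnsets(part)
  keep <- timestamps(series) >= w[1] & timestamps(series) < w[length(w)]
  series[keep]
}

#' Subset an EpochSeries by epoch index
#'
#' @param x an [EpochSeries-class].
#' @param i logical or integer epoch index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EpochSeries", function(x, i, j, ..., drop = FALSE) {
  EpochSeries(x@subjectId, x@timestamp[i], x@accel[i], x@wear[i],
              x@state[i], x@dayIndex[i], x@period[i], x@imputed[i],
              x@epochLength)
})

#' Tag epochs with entire-day index and day/night period
#'
#' Entire day d spans `[wakeOnsets[d], wakeOnsets[d+1])`, the day
#' period `[wakeOnsets[d], sleepOnsets[d])` and the night period
#' `[sleepOnsets[d], wakeOnsets[d+1])` (all half-open; a timestamp
#' indexes the epoch's start).
#'
#' @param series an [EpochSeries-class].
#' @param part a [DayPartition-class] covering the series time span.
#' @return the series with `dayIndex` and `period` filled.
#' @export
partitionPeriods <- function(series, part) {
  ts <- timestamps(series)
  w <- wakeOnsets(part); s <- sleepOnsets(part)
  d <- findInterval(ts, w)
  if (any(d < 1L | d > nDays(part) | ts >= w[length(w)]))
    stop("structural error: epoch outside all entire days")
  per <- ifelse(ts < s[d], "day", "night")
  series@dayIndex <- as.integer(d)
  series@period <- per
  validObject(series)
  series
}

#' Binarize a tagged series into rest/active and sleep/wake states
#'
#' Day-period epochs are classified from acceleration: strictly below
#' the threshold is rest (0), at or above it active (1) — 40 mg itself
#' is active. Night-period epochs take the sleep/wake label: sleep is
#' 0, wake is 1, regardless of acceleration. `observed` mirrors the
#' wear mask; unobserved states are `NA`.
#'
#' @param series an [EpochSeries-class] tagged by [partitionPeriods()].
#' @param threshold rest/active cut point in milligravity (default 40).
#' @return a [BinarySeries-class].
#' @export
binarizeRestActive <- function(series, threshold = 40) {
  stopifnot(threshold > 0)
  if (anyNA(periodLabel(series)))
    stop("series must be period-tagged (run partitionPeriods first)")
  day <- periodLabel(series) == "day"
  st <- integer(nEpochs(series))
  st[day] <- as.integer(accel(series)[day] >= threshold)
  st[!day] <- as.integer(epochState(series)[!day] == "wake")
  st[!wearFlag(series)] <- NA_integer_
  new("BinarySeries", states = st, observed = wearFlag(series),
      period = periodLabel(series), dayIndex = dayIndex(series),
      timestamp = timestamps(series))
}

#' Aggregate an epoch series to wake-anchored hourly means
#'
#' Hour 0 of each entire day starts at that day's wake onset; each day
#' contributes 24 slots. The value of a slot is the mean acceleration
#' over its observed (wear) epochs and is missing when no epoch was
#' observed. Epochs falling beyond hour 23 of an entire day longer
#' than 24 h are not assigned to any slot.
#'
#' @param series an [EpochSeries-class] tagged by [partitionPeriods()].
#' @param part the matching [DayPartition-class].
#' @return an [HourlySeries-class] with `nDays(part) * 24` entries in
#'   day-major order.
#' @export
hourlyAggregate <- function(series, part) {
  D <- nDays(part)
  d <- dayIndex(series)
  if (anyNA(d)) stop("series must be tagged (run partitionPeriods first)")
  off <- timestamps(series) - wakeOnsets(part)[d]
  hr <- off %/% 3600
  keep <- wearFlag(series) & hr <= 23
  slot <- (d - 1L) * 24L + hr + 1L       # 1 .. D*24
  cnt <- tabulate(slot[keep], nbins = D * 24L)
  sums <- rep(0, D * 24L)
  if (any(keep)) {
    agg <- rowsum(accel(series)[keep], group = slot[keep])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  vals <- ifelse(cnt > 0L, sums / cnt, NA_real_)
  new("HourlySeries", values = vals, observedCount = as.integer(cnt),
      dayIndex = rep(seq_len(D), each = 24L),
      hourOfDay = rep(0:23, times = D))
}

#' Write an EpochCohort in the epoch CSV dialect
#'
#' Emits `subject_id,timestamp,accel_mg,wear,state,imputed` with
#' integer-second timestamps, the same dialect [readEpochCSV()] reads.
#'
#' @param cohort an [EpochCohort-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEpochCSV <- function(cohort, path) {
  rows <- lapply(cohortSeries(cohort), function(es) {
    data.frame(subject_id = subjectId(es),
               timestamp = format(timestamps(es), scientific = FALSE, trim = TRUE),
               accel_mg = accel(es),
               wear = as.integer(wearFlag(es)),
               state = epochState(es),
               imputed = as.integer(isImputed(es)))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
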