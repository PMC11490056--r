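#' @import methods
NULL

#' EpochSeries: a per-subject 60-second epoch accelerometer series
#'
#' One subject's wrist-accelerometer recording on a regular 60-s epoch
#' grid. Non-wear is a flag on the grid, never a missing row: the
#' timestamp vector is strictly increasing with spacing exactly
#' `epochLength`. Acceleration is an ENMO-like magnitude in
#' milligravity (mg). The sleep/wake label column carries the output of
#' an upstream sleep-detection step; it drives night-period
#' binarization and the day/night partition.
#'
#' @slot subjectId single character identifier.
#' @slot timestamp numeric, seconds since series start, multiples of 60.
#' @slot accel numeric, acceleration in mg; finite and non-negative
#'   wherever `wear` is `TRUE`.
#' @slot wear logical wear flag per epoch.
#' @slot state character, `"wake"` or `"sleep"` per epoch.
#' @slot dayIndex integer entire-day index per epoch (`NA` before
#'   [partitionPeriods()] has tagged the series).
#' @slot period character, `"day"` or `"night"` per epoch (`NA` before
#'   tagging).
#' @slot imputed logical, `TRUE` where the value was filled by
#'   epoch-level mean imputation.
#' @slot epochLength epoch duration in seconds (fixed at 60).
#'
#' @seealso [EpochSeries()] for the constructor,
#'   [partitionPeriods()], [binarizeRestActive()], [hourlyAggregate()].
#' @export
setClass("EpochSeries",
  representation(
    subjectId = "character",
    timestamp = "numeric",
    accel = "numeric",
    wear = "logical",
    state = "character",
    dayIndex = "integer",
    period = "character",
    imputed = "logical",
    epochLength = "numeric"
  ),
  prototype(epochLength = 60)
)

setValidity("EpochSeries", function(object) {
  msg <- character()
  n <- length(object@timestamp)
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-NA string")
  for (sl in c("accel", "wear", "state", "dayIndex", "period", "imputed")) {
    if (length(slot(object, sl)) != n)
      msg <- c(msg, sprintf("slot '%s' must have length %d", sl, n))
  }
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number")
  if (n > 1L) {
    d <- diff(object@timestamp)
    if (any(d != object@epochLength))
      msg <- c(msg, "timestamps must be strictly increasing with spacing exactly epochLength (non-wear is a flag, not a missing row)")
  }
  if (n > 0L) {
    bad <- object@wear & (!is.finite(object@accel) | object@accel < 0)
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "accel must be finite and >= 0 wherever wear is TRUE")
    if (!all(object@state %in% c("wake", "sleep")))
      msg <- c(msg, "state must be 'wake' or 'sleep'")
    if (!all(is.na(object@period) | object@period %in% c("day", "night")))
      msg <- c(msg, "period must be 'day', 'night' or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSeries
#'
#' @param subjectId single character identifier.
#' @param timestamp numeric seconds since series start (multiples of the
#'   epoch length).
#' @param accel numeric acceleration in milligravity.
#' @param wear logical wear flag (default all `TRUE`).
#' @param state character `"wake"`/`"sleep"` labels (default all
#'   `"wake"`).
#' @param dayIndex,period optional per-epoch entire-day index and
#'   day/night tag; usually filled by [partitionPeriods()].
#' @param imputed logical imputation provenance flag (default all
#'   `FALSE`).
#' @param epochLength epoch duration in seconds, fixed at 60 for this
#'   analysis.
#' @return an [EpochSeries-class] object.
#' @examples
#' es <- EpochSeries("s1", timestamp = seq(0, 540, by = 60),
#'                   accel = rep(10, 10))
#' nEpochs(es)
#' @export
EpochSeries <- function(subjectId, timestamp, accel,
                        wear = rep(TRUE, length(timestamp)),
                        state = rep("wake", length(timestamp)),
                        dayIndex = rep(NA_integer_, length(timestamp)),
                        period = rep(NA_character_, length(timestamp)),
                        imputed = rep(FALSE, length(timestamp)),
                        epochLength = 60) {
  new("EpochSeries",
      subjectId = as.character(subjectId),
      timestamp = as.numeric(timestamp),
      accel = as.numeric(accel),
      wear = as.logical(wear),
      state = as.character(state),
      dayIndex = as.integer(dayIndex),
      period = as.character(period),
      imputed = as.logical(imputed),
      epochLength = as.numeric(epochLength))
}

#' DayPartition: wake-to-wake day anchors for one subject
#'
#' Wake onsets and sleep onsets defining, for each of D entire days
#' (wake onset to next wake onset, half-open), a day period
#' `[wakeOnset, sleepOnset)` and a night period
#' `[sleepOnset, nextWakeOnset)`.
#'
#' @slot wakeOnsets numeric of length D+1 (the last anchor closes day D).
#' @slot sleepOnsets numeric of length D.
#' @export
setClass("DayPartition",
  representation(wakeOnsets = "numeric", sleepOnsets = "numeric"))

setValidity("DayPartition", function(object) {
  D <- length(object@sleepOnsets)
  if (length(object@wakeOnsets) != D + 1L)
    return("wakeOnsets must have length(sleepOnsets) + 1")
  if (D < 1L) return("at least one full entire day is required")
  w <- object@wakeOnsets; s <- object@sleepOnsets
  if (!all(w[seq_len(D)] < s & s < w[seq_len(D) + 1L]))
    return("must satisfy wakeOnsets[d] < sleepOnsets[d] < wakeOnsets[d+1]")
  TRUE
})

#' @rdname DayPartition-class
#' @param wakeOnsets,sleepOnsets numeric timestamp anchors (seconds).
#' @return a `DayPartition` object.
#' @export
DayPartition <- function(wakeOnsets, sleepOnsets) {
  new("DayPartition", wakeOnsets = as.numeric(wakeOnsets),
      sleepOnsets = as.numeric(sleepOnsets))
}

#' BinarySeries: rest/active (day) and sleep/wake (night) states
#'
#' The binarized series used by the transition-probability metrics:
#' 0 = rest or sleep, 1 = active or wake, on the same grid as the
#' source [EpochSeries-class]. `observed` mirrors the wear mask.
#'
#' @slot states integer 0/1 per epoch (`NA` where unobserved).
#' @slot observed logical per epoch.
#' @slot period character `"day"`/`"night"` tag per epoch.
#' @slot dayIndex integer entire-day index per epoch.
#' @slot timestamp numeric per epoch.
#' @export
setClass("BinarySeries",
  representation(states = "integer", observed = "logical",
                 period = "character", dayIndex = "integer",
                 timestamp = "numeric"))

setValidity("BinarySeries", function(object) {
  n <- length(object@states)
  if (length(object@observed) != n || length(object@period) != n ||
      length(object@dayIndex) != n || length(object@timestamp) != n)
    return("all slots must have the same length")
  if (!all(object@states %in% c(0L, 1L, NA_integer_)))
    return("states must be 0, 1 or NA")
  TRUE
})

#' HourlySeries: wake-anchored hourly mean acceleration
#'
#' Per clock-hour mean acceleration used by interdaily stability and
#' intradaily variability. Hours are anchored at each subject's wake
#' onset: hour 0 is the first hour awake of each entire day, giving 24
#' aligned slots per day. A value is missing exactly when no observed
#' epoch contributed.
#'
#' @slot values numeric hourly means (mg), `NA` when unobserved.
#' @slot observedCount integer epochs contributing per hour (0--60).
#' @slot dayIndex integer entire-day index per entry.
#' @slot hourOfDay integer 0--23 per entry.
#' @export
setClass("HourlySeries",
  representation(values = "numeric", observedCount = "integer",
                 dayIndex = "integer", hourOfDay = "integer"))

setValidity("HourlySeries", function(object) {
  n <- length(object@values)
  if (length(object@observedCount) != n || length(object@dayIndex) != n ||
      length(object@hourOfDay) != n)
    return("all slots must have the same length")
  if (any(is.na(object@values) != (object@observedCount == 0L)))
    return("value must be missing exactly when observedCount is 0")
  if (n %% 24L != 0L)
    return("24 hour slots per day are required")
  if (!all(object@hourOfDay %in% 0:23))
    return("hourOfDay must lie in 0..23")
  TRUE
})

#' DfaProfile: detrended fluctuation analysis profile
#'
#' Box sizes, fluctuation function and fitted scaling exponent from
#' [dfaAlpha()].
#'
#' @slot boxSizes integer box sizes s (epochs).
#' @slot fluctuations numeric F(s), root-mean-square detrended
#'   fluctuation per box size.
#' @slot alpha fitted log-log slope.
#' @slot fitRange numeric length-2, the (min, max) box sizes used.
#' @export
setClass("DfaProfile",
  representation(boxSizes = "integer", fluctuations = "numeric",
                 alpha = "numeric", fitRange = "numeric"))

#' EpochCohort: a collection of subjects with partitions and metadata
#'
#' Container tying together per-subject [EpochSeries-class] objects,
#' their [DayPartition-class]s, optional generator ground truth, and
#' optional strata labels.
#'
#' @slot series named list of `EpochSeries`.
#' @slot partitions named list of `DayPartition` (same names).
#' @slot truth data.frame of generator ground truth
#'   (`subject_id,param,value`), possibly empty.
#' @slot strata data.frame with columns `subject_id`, `sex`,
#'   `age_group`, possibly empty.
#' @export
setClass("EpochCohort",
  representation(series = "list", partitions = "list",
                 truth = "data.frame", strata = "data.frame"))

setValidity("EpochCohort", function(object) {
  if (!identical(names(object@series), names(object@partitions)))
    return("series and partitions must be parallel named lists")
  if (length(object@series) &&
      !all(vapply(object@series, is, logical(1), "EpochSeries")))
    return("series must contain EpochSeries objects")
  TRUE
})

#' @rdname EpochCohort-class
#' @param series named list of [EpochSeries-class] objects.
#' @param partitions named list of [DayPartition-class] objects.
#' @param truth,strata optional data.frames (see slots).
#' @return an `EpochCohort`.
#' @export
EpochCohort <- function(series, partitions,
                        truth = data.frame(), strata = data.frame()) {
  new("EpochCohort", series = series, partitions = partitions,
      truth = truth, strata = strata)
}
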