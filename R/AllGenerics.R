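#' Accessors for actifrag classes
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x an actifrag object.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("accel", function(x) standardGeneric("accel"))
#' @rdname accessors
#' @export
setGeneric("wearFlag", function(x) standardGeneric("wearFlag"))
#' @rdname accessors
#' @export
setGeneric("epochState", function(x) standardGeneric("epochState"))
#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setGeneric("dayIndex", function(x) standardGeneric("dayIndex"))
#' @rdname accessors
#' @export
setGeneric("periodLabel", function(x) standardGeneric("periodLabel"))
#' @rdname accessors
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))
#' @rdname accessors
#' @export
setGeneric("wakeOnsets", function(x) standardGeneric("wakeOnsets"))
#' @rdname accessors
#' @export
setGeneric("sleepOnsets", function(x) standardGeneric("sleepOnsets"))
#' @rdname accessors
#' @export
setGeneric("nDays", function(x) standardGeneric("nDays"))
#' @rdname accessors
#' @export
setGeneric("hourlyValues", function(x) standardGeneric("hourlyValues"))
#' @rdname accessors
#' @export
setGeneric("observedCount", function(x) standardGeneric("observedCount"))
#' @rdname accessors
#' @export
setGeneric("dfaExponent", function(x) standardGeneric("dfaExponent"))
#' @rdname accessors
#' @export
setGeneric("cohortSeries", function(x) standardGeneric("cohortSeries"))
#' @rdname accessors
#' @export
setGeneric("cohortPartitions", function(x) standardGeneric("cohortPartitions"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setGeneric("cohortStrata", function(x) standardGeneric("cohortStrata"))

#' @rdname accessors
#' @export
setMethod("subjectId", "EpochSeries", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSeries", function(x) length(x@timestamp))
#' @rdname accessors
#' @export
setMethod("accel", "EpochSeries", function(x) x@accel)
#' @rdname accessors
#' @export
setMethod("wearFlag", "EpochSeries", function(x) x@wear)
#' @rdname accessors
#' @export
setMethod("epochState", "EpochSeries", function(x) x@state)
#' @rdname accessors
#' @export
setMethod("timestamps", "EpochSeries", function(x) x@timestamp)
#' @rdname accessors
#' @export
setMethod("dayIndex", "EpochSeries", function(x) x@dayIndex)
#' @rdname accessors
#' @export
setMethod("periodLabel", "EpochSeries", function(x) x@period)
#' @rdname accessors
#' @export
setMethod("isImputed", "EpochSeries", function(x) x@imputed)

#' @rdname accessors
#' @export
setMethod("wakeOnsets", "DayPartition", function(x) x@wakeOnsets)
#' @rdname accessors
#' @export
setMethod("sleepOnsets", "DayPartition", function(x) x@sleepOnsets)
#' @rdname accessors
#' @export
setMethod("nDays", "DayPartition", function(x) length(x@sleepOnsets))

#' @rdname accessors
#' @export
setMethod("hourlyValues", "HourlySeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("observedCount", "HourlySeries", function(x) x@observedCount)
#' @rdname accessors
#' @export
setMethod("dayIndex", "HourlySeries", function(x) x@dayIndex)

#' @rdname accessors
#' @export
setMethod("dfaExponent", "DfaProfile", function(x) x@alpha)

#' @rdname accessors
#' @export
setMethod("cohortSeries", "EpochCohort", function(x) x@series)
#' @rdname accessors
#' @export
setMethod("cohortPartitions", "EpochCohort", function(x) x@partitions)
#' @rdname accessors
#' @export
setMethod("cohortTruth", "EpochCohort", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("cohortStrata", "EpochCohort", function(x) x@strata)
#' @rdname accessors
#' @export
setMethod("nEpochs", "BinarySeries", function(x) length(x@states))

setMethod("show", "EpochSeries", function(object) {
  cat(sprintf("EpochSeries '%s': %d epochs of %gs (%.1f h), %.1f%% wear\n",
              object@subjectId, length(object@timestamp),
              object@epochLength,
              length(object@timestamp) * object@epochLength / 3600,
              if (length(object@wear)) 100 * mean(object@wear) else NA))
})

setMethod("show", "DayPartition", function(object) {
  cat(sprintf("DayPartition: %d entire days (wake-to-wake)\n",
              length(object@sleepOnsets)))
})

setMethod("show", "HourlySeries", function(object) {
  cat(sprintf("HourlySeries: %d days x 24 wake-anchored slots, %d observed\n",
              length(object@values) %/% 24L, sum(object@observedCount > 0L)))
})

setMethod("show", "DfaProfile", function(object) {
  cat(sprintf("DfaProfile: alpha = %.3f over %d box sizes in [%d, %d]\n",
              object@alpha, length(object@boxSizes),
              object@fitRange[1], object@fitRange[2]))
})

setMethod("show", "EpochCohort", function(object) {
  cat(sprintf("EpochCohort: %d subjects%s%s\n", length(object@series),
              if (nrow(object@truth)) ", with ground truth" else "",
              if (nrow(object@strata)) ", with strata" else ""))
})
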