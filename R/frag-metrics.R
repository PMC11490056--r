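#' Interdaily stability (IS)
#'
#' Nonparametric consistency of the 24-h activity profile across days:
#' the ratio of the variance of the 24 hour-slot means to the total
#' variance of the hourly series,
#' \deqn{IS = \frac{N \sum_{h=1}^{p} (\bar x_h - \bar x)^2}
#'            {p \sum_{i=1}^{N} (x_i - \bar x)^2},}
#' with p = 24 wake-anchored clock-hour slots, N the number of
#' observed hourly values, \eqn{\bar x_h} the mean of slot h across
#' days and \eqn{\bar x} the grand mean. IS is 1 when every day
#' repeats the same profile and tends to p/N for structureless noise.
#' Requires every slot to be observed on at least two days.
#'
#' @param hourly an [HourlySeries-class].
#' @return a list `value` (IS in \[0,1\] or `NA`) and `reason`
#'   (`NA` or why the value is missing).
#' @export
interdailyStability <- function(hourly) {
  x <- hourlyValues(hourly)
  h <- hourly@hourOfDay
  obs <- !is.na(x)
  perSlot <- tabulate(h[obs] + 1L, nbins = 24L)
  if (any(perSlot < 2L))
    return(list(value = NA_real_, reason = "insufficient hourly coverage"))
  xo <- x[obs]; ho <- h[obs]
  gm <- mean(xo)
  tot <- sum((xo - gm)^2)
  if (tot <= 0)
    return(list(value = NA_real_, reason = "constant signal"))
  slotMeans <- rowsum(xo, ho)[, 1] / perSlot
  N <- length(xo)
  list(value = (N * sum((slotMeans - gm)^2)) / (24 * tot), reason = NA_character_)
}

#' Intradaily variability (IV)
#'
#' Hourly fragmentation of the rhythm: the mean squared difference of
#' consecutive hourly values relative to the overall variance,
#' \deqn{IV = \frac{N \sum (x_i - x_{i-1})^2}{(N-1)\sum (x_i - \bar x)^2}}
#' over consecutive observed pairs. With missing hours, difference
#' terms are only formed where two adjacent clock hours are both
#' observed (pairs spanning an omitted hour are skipped, not bridged),
#' and the ratio generalizes to (mean squared difference over valid
#' pairs) / (sum of squares about the mean / N). IV is near 2 for
#' uncorrelated noise, 4 for a perfectly alternating series, and small
#' for smooth profiles.
#'
#' @param hourly an [HourlySeries-class].
#' @return a list `value` (positive real or `NA`) and `reason`.
#' @export
intradailyVariability <- function(hourly) {
  x <- hourlyValues(hourly)
  obs <- !is.na(x)
  N <- sum(obs)
  if (N < 2L)
    return(list(value = NA_real_, reason = "insufficient hourly coverage"))
  # entries are day-major so consecutive entries are adjacent clock
  # hours (hour 23 of day d abuts hour 0 of day d+1)
  pair <- obs[-1] & obs[-length(obs)]
  if (!any(pair))
    return(list(value = NA_real_, reason = "no adjacent observed hour pairs"))
  tot <- sum((x[obs] - mean(x[obs]))^2)
  if (tot <= 0)
    return(list(value = NA_real_, reason = "constant signal"))
  d2 <- (x[-1] - x[-length(x)])[pair]^2
  list(value = (sum(d2) / sum(pair)) / (tot / N), reason = NA_character_)
}

#' Extract same-state bouts from a binarized series
#'
#' Finds maximal runs of identical state within each (day, period)
#' instance of the series. A run abutting a period boundary or an
#' unobserved epoch carries the corresponding censored flag: its true
#' duration is unknown, and censored bouts are excluded by the
#' transition-probability estimator.
#'
#' @param binary a [BinarySeries-class].
#' @return a data.frame with columns `state`, `start` (timestamp),
#'   `length` (epochs), `left_censored`, `right_censored`, `period`,
#'   `day_index`; zero rows when nothing is observed.
#' @export
extractBouts <- function(binary) {
  n <- nEpochs(binary)
  empty <- data.frame(state = integer(0), start = numeric(0),
                      length = integer(0), left_censored = logical(0),
                      right_censored = logical(0), period = character(0),
                      day_index = integer(0))
  if (n == 0L) return(empty)
  obs <- binary@observed & !is.na(binary@states)
  # segment id changes at period/day boundaries and at observation gaps;
  # a bout touching a segment edge is censored (true duration unknown)
  seg <- cumsum(c(TRUE,
    binary@period[-1] != binary@period[-n] |
    binary@dayIndex[-1] != binary@dayIndex[-n] |
    obs[-1] != obs[-n]))
  stNum <- ifelse(obs, binary@states, -1L)
  r <- rle(seg * 4L + stNum + 2L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- stNum[starts] >= 0L
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    state = binary@states[starts],
    start = binary@timestamp[starts],
    length = (ends - starts + 1L),
    left_censored = starts == 1L | seg[starts] != seg[pmax(starts - 1L, 1L)],
    right_censored = ends == n | seg[ends] != seg[pmin(ends + 1L, n)],
    period = binary@period[starts],
    day_index = binary@dayIndex[starts])
}

#' Transition probabilities from bout durations
#'
#' Per-epoch probabilities of state change, estimated per period as
#' the reciprocal of the mean duration (in epochs) of uncensored bouts
#' of the originating state, pooled over all retained days:
#' `tp_ra_d` from day rest bouts, `tp_ar_d` from day active bouts,
#' `tp_ws_n` from night wake bouts, `tp_sw_n` from night sleep bouts.
#' Under first-order dynamics bout durations are geometric with mean
#' 1/p, making the estimator consistent for the per-epoch transition
#' probability.
#'
#' @param bouts a bout data.frame from [extractBouts()].
#' @return a list with elements `tp_ra_d`, `tp_ar_d`, `tp_ws_n`,
#'   `tp_sw_n`, each a list `value`/`reason`.
#' @export
transitionProbabilities <- function(bouts) {
  est <- function(state, period) {
    keep <- bouts$state == state & bouts$period == period &
      !bouts$left_censored & !bouts$right_censored
    if (!any(keep))
      return(list(value = NA_real_,
                  reason = sprintf("no uncensored %s-period bouts of state %d",
                                   period, state)))
    list(value = 1 / mean(bouts$length[keep]), reason = NA_character_)
  }
  list(tp_ra_d = est(0L, "day"), tp_ar_d = est(1L, "day"),
       tp_ws_n = est(1L, "night"), tp_sw_n = est(0L, "night"))
}

#' Activity balance index (ABI)
#'
#' Bounded transform of the DFA scaling exponent peaking at
#' alpha = 1 (1/f-like dynamics):
#' \deqn{ABI = \exp(-|\alpha - 1| / e^{-2}).}
#' ABI is 1 iff alpha = 1 and decreases symmetrically and strictly as
#' alpha departs from 1 on either side.
#'
#' @param alpha DFA scaling exponent (or `NA`).
#' @param scale decay constant of the transform (default `exp(-2)`).
#' @return ABI in (0, 1\], or `NA` when alpha is missing.
#' @export
activityBalanceIndex <- function(alpha, scale = exp(-2)) {
  ifelse(is.na(alpha), NA_real_, exp(-abs(alpha - 1) / scale))
}

#' Compute the eight fragmentation metrics for one subject
#'
#' Applies the chosen non-wear handling, then computes interdaily
#' stability and intradaily variability on the wake-anchored hourly
#' aggregate, the four transition probabilities on binarized period
#' bouts, the DFA scaling exponent on the 60-s epoch acceleration
#' series (under omission, observed epochs are concatenated, closing
#' the gaps), and the activity balance index from alpha. Metrics that
#' cannot be computed are returned missing with a reason; the function
#' never fails on a computable subset.
#'
#' @param series a tagged [EpochSeries-class].
#' @param part the matching [DayPartition-class].
#' @param handling `"omit"` or `"impute"` (see [imputeEpochMean()]).
#' @param threshold rest/active cut point in mg (default 40).
#' @return a list with `values` (named numeric of the 8 metrics,
#'   `NA` where missing) and `reasons` (named character).
#' @export
computeMetricVector <- function(series, part, handling = c("omit", "impute"),
                                threshold = 40) {
  handling <- match.arg(handling)
  if (handling == "impute") series <- imputeEpochMean(series, part)
  hourly <- hourlyAggregate(series, part)
  isRes <- interdailyStability(hourly)
  ivRes <- intradailyVariability(hourly)
  tps <- transitionProbabilities(extractBouts(binarizeRestActive(series, threshold)))
  sig <- accel(series)[wearFlag(series)]
  prof <- dfaAlpha(sig)
  alphaVal <- if (is(prof, "DfaProfile")) dfaExponent(prof) else NA_real_
  alphaReason <- if (is(prof, "DfaProfile")) NA_character_ else prof$reason
  values <- c(IS = isRes$value, IV = ivRes$value,
              TP_ra_d = tps$tp_ra_d$value, TP_ar_d = tps$tp_ar_d$value,
              TP_ws_n = tps$tp_ws_n$value, TP_sw_n = tps$tp_sw_n$value,
              alpha = alphaVal,
              ABI = activityBalanceIndex(alphaVal))
  reasons <- c(IS = isRes$reason, IV = ivRes$reason,
               TP_ra_d = tps$tp_ra_d$reason, TP_ar_d = tps$tp_ar_d$reason,
               TP_ws_n = tps$tp_ws_n$reason, TP_sw_n = tps$tp_sw_n$reason,
               alpha = alphaReason,
               ABI = if (is.na(alphaVal)) "alpha missing" else NA_character_)
  list(values = values, reasons = reasons)
}

#' Compute metric vectors for every subject of a cohort
#'
#' @param cohort an [EpochCohort-class].
#' @param handling `"omit"` or `"impute"`.
#' @param threshold rest/active cut point in mg.
#' @return a data.frame in long form:
#'   `subject_id,metric,value,reason`.
#' @export
computeCohortMetrics <- function(cohort, handling = c("omit", "impute"),
                                 threshold = 40) {
  handling <- match.arg(handling)
  sers <- cohortSeries(cohort); parts <- cohortPartitions(cohort)
  rows <- lapply(names(sers), function(sid) {
    mv <- computeMetricVector(sers[[sid]], parts[[sid]], handling, threshold)
    data.frame(subject_id = sid, metric = names(mv$values),
               value = unname(mv$values), reason = unname(mv$reasons))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
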