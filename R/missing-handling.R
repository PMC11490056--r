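#' Omission view of non-wear
#'
#' Under omission, non-wear epochs are excluded from the signal: no
#' value is altered and the grid is preserved, so hourly aggregation
#' and bout extraction keep their clock alignment while every
#' downstream computation sees only `wear = TRUE` epochs. The series
#' itself already carries that contract through its wear mask, so this
#' is the identity on the data; it exists to make the handling
#' explicit at call sites.
#'
#' @param series an [EpochSeries-class].
#' @return the same series.
#' @export
omitNonwear <- function(series) series

#' Epoch-level mean imputation of non-wear
#'
#' Fills each non-wear epoch with the average, at the epoch level, of
#' the equivalent moment on the other retained days when the device
#' was worn. The equivalent moment is the same wake-anchored offset
#' within the entire day (days are defined wake-to-wake, so this
#' aligns behavioural phase across days with varying wake times). For
#' night epochs the sleep/wake label is imputed by majority vote
#' across the same positions, ties resolved to sleep. Positions
#' unobserved on every other day are left missing (those epochs fall
#' back to omission). Observed epochs are never altered; filled epochs
#' get `wear = TRUE` and an `imputed` provenance flag.
#'
#' @param series a tagged [EpochSeries-class].
#' @param part the matching [DayPartition-class].
#' @return the imputed [EpochSeries-class].
#' @export
imputeEpochMean <- function(series, part) {
  if (all(wearFlag(series))) return(series)
  D <- nDays(part)
  d <- dayIndex(series)
  off <- (timestamps(series) - wakeOnsets(part)[d]) %/% series@epochLength + 1L
  maxOff <- max(off)
  # accel and wake-indicator matrices, position x day, NA where unworn
  A <- matrix(NA_real_, maxOff, D)
  Wk <- matrix(NA_integer_, maxOff, D)
  idx <- cbind(off, d)
  worn <- wearFlag(series)
  A[idx[worn, , drop = FALSE]] <- accel(series)[worn]
  Wk[idx[worn, , drop = FALSE]] <- as.integer(epochState(series)[worn] == "wake")
  sumA <- rowSums(A, na.rm = TRUE); cntA <- rowSums(!is.na(A))
  sumW <- rowSums(Wk, na.rm = TRUE)
  # the target epoch's own cell is NA (it is unworn), so the row sums
  # already cover exactly the *other* days at the same position
  miss <- which(!worn)
  cnt <- cntA[off[miss]]
  fill <- cnt >= 1L
  tgt <- miss[fill]
  accelV <- accel(series); wearV <- wearFlag(series)
  impV <- isImputed(series); stateV <- epochState(series)
  accelV[tgt] <- sumA[off[tgt]] / cnt[fill]
  wearV[tgt] <- TRUE
  impV[tgt] <- TRUE
  nightTgt <- tgt[periodLabel(series)[tgt] == "night"]
  if (length(nightTgt)) {
    wk <- sumW[off[nightTgt]]
    stateV[nightTgt] <- ifelse(wk > cntA[off[nightTgt]] / 2, "wake", "sleep")
  }
  if (any(!fill))
    warning(sprintf("%d epoch(s) unobserved on every day were left missing",
                    sum(!fill)))
  series@accel <- accelV; series@wear <- wearV
  series@imputed <- impV; series@state <- stateV
  validObject(series)
  series
}
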