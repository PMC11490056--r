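#' Intraclass correlation, ICC(A,1)
#'
#' Agreement between reference and batch metric values across
#' subjects: two-way mixed-effects, absolute-agreement, single-measures
#' ICC with k = 2 raters (reference and batch),
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}
#'       {MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' error mean squares of the two-way ANOVA decomposition. Absolute
#' agreement penalizes systematic bias between batch and reference,
#' the conservative choice for a method-agreement design. Pairs with
#' any missing value are dropped.
#'
#' @param ref,sim numeric vectors of per-subject values, aligned.
#' @return a list: `value` (ICC in \[-1, 1\] or `NA`), `n` (complete
#'   pairs used), `reason`.
#' @export
iccAgreement <- function(ref, sim) {
  ok <- is.finite(ref) & is.finite(sim)
  x <- ref[ok]; y <- sim[ok]
  n <- length(x)
  if (n < 3L)
    return(list(value = NA_real_, n = n, reason = "fewer than 3 complete pairs"))
  k <- 2
  m <- mean(c(x, y))
  rowMean <- (x + y) / 2
  colMean <- c(mean(x), mean(y))
  msr <- k * sum((rowMean - m)^2) / (n - 1)
  msc <- n * sum((colMean - m)^2) / (k - 1)
  mse <- (sum((x - rowMean - colMean[1] + m)^2) +
          sum((y - rowMean - colMean[2] + m)^2)) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (msr <= 0 || denom <= 0)
    return(list(value = NA_real_, n = n, reason = "zero between-subject variance"))
  list(value = (msr - mse) / denom, n = n, reason = NA_character_)
}

#' Mean absolute percent error
#'
#' \deqn{MAPE = 100 \cdot \mathrm{mean}_i |sim_i - ref_i| / |ref_i|,}
#' over complete pairs, excluding pairs whose reference magnitude is
#' below a floor (default 1e-8) to keep near-zero references from
#' blowing up the mean; the exclusion count is reported.
#'
#' @param ref,sim numeric vectors of per-subject values, aligned.
#' @param eps reference-magnitude floor.
#' @return a list: `value` (percent or `NA`), `n` (pairs used),
#'   `n_excluded`, `reason`.
#' @export
mape <- function(ref, sim, eps = 1e-8) {
  ok <- is.finite(ref) & is.finite(sim)
  small <- ok & abs(ref) < eps
  use <- ok & !small
  if (!any(use))
    return(list(value = NA_real_, n = 0L, n_excluded = sum(small),
                reason = "no usable pairs"))
  list(value = 100 * mean(abs(sim[use] - ref[use]) / abs(ref[use])),
       n = sum(use), n_excluded = sum(small), reason = NA_character_)
}

#' Reliability table over batches
#'
#' For every metric x batch x handling cell, pairs each subject's
#' batch value with the reference value (scenario 3, complete 7 days),
#' computes ICC(A,1) and MAPE, and flags them against the
#' acceptability cut points (ICC at least `iccCut`, MAPE at most
#' `mapeCut`). Cells with fewer than 3 complete pairs (e.g. IS when
#' too few days allow it to be computed for anyone) are omitted.
#'
#' Interdaily stability needs every hour slot observed at least
#' twice, so batches with fewer than `minDaysIS` retained days cannot
#' test it; IS rows below that are excluded by design rather than
#' left to complete-case selection (which would score IS on the
#' accidental subset of subjects whose non-wear blocks happened to
#' overlap in clock time).
#'
#' @param batchMetrics long data.frame with columns
#'   `subject_id,metric,value,scenario,n_days,handling` (one row per
#'   subject x metric per batch x handling).
#' @param refMetrics long data.frame `subject_id,metric,value` of
#'   reference values.
#' @param iccCut,mapeCut acceptability cut points (defaults 0.75, 15).
#' @param minDaysIS smallest number of retained days at which IS is
#'   testable (default 3).
#' @return a data.frame
#'   `metric,scenario,n_days,handling,icc,mape,n_used,icc_pass,mape_pass`.
#' @export
reliabilityTable <- function(batchMetrics, refMetrics,
                             iccCut = 0.75, mapeCut = 15, minDaysIS = 3) {
  batchMetrics <- batchMetrics[!(batchMetrics$metric == "IS" &
                                 batchMetrics$n_days < minDaysIS), ]
  cells <- unique(batchMetrics[c("metric", "scenario", "n_days", "handling")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sub <- batchMetrics[batchMetrics$metric == cl$metric &
                        batchMetrics$scenario == cl$scenario &
                        batchMetrics$n_days == cl$n_days &
                        batchMetrics$handling == cl$handling, ]
    ref <- refMetrics[refMetrics$metric == cl$metric, ]
    idx <- match(sub$subject_id, ref$subject_id)
    icc <- iccAgreement(ref$value[idx], sub$value)
    mp <- mape(ref$value[idx], sub$value)
    if (icc$n < 3L) return(NULL)
    data.frame(metric = cl$metric, scenario = cl$scenario,
               n_days = cl$n_days, handling = cl$handling,
               icc = icc$value, mape = mp$value, n_used = icc$n,
               icc_pass = !is.na(icc$value) && icc$value >= iccCut,
               mape_pass = !is.na(mp$value) && mp$value <= mapeCut)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$metric, out$scenario, out$handling, out$n_days), ,
      drop = FALSE]
}

#' Minimum valid days per metric
#'
#' For each metric x scenario x handling, the smallest number of
#' retained days such that that batch and every larger number of days
#' pass both cut points (terminal-run rule: a recommendation that
#' fails again at more days is not usable). `NA` when even the largest
#' tested number of days fails.
#'
#' @param table a [reliabilityTable()] result.
#' @return a data.frame `metric,scenario,handling,min_days`.
#' @export
minimumValidDays <- function(table) {
  cells <- unique(table[c("metric", "scenario", "handling")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sub <- table[table$metric == cl$metric & table$scenario == cl$scenario &
                 table$handling == cl$handling, ]
    sub <- sub[order(sub$n_days), ]
    pass <- sub$icc_pass & sub$mape_pass
    minDays <- NA_integer_
    if (length(pass) && pass[length(pass)]) {
      # last index before the terminal run of passes
      fail <- which(!pass)
      first <- if (length(fail)) fail[length(fail)] + 1L else 1L
      minDays <- sub$n_days[first]
    }
    data.frame(metric = cl$metric, scenario = cl$scenario,
               handling = cl$handling, min_days = minDays)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stratified reliability tables
#'
#' Recomputes the reliability table within each level of a stratum
#' label (e.g. sex or age group), independently. Strata with fewer
#' than 3 subjects are skipped with a warning.
#'
#' @param batchMetrics,refMetrics as in [reliabilityTable()].
#' @param strata data.frame `subject_id` plus one label column.
#' @param by name of the label column in `strata`.
#' @param iccCut,mapeCut acceptability cut points.
#' @return a data.frame like [reliabilityTable()] with an extra
#'   `stratum` column.
#' @export
stratifiedReliability <- function(batchMetrics, refMetrics, strata, by,
                                  iccCut = 0.75, mapeCut = 15) {
  stopifnot(by %in% names(strata))
  out <- list()
  for (lev in unique(strata[[by]])) {
    ids <- strata$subject_id[strata[[by]] == lev]
    if (length(ids) < 3L) {
      warning(sprintf("stratum '%s' has fewer than 3 subjects; skipped", lev))
      next
    }
    tab <- reliabilityTable(batchMetrics[batchMetrics$subject_id %in% ids, ],
                            refMetrics[refMetrics$subject_id %in% ids, ],
                            iccCut, mapeCut)
    tab$stratum <- lev
    out[[lev]] <- tab
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
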