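#' CohortSpec: parameters of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the reliability
#' analysis assumes: wake-to-wake days with drawn wake and sleep-onset
#' times, first-order two-state Markov bout dynamics per period
#' (rest/active by day, sleep/wake by night) with known per-epoch
#' transition probabilities, state-conditional lognormal acceleration
#' levels separated at the 40 mg rest threshold, a multiplicative
#' per-day jitter that controls day-to-day (in)stability, and
#' subject-level heterogeneity in transition probabilities and levels
#' so that between-subject variance — the quantity ICC relies on — is
#' present.
#'
#' Transition probabilities are per-60-s-epoch: `dayTpRa` is
#' rest-to-active, `dayTpAr` active-to-rest (day period); `nightTpWs`
#' is wake-to-sleep, `nightTpSw` sleep-to-wake (night period). Mean
#' bout duration in epochs is the reciprocal of the corresponding
#' probability.
#'
#' @slot nSubjects number of subjects.
#' @slot nDays entire days per subject (default 7).
#' @slot wakeTimeMean,wakeTimeSd wake-up clock time, hours.
#' @slot sleepOnsetMean,sleepOnsetSd sleep-onset clock time, hours.
#' @slot dayTpRa,dayTpAr,nightTpWs,nightTpSw cohort-mean per-epoch
#'   transition probabilities, each in (0,1).
#' @slot activeLevelMean,activeLevelSd,restLevelMean,restLevelSd
#'   acceleration level distributions (mg); rest is truncated below
#'   40 mg and active at or above it so binarization recovers the
#'   latent state.
#' @slot dayToDayJitter sd of the lognormal per-day level multiplier;
#'   0 makes all days exchangeable.
#' @slot tpSubjectSd sd of subject effects on the logit of each
#'   transition probability (0 = homogeneous cohort).
#' @slot levelSubjectSd sd of lognormal subject multipliers on the
#'   level means.
#' @slot strata whether to attach balanced sex/age-group labels.
#' @slot seed RNG seed.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "numeric", nDays = "numeric",
                 wakeTimeMean = "numeric", wakeTimeSd = "numeric",
                 sleepOnsetMean = "numeric", sleepOnsetSd = "numeric",
                 dayTpRa = "numeric", dayTpAr = "numeric",
                 nightTpWs = "numeric", nightTpSw = "numeric",
                 activeLevelMean = "numeric", activeLevelSd = "numeric",
                 restLevelMean = "numeric", restLevelSd = "numeric",
                 dayToDayJitter = "numeric", tpSubjectSd = "numeric",
                 levelSubjectSd = "numeric", strata = "logical",
                 seed = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nDays < 1) msg <- c(msg, "nDays must be >= 1")
  p <- c(object@dayTpRa, object@dayTpAr, object@nightTpWs, object@nightTpSw)
  if (any(p <= 0 | p >= 1))
    msg <- c(msg, "all transition probabilities must lie in (0,1)")
  if (object@restLevelMean >= 40)
    msg <- c(msg, "rest level distribution must be supported below 40 mg")
  if (object@activeLevelMean < 40)
    msg <- c(msg, "active level distribution must be supported above 40 mg")
  if (object@wakeTimeMean >= object@sleepOnsetMean)
    msg <- c(msg, "wake time must precede sleep onset within the day")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults describe a realistic older-adult wrist-actigraphy cohort:
#' waking around 07:00 and falling asleep around 23:00 (sd 0.5 h), a
#' fragmented day with mean rest bouts of ~3 min and active bouts of
#' ~4 min, fragmented night sleep typical of older-adult actigraphy
#' (mean sleep bouts ~20 min, night wake bouts ~3 min, sleep
#' efficiency ~87%), rest around 15 mg and activity around 120 mg,
#' moderate day-to-day jitter and subject heterogeneity.
#'
#' @param nSubjects,nDays cohort dimensions.
#' @param wakeTimeMean,wakeTimeSd,sleepOnsetMean,sleepOnsetSd clock
#'   hours.
#' @param dayTpRa,dayTpAr,nightTpWs,nightTpSw per-epoch transition
#'   probabilities in (0,1).
#' @param activeLevelMean,activeLevelSd,restLevelMean,restLevelSd mg.
#' @param dayToDayJitter,tpSubjectSd,levelSubjectSd heterogeneity
#'   scales (see [CohortSpec-class]).
#' @param strata attach balanced sex and age-group labels.
#' @param seed RNG seed.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjects = 100, nDays = 7,
                       wakeTimeMean = 7, wakeTimeSd = 0.5,
                       sleepOnsetMean = 23, sleepOnsetSd = 0.5,
                       dayTpRa = 0.30, dayTpAr = 0.25,
                       nightTpWs = 0.35, nightTpSw = 0.05,
                       activeLevelMean = 120, activeLevelSd = 80,
                       restLevelMean = 15, restLevelSd = 8,
                       dayToDayJitter = 0.15, tpSubjectSd = 0.4,
                       levelSubjectSd = 0.25, strata = FALSE,
                       seed = 1L) {
  new("CohortSpec", nSubjects = nSubjects, nDays = nDays,
      wakeTimeMean = wakeTimeMean, wakeTimeSd = wakeTimeSd,
      sleepOnsetMean = sleepOnsetMean, sleepOnsetSd = sleepOnsetSd,
      dayTpRa = dayTpRa, dayTpAr = dayTpAr,
      nightTpWs = nightTpWs, nightTpSw = nightTpSw,
      activeLevelMean = activeLevelMean, activeLevelSd = activeLevelSd,
      restLevelMean = restLevelMean, restLevelSd = restLevelSd,
      dayToDayJitter = dayToDayJitter, tpSubjectSd = tpSubjectSd,
      levelSubjectSd = levelSubjectSd, strata = strata, seed = seed)
}

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

lnormPars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Two-state Markov chain of length n as alternating geometric bouts.
# p01 = P(0 -> 1), p10 = P(1 -> 0); starts from the stationary law
# unless `start` is given. With `endState`, the chain is conditioned
# on its final state by rejection (used for night periods, which by
# construction begin at sleep onset and end just before wake onset).
# Bout lengths are drawn in chunks so the cost is O(number of bouts).
markovStates <- function(n, p01, p10, start = NA, endState = NA) {
  if (n <= 0L) return(integer(0))
  repeat {
    cur <- if (is.na(start))
      as.integer(stats::runif(1) < p01 / (p01 + p10))
    else as.integer(start)
    states <- integer(0); lens <- integer(0); total <- 0L
    while (total < n) {
      k <- max(16L, as.integer(ceiling((n - total) * (p01 + p10) / 2)) + 8L)
      st <- rep_len(c(cur, 1L - cur), k)
      l <- 1L + stats::rgeom(k, ifelse(st == 0L, p01, p10))
      states <- c(states, st); lens <- c(lens, l)
      total <- total + sum(l)
      cur <- 1L - st[k]
    }
    out <- rep.int(states, lens)[seq_len(n)]
    if (is.na(endState) || out[n] == endState) return(out)
  }
}

drawLevels <- function(n, pars, jitterFac, lower = NULL, upper = NULL) {
  x <- stats::rlnorm(n, pars["meanlog"], pars["sdlog"]) * jitterFac
  if (!is.null(upper)) x <- pmin(x, upper)
  if (!is.null(lower)) x <- pmax(x, lower)
  x
}

#' Generate a synthetic cohort with known bout dynamics
#'
#' Simulates, per subject: daily wake and sleep-onset times on a 60-s
#' grid; a first-order two-state Markov chain per day period
#' (rest/active) and night period (sleep/wake) with the subject's
#' per-epoch transition probabilities; and state-conditional lognormal
#' acceleration levels, scaled by a per-day jitter factor and
#' truncated to keep rest strictly below and activity at or above
#' 40 mg. Wear is complete. The `truth` table of the returned cohort
#' records each subject's drawn transition probabilities and level
#' multipliers in long form (`subject_id,param,value`). Fully
#' reproducible from the spec seed.
#'
#' @param spec a [CohortSpec-class].
#' @return an [EpochCohort-class] with tagged series, partitions,
#'   ground truth and (if requested) strata labels.
#' @examples
#' coh <- generateCohort(cohortSpec(nSubjects = 2, nDays = 2, seed = 42))
#' coh
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  set.seed(spec@seed %% .Machine$integer.max)
  nS <- as.integer(spec@nSubjects); D <- as.integer(spec@nDays)
  restPars <- lnormPars(spec@restLevelMean, spec@restLevelSd)
  activePars <- lnormPars(spec@activeLevelMean, spec@activeLevelSd)
  sleepPars <- lnormPars(max(spec@restLevelMean * 0.3, 1),
                         max(spec@restLevelSd * 0.3, 0.5))
  series <- list(); partitions <- list(); truthRows <- list()
  ids <- sprintf("S%04d", seq_len(nS))
  for (k in seq_len(nS)) {
    sid <- ids[k]
    # subject-level parameters
    tp <- c(ra = spec@dayTpRa, ar = spec@dayTpAr,
            ws = spec@nightTpWs, sw = spec@nightTpSw)
    if (spec@tpSubjectSd > 0)
      tp <- invlogit(logit(tp) + stats::rnorm(4, 0, spec@tpSubjectSd))
    levMult <- if (spec@levelSubjectSd > 0)
      exp(stats::rnorm(2, 0, spec@levelSubjectSd)) else c(1, 1)
    # daily anchors on the 60-s grid, relative to the first wake onset
    wakeClock <- stats::rnorm(D + 1L, spec@wakeTimeMean, spec@wakeTimeSd)
    sleepClock <- stats::rnorm(D, spec@sleepOnsetMean, spec@sleepOnsetSd)
    toGrid <- function(h, d) round((d * 24 + h - wakeClock[1]) * 60) * 60
    w <- toGrid(wakeClock, seq_len(D + 1L) - 1L)
    s <- toGrid(sleepClock, seq_len(D) - 1L)
    # guard against pathological draws breaking the interleaving
    s <- pmin(pmax(s, w[seq_len(D)] + 3600), w[seq_len(D) + 1L] - 3600)
    part <- DayPartition(w, s)

    nTot <- (w[D + 1L] - w[1]) %/% 60L
    ts <- seq(0, by = 60, length.out = nTot)
    accelV <- numeric(nTot); stateV <- rep("wake", nTot)
    dayI <- findInterval(ts, w)
    per <- ifelse(ts < s[dayI], "day", "night")
    for (d in seq_len(D)) {
      jit <- if (spec@dayToDayJitter > 0)
        exp(stats::rnorm(1, 0, spec@dayToDayJitter)) else 1
      iDay <- which(dayI == d & per == "day")
      iNight <- which(dayI == d & per == "night")
      stDay <- markovStates(length(iDay), tp["ra"], tp["ar"])
      # night chain: 0 = sleep, 1 = wake; sleep->wake prob = tp_sw.
      # Conditioned to begin and end asleep: the night period runs from
      # sleep onset to the epoch before wake onset, so its boundary
      # epochs are sleep by definition (this also makes the sleep/wake
      # labels recover the day partition exactly on re-read).
      stNight <- markovStates(length(iNight), tp["sw"], tp["ws"],
                              start = 0L, endState = 0L)
      accelV[iDay] <- ifelse(stDay == 1L,
        drawLevels(length(iDay), activePars, jit * levMult[1], lower = 40),
        drawLevels(length(iDay), restPars, jit * levMult[2], upper = 39.9))
      accelV[iNight] <- ifelse(stNight == 1L,
        drawLevels(length(iNight), restPars, jit * levMult[2], upper = 39.9),
        drawLevels(length(iNight), sleepPars, jit * levMult[2], upper = 39.9))
      stateV[iNight] <- ifelse(stNight == 1L, "wake", "sleep")
    }
    es <- EpochSeries(sid, ts, accelV, state = stateV,
                      dayIndex = dayI, period = per)
    series[[sid]] <- es
    partitions[[sid]] <- part
    truthRows[[sid]] <- data.frame(
      subject_id = sid,
      param = c("day_tp_ra", "day_tp_ar", "night_tp_ws", "night_tp_sw",
                "active_level_mult", "rest_level_mult"),
      value = c(unname(tp), levMult))
  }
  strata <- if (spec@strata) {
    data.frame(subject_id = ids,
               sex = rep_len(c("F", "M"), nS),
               age_group = rep_len(c("<70", ">=70", ">=70", "<70"), nS))
  } else data.frame()
  EpochCohort(series, partitions,
              truth = do.call(rbind, c(truthRows, list(make.row.names = FALSE))),
              strata = strata)
}

#' Generate canonical reference noise with known DFA exponents
#'
#' Validation inputs for the detrended fluctuation analysis: white
#' noise (alpha = 0.5), fractional Gaussian noise with Hurst exponent
#' H (alpha = H), and a random walk (alpha = 1.5). fGn is generated by
#' exact-covariance circulant embedding (Davies-Harte), so the sample
#' has the exact target autocovariance in distribution.
#'
#' @param kind one of `"white"`, `"fgn"`, `"random_walk"`.
#' @param n series length (>= 256).
#' @param hurst Hurst exponent in (0,1), used for `kind = "fgn"`.
#' @param seed RNG seed.
#' @return a numeric vector of length `n`.
#' @export
generateReferenceNoise <- function(kind = c("white", "fgn", "random_walk"),
                                   n, hurst = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 256) stop("n must be >= 256")
  set.seed(seed %% .Machine$integer.max)
  switch(kind,
    white = stats::rnorm(n),
    random_walk = cumsum(stats::rnorm(n)),
    fgn = {
      if (hurst <= 0 || hurst >= 1) stop("hurst must lie in (0,1)")
      fgnCirculant(n, hurst)
    })
}

# Davies-Harte circulant embedding of fractional Gaussian noise.
# gamma(k) = 0.5 * (|k+1|^2H - 2|k|^2H + |k-1|^2H), unit variance.
fgnCirculant <- function(n, H) {
  m <- 2^ceiling(log2(2 * (n - 1)))
  g <- m / 2
  k <- 0:g
  gam <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(gam, rev(gam[2:g]))
  lam <- Re(stats::fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop("circulant embedding is not nonnegative definite for this H/n")
  lam <- pmax(lam, 0)
  a <- complex(length.out = m)
  a[1] <- sqrt(lam[1] / m) * stats::rnorm(1)
  a[g + 1] <- sqrt(lam[g + 1] / m) * stats::rnorm(1)
  u <- stats::rnorm(g - 1); v <- stats::rnorm(g - 1)
  a[2:g] <- sqrt(lam[2:g] / (2 * m)) * complex(real = u, imaginary = v)
  a[(g + 2):m] <- Conj(a[g:2])
  Re(stats::fft(a))[seq_len(n)]
}
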