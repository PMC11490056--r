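# Independent brute-force reference implementations used to
# cross-check the vectorized package code, plus small fixture
# builders. These deliberately use naive loops / stats::aov so they
# share no code path with the implementation under test.

makeHourly <- function(values) {
  stopifnot(length(values) %% 24 == 0)
  D <- length(values) / 24
  cnt <- ifelse(is.na(values), 0L, 60L)
  new("HourlySeries", values = as.numeric(values),
      observedCount = as.integer(cnt),
      dayIndex = rep(seq_len(D), each = 24L),
      hourOfDay = rep(0:23, times = D))
}

naiveIS <- function(values) {
  obs <- which(!is.na(values))
  hrs <- (obs - 1) %% 24
  xs <- values[obs]
  xbar <- mean(xs)
  num <- 0
  for (h in 0:23) {
    v <- xs[hrs == h]
    if (length(v) < 2) return(NA_real_)
    num <- num + (mean(v) - xbar)^2
  }
  den <- 0
  for (x in xs) den <- den + (x - xbar)^2
  if (den == 0) return(NA_real_)
  length(xs) * num / (24 * den)
}

naiveIV <- function(values) {
  obs <- !is.na(values)
  xs <- values[obs]
  N <- length(xs)
  xbar <- mean(xs)
  den <- 0
  for (x in xs) den <- den + (x - xbar)^2
  num <- 0; np <- 0
  for (i in 2:length(values)) {
    if (obs[i] && obs[i - 1]) {
      num <- num + (values[i] - values[i - 1])^2
      np <- np + 1
    }
  }
  if (np == 0 || den == 0) return(NA_real_)
  (num / np) / (den / N)
}

aovICC <- function(x, y) {
  n <- length(x); k <- 2
  df <- data.frame(y = c(x, y),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  a <- stats::anova(stats::aov(y ~ subj + rater, data = df))
  msr <- a["subj", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

naiveMAPE <- function(ref, sim, eps = 1e-8) {
  tot <- 0; n <- 0
  for (i in seq_along(ref)) {
    if (is.finite(ref[i]) && is.finite(sim[i]) && abs(ref[i]) >= eps) {
      tot <- tot + abs(sim[i] - ref[i]) / abs(ref[i])
      n <- n + 1
    }
  }
  if (n == 0) return(NA_real_)
  100 * tot / n
}

# day-period-only binary series on a 60-s grid, for bout tests
dayBinary <- function(states, observed = rep(TRUE, length(states))) {
  new("BinarySeries", states = as.integer(states),
      observed = observed,
      period = rep("day", length(states)),
      dayIndex = rep(1L, length(states)),
      timestamp = seq(0, by = 60, length.out = length(states)))
}

# tiny deterministic cohort shared across tests
smallCohort <- function(n = 4, days = 7, seed = 99, ...) {
  generateCohort(cohortSpec(nSubjects = n, nDays = days, seed = seed, ...))
}
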