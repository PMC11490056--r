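#' Detrended fluctuation analysis scaling exponent
#'
#' First-order DFA: the series is centered and integrated; the profile
#' is split into non-overlapping boxes of size s; a linear trend is
#' removed within each box; F(s) is the root-mean-square residual over
#' all boxes; and alpha is the ordinary-least-squares slope of
#' log F(s) against log s. Box sizes are 12 log2-spaced integers
#' between `minBoxSize` and `min(length/4, maxBoxSize)`. alpha is 0.5
#' for uncorrelated noise, 1 for 1/f dynamics, and 1.5 for Brownian
#' motion; for fractional Gaussian noise alpha equals the Hurst
#' exponent.
#'
#' The default fit range of 10--90 epochs (10--90 min on a 60-s grid)
#' follows standard first-order DFA practice: boxes shorter than
#' about 10 points bias the fluctuation function upward for
#' correlated series, and the upper bound stays below the
#' ultradian/circadian crossover so that alpha captures bout-scale
#' fractal dynamics rather than the daily cycle. A fixed range also
#' makes alpha comparable across recordings of different lengths:
#' with a length-dependent bound, alpha acquires a duration-dependent
#' bias that absolute-agreement reliability comparisons across wear
#' protocols would register as disagreement. For exactly self-affine
#' inputs (the noise validation series) the fit range does not affect
#' the exponent.
#'
#' @param x numeric series (e.g. the concatenated observed 60-s epoch
#'   accelerations); length must be at least `minLength`.
#' @param nBoxSizes number of box sizes on the log2 grid (default 12).
#' @param minLength minimum series length (default 256).
#' @param minBoxSize,maxBoxSize bounds on the box size in epochs
#'   (defaults 10 and 90).
#' @return a [DfaProfile-class], or a list `value = NA, reason = ...`
#'   when the series is too short or has zero variance.
#' @examples
#' wn <- generateReferenceNoise("white", n = 4096, seed = 7)
#' dfaAlpha(wn)
#' @export
dfaAlpha <- function(x, nBoxSizes = 12, minLength = 256,
                     minBoxSize = 10, maxBoxSize = 90) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < minLength)
    return(list(value = NA_real_,
                reason = sprintf("series too short for DFA (%d < %d)", n, minLength)))
  if (stats::var(x) == 0)
    return(list(value = NA_real_, reason = "zero-variance series"))
  y <- cumsum(x - mean(x))
  sMax <- min(n / 4, maxBoxSize)
  sGrid <- unique(round(2^seq(log2(minBoxSize), log2(sMax),
                              length.out = nBoxSizes)))
  sGrid <- sGrid[sGrid >= 4]
  fs <- vapply(sGrid, function(s) {
    m <- n %/% s
    Y <- matrix(y[seq_len(m * s)], nrow = s)
    t <- seq_len(s); tc <- t - mean(t); stt <- sum(tc^2)
    mu <- colMeans(Y)
    b <- as.numeric(crossprod(tc, Y)) / stt
    res <- Y - rep(mu, each = s) - outer(tc, b)
    sqrt(sum(res^2) / (m * s))
  }, numeric(1))
  keep <- fs > 0
  fit <- stats::lm.fit(cbind(1, log(sGrid[keep])), log(fs[keep]))
  new("DfaProfile", boxSizes = as.integer(sGrid),
      fluctuations = fs, alpha = unname(fit$coefficients[2]),
      fitRange = range(sGrid))
}
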