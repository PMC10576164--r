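#' Bayes-factor test for oscillation in a replicated time series
#'
#' The full detection pipeline: replicates are collapsed to their mean with
#' the squared standard error of the mean entering the covariance diagonal
#' (see [collapseReplicates()]), the data are normalized, and the marginal
#' log-likelihood is maximized separately under the diagonal null kernel and
#' the oscillatory alternative kernel. The Bayes factor is
#' `exp(mll_alt - mll_null)`; a Bonferroni-type prior odds `1/nTests`
#' multiplies it before classification against the cutoff (default 14,
#' the Bayes-factor bound equivalent of a 0.005 P-value threshold).
#'
#' @param ds a [RhythmDataset-class].
#' @param nTests number of datasets tested together (prior-odds correction).
#' @param cutoff classification cutoff on the corrected odds (default 14).
#' @param altFamily alternative kernel: `"nonstationary"` (default) or
#'   `"spectral_mixture"` (comparison baseline).
#' @param collapse replicate handling, `"mean_sem"` (default) or `"stack"`.
#' @param normalize normalization, `"zscore"` (default), `"center"`, `"none"`.
#' @param varianceModeration `"pooled"` (default) replaces the per-time-point
#'   squared standard errors estimated from the replicates by their average
#'   across time points before fitting; with typical triplicates each
#'   per-point variance estimate has only 2 degrees of freedom, and treating
#'   those raw estimates as known lets the flexible kernel exploit the points
#'   whose variance happened to be underestimated, inflating null Bayes
#'   factors. Pooling assumes a common replicate noise level across the time
#'   course. `"per_point"` uses the raw squared standard errors. Variances
#'   supplied explicitly in the input dataset are never moderated.
#' @param control a [gpControl()] list; `control$seed` makes the call
#'   deterministic.
#' @return an [OscillationCall-class].
#' @examples
#' t <- seq(0, 48, by = 3)
#' ds <- RhythmDataset(t, sapply(1:3, function(i) 3 * sin(2 * pi * t / 24)))
#' \donttest{bayesFactor(ds, control = gpControl(restarts = 2))}
#' @export
bayesFactor <- function(ds, nTests = 1L, cutoff = 14,
                        altFamily = c("nonstationary", "spectral_mixture"),
                        collapse = c("mean_sem", "stack"),
                        normalize = c("zscore", "center", "none"),
                        varianceModeration = c("pooled", "per_point"),
                        control = gpControl()) {
  altFamily <- match.arg(altFamily)
  collapse <- match.arg(collapse)
  normalize <- match.arg(normalize)
  varianceModeration <- match.arg(varianceModeration)
  if (nTests < 1L) stop("nTests must be >= 1")
  userNV <- length(noiseVar(ds)) > 0L
  work <- if (ncol(obsValues(ds)) > 1L) collapseReplicates(ds, collapse) else ds
  if (collapse == "mean_sem" && varianceModeration == "pooled" && !userNV &&
      length(noiseVar(work)) > 0L)
    work@noiseVar <- rep(mean(work@noiseVar), length(work@noiseVar))
  work <- tryCatch(normalizeDataset(work, normalize),
                   error = function(e) normalizeDataset(work, "center"))
  fitNull <- optimizeHyperparams(work, "diagonal", control)
  fitAlt <- optimizeHyperparams(work, altFamily, control)
  dmll <- mll(fitAlt) - mll(fitNull)
  bf <- exp(dmll)  # may overflow; log10BF stays finite
  l10 <- dmll / log(10)
  odds <- bf / nTests
  label <- classifyOscillation(odds, cutoff = cutoff,
                               log10Odds = l10 - log10(nTests))
  new("OscillationCall", bayesFactor = bf, log10BF = l10,
      posteriorOdds = odds, nTests = as.integer(nTests), label = label,
      fits = list(null = fitNull, alt = fitAlt))
}

#' Prior-odds (Bonferroni-type) correction of a Bayes factor
#'
#' Multiplies the Bayes factor by the prior odds `1/nTests`, the simplest
#' multiplicative multiple-testing penalty: with a single test the Bayes
#' factor is returned unchanged, and the corrected odds decrease
#' monotonically in the number of tests.
#'
#' @param bf positive Bayes factor.
#' @param nTests positive integer number of datasets tested together.
#' @return the corrected posterior odds.
#' @export
priorOddsCorrection <- function(bf, nTests) {
  if (any(nTests < 1)) stop("nTests must be >= 1")
  bf / nTests
}

#' Convert a P-value to its Bayes-factor bound
#'
#' The calibration `-1 / (e * p * ln p)` upper-bounds the Bayes factor
#' achievable at P-value `p` under weak assumptions on the alternative; it
#' lets P-value methods be compared on the Bayes-factor scale. The formula
#' is valid for `p <= 1/e`; above that the bound is clamped to 1 by default
#' (`clamp = FALSE` applies the raw formula everywhere, which some published
#' comparisons do).
#'
#' @param p numeric vector of P-values in (0, 1].
#' @param clamp clamp the bound to 1 for `p > 1/e` (default `TRUE`).
#' @return positive Bayes-factor bounds.
#' @examples
#' pvalueToBFBound(0.005) # ~ 13.9, the origin of the cutoff-14 guideline
#' @export
pvalueToBFBound <- function(p, clamp = TRUE) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  raw <- -1 / (exp(1) * p * log(p))
  raw[p == 1] <- if (clamp) 1 else Inf
  if (clamp) raw[p > exp(-1)] <- 1
  raw
}

#' Classify corrected odds into oscillatory / weak / non-oscillatory
#'
#' Odds at least twice the cutoff are called oscillatory; odds within the
#' weak band (default half to twice the cutoff) are "weak" oscillations;
#' smaller odds are non-oscillatory.
#'
#' @param odds prior-odds-corrected Bayes factor (scalar).
#' @param cutoff positive cutoff, default 14.
#' @param weakBand length-2 interval `[lo, hi)`; default
#'   `c(cutoff / 2, cutoff * 2)`.
#' @param log10Odds optional log10 of `odds`, used instead of `odds` when the
#'   latter overflowed to `Inf`.
#' @return one of `"oscillatory"`, `"weak"`, `"non-oscillatory"`.
#' @export
classifyOscillation <- function(odds, cutoff = 14, weakBand = NULL,
                                log10Odds = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(weakBand)) weakBand <- c(cutoff / 2, cutoff * 2)
  if (length(weakBand) != 2L || weakBand[1L] > weakBand[2L])
    stop("malformed weak band")
  l10 <- if (!is.null(log10Odds) && !is.finite(odds)) log10Odds
         else log10(odds)
  if (l10 >= log10(weakBand[2L])) "oscillatory"
  else if (l10 >= log10(weakBand[1L])) "weak"
  else "non-oscillatory"
}

#' @describeIn OscillationCall-accessors the Bayes factor.
#' @param x an `OscillationCall`.
#' @name OscillationCall-accessors
#' @aliases bfValue log10BF posteriorOdds callLabel
#' @export
setMethod("bfValue", "OscillationCall", function(x) x@bayesFactor)

#' @rdname OscillationCall-accessors
#' @export
setMethod("log10BF", "OscillationCall", function(x) x@log10BF)

#' @rdname OscillationCall-accessors
#' @export
setMethod("posteriorOdds", "OscillationCall", function(x) x@posteriorOdds)

#' @rdname OscillationCall-accessors
#' @export
setMethod("callLabel", "OscillationCall", function(x) x@label)

setMethod("show", "OscillationCall", function(object) {
  cat(sprintf("OscillationCall: BF = %.4g (log10 BF = %.3f)\n",
              object@bayesFactor, object@log10BF))
  if (object@nTests > 1L)
    cat(sprintf("  corrected odds = %.4g (nTests = %d)\n",
                object@posteriorOdds, object@nTests))
  cat(sprintf("  label: %s\n", object@label))
})
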