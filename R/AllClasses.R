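#' @import methods
#' @importFrom stats approx optim optimize sd var lm pf runif rnorm sample
#'   median quantile setNames anova
#' @importFrom utils read.csv write.csv packageVersion capture.output
#' @useDynLib rhythmGP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' RhythmDataset: replicated time-series observations of one signal
#'
#' The canonical container consumed by every detector in the package: an
#' ordered vector of observation times (hours), a matrix of replicate values
#' aligned to those times (missing entries allowed), and an optional vector of
#' per-time-point measurement-error variances (e.g. squared standard errors of
#' the mean of qPCR technical replicates) that enter the Gaussian-process
#' likelihood on the covariance diagonal.
#'
#' @slot times numeric, strictly increasing observation times in hours.
#' @slot values numeric matrix, one row per time point, one column per
#'   replicate; `NA` marks a missing observation.
#' @slot noiseVar numeric, length 0 (absent) or one nonnegative measurement
#'   variance per time point.
#' @slot label character(1), free-text identifier.
#' @export
setClass("RhythmDataset",
  representation(
    times    = "numeric",
    values   = "matrix",
    noiseVar = "numeric",
    label    = "character"
  ),
  prototype(noiseVar = numeric(0), label = NA_character_)
)

setValidity("RhythmDataset", function(object) {
  msg <- character(0)
  n <- length(object@times)
  if (n == 0L)
    msg <- c(msg, "dataset has no time points")
  if (any(!is.finite(object@times)))
    msg <- c(msg, "times must be finite")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@values) != n)
    msg <- c(msg, sprintf("values has %d rows but there are %d times",
                          nrow(object@values), n))
  if (n > 0L && any(rowSums(!is.na(object@values)) == 0L))
    msg <- c(msg, "every time point needs at least one non-missing replicate")
  if (length(object@noiseVar) > 0L) {
    if (length(object@noiseVar) != n)
      msg <- c(msg, "noiseVar must have one entry per time point")
    else if (any(!is.finite(object@noiseVar)) || any(object@noiseVar < 0))
      msg <- c(msg, "noiseVar entries must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Diagonal (white-noise) kernel hyperparameters
#'
#' The null, non-oscillatory covariance: epsilon^2 on the diagonal, zero
#' elsewhere, so values at distinct times are a priori uncorrelated.
#'
#' @slot epsilon numeric(1), positive noise scale.
#' @export
setClass("DiagonalHyperparams",
  representation(epsilon = "numeric"))

setValidity("DiagonalHyperparams", function(object) {
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    "epsilon must be a single positive finite number"
  else TRUE
})

#' Non-stationary oscillatory kernel hyperparameters
#'
#' Hyperparameters of the oscillatory alternative kernel
#' `w(x) w(x') k_gibbs(x,x') cos(2*pi*(x*mu(x) - x'*mu(x'))) + epsilon^2
#' delta_{xx'}`. The latent amplitude `w(x)`, Gibbs lengthscale `l(x)` (hours)
#' and frequency `mu(x)` (cycles/hour) are exponentiated piecewise-linear
#' interpolants of log-scale values held at `anchorTimes`; outside the anchor
#' span the nearest anchor value is held constant, and a single anchor (M = 1)
#' gives constant functions, i.e. the stationary quasi-periodic kernel.
#'
#' @slot wAnchors numeric, log-amplitude values at the anchors.
#' @slot lAnchors numeric, log-lengthscale values (log hours).
#' @slot muAnchors numeric, log-frequency values (log cycles/hour).
#' @slot anchorTimes numeric, ordered anchor locations (hours).
#' @slot epsilon numeric(1), positive noise scale.
#' @export
setClass("NonStationaryHyperparams",
  representation(
    wAnchors    = "numeric",
    lAnchors    = "numeric",
    muAnchors   = "numeric",
    anchorTimes = "numeric",
    epsilon     = "numeric"
  ))

setValidity("NonStationaryHyperparams", function(object) {
  msg <- character(0)
  m <- length(object@anchorTimes)
  if (m < 1L) msg <- c(msg, "need at least one anchor")
  if (length(object@wAnchors) != m || length(object@lAnchors) != m ||
      length(object@muAnchors) != m)
    msg <- c(msg, "anchor vectors must all match length(anchorTimes)")
  if (m > 1L && is.unsorted(object@anchorTimes, strictly = TRUE))
    msg <- c(msg, "anchorTimes must be strictly increasing")
  if (any(!is.finite(c(object@wAnchors, object@lAnchors, object@muAnchors,
                       object@anchorTimes))))
    msg <- c(msg, "anchor values must be finite")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    msg <- c(msg, "epsilon must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' Spectral-mixture kernel hyperparameters
#'
#' Stationary comparison kernel: a weighted sum of Q Gaussian-envelope cosine
#' terms, `sum_q w_q exp(-2 pi^2 tau^2 v_q) cos(2 pi mu_q tau)` with
#' `tau = x - x'`, plus `epsilon^2` on the diagonal.
#'
#' @slot weights numeric, positive component weights (variances).
#' @slot means numeric, component frequencies in cycles/hour (>= 0).
#' @slot variances numeric, positive component bandwidths.
#' @slot epsilon numeric(1), positive noise scale.
#' @export
setClass("SpectralMixtureHyperparams",
  representation(
    weights   = "numeric",
    means     = "numeric",
    variances = "numeric",
    epsilon   = "numeric"
  ))

setValidity("SpectralMixtureHyperparams", function(object) {
  msg <- character(0)
  q <- length(object@weights)
  if (q < 1L) msg <- c(msg, "need at least one mixture component")
  if (length(object@means) != q || length(object@variances) != q)
    msg <- c(msg, "weights, means and variances must share length Q")
  if (any(object@weights <= 0) || any(object@variances <= 0) ||
      any(object@means < 0))
    msg <- c(msg, "weights and variances must be positive, means nonnegative")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    msg <- c(msg, "epsilon must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' A fitted Gaussian-process model
#'
#' Result of type-II maximum-likelihood hyperparameter optimization for one
#' kernel family on one dataset.
#'
#' @slot kernelFamily character(1): "diagonal", "nonstationary" or
#'   "spectral_mixture".
#' @slot hyperparams the family-specific hyperparameter object at the optimum.
#' @slot mll numeric(1), the maximized marginal log-likelihood.
#' @slot trace data.frame with one row per optimizer restart (columns
#'   `restart`, `converged`, `mll`).
#' @export
setClass("GPFit",
  representation(
    kernelFamily = "character",
    hyperparams  = "ANY",
    mll          = "numeric",
    trace        = "data.frame"
  ))

setValidity("GPFit", function(object) {
  msg <- character(0)
  if (!object@kernelFamily %in%
      c("diagonal", "nonstationary", "spectral_mixture"))
    msg <- c(msg, "unknown kernel family")
  if (length(object@mll) != 1L || !is.finite(object@mll))
    msg <- c(msg, "mll must be a single finite number")
  if (nrow(object@trace) > 0L) {
    finite <- object@trace$mll[is.finite(object@trace$mll)]
    if (length(finite) && max(finite) > object@mll + 1e-8)
      msg <- c(msg, "mll must be the maximum over recorded restarts")
  }
  if (length(msg)) msg else TRUE
})

#' An oscillation-detection verdict
#'
#' The Bayes factor `exp(mll_alt - mll_null)` between the oscillatory and the
#' diagonal null fit, the prior-odds-corrected posterior odds, and the
#' resulting label.
#'
#' @slot bayesFactor numeric(1), may overflow to `Inf`; see `log10BF`.
#' @slot log10BF numeric(1), always finite.
#' @slot posteriorOdds numeric(1), Bayes factor times the 1/nTests prior odds.
#' @slot nTests integer(1), number of datasets tested together.
#' @slot label character(1): "oscillatory", "weak" or "non-oscillatory".
#' @slot fits list with elements `null` and `alt`, the two [GPFit] objects.
#' @export
setClass("OscillationCall",
  representation(
    bayesFactor   = "numeric",
    log10BF       = "numeric",
    posteriorOdds = "numeric",
    nTests        = "integer",
    label         = "character",
    fits          = "list"
  ))

setValidity("OscillationCall", function(object) {
  msg <- character(0)
  if (!is.finite(object@log10BF))
    msg <- c(msg, "log10BF must be finite")
  if (object@nTests < 1L)
    msg <- c(msg, "nTests must be >= 1")
  if (!object@label %in% c("oscillatory", "weak", "non-oscillatory"))
    msg <- c(msg, "unknown label")
  if (length(msg)) msg else TRUE
})

#' A synthetic-wave recipe
#'
#' Parameters of one simulated benchmark waveform family, with the replicate,
#' noise and missing-data structure of a typical qPCR time course: by default
#' 3 replicates over 48 h at 3 h spacing (17 time points).
#'
#' @slot family character(1), one of "noise", "stationary_symmetric",
#'   "stationary_sawtooth", "nonstat_decreasing", "nonstat_random_period",
#'   "nonstat_random_sawtooth".
#' @slot params named list of family-specific amplitude/period parameters.
#' @slot sigma numeric(1), replicate Gaussian noise sd.
#' @slot duration,spacing numeric(1), time grid in hours (both endpoints
#'   included).
#' @slot nReplicates integer(1).
#' @slot missingFraction numeric(1) in [0, 1).
#' @slot seed integer(1).
#' @export
setClass("WaveSpec",
  representation(
    family          = "character",
    params          = "list",
    sigma           = "numeric",
    duration        = "numeric",
    spacing         = "numeric",
    nReplicates     = "integer",
    missingFraction = "numeric",
    seed            = "integer"
  ))

setValidity("WaveSpec", function(object) {
  msg <- character(0)
  fams <- c("noise", "stationary_symmetric", "stationary_sawtooth",
            "nonstat_decreasing", "nonstat_random_period",
            "nonstat_random_sawtooth")
  if (!object@family %in% fams)
    msg <- c(msg, paste("family must be one of:", paste(fams, collapse = ", ")))
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@duration / object@spacing + 1 < 4)
    msg <- c(msg, "duration/spacing must yield at least 4 time points")
  if (object@missingFraction < 0 || object@missingFraction >= 1)
    msg <- c(msg, "missingFraction must lie in [0, 1)")
  pp <- unlist(object@params[names(object@params) %in%
                             c("tau", "tau1", "tau2", "muPeriod")])
  if (length(pp) && any(pp <= 0)) msg <- c(msg, "periods must be positive")
  if (length(msg)) msg else TRUE
})

#' ROC curve and area under it
#'
#' @slot fpr,tpr numeric, nondecreasing from (0,0) to (1,1).
#' @slot auc numeric(1) in [0, 1]; equals the Mann-Whitney statistic of the
#'   scores (ties half-credit).
#' @slot detector character(1).
#' @slot nPos,nNeg integer(1).
#' @export
setClass("ROCResult",
  representation(
    fpr      = "numeric",
    tpr      = "numeric",
    auc      = "numeric",
    detector = "character",
    nPos     = "integer",
    nNeg     = "integer"
  ))

setValidity("ROCResult", function(object) {
  msg <- character(0)
  if (length(object@fpr) != length(object@tpr))
    msg <- c(msg, "fpr and tpr must have equal length")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msg <- c(msg, "fpr and tpr must be nondecreasing")
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A population of mean-field-coupled Poincare oscillators
#'
#' N phase-amplitude limit-cycle oscillators in Cartesian coordinates
#' (x_i, y_i), each with limit-cycle radius A_i, radial relaxation rate
#' gamma_i (1/h) and free-running period tau_i (h), coupled through the mean
#' field M = (K/N) sum_i x_i applied to dx_i/dt.
#'
#' @slot tau,amplitude,gamma numeric, per-oscillator parameters (length N).
#' @slot coupling numeric(1), mean-field coupling strength K.
#' @slot state numeric matrix N x 2, columns x and y.
#' @slot noiseScale numeric(1), additive white-noise scale for stochastic
#'   integration (0 = deterministic).
#' @slot seed integer(1).
#' @export
setClass("PoincarePopulation",
  representation(
    tau        = "numeric",
    amplitude  = "numeric",
    gamma      = "numeric",
    coupling   = "numeric",
    state      = "matrix",
    noiseScale = "numeric",
    seed       = "integer"
  ))

setValidity("PoincarePopulation", function(object) {
  msg <- character(0)
  n <- length(object@tau)
  if (n < 1L) msg <- c(msg, "need at least one oscillator")
  if (length(object@amplitude) != n || length(object@gamma) != n)
    msg <- c(msg, "tau, amplitude and gamma must share length N")
  if (any(object@tau <= 0)) msg <- c(msg, "periods tau must be positive")
  if (any(object@gamma <= 0)) msg <- c(msg, "relaxation rates must be positive")
  if (any(object@amplitude < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (!all(dim(object@state) == c(n, 2L)))
    msg <- c(msg, "state must be an N x 2 matrix")
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
  if (length(msg)) msg else TRUE
})
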