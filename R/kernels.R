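#' Constructors for kernel hyperparameter objects
#'
#' @param epsilon positive noise scale.
#' @return a [DiagonalHyperparams-class].
#' @rdname kernel-hyperparams
#' @export
diagonalHyperparams <- function(epsilon) {
  new("DiagonalHyperparams", epsilon = as.numeric(epsilon))
}

#' @param wAnchors,lAnchors,muAnchors log-scale anchor values for the latent
#'   amplitude, lengthscale (log hours) and frequency (log cycles/hour)
#'   functions; recycled to `length(anchorTimes)` if scalar.
#' @param anchorTimes ordered anchor locations (hours).
#' @rdname kernel-hyperparams
#' @export
nonstationaryHyperparams <- function(wAnchors, lAnchors, muAnchors,
                                     anchorTimes, epsilon) {
  m <- length(anchorTimes)
  rec <- function(v) if (length(v) == 1L) rep(as.numeric(v), m) else as.numeric(v)
  new("NonStationaryHyperparams",
      wAnchors = rec(wAnchors), lAnchors = rec(lAnchors),
      muAnchors = rec(muAnchors), anchorTimes = as.numeric(anchorTimes),
      epsilon = as.numeric(epsilon))
}

#' @param weights,means,variances spectral-mixture component parameters
#'   (weights and variances positive; means in cycles/hour).
#' @rdname kernel-hyperparams
#' @export
spectralMixtureHyperparams <- function(weights, means, variances, epsilon) {
  new("SpectralMixtureHyperparams", weights = as.numeric(weights),
      means = as.numeric(means), variances = as.numeric(variances),
      epsilon = as.numeric(epsilon))
}

#' Evaluate an exponentiated piecewise-linear latent function
#'
#' The input-dependent hyperparameter functions w(x), l(x), mu(x) of the
#' non-stationary kernel are parametrized as `exp(s(x))` with `s` the linear
#' interpolant of log-scale values at ordered anchor times; outside the
#' anchor span the nearest anchor value is held constant, and a single
#' anchor gives a globally constant function.
#'
#' @param anchors log-scale values at the anchors.
#' @param anchorTimes ordered anchor locations.
#' @param x numeric vector of evaluation points.
#' @return positive numeric vector `exp(s(x))`.
#' @export
latentEval <- function(anchors, anchorTimes, x) {
  if (length(anchors) == 0L) stop("empty anchors")
  if (length(anchors) != length(anchorTimes))
    stop("anchors and anchorTimes must be aligned")
  if (length(anchors) == 1L) return(rep(exp(anchors), length(x)))
  s <- approx(anchorTimes, anchors, xout = x, rule = 2)$y
  exp(s)
}

#' Gibbs kernel with input-dependent lengthscale
#'
#' `k(x, x') = sqrt(2 l(x) l(x') / (l(x)^2 + l(x')^2)) *
#' exp(-(x - x')^2 / (l(x)^2 + l(x')^2))`: symmetric, in (0, 1], equal to 1
#' iff `x == x'`, and reducing to the squared-exponential kernel with
#' lengthscale c when `l` is constant at c.
#'
#' @param x,x2 numeric input locations (vectorized, recycled).
#' @param lFn a strictly positive function of the input, `l(x)`.
#' @return numeric kernel values.
#' @export
gibbsKernel <- function(x, x2, lFn) {
  l1 <- lFn(x)
  l2 <- lFn(x2)
  if (any(l1 <= 0) || any(l2 <= 0)) stop("lengthscale function must be positive")
  s <- l1^2 + l2^2
  sqrt(2 * l1 * l2 / s) * exp(-(x - x2)^2 / s)
}

.ns_latents <- function(times, hp) {
  list(w  = latentEval(hp@wAnchors,  hp@anchorTimes, times),
       l  = latentEval(hp@lAnchors,  hp@anchorTimes, times),
       mu = latentEval(hp@muAnchors, hp@anchorTimes, times))
}

.ns_cov <- function(times1, times2, hp, noise = FALSE) {
  a <- .ns_latents(times1, hp)
  b <- .ns_latents(times2, hp)
  T1 <- matrix(times1, length(times1), length(times2))
  T2 <- matrix(times2, length(times1), length(times2), byrow = TRUE)
  L1 <- matrix(a$l, length(times1), length(times2))
  L2 <- matrix(b$l, length(times1), length(times2), byrow = TRUE)
  S <- L1^2 + L2^2
  gib <- sqrt(2 * L1 * L2 / S) * exp(-(T1 - T2)^2 / S)
  phase <- 2 * pi * (T1 * matrix(a$mu, nrow(T1), ncol(T1)) -
                     T2 * matrix(b$mu, nrow(T1), ncol(T1), byrow = TRUE))
  K <- outer(a$w, b$w) * gib * cos(phase)
  if (noise) K <- K + hp@epsilon^2 * outer(times1, times2, "==")
  if (any(!is.finite(K)))
    stop("non-finite non-stationary kernel entries; check w/l/mu anchors")
  K
}

.sm_cov <- function(times1, times2, hp, noise = FALSE) {
  D <- outer(times1, times2, "-")
  K <- matrix(0, length(times1), length(times2))
  for (q in seq_along(hp@weights)) {
    K <- K + hp@weights[q] *
      exp(-2 * pi^2 * D^2 * hp@variances[q]) * cos(2 * pi * hp@means[q] * D)
  }
  if (noise) K <- K + hp@epsilon^2 * (D == 0 & outer(times1, times2, "=="))
  K
}

#' @describeIn covMatrix diagonal null kernel: `epsilon^2 * I`.
#' @export
setMethod("covMatrix", signature(times = "numeric", hp = "DiagonalHyperparams"),
  function(times, hp) {
    diag(hp@epsilon^2, nrow = length(times))
  })

#' @describeIn covMatrix non-stationary oscillatory kernel
#'   `w(t_i) w(t_j) k_gibbs(t_i, t_j) cos(2 pi (t_i mu(t_i) - t_j mu(t_j)))`
#'   plus `epsilon^2` on the diagonal.
#' @export
setMethod("covMatrix",
  signature(times = "numeric", hp = "NonStationaryHyperparams"),
  function(times, hp) {
    K <- .ns_cov(times, times, hp)
    K <- (K + t(K)) / 2  # enforce exact symmetry against rounding
    K + diag(hp@epsilon^2, nrow = length(times))
  })

#' @describeIn covMatrix stationary spectral-mixture kernel plus `epsilon^2`
#'   on the diagonal.
#' @export
setMethod("covMatrix",
  signature(times = "numeric", hp = "SpectralMixtureHyperparams"),
  function(times, hp) {
    K <- .sm_cov(times, times, hp)
    K <- (K + t(K)) / 2
    K + diag(hp@epsilon^2, nrow = length(times))
  })

#' @describeIn crossCovMatrix diagonal kernel: zero off the identical-time
#'   entries (latent signal is pure noise).
#' @export
setMethod("crossCovMatrix",
  signature(times1 = "numeric", times2 = "numeric", hp = "DiagonalHyperparams"),
  function(times1, times2, hp) {
    matrix(0, length(times1), length(times2))
  })

#' @describeIn crossCovMatrix non-stationary kernel without the noise term.
#' @export
setMethod("crossCovMatrix",
  signature(times1 = "numeric", times2 = "numeric",
            hp = "NonStationaryHyperparams"),
  function(times1, times2, hp) .ns_cov(times1, times2, hp))

#' @describeIn crossCovMatrix spectral-mixture kernel without the noise term.
#' @export
setMethod("crossCovMatrix",
  signature(times1 = "numeric", times2 = "numeric",
            hp = "SpectralMixtureHyperparams"),
  function(times1, times2, hp) .sm_cov(times1, times2, hp))

#' Serialize kernel hyperparameters to a flat named list
#'
#' Round-trips through [hpFromList()] (and hence JSON/YAML) for reproducible
#' refit-free rescoring.
#'
#' @param hp a hyperparameter object.
#' @return a named list with a `family` element.
#' @export
hpToList <- function(hp) {
  if (is(hp, "DiagonalHyperparams"))
    return(list(family = "diagonal", epsilon = hp@epsilon))
  if (is(hp, "NonStationaryHyperparams"))
    return(list(family = "nonstationary", wAnchors = hp@wAnchors,
                lAnchors = hp@lAnchors, muAnchors = hp@muAnchors,
                anchorTimes = hp@anchorTimes, epsilon = hp@epsilon))
  if (is(hp, "SpectralMixtureHyperparams"))
    return(list(family = "spectral_mixture", weights = hp@weights,
                means = hp@means, variances = hp@variances,
                epsilon = hp@epsilon))
  stop("unknown hyperparameter class")
}

#' @rdname hpToList
#' @param x a list produced by [hpToList()].
#' @export
hpFromList <- function(x) {
  switch(x$family,
    diagonal = diagonalHyperparams(x$epsilon),
    nonstationary = nonstationaryHyperparams(x$wAnchors, x$lAnchors,
                                             x$muAnchors, x$anchorTimes,
                                             x$epsilon),
    spectral_mixture = spectralMixtureHyperparams(x$weights, x$means,
                                                  x$variances, x$epsilon),
    stop("unknown family: ", x$family))
}
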