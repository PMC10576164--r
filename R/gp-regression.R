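#' Optimizer configuration for GP hyperparameter fitting
#'
#' Defaults encode circadian-range search priors on normalized data: restart
#' initializations draw the Gibbs lengthscale log-uniformly from 3-48 h, the
#' period 1/mu from 6-48 h, the amplitude w from 0.1-3 and the noise scale
#' epsilon from 0.01-2; the frequency is box-bounded to periods in 4-96 h
#' (Nyquist-adjacent floor for 3 h sampling, ceiling at twice a 48 h record).
#'
#' @param restarts number of optimizer restarts (default 8).
#' @param seed integer seed making the restarts reproducible.
#' @param anchors number of latent-function anchor points M (default 3).
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param smQ spectral-mixture component count (default 2).
#' @param boundsPeriod allowed period range (h) for the frequency latents.
#' @param priorPeriod,priorLengthscale,priorW,priorEps restart-initialization
#'   ranges (log-uniform draws).
#' @param jitter relative diagonal jitter added before factorization.
#' @return a list of class `gpControl`.
#' @export
gpControl <- function(restarts = 8L, seed = 1L, anchors = 3L, maxit = 100L,
                      smQ = 2L,
                      boundsPeriod = c(4, 96),
                      priorPeriod = c(6, 48),
                      priorLengthscale = c(3, 48),
                      priorW = c(0.1, 3),
                      priorEps = c(0.01, 2),
                      jitter = 1e-8) {
  structure(list(restarts = as.integer(restarts), seed = as.integer(seed),
                 anchors = as.integer(anchors), maxit = as.integer(maxit),
                 smQ = as.integer(smQ), boundsPeriod = boundsPeriod,
                 priorPeriod = priorPeriod,
                 priorLengthscale = priorLengthscale, priorW = priorW,
                 priorEps = priorEps, jitter = jitter),
            class = "gpControl")
}

.ds_vectors <- function(ds) {
  if (ncol(ds@values) != 1L)
    stop("GP fitting expects a single-replicate dataset; ",
         "collapseReplicates() first")
  y <- as.numeric(ds@values[, 1L])
  if (anyNA(y)) stop("missing values must be dropped before fitting")
  nv <- if (length(ds@noiseVar)) ds@noiseVar else rep(0, length(y))
  list(t = ds@times, y = y, nv = nv)
}

#' Exact Gaussian-process marginal log-likelihood
#'
#' Computes `-1/2 y' C^-1 y - 1/2 log|C| - (n/2) log(2 pi)` with
#' `C = K(hyperparams) + diag(noiseVar)` built by the plain-R [covMatrix()]
#' path and factorized by Cholesky after adding a relative jitter of
#' `1e-8 * mean(diag(C))`. Returns `-Inf` when C is not factorizable. The
#' optimizer uses an equivalent compiled evaluation; this function is the
#' readable reference implementation and the one users call directly.
#'
#' @param ds a single-replicate [RhythmDataset-class] (see
#'   [collapseReplicates()]).
#' @param hp a kernel hyperparameter object.
#' @return the marginal log-likelihood (scalar).
#' @export
marginalLogLikelihood <- function(ds, hp) {
  d <- .ds_vectors(ds)
  C <- covMatrix(d$t, hp) + diag(d$nv, nrow = length(d$t))
  C <- C + diag(1e-8 * mean(diag(C)), nrow = nrow(C))
  L <- tryCatch(t(chol(C)), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  alpha <- forwardsolve(L, d$y)
  -0.5 * sum(alpha^2) - sum(log(diag(L))) - 0.5 * length(d$y) * log(2 * pi)
}

.family_of <- function(hp) {
  if (is(hp, "DiagonalHyperparams")) "diagonal"
  else if (is(hp, "NonStationaryHyperparams")) "nonstationary"
  else if (is(hp, "SpectralMixtureHyperparams")) "spectral_mixture"
  else stop("unknown hyperparameter class")
}

#' Fit GP hyperparameters by type-II maximum likelihood
#'
#' Multi-restart bounded quasi-Newton (L-BFGS-B) maximization of the
#' marginal log-likelihood over log-hyperparameters. The single-parameter
#' diagonal family is optimized by golden-section search to tolerance 1e-10.
#' Restart initializations are drawn from the log-uniform priors in
#' `control`; the best restart wins, ties broken by lowest restart index.
#' Deterministic given `control$seed`.
#'
#' @param ds a single-replicate [RhythmDataset-class] with at least 4
#'   distinct time points.
#' @param family `"diagonal"`, `"nonstationary"` or `"spectral_mixture"`.
#' @param control a [gpControl()] list.
#' @return a [GPFit-class].
#' @export
optimizeHyperparams <- function(ds,
                                family = c("nonstationary", "diagonal",
                                           "spectral_mixture"),
                                control = gpControl()) {
  family <- match.arg(family)
  d <- .ds_vectors(ds)
  if (length(unique(d$t)) < 4L)
    stop("need at least 4 distinct time points to fit")

  if (family == "diagonal") {
    obj <- function(le) .mll_diagonal_cpp(d$y, d$nv, le)
    opt <- optimize(obj, lower = log(1e-4), upper = log(10),
                    maximum = TRUE, tol = 1e-10)
    hp <- diagonalHyperparams(exp(opt$maximum))
    return(new("GPFit", kernelFamily = family, hyperparams = hp,
               mll = opt$objective,
               trace = data.frame(restart = 1L, converged = TRUE,
                                  mll = opt$objective)))
  }

  M <- if (family == "nonstationary") control$anchors else control$smQ
  anchorTimes <- if (family == "nonstationary") {
    if (M == 1L) mean(range(d$t)) else seq(min(d$t), max(d$t), length.out = M)
  } else numeric(0)

  logMuBounds <- rev(-log(control$boundsPeriod))  # period box -> frequency box
  if (family == "nonstationary") {
    lower <- c(rep(log(1e-3), M), rep(log(1), M), rep(logMuBounds[1L], M),
               log(1e-3))
    upper <- c(rep(log(10), M), rep(log(96), M), rep(logMuBounds[2L], M),
               log(10))
    objective <- function(th) .mll_nonstationary_cpp(d$t, d$y, d$nv, th,
                                                     anchorTimes)
  } else {
    lower <- c(rep(log(1e-3), M), rep(logMuBounds[1L], M), rep(log(1e-6), M),
               log(1e-3))
    upper <- c(rep(log(10), M), rep(logMuBounds[2L], M), rep(log(1), M),
               log(10))
    objective <- function(th) .mll_spectral_mixture_cpp(d$t, d$y, d$nv, th, M)
  }
  # L-BFGS-B cannot digest non-finite objectives
  safeNeg <- function(th) {
    v <- objective(th)
    if (!is.finite(v)) 1e10 else -v
  }

  drawInit <- function() {
    lw <- runif(M, log(control$priorW[1L]), log(control$priorW[2L]))
    lm <- -runif(M, log(control$priorPeriod[1L]), log(control$priorPeriod[2L]))
    le <- runif(1L, log(control$priorEps[1L]), log(control$priorEps[2L]))
    th <- if (family == "nonstationary") {
      ll <- runif(M, log(control$priorLengthscale[1L]),
                  log(control$priorLengthscale[2L]))
      c(lw, ll, lm, le)
    } else {
      lv <- runif(M, log(1e-5), log(1e-2))  # component bandwidths
      c(lw, lm, lv, le)
    }
    pmin(pmax(th, lower), upper)
  }

  # two deterministic circadian-range initializations precede the random
  # restarts so that period-24 optima are found reliably when they exist
  informedInit <- function(r) {
    lw <- rep(0, M)
    le <- log(0.1)
    if (family == "nonstationary") {
      if (r == 1L) c(lw, rep(log(24), M), rep(log(1 / 24), M), le)
      else c(lw, rep(log(12), M), rep(log(1 / 16), M), le)
    } else {
      if (r == 1L) c(lw, rep(log(1 / 24), M), rep(log(1e-4), M), le)
      else c(lw, rep(log(1 / 16), M), rep(log(1e-3), M), le)
    }
  }

  best <- NULL
  trace <- data.frame(restart = integer(0), converged = logical(0),
                      mll = numeric(0))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(control$seed)
  for (r in seq_len(control$restarts)) {
    th0 <- if (r <= 2L) pmin(pmax(informedInit(r), lower), upper)
           else drawInit()
    tries <- 0L
    while (!is.finite(objective(th0)) && tries < 20L) {
      th0 <- drawInit()
      tries <- tries + 1L
    }
    fit <- tryCatch(
      optim(th0, safeNeg, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = control$maxit)),
      error = function(e) NULL)
    if (is.null(fit)) {
      trace <- rbind(trace, data.frame(restart = r, converged = FALSE,
                                       mll = -Inf))
      next
    }
    val <- objective(fit$par)  # true MLL (not the clamped surrogate)
    trace <- rbind(trace, data.frame(restart = r,
                                     converged = fit$convergence == 0L,
                                     mll = val))
    if (is.finite(val) && (is.null(best) || val > best$val + 1e-12))
      best <- list(par = fit$par, val = val)
  }
  if (is.null(best))
    stop("all restarts failed to produce a finite marginal likelihood; trace:\n",
         paste(capture.output(print(trace)), collapse = "\n"))

  hp <- if (family == "nonstationary") {
    nonstationaryHyperparams(best$par[seq_len(M)],
                             best$par[M + seq_len(M)],
                             best$par[2L * M + seq_len(M)],
                             anchorTimes, exp(best$par[3L * M + 1L]))
  } else {
    spectralMixtureHyperparams(exp(best$par[seq_len(M)]),
                               exp(best$par[M + seq_len(M)]),
                               exp(best$par[2L * M + seq_len(M)]),
                               exp(best$par[3L * M + 1L]))
  }
  new("GPFit", kernelFamily = family, hyperparams = hp, mll = best$val,
      trace = trace)
}

#' @describeIn GPFit-accessors maximized marginal log-likelihood.
#' @param x a `GPFit`.
#' @name GPFit-accessors
#' @aliases mll kernelFamily hyperparams
#' @export
setMethod("mll", "GPFit", function(x) x@mll)

#' @rdname GPFit-accessors
#' @export
setMethod("kernelFamily", "GPFit", function(x) x@kernelFamily)

#' @rdname GPFit-accessors
#' @export
setMethod("hyperparams", "GPFit", function(x) x@hyperparams)

setMethod("show", "GPFit", function(object) {
  cat(sprintf("GPFit [%s]: MLL = %.4f over %d restart(s)\n",
              object@kernelFamily, object@mll, nrow(object@trace)))
})

#' Posterior predictive curve of a fitted GP
#'
#' Standard Gaussian-process prediction under the fitted kernel: mean
#' `K* C^-1 y` and marginal standard deviation of a new noisy observation,
#' `sqrt(k(t*, t*) + epsilon^2 - k*' C^-1 k*)`, where
#' `C = K + epsilon^2 I + diag(noiseVar)`. Far from all observations the sd
#' reverts to the prior `sqrt(w(t)^2 + epsilon^2)`.
#'
#' @param ds the single-replicate [RhythmDataset-class] the fit was made on.
#' @param fit a [GPFit-class].
#' @param queryTimes finite numeric vector of prediction times (hours).
#' @return a data.frame with columns `time`, `mean`, `sd`.
#' @export
gpPosterior <- function(ds, fit, queryTimes) {
  if (any(!is.finite(queryTimes))) stop("query times must be finite")
  d <- .ds_vectors(ds)
  hp <- fit@hyperparams
  C <- covMatrix(d$t, hp) + diag(d$nv, nrow = length(d$t))
  C <- C + diag(1e-8 * mean(diag(C)), nrow = nrow(C))
  L <- t(chol(C))
  Kstar <- crossCovMatrix(queryTimes, d$t, hp)
  alpha <- backsolve(t(L), forwardsolve(L, d$y))
  postMean <- as.numeric(Kstar %*% alpha)
  V <- forwardsolve(L, t(Kstar))
  priorVar <- diag(crossCovMatrix(queryTimes, queryTimes, hp)) + hp@epsilon^2
  postVar <- pmax(priorVar - colSums(V^2), 0)
  data.frame(time = queryTimes, mean = postMean, sd = sqrt(postVar))
}
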