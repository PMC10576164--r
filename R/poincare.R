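#' Construct a population of mean-field-coupled Poincare oscillators
#'
#' Each oscillator obeys
#' `dx/dt = gamma x (A - r) - (2 pi / tau) y + M`,
#' `dy/dt = gamma y (A - r) + (2 pi / tau) x` with `r = sqrt(x^2 + y^2)` and mean field
#' `M = (K/N) sum_i x_i`: a limit cycle of radius A approached at radial
#' relaxation rate gamma, rotating with period tau, nudged by the population
#' mean of x. The default population emulates a dish of dexamethasone-naive
#' cells: N = 100 oscillators with periods drawn from Normal(24, 1.5) h,
#' gamma = 0.1 1/h, initial radii on the limit cycle and initial phases
#' uniform on the circle (a dephased population whose mean field is flat
#' until coupling synchronizes it).
#'
#' @param N number of oscillators.
#' @param tau free-running periods (h); scalar or length N; default drawn
#'   from Normal(tauMean, tauSd) under `seed`.
#' @param amplitude limit-cycle radii A_i; scalar or length N.
#' @param gamma radial relaxation rates (1/h); scalar or length N.
#' @param coupling mean-field coupling strength K.
#' @param noiseScale additive white-noise scale for stochastic integration.
#' @param tauMean,tauSd period distribution when `tau` is not given.
#' @param seed integer seed for periods and initial phases.
#' @return a [PoincarePopulation-class].
#' @export
poincarePopulation <- function(N = 100L, tau = NULL, amplitude = 1,
                               gamma = 0.1, coupling = 0, noiseScale = 0,
                               tauMean = 24, tauSd = 1.5, seed = 1L) {
  N <- as.integer(N)
  rec <- function(v) if (length(v) == 1L) rep(v, N) else v
  state <- withr_seed(seed, {
    if (is.null(tau)) tau <- rnorm(N, tauMean, tauSd)
    tau <- rec(tau)
    phases <- runif(N, 0, 2 * pi)
    list(tau = tau, phases = phases)
  })
  tau <- state$tau
  amplitude <- rec(amplitude)
  r0 <- amplitude
  new("PoincarePopulation", tau = tau, amplitude = amplitude,
      gamma = rec(gamma), coupling = coupling,
      state = cbind(x = r0 * cos(state$phases), y = r0 * sin(state$phases)),
      noiseScale = noiseScale, seed = as.integer(seed))
}

setMethod("show", "PoincarePopulation", function(object) {
  cat(sprintf("PoincarePopulation: N = %d, K = %g, noise = %g, mean tau = %.1f h\n",
              length(object@tau), object@coupling, object@noiseScale,
              mean(object@tau)))
})

#' Integrate a Poincare oscillator population
#'
#' Fixed-step Euler-Maruyama integration (deterministic Euler when the
#' noise scale is 0) with additive noise on both state variables. Returns
#' the sampled trajectory of every oscillator plus a [RhythmDataset-class]
#' of the population-average x(t) (the qPCR-like observable), optionally
#' replicated with added measurement noise.
#'
#' @param pop a [PoincarePopulation-class].
#' @param tEnd end time (h).
#' @param dt integration step (h), default 0.01.
#' @param sampleEvery output sampling interval (h), default 3.
#' @param tStart first sampled time (h), default 0 (set > 0 to discard a
#'   transient).
#' @param nReplicates replicates of the population average in the returned
#'   dataset.
#' @param replicateNoise sd of Gaussian measurement noise per replicate.
#' @param seed integer seed for the integration noise and replicate noise.
#' @return a list with `times`, `x` (samples x N matrix), `y`, `meanX`, and
#'   `dataset` (a [RhythmDataset-class]).
#' @export
simulatePoincare <- function(pop, tEnd = 48, dt = 0.01, sampleEvery = 3,
                             tStart = 0, nReplicates = 1L,
                             replicateNoise = 0, seed = pop@seed) {
  if (dt > sampleEvery || sampleEvery > tEnd)
    stop("require dt <= sampleEvery <= tEnd")
  N <- length(pop@tau)
  x <- pop@state[, 1L]
  y <- pop@state[, 2L]
  omega <- 2 * pi / pop@tau
  gamma <- pop@gamma
  A <- pop@amplitude
  K <- pop@coupling
  maxR <- 100 * max(A, 1e-3)
  nSteps <- round(tEnd / dt)
  stepsPerSample <- round(sampleEvery / dt)
  sampleTimes <- seq(0, tEnd, by = sampleEvery)
  keep <- sampleTimes >= tStart
  Xs <- matrix(NA_real_, sum(keep), N)
  Ys <- matrix(NA_real_, sum(keep), N)
  row <- 0L
  sq <- sqrt(dt) * pop@noiseScale
  withr_seed(seed, {
    if (0 >= tStart) {
      row <- 1L
      Xs[1L, ] <- x
      Ys[1L, ] <- y
    }
    for (s in seq_len(nSteps)) {
      r <- sqrt(x^2 + y^2)
      M <- K * mean(x)
      dx <- (gamma * x * (A - r) - omega * y + M) * dt
      dy <- (gamma * y * (A - r) + omega * x) * dt
      if (pop@noiseScale > 0) {
        dx <- dx + sq * rnorm(N)
        dy <- dy + sq * rnorm(N)
      }
      x <- x + dx
      y <- y + dy
      if (any(sqrt(x^2 + y^2) > maxR))
        stop("integration unstable (radius blew up); decrease dt = ", dt)
      if (s %% stepsPerSample == 0L && (s * dt) >= tStart - 1e-9) {
        row <- row + 1L
        Xs[row, ] <- x
        Ys[row, ] <- y
      }
    }
  }, offset = 7L)
  times <- sampleTimes[keep]
  meanX <- rowMeans(Xs)
  vals <- if (nReplicates > 1L || replicateNoise > 0) {
    withr_seed(seed, meanX +
      matrix(rnorm(length(meanX) * nReplicates, 0, replicateNoise),
             length(meanX), nReplicates), offset = 11L)
  } else matrix(meanX, ncol = 1L)
  ds <- RhythmDataset(times - min(times), vals, label = "poincare_meanfield")
  list(times = times, x = Xs, y = Ys, meanX = meanX, dataset = ds)
}

#' Bayes-factor sensitivity scan over amplitude and coupling
#'
#' For each (amplitude, coupling) grid cell, simulates the population,
#' samples a 36 h window of the population average at 3 h spacing with 3
#' noisy replicates, runs the Bayes-factor detector, and records the median
#' log10 Bayes factor over seeds. Captures how single-cell amplitude and
#' intercellular coupling each push a noisy, dephased population over the
#' detectability threshold.
#'
#' @param amplitudes,couplings numeric grids (nonempty).
#' @param N population size.
#' @param noiseScale integration noise scale.
#' @param nSeeds seeds per cell.
#' @param replicateNoise measurement noise added to each replicate.
#' @param control a [gpControl()] list for the detector.
#' @param dt integration step (h).
#' @param seed master seed.
#' @return a data.frame with columns `amplitude`, `coupling`,
#'   `medianLog10BF`.
#' @export
bfSensitivityScan <- function(amplitudes, couplings, N = 100L,
                              noiseScale = 0.1, nSeeds = 3L,
                              replicateNoise = 0.05,
                              control = gpControl(restarts = 4L), dt = 0.05,
                              seed = 1L) {
  if (!length(amplitudes) || !length(couplings)) stop("grids must be nonempty")
  out <- expand.grid(amplitude = amplitudes, coupling = couplings)
  out$medianLog10BF <- NA_real_
  for (i in seq_len(nrow(out))) {
    l10 <- vapply(seq_len(nSeeds), function(s) {
      pop <- poincarePopulation(N = N, amplitude = out$amplitude[i],
                                coupling = out$coupling[i],
                                noiseScale = noiseScale,
                                seed = seed + 1000L * s + i)
      sim <- simulatePoincare(pop, tEnd = 48, dt = dt, sampleEvery = 3,
                              tStart = 12, nReplicates = 3L,
                              replicateNoise = replicateNoise)
      log10BF(bayesFactor(sim$dataset, control = control))
    }, numeric(1))
    out$medianLog10BF[i] <- median(l10)
  }
  out
}
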