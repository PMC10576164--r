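#' Construct a synthetic-wave recipe
#'
#' Six waveform families cover the benchmark taxonomy: pure Gaussian noise
#' (`noise`, the non-oscillatory class), a sum of two sines
#' (`stationary_symmetric`), a sawtooth (`stationary_sawtooth`), a sine with
#' monotonically decreasing period `A sin(2 pi t / (1 + |t - tau|))`
#' (`nonstat_decreasing`, `tau >= 48`), a sine whose period is redrawn from
#' `Normal(muPeriod, sdPeriod)` at the start of every cycle
#' (`nonstat_random_period`), and a sawtooth with per-cycle period drawn
#' from `Uniform(tau1, tau2)` (`nonstat_random_sawtooth`). All families share
#' the replicated qPCR-like geometry: by default 3 replicates over 48 h at
#' 3 h spacing, both endpoints included (17 time points), with independent
#' `Normal(0, sigma)` noise per replicate per time point.
#'
#' @param family one of the six family names above.
#' @param A,A1,A2 amplitudes.
#' @param tau,tau1,tau2 periods (hours).
#' @param muPeriod,sdPeriod mean and sd of the per-cycle period for
#'   `nonstat_random_period`.
#' @param sigma replicate Gaussian noise sd.
#' @param duration,spacing time grid (hours), endpoints inclusive.
#' @param nReplicates number of replicates.
#' @param missingFraction fraction of time points to drop (applied by
#'   [genWave()] via [applyMissingness()]).
#' @param seed integer seed.
#' @return a [WaveSpec-class].
#' @export
waveSpec <- function(family, A = 1, A1 = 1, A2 = 1, tau = 24, tau1 = 18,
                     tau2 = 26, muPeriod = 24, sdPeriod = 1.33, sigma = 0.1,
                     duration = 48, spacing = 3, nReplicates = 3L,
                     missingFraction = 0, seed = 1L) {
  new("WaveSpec", family = family,
      params = list(A = A, A1 = A1, A2 = A2, tau = tau, tau1 = tau1,
                    tau2 = tau2, muPeriod = muPeriod, sdPeriod = sdPeriod),
      sigma = sigma, duration = duration, spacing = spacing,
      nReplicates = as.integer(nReplicates),
      missingFraction = missingFraction, seed = as.integer(seed))
}

setMethod("show", "WaveSpec", function(object) {
  cat(sprintf("WaveSpec [%s]: sigma = %g, %d replicates, %g h at %g h spacing, missing %g\n",
              object@family, object@sigma, object@nReplicates,
              object@duration, object@spacing, object@missingFraction))
})

# period sequence for the random-period families: draw until the cycle
# starts cover the full duration; cycle start phi_k = cumsum of periods
.draw_cycles <- function(drawFn, duration) {
  periods <- numeric(0)
  total <- 0
  while (total <= duration) {
    p <- drawFn()
    while (p <= 0) p <- drawFn()  # guard against nonpositive period draws
    periods <- c(periods, p)
    total <- total + p
  }
  starts <- c(0, cumsum(periods))
  list(periods = periods, starts = starts[-length(starts)])
}

.frac <- function(z) z - floor(z)

#' Deterministic waveform of a wave recipe
#'
#' The noiseless waveform `f(t)` shared by all replicates, evaluated at `t`.
#' For the random-period families the per-cycle period sequence is drawn
#' from the spec's seed, so the waveform itself is reproducible.
#'
#' @param spec a [WaveSpec-class].
#' @param t numeric vector of times (hours).
#' @return numeric vector `f(t)`.
#' @export
waveform <- function(spec, t) {
  p <- spec@params
  switch(spec@family,
    noise = rep(0, length(t)),
    stationary_symmetric =
      p$A1 * sin(2 * pi * t / p$tau1) + p$A2 * sin(2 * pi * t / p$tau2),
    stationary_sawtooth = p$A * .frac(t / p$tau),
    nonstat_decreasing = {
      if (p$tau < 48) stop("nonstat_decreasing requires tau >= 48")
      p$A * sin(2 * pi * t / (1 + abs(t - p$tau)))
    },
    nonstat_random_period = {
      cyc <- withr_seed(spec@seed, .draw_cycles(
        function() rnorm(1L, p$muPeriod, p$sdPeriod), spec@duration))
      k <- findInterval(t, cyc$starts)
      p$A * sin(2 * pi * (t - cyc$starts[k]) / cyc$periods[k])
    },
    nonstat_random_sawtooth = {
      cyc <- withr_seed(spec@seed, .draw_cycles(
        function() runif(1L, p$tau1, p$tau2), spec@duration))
      k <- findInterval(t, cyc$starts)
      p$A * .frac((t - cyc$starts[k]) / cyc$periods[k])
    },
    stop("invalid wave family: ", spec@family))
}

# evaluate expr under a temporary RNG state seeded with `seed + offset`
withr_seed <- function(seed, expr, offset = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed((as.numeric(seed) + offset) %% 2147483647)
  force(expr)
}

#' Generate a replicated synthetic wave
#'
#' Evaluates the deterministic waveform on the inclusive time grid
#' `t = 0, spacing, ..., duration`, adds independent `Normal(0, sigma)`
#' noise per replicate per time point, and applies the spec's missingness
#' fraction. Reproducible from the spec's seed: the period sequence (where
#' applicable), the replicate noise and the dropped time points all derive
#' from it.
#'
#' @param spec a [WaveSpec-class].
#' @return a [RhythmDataset-class].
#' @export
genWave <- function(spec) {
  validObject(spec)
  t <- seq(0, spec@duration, by = spec@spacing)
  f <- waveform(spec, t)
  vals <- withr_seed(spec@seed,
    f + matrix(rnorm(length(t) * spec@nReplicates, 0, spec@sigma),
               length(t), spec@nReplicates),
    offset = 1L)
  ds <- RhythmDataset(t, vals, label = spec@family)
  if (spec@missingFraction > 0)
    ds <- applyMissingness(ds, spec@missingFraction, seed = spec@seed + 2L)
  ds
}

#' Randomly drop time points from a dataset
#'
#' Removes `floor(fraction * n + 0.5)` time points chosen uniformly without
#' replacement; the same time points are removed from every replicate, as in
#' the missing-data regime of sparsely sampled experiments.
#'
#' @param ds a [RhythmDataset-class].
#' @param fraction fraction in [0, 1) of time points to drop.
#' @param seed integer seed; the same seed reproduces the same dropped set.
#' @return the thinned [RhythmDataset-class].
#' @export
applyMissingness <- function(ds, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  if (fraction == 0) return(ds)
  n <- nTimePoints(ds)
  ndrop <- floor(fraction * n + 0.5)
  if (n - ndrop < 4L)
    stop("missingness would leave fewer than 4 time points")
  drop <- withr_seed(seed, sample(n, ndrop))
  keep <- sort(setdiff(seq_len(n), drop))
  nv <- if (length(ds@noiseVar)) ds@noiseVar[keep] else numeric(0)
  new("RhythmDataset", times = ds@times[keep],
      values = ds@values[keep, , drop = FALSE], noiseVar = nv,
      label = ds@label)
}

#' Generate a labeled oscillatory/non-oscillatory benchmark collection
#'
#' `nPerClass` waves from each recipe with per-wave seeds derived
#' deterministically from the master seed; labels are 1 for the oscillatory
#' spec and 0 for the null spec.
#'
#' @param oscSpec,nullSpec [WaveSpec-class] recipes sharing grid geometry.
#' @param nPerClass waves per class.
#' @param seed master seed.
#' @return a list with elements `datasets` (list of [RhythmDataset-class])
#'   and `labels` (integer vector).
#' @export
makeBenchmarkPair <- function(oscSpec, nullSpec, nPerClass, seed = 1L) {
  if (oscSpec@duration != nullSpec@duration ||
      oscSpec@spacing != nullSpec@spacing)
    stop("specs must share grid geometry")
  seeds <- withr_seed(seed, sample.int(2147483646L, 2L * nPerClass))
  gen1 <- function(spec, s) {
    spec@seed <- as.integer(s)
    genWave(spec)
  }
  datasets <- c(lapply(seeds[seq_len(nPerClass)], gen1, spec = oscSpec),
                lapply(seeds[nPerClass + seq_len(nPerClass)], gen1,
                       spec = nullSpec))
  list(datasets = datasets,
       labels = rep(c(1L, 0L), each = nPerClass))
}

#' Figure-style wave and benchmark presets
#'
#' Named parameter sets for the benchmark waveforms: `fig2a`/`fig2b` the
#' low-noise (sigma 0.1) half-missing noise and two-sine pair
#' (A1 = A2 = 3, tau1 = 18, tau2 = 26); `fig2d`/`fig2e` the high-noise
#' (sigma 1) no-missing noise and sawtooth (A = 5, tau = 18) pair;
#' `fig3a`/`fig3b` sigma 0.1 half-missing noise and decreasing-period sine
#' (A = 5, tau = 72); `fig3d`/`fig3e` sigma 0.5 half-missing noise and
#' random-period sine (A = 1.5, period ~ Normal(24, 1.33)); `fig3g`/`fig3h`
#' sigma 0.1 no-missing noise and random-period sawtooth (A = 5,
#' period ~ Uniform(12, 30)).
#'
#' @param name preset name.
#' @param seed integer seed stored in the spec.
#' @return a [WaveSpec-class].
#' @export
wavePreset <- function(name = c("fig2a", "fig2b", "fig2d", "fig2e", "fig3a",
                                "fig3b", "fig3d", "fig3e", "fig3g", "fig3h"),
                       seed = 1L) {
  name <- match.arg(name)
  switch(name,
    fig2a = waveSpec("noise", sigma = 0.1, missingFraction = 0.5, seed = seed),
    fig2b = waveSpec("stationary_symmetric", A1 = 3, A2 = 3, tau1 = 18,
                     tau2 = 26, sigma = 0.1, missingFraction = 0.5,
                     seed = seed),
    fig2d = waveSpec("noise", sigma = 1, seed = seed),
    fig2e = waveSpec("stationary_sawtooth", A = 5, tau = 18, sigma = 1,
                     seed = seed),
    fig3a = waveSpec("noise", sigma = 0.1, missingFraction = 0.5, seed = seed),
    fig3b = waveSpec("nonstat_decreasing", A = 5, tau = 72, sigma = 0.1,
                     missingFraction = 0.5, seed = seed),
    fig3d = waveSpec("noise", sigma = 0.5, missingFraction = 0.5, seed = seed),
    fig3e = waveSpec("nonstat_random_period", A = 1.5, muPeriod = 24,
                     sdPeriod = 1.33, sigma = 0.5, missingFraction = 0.5,
                     seed = seed),
    fig3g = waveSpec("noise", sigma = 0.1, seed = seed),
    fig3h = waveSpec("nonstat_random_sawtooth", A = 5, tau1 = 12, tau2 = 30,
                     sigma = 0.1, seed = seed))
}

#' @rdname wavePreset
#' @details `benchmarkPreset()` returns the oscillatory/null recipe pair
#'   behind each ROC benchmark: `fig2` = fig2b vs fig2a, `fig2f` = fig2e vs
#'   fig2d, `fig3c` = fig3b vs fig3a, `fig3f` = fig3e vs fig3d, `fig3i` =
#'   fig3h vs fig3g.
#' @export
benchmarkPreset <- function(name = c("fig2", "fig2f", "fig3c", "fig3f",
                                     "fig3i")) {
  name <- match.arg(name)
  pair <- switch(name,
    fig2  = c("fig2b", "fig2a"),
    fig2f = c("fig2e", "fig2d"),
    fig3c = c("fig3b", "fig3a"),
    fig3f = c("fig3e", "fig3d"),
    fig3i = c("fig3h", "fig3g"))
  list(osc = wavePreset(pair[1L]), null = wavePreset(pair[2L]))
}
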