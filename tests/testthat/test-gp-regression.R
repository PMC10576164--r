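test_that("marginal likelihood reproduces closed-form Gaussian cases", {
  # two zero observations, unit diagonal covariance: -log(2 pi)
  ds2 <- RhythmDataset(c(0, 3), c(0, 0), dropEmpty = FALSE)
  expect_equal(marginalLogLikelihood(ds2, diagonalHyperparams(1)),
               -log(2 * pi), tolerance = 1e-6)
  # single observation a under a standard normal: -a^2/2 - log(2 pi)/2
  a <- 1.7
  ds1 <- RhythmDataset(5, a, dropEmpty = FALSE)
  expect_equal(marginalLogLikelihood(ds1, diagonalHyperparams(1)),
               -0.5 * a^2 - 0.5 * log(2 * pi), tolerance = 1e-6)
})

test_that("Cholesky MLL, compiled MLL and the dense-algebra oracle agree", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    t <- sort(runif(n, 0, 48))
    y <- rnorm(n)
    nv <- runif(n, 0, 0.5)
    ds <- RhythmDataset(t, y, noiseVar = nv, dropEmpty = FALSE)
    anchorTimes <- seq(min(t), max(t), length.out = 3)
    hp <- randomNSHyperparams(anchorTimes)
    ref <- mllOracle(ds, hp)
    expect_equal(marginalLogLikelihood(ds, hp), ref, tolerance = 1e-8)
    theta <- c(hp@wAnchors, hp@lAnchors, hp@muAnchors, log(hp@epsilon))
    expect_equal(rhythmGP:::.mll_nonstationary_cpp(t, y, nv, theta,
                                                   anchorTimes),
                 ref, tolerance = 1e-8)
    # diagonal family closed form
    hpd <- diagonalHyperparams(runif(1, 0.1, 2))
    expect_equal(marginalLogLikelihood(ds, hpd),
                 rhythmGP:::.mll_diagonal_cpp(y, nv, log(hpd@epsilon)),
                 tolerance = 1e-7)
    # spectral mixture path
    hps <- spectralMixtureHyperparams(runif(2, 0.1, 2), runif(2, 0.02, 0.2),
                                      runif(2, 1e-5, 1e-2), runif(1, 0.1, 1))
    expect_equal(rhythmGP:::.mll_spectral_mixture_cpp(
                   t, y, nv, c(log(hps@weights), log(hps@means),
                               log(hps@variances), log(hps@epsilon)), 2L),
                 mllOracle(ds, hps), tolerance = 1e-8)
  }
})

test_that("diagonal fit recovers the noise scale of pure noise", {
  # MLE of a pure Gaussian scale: epsilon-hat ~ population sd of the data
  for (s in 1:5) {
    ds <- normalizeDataset(collapseReplicates(makeNoiseDataset(seed = s)),
                           "center")
    ds@noiseVar <- numeric(0)
    fit <- optimizeHyperparams(ds, "diagonal")
    y <- obsValues(ds)[, 1]
    expect_equal(hyperparams(fit)@epsilon, sqrt(mean(y^2)), tolerance = 0.2)
    # and the maximized MLL matches the closed-form plug-in value
    expect_equal(mll(fit),
                 marginalLogLikelihood(ds, diagonalHyperparams(sqrt(mean(y^2)))),
                 tolerance = 1e-6)
  }
})

test_that("the oscillatory kernel recovers a 24 h period from a clean sine", {
  t <- grid48
  ds <- RhythmDataset(t, sin(2 * pi * t / 24))
  ds <- normalizeDataset(ds, "zscore")
  fit <- optimizeHyperparams(ds, "nonstationary", gpControl(seed = 5))
  hp <- hyperparams(fit)
  muBar <- mean(latentEval(hp@muAnchors, hp@anchorTimes, t))
  expect_gte(muBar, 1 / 26)
  expect_lte(muBar, 1 / 22)
})

test_that("more restarts never decrease the fitted likelihood, and fits are reproducible", {
  ds <- normalizeDataset(collapseReplicates(makeSineDataset(seed = 8)))
  f1 <- optimizeHyperparams(ds, "nonstationary", gpControl(restarts = 1, seed = 4))
  f8 <- optimizeHyperparams(ds, "nonstationary", gpControl(restarts = 8, seed = 4))
  expect_gte(mll(f8), mll(f1))
  expect_equal(nrow(f8@trace), 8L)

  g8 <- optimizeHyperparams(ds, "nonstationary", gpControl(restarts = 8, seed = 4))
  expect_equal(f8, g8)
})

test_that("optimization does not disturb the caller's RNG stream", {
  ds <- normalizeDataset(collapseReplicates(makeSineDataset(seed = 8)))
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(optimizeHyperparams(ds, "diagonal"))
  invisible(optimizeHyperparams(ds, "nonstationary", fastControl()))
  expect_identical(rnorm(3), before)
})

test_that("posterior prediction interpolates, reverts to the prior, and is flat for the null", {
  t <- grid48
  ds <- RhythmDataset(t, sin(2 * pi * t / 24))

  # diagonal kernel: no cross-covariance, prior mean zero everywhere new
  fitd <- optimizeHyperparams(ds, "diagonal")
  postd <- gpPosterior(ds, fitd, c(1.5, 25.5))
  expect_equal(postd$mean, c(0, 0))

  # noise-free interpolation with a near-zero epsilon
  hp <- nonstationaryHyperparams(log(1), log(12), log(1 / 24), 24, 1e-5)
  fit <- new("GPFit", kernelFamily = "nonstationary", hyperparams = hp,
             mll = 0, trace = data.frame())
  post <- gpPosterior(ds, fit, t)
  expect_equal(post$mean, sin(2 * pi * t / 24), tolerance = 1e-4)

  # far from the data the sd reverts to the prior sqrt(w^2 + eps^2)
  hpfar <- nonstationaryHyperparams(log(1.3), log(5), log(1 / 24), 24, 0.2)
  fitfar <- new("GPFit", kernelFamily = "nonstationary", hyperparams = hpfar,
                mll = 0, trace = data.frame())
  far <- gpPosterior(ds, fitfar, 500)
  expect_equal(far$sd, sqrt(1.3^2 + 0.2^2), tolerance = 1e-6)
  expect_error(gpPosterior(ds, fitfar, c(1, NA)), "finite")
})
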