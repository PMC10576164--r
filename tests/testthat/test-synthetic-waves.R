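test_that("noiseless waveforms evaluate to their closed forms", {
  saw <- waveSpec("stationary_sawtooth", A = 5, tau = 18, sigma = 0)
  expect_equal(waveform(saw, 9), 2.5)          # {9/18} = 0.5
  expect_equal(waveform(saw, c(0, 18, 27)), c(0, 0, 2.5))

  dec <- waveSpec("nonstat_decreasing", A = 5, tau = 72, sigma = 0)
  expect_equal(waveform(dec, 0), 0)
  expect_equal(waveform(dec, 48), 5 * sin(2 * pi * 48 / 25))
  expect_error(waveform(waveSpec("nonstat_decreasing", tau = 30), 0), ">= 48")

  sym <- waveSpec("stationary_symmetric", A1 = 3, A2 = 3, tau1 = 18,
                  tau2 = 26, sigma = 0)
  expect_equal(waveform(sym, 0), 0)
  expect_equal(waveform(sym, 6), 3 * sin(2 * pi / 3) + 3 * sin(12 * pi / 26))

  expect_equal(waveform(waveSpec("noise", sigma = 1), grid48), rep(0, 17))
})

test_that("noiseless replicates are identical; noisy replicates differ", {
  dsn <- genWave(waveSpec("stationary_symmetric", A1 = 3, A2 = 3, sigma = 0))
  v <- obsValues(dsn)
  expect_equal(v[, 1], v[, 2])
  expect_equal(v[, 1], v[, 3])
  dsy <- genWave(waveSpec("stationary_symmetric", A1 = 3, A2 = 3, sigma = 0.5))
  expect_false(any(obsValues(dsy)[, 1] == obsValues(dsy)[, 2]))
})

test_that("the default grid spans 0-48 h inclusive at 3 h spacing", {
  ds <- genWave(waveSpec("noise", sigma = 0.1))
  expect_equal(obsTimes(ds), seq(0, 48, by = 3))
  expect_equal(dim(obsValues(ds)), c(17L, 3L))
})

test_that("generated noise matches its nominal scale", {
  spec <- waveSpec("noise", sigma = 0.7, duration = 48, spacing = 3,
                   nReplicates = 200L, seed = 5)
  draws <- as.vector(obsValues(genWave(spec)))  # 3400 draws
  spec2 <- waveSpec("noise", sigma = 0.7, nReplicates = 400L, seed = 6)
  draws <- c(draws, as.vector(obsValues(genWave(spec2))))
  expect_equal(sd(draws), 0.7, tolerance = 0.05)
})

test_that("random-period families share one period sequence across replicates", {
  spec <- waveSpec("nonstat_random_period", A = 1.5, muPeriod = 24,
                   sdPeriod = 1.33, sigma = 0, seed = 3)
  v <- obsValues(genWave(spec))
  expect_equal(v[, 1], v[, 3])
  # regenerating from the same spec reproduces the waveform exactly
  expect_equal(waveform(spec, grid48), waveform(spec, grid48))

  # sine families reset phase at 0 at each cycle start: continuous there
  set.seed(3)
  cyc <- rhythmGP:::.draw_cycles(function() rnorm(1, 24, 1.33), 48)
  starts <- cyc$starts[-1]
  expect_equal(waveform(spec, starts), rep(0, length(starts)),
               tolerance = 1e-12)
  eps <- 1e-8
  expect_equal(waveform(spec, starts - eps), rep(0, length(starts)),
               tolerance = 1e-5)

  # sawtooth resets are discontinuous: just below a boundary the wave sits
  # near its amplitude, at the boundary it drops to 0
  sawspec <- waveSpec("nonstat_random_sawtooth", A = 5, tau1 = 12, tau2 = 30,
                      sigma = 0, seed = 9)
  set.seed(9)
  cyc2 <- rhythmGP:::.draw_cycles(function() runif(1, 12, 30), 48)
  b <- cyc2$starts[2]
  expect_equal(waveform(sawspec, b), 0)
  expect_gt(waveform(sawspec, b - 1e-6), 4.9)
})

test_that("missingness drops the stated number of points, identically across replicates", {
  ds <- genWave(waveSpec("noise", sigma = 0.5))
  expect_identical(applyMissingness(ds, 0), ds)
  half <- applyMissingness(ds, 0.5, seed = 4)
  expect_equal(nTimePoints(half), 8L)          # floor(0.5*17 + 0.5) = 9 dropped
  expect_identical(applyMissingness(ds, 0.5, seed = 4), half)
  expect_false(identical(applyMissingness(ds, 0.5, seed = 5), half))
  expect_true(all(obsTimes(half) %in% obsTimes(ds)))
  expect_error(applyMissingness(ds, 0.8), "fewer than 4")
  expect_error(applyMissingness(ds, 1), "fraction")
})

test_that("benchmark collections are labeled, sized, and reproducible", {
  pair <- benchmarkPreset("fig2")
  coll <- makeBenchmarkPair(pair$osc, pair$null, 5, seed = 2)
  expect_length(coll$datasets, 10L)
  expect_equal(coll$labels, rep(c(1L, 0L), each = 5))
  coll2 <- makeBenchmarkPair(pair$osc, pair$null, 5, seed = 2)
  expect_equal(obsValues(coll$datasets[[3]]), obsValues(coll2$datasets[[3]]))
  expect_false(isTRUE(all.equal(obsValues(coll$datasets[[1]]),
                                obsValues(coll$datasets[[2]]))))

  tiny <- makeBenchmarkPair(pair$osc, pair$null, 1, seed = 1)
  expect_equal(tiny$labels, c(1L, 0L))

  bad <- pair$osc
  bad@duration <- 24
  expect_error(makeBenchmarkPair(bad, pair$null, 2), "geometry")
})

test_that("presets carry the documented parameters", {
  p <- wavePreset("fig2b")
  expect_equal(p@params$A1, 3)
  expect_equal(p@params$tau2, 26)
  expect_equal(p@missingFraction, 0.5)
  expect_equal(p@sigma, 0.1)
  expect_equal(wavePreset("fig3e")@params$sdPeriod, 1.33)
  expect_equal(wavePreset("fig3h")@params$tau1, 12)
  expect_equal(wavePreset("fig2d")@sigma, 1)
  expect_equal(benchmarkPreset("fig3c")$osc@family, "nonstat_decreasing")
})
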