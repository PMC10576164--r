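test_that("ROC construction handles separation, ties, and inversion", {
  perfect <- rocCurve(c(5, 4, 3, 1, 0.5, 0.1), c(1, 1, 1, 0, 0, 0))
  expect_equal(auc(perfect), 1)
  expect_equal(perfect@fpr[1], 0)
  expect_equal(perfect@tpr[length(perfect@tpr)], 1)

  allTied <- rocCurve(rep(2, 10), rep(c(1, 0), 5))
  expect_equal(auc(allTied), 0.5)

  set.seed(1)
  sc <- rnorm(40)
  lab <- rbinom(40, 1, 0.5)
  lab[1:2] <- c(0, 1)  # both classes guaranteed
  expect_equal(auc(rocCurve(sc, lab)) + auc(rocCurve(sc, 1 - lab)), 1,
               tolerance = 1e-12)
  expect_error(rocCurve(1:5, rep(1, 5)), "both classes")
})

test_that("trapezoid AUC equals the rank-based Mann-Whitney statistic", {
  set.seed(33)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    sc <- sample(round(rnorm(n), sample(0:2, 1)))  # coarse rounding forces ties
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
    r <- rank(sc)
    n1 <- sum(lab == 1)
    n0 <- sum(lab == 0)
    mw <- (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(auc(rocCurve(sc, lab)), mw, tolerance = 1e-12)
  }
})

test_that("cosinor detects a clean cosine and respects its grid correction", {
  t <- grid48
  ds <- RhythmDataset(t, 2 * cos(2 * pi * t / 24 + 1) + 5)
  expect_lt(cosinorPvalue(ds, periods = c(20, 21.5, 23, 24.5, 26)), 1e-6)

  noise <- makeNoiseDataset(seed = 17)
  p1 <- cosinorPvalue(noise, periods = 24)
  p5 <- cosinorPvalue(noise, periods = c(20, 21.5, 23, 24.5, 26))
  expect_lte(p5, 1)
  expect_gte(p5, p1 * 1)  # multiplicity can only raise the corrected value
  expect_error(cosinorPvalue(RhythmDataset(0:3 * 3, 1:4)), "5 observations")
})

test_that("cosinor type-I error on pure noise is near nominal", {
  set.seed(71)
  p <- replicate(100, {
    t <- grid48
    ds <- RhythmDataset(t, matrix(rnorm(17 * 3), 17, 3))
    cosinorPvalue(ds)
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.10)
  # and not hopelessly conservative either
  expect_gte(mean(p < 0.5), 0.2)
})

test_that("Lomb-Scargle periodogram flags sinusoids and stays calm on noise", {
  t <- grid48
  # a clean sinusoid on 17 points peaks at z ~ (n-1)/2 = 8, so the null tail
  # gives p ~ M exp(-8) ~ 2e-3: small, but bounded below by the record length
  ds <- RhythmDataset(t, 3 * sin(2 * pi * t / 24))
  expect_lt(lombScarglePvalue(ds), 0.01)
  # stacking the replicates sharpens it by orders of magnitude
  ds3 <- RhythmDataset(t, sapply(1:3, function(i) 3 * sin(2 * pi * t / 24)))
  expect_lt(lombScarglePvalue(collapseReplicates(ds3, "stack")), 1e-8)

  flat <- RhythmDataset(t, rep(2.5, 17))
  expect_equal(lombScarglePvalue(flat), 1)

  # peak height for a clean sinusoid on n points approaches (n-1)/2
  o <- rhythmGP:::.stacked_obs(ds)
  y <- o$y - mean(o$y)
  w <- 2 * pi / 24
  tau <- atan2(sum(sin(2 * w * o$t)), sum(cos(2 * w * o$t))) / (2 * w)
  ct <- cos(w * (o$t - tau)); st <- sin(w * (o$t - tau))
  z24 <- (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) /
    (2 * var(o$y))
  expect_equal(z24, (length(y) - 1) / 2, tolerance = 0.05)
})

test_that("per-frequency Lomb-Scargle power on white noise is Exp(1)", {
  set.seed(55)
  z <- replicate(300, {
    t <- grid48
    y <- rnorm(17)
    yc <- y - mean(y)
    w <- 2 * pi / 17.3  # fixed off-grid-period probe frequency
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / (2 * var(y))
  })
  ks <- suppressWarnings(stats::ks.test(z, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("collections are scored under a common contract", {
  pair <- benchmarkPreset("fig2")
  coll <- makeBenchmarkPair(pair$osc, pair$null, 1, seed = 3)
  sc <- scoreCollection(coll, "odegp", control = fastControl())
  expect_equal(nrow(sc), 2L)
  expect_true(all(is.finite(sc$score)))
  expect_gt(sc$score[sc$label == 1], sc$score[sc$label == 0])

  t <- grid48
  clean <- list(datasets = list(RhythmDataset(t, 3 * sin(2 * pi * t / 24))),
                labels = 1L)
  expect_gt(scoreCollection(clean, "cosinor")$score, 6)

  flat <- list(datasets = list(RhythmDataset(t, rep(1, 17))),
               labels = 0L)
  expect_lt(abs(scoreCollection(flat, "lomb_scargle")$score), 0.1)

  # adapter contract: any scalar-scoring function plugs in
  ad <- scoreCollection(coll, function(ds) sd(obsValues(ds), na.rm = TRUE))
  expect_equal(nrow(ad), 2L)

  # failures are kept in the table at the worst observed score
  bomb <- function(ds) if (sd(obsValues(ds)) > 1) stop("boom") else 0.2
  fb <- scoreCollection(coll, bomb)
  expect_true(any(fb$failed))
  expect_equal(fb$score[fb$failed], min(fb$score))
  expect_error(scoreCollection(coll, "nonesuch"), "unknown detector")
})

test_that("runBenchmark returns per-detector AUCs and tolerates an empty detector list", {
  res <- runBenchmark("fig2", detectors = character(0), nPerClass = 2)
  expect_equal(nrow(res$table), 0L)

  outDir <- withr::local_tempdir()
  res2 <- runBenchmark("fig2", detectors = c("cosinor", "lomb_scargle"),
                       nPerClass = 10, seed = 6, outDir = outDir)
  expect_equal(res2$table$detector, c("cosinor", "lomb_scargle"))
  expect_true(all(res2$table$auc >= 0 & res2$table$auc <= 1))
  expect_true(file.exists(file.path(outDir, "auc_table.csv")))
  expect_true(file.exists(file.path(outDir, "roc_cosinor.csv")))
})

test_that("noisier waves are harder for every internal detector", {
  mkpair <- function(sigma) {
    osc <- waveSpec("stationary_symmetric", A1 = 0.5, A2 = 0.5, tau1 = 18,
                    tau2 = 26, sigma = sigma)
    nul <- waveSpec("noise", sigma = sigma)
    makeBenchmarkPair(osc, nul, 15, seed = 12)
  }
  lo <- mkpair(0.1)
  hi <- mkpair(1)
  for (det in c("cosinor", "lomb_scargle")) {
    aucLo <- auc(rocCurve(scoreCollection(lo, det)$score, lo$labels))
    aucHi <- auc(rocCurve(scoreCollection(hi, det)$score, hi$labels))
    expect_gte(aucLo, aucHi)
  }
})
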