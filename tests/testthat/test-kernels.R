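test_that("latent functions interpolate, hold at boundaries, and stay constant with one anchor", {
  expect_equal(latentEval(log(2), 10, x = c(-5, 0, 99)), rep(2, 3))
  # linear interpolation of log values: midpoint of log(1), log(e) is 1/2
  expect_equal(latentEval(c(log(1), 1), c(0, 48), x = 24), exp(0.5))
  expect_equal(latentEval(c(log(3), log(7)), c(0, 48), x = -10), 3)
  expect_equal(latentEval(c(log(3), log(7)), c(0, 48), x = 100), 7)
  expect_error(latentEval(numeric(0), numeric(0), 1), "empty")
})

test_that("Gibbs kernel matches its closed form and stationary limit", {
  lconst <- function(x) rep(2, length(x))
  expect_equal(gibbsKernel(5, 5, lconst), 1)
  # constant lengthscale c: squared exponential exp(-d^2 / (2 c^2))
  d <- c(0.5, 1, 4, 9)
  expect_equal(gibbsKernel(d, rep(0, 4), lconst), exp(-d^2 / (2 * 4)),
               tolerance = 1e-14)
  # zero lag with l(x)=1, l(x')=3: prefactor sqrt(2*1*3/(1+9)) = sqrt(6/10)
  lvar <- function(x) ifelse(x < 1, 1, 3)
  expect_equal(gibbsKernel(0, 2, lvar), sqrt(6 / 10) * exp(-4 / 10))
  expect_equal(sqrt(6 / 10), 0.7745966692414834)
  expect_error(gibbsKernel(0, 1, function(x) rep(-1, length(x))), "positive")
})

test_that("diagonal kernel matrices are epsilon^2 identities", {
  expect_equal(covMatrix(c(0, 3, 6), diagonalHyperparams(1)), diag(3))
  expect_equal(diag(covMatrix(1:4, diagonalHyperparams(0.5))), rep(0.25, 4))
  expect_equal(dim(covMatrix(numeric(0), diagonalHyperparams(1))), c(0L, 0L))
})

test_that("non-stationary kernel has the stated diagonal and nests the stationary case", {
  t <- seq(0, 48, by = 3)
  hp <- nonstationaryHyperparams(log(1.5), log(10), log(1 / 24),
                                 anchorTimes = 24, epsilon = 0.3)
  K <- covMatrix(t, hp)
  expect_equal(diag(K), rep(1.5^2 + 0.3^2, length(t)))
  expect_equal(K, t(K))

  # constant anchors reproduce the closed-form stationary quasi-periodic kernel
  D <- outer(t, t, "-")
  Kref <- 1.5^2 * exp(-D^2 / (2 * 100)) * cos(2 * pi * D / 24) +
    diag(0.3^2, length(t))
  expect_equal(K, Kref, tolerance = 1e-12)

  # multiple constant anchors give the same matrix (M = 1 vs M = 3)
  hp3 <- nonstationaryHyperparams(rep(log(1.5), 3), rep(log(10), 3),
                                  rep(log(1 / 24), 3),
                                  anchorTimes = c(0, 24, 48), epsilon = 0.3)
  expect_equal(covMatrix(t, hp3), K, tolerance = 1e-12)

  # as w -> 0 the kernel collapses onto the diagonal null
  hpw <- nonstationaryHyperparams(log(1e-9), log(10), log(1 / 24), 24, 0.3)
  expect_lt(norm(covMatrix(t, hpw) - covMatrix(t, diagonalHyperparams(0.3)),
                 "2"), 1e-15)
})

test_that("spectral mixture kernel limits behave as expected", {
  t <- seq(0, 48, by = 3)
  # vanishing bandwidth: pure cosine of the component frequency
  hp <- spectralMixtureHyperparams(2, 1 / 24, 1e-300, 0.5)
  K <- covMatrix(t, hp)
  D <- outer(t, t, "-")
  expect_equal(K, 2 * cos(2 * pi * D / 24) + diag(0.25, length(t)),
               tolerance = 1e-10)
  # zero-lag entries: sum of weights + epsilon^2
  hp2 <- spectralMixtureHyperparams(c(1, 3), c(1 / 24, 1 / 12), c(1e-3, 1e-3),
                                    0.5)
  expect_equal(diag(covMatrix(t, hp2)), rep(1 + 3 + 0.25, length(t)))
  # zero mean frequency: monotone squared-exponential-type decay, no ringing
  hp0 <- spectralMixtureHyperparams(1, 0, 1e-3, 0.1)
  row <- covMatrix(t, hp0)[1, ]
  expect_true(all(diff(row[-1]) <= 1e-12))
  expect_true(all(row > 0))
})

test_that("random kernel matrices are symmetric and PSD up to jitter", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    t <- sort(runif(n, 0, 48))
    hp <- if (i %% 2 == 0) {
      randomNSHyperparams(anchorTimes = sort(runif(3, 0, 48)))
    } else {
      spectralMixtureHyperparams(runif(2, 0.1, 3), runif(2, 1 / 48, 1 / 6),
                                 runif(2, 1e-5, 1e-2), runif(1, 0.05, 1))
    }
    K <- covMatrix(t, hp)
    expect_equal(K, t(K), tolerance = 1e-14)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(diag(K)))
  }
})

test_that("hyperparameters serialize to flat lists and back", {
  hps <- list(diagonalHyperparams(0.7),
              nonstationaryHyperparams(c(0, 1), c(1, 2), c(-3, -2),
                                       c(0, 48), 0.2),
              spectralMixtureHyperparams(c(1, 2), c(0.04, 0.08),
                                         c(1e-3, 1e-4), 0.3))
  for (hp in hps) {
    back <- hpFromList(jsonlite::fromJSON(jsonlite::toJSON(hpToList(hp),
                                                           digits = NA,
                                                           auto_unbox = TRUE)))
    expect_equal(back, hp)
  }
})
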