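# Shared fixture builders: everything is generated in code at test time.

grid48 <- seq(0, 48, by = 3)

# replicated sine dataset: f(t) = A sin(2 pi t / period) + N(0, sigma)
makeSineDataset <- function(A = 3, period = 24, sigma = 0.1, nrep = 3,
                            t = grid48, seed = 1) {
  set.seed(seed)
  f <- A * sin(2 * pi * t / period)
  RhythmDataset(t, f + matrix(rnorm(length(t) * nrep, 0, sigma),
                              length(t), nrep),
                label = "sine")
}

makeNoiseDataset <- function(sigma = 1, nrep = 3, t = grid48, seed = 1) {
  set.seed(seed)
  RhythmDataset(t, matrix(rnorm(length(t) * nrep, 0, sigma),
                          length(t), nrep),
                label = "noise")
}

# independent dense-algebra MLL oracle: explicit inverse + eigenvalue
# log-determinant, no Cholesky, no compiled code
mllOracle <- function(ds, hp) {
  t <- obsTimes(ds)
  y <- as.numeric(obsValues(ds)[, 1])
  nv <- if (length(noiseVar(ds))) noiseVar(ds) else rep(0, length(y))
  C <- covMatrix(t, hp) + diag(nv, nrow = length(t))
  C <- C + diag(1e-8 * mean(diag(C)), nrow = nrow(C))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(-Inf)
  Cinv <- solve(C)
  -0.5 * drop(y %*% Cinv %*% y) - 0.5 * sum(log(ev)) -
    0.5 * length(y) * log(2 * pi)
}

randomNSHyperparams <- function(anchorTimes) {
  nonstationaryHyperparams(
    wAnchors = runif(length(anchorTimes), log(0.2), log(2)),
    lAnchors = runif(length(anchorTimes), log(3), log(40)),
    muAnchors = -runif(length(anchorTimes), log(6), log(48)),
    anchorTimes = anchorTimes,
    epsilon = runif(1, 0.05, 1))
}

fastControl <- function(seed = 1, restarts = 4) {
  gpControl(restarts = restarts, seed = seed)
}
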