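---
title: "Detecting oscillations in replicated time series with rhythmGP"
author: "rhythmGP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting oscillations in replicated time series with rhythmGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmGP)
```

## The problem

Circadian-range rhythms in gene expression are usually assayed by qPCR time
courses: a handful of time points over one or two days, a few biological
replicates per point, appreciable measurement error, and frequently missing
or unevenly spaced observations. Deciding whether such a trace is
oscillatory is harder than it looks: classical tests (Cosinor, Lomb-Scargle,
JTK-style rank tests) assume a fixed waveform or stationary periodicity and
return only a P-value against the null, saying nothing about how well an
oscillatory model actually explains the data. Real traces are also often
*non-stationary* -- the peak-to-peak interval drifts as cultures
desynchronize or differentiate.

rhythmGP treats detection as Bayesian model comparison between two Gaussian
process (GP) priors over the signal:

* **Null (non-rhythmic)**: a diagonal kernel
  $K_D(x, x') = \epsilon^2\,\delta_{xx'}$ -- values at different times are a
  priori uncorrelated, so the trace is exchangeable noise.
* **Alternative (rhythmic)**: a non-stationary oscillatory kernel
  $$K_{NS}(x,x') = w(x)\,w(x')\,k_{\mathrm{gibbs}}(x,x')\,
    \cos\!\big(2\pi(x\,\mu(x) - x'\,\mu(x'))\big) + \epsilon^2\,\delta_{xx'},$$
  where $k_{\mathrm{gibbs}}$ is the Gibbs kernel
  $\sqrt{2\ell(x)\ell(x')/(\ell(x)^2+\ell(x')^2)}\,
  \exp\!\big(-(x-x')^2/(\ell(x)^2+\ell(x')^2)\big)$. The latent functions
  $w(x)$ (amplitude), $\ell(x)$ (correlation lengthscale, hours) and
  $\mu(x)$ (frequency, cycles/hour) depend on time, so amplitude, smoothness
  and period may all drift across the record.

Each kernel's hyperparameters are fitted by type-II maximum likelihood
(maximizing the marginal log-likelihood, MLL), and the evidence ratio

$$\mathrm{BF} = \exp(\mathrm{MLL}_{NS} - \mathrm{MLL}_{D})$$

is the Bayes factor for rhythmicity. Because both hypotheses are modelled,
a small BF is evidence *for* the null, not merely absence of evidence.
When $m$ datasets are tested together, a Bonferroni-type prior odds $1/m$
multiplies the BF before classification.

## Classification cutoffs

The default cutoff is 14, the Bayes-factor-bound equivalent of a 0.005
P-value under the calibration $\mathrm{BFB}(p) = -1/(e\,p\ln p)$ (valid for
$p \le 1/e$; clamped to 1 above, where `pvalueToBFBound(..., clamp = FALSE)`
exposes the raw formula). Corrected odds at least twice the cutoff are
labelled `oscillatory`, odds in $[\mathrm{cutoff}/2, 2\,\mathrm{cutoff})$
`weak`, smaller odds `non-oscillatory`. The weak band is a pragmatic
half-octave convention: evidence within a factor two of the threshold
should not be over-interpreted in either direction.

`pvalueToBFBound()` also lets P-value-producing methods be compared with
Bayes-factor methods on one scale, which is how the internal Cosinor and
Lomb-Scargle baselines are reported in the benchmark module.

## Parametrization of the latent functions

The functional forms of $w$, $\ell$, $\mu$ are a genuine design choice: the
kernel only requires them to be positive functions of time. rhythmGP uses
exponentiated piecewise-linear interpolants over $M$ anchor points equally
spaced across the observed range (`gpControl(anchors = M)`, default
$M = 3$), with the nearest anchor held constant outside the span:

* $M = 1$ recovers the stationary quasi-periodic kernel exactly (a useful
  nesting: with constant anchors, `covMatrix()` equals the closed form
  $w^2 e^{-\Delta^2/2\ell^2}\cos(2\pi\mu\Delta) + \epsilon^2\delta$ to
  $10^{-12}$);
* $M \ge 2$ realizes genuine non-stationarity with only $3M + 1$
  hyperparameters;
* positivity is automatic through the exponential.

Two caveats are documented rather than hidden. First, the decomposition is
not identifiable: the phase $2\pi x \mu(x)$ can be produced by different
$\mu$ profiles, so individual anchor values should not be interpreted as
"the" instantaneous frequency; the fitted curve (posterior mean) is the
meaningful object. Second, the literal non-stationary form is not
guaranteed positive semidefinite for every latent configuration; a relative
jitter of $10^{-8}\times$ the mean diagonal is added before factorization
and any hyperparameter draw whose covariance still fails to factorize is
rejected (treated as $-\infty$ MLL) during optimization.

## Optimization

`optimizeHyperparams()` runs bounded L-BFGS-B on log-hyperparameters with
`restarts` restarts (default 8): two deterministic circadian-range
initializations (periods 24 h and 16 h, unit amplitude) followed by random
draws from log-uniform priors -- lengthscale 3-48 h, period 6-48 h,
amplitude 0.1-3 (on normalized data), noise 0.01-2. The informed
initializations make period-24 optima reproducible across seeds; without
them, 3 h sampling admits aliased local optima in which a faster chirp
interpolates the same samples. Frequencies are box-bounded to periods in
[4, 96] h: just below the 6 h Nyquist period of the default 3 h grid at the
low end, twice a 48 h record at the high end. The diagonal family has one
parameter and is solved by golden-section search to $10^{-10}$. Everything
is deterministic given `gpControl(seed = ...)`, and ties between restarts
go to the lowest restart index.

## Preprocessing and measurement error

`bayesFactor()` collapses replicates to their per-time-point mean and
carries the squared standard error of the mean into the covariance diagonal
(`collapseReplicates(mode = "mean_sem")`); data are then z-scored using the
population-sd convention (measurement variances are rescaled by the squared
divisor). With the default `varianceModeration = "pooled"`, the
replicate-derived variances are averaged across time points before fitting.
This moderation matters: a per-point variance estimated from three
replicates has two degrees of freedom, and treating such estimates as known
lets the flexible kernel concentrate its fit on the points whose variance
happened to be underestimated. In simulations under a common noise level
this inflated null Bayes factors by an order of magnitude or more; pooling
(the natural estimator when replicate noise is homogeneous, as in the
synthetic families and typical qPCR designs) restores calibrated behaviour
-- over 50 pure-noise datasets ($\sigma = 1$, 3 replicates, 17 points) the
median BF is well below the cutoff, while a 24 h sine with amplitude 3 and
$\sigma = 0.1$ exceeds it in every run. Per-point variances supplied
explicitly by the user (a `noise_var` column) are never moderated, and
`varianceModeration = "per_point"` restores the raw scheme.

A time point missing in some replicates contributes its observed replicates
only; a single surviving replicate gets variance 0 there (the learned
$\epsilon$ absorbs its noise). Times are kept in hours as given -- no
rescaling to $[0,1]$ -- since the frequency bounds do that job
interpretably.

## The synthetic benchmark generator

`waveSpec()` / `genWave()` emulate a standard simulated qPCR design: three
replicates over 48 h at 3 h spacing (both endpoints, 17 points), Gaussian
replicate noise, and optional random dropping of whole time points
(`applyMissingness()`, `floor(0.5 n + 0.5)` = 9 of 17 dropped at the
half-missing setting, the same points in every replicate). Six waveform
families span stationary/non-stationary and symmetric/asymmetric shapes:
pure noise; two-sine sums; sawtooths; a decreasing-period chirp
$A\sin(2\pi t/(1+|t-\tau|))$ with $\tau \ge 48$ (default 72); and sine or
sawtooth waves whose period is redrawn each cycle from
$\mathcal N(\mu_\tau, \sigma_\tau)$ or $\mathcal U(\tau_1, \tau_2)$, phase
resetting to zero at cycle starts (continuous for sines, discontinuous for
sawtooths). The per-cycle period sequence is drawn once per wave and shared
by the replicates: replicates are noisy measurements of one underlying
trajectory. `wavePreset()` and `benchmarkPreset()` hard-code the
figure-caption parameter pairings used in the ROC experiments.

What the generator does *not* emulate: amplitude damping, baseline drift,
replicate-specific phase, heteroscedastic noise, or correlated errors
between time points. Passing the synthetic benchmarks therefore shows that
the detector separates structured from exchangeable traces under idealized
noise, not that it is robust to every artifact of real qPCR data.

### A note on reproducing published AUC values

The acceptance-style benchmarks regenerate the published wave pairings and
re-measure ROC AUCs at 100+100 waves per class. Under the conditions as
printed (3 replicates, the captioned $\sigma$ and missingness), *every*
correctly working detector we implemented -- including plain Cosinor, which
involves none of this package's GP machinery -- separates the classes
almost perfectly (AUC $\approx 1.0$), whereas the published curves report
0.81-0.97. Reducing each wave to a single replicate brings Cosinor to
within half a point of its published value, which suggests the published
benchmark effectively scored less information per wave than the stated
three-replicate design provides. We deliberately keep the generator
faithful to the stated conditions and report the AUCs we measure.

## The Poincare population model

To study *why* population-level rhythms strengthen, `poincarePopulation()`
/ `simulatePoincare()` integrate $N$ mean-field-coupled limit-cycle
oscillators
$$\dot x_i = \gamma_i x_i (A_i - r_i) - \tfrac{2\pi}{\tau_i} y_i + M,\qquad
  \dot y_i = \gamma_i y_i (A_i - r_i) + \tfrac{2\pi}{\tau_i} x_i,$$
with $r_i = \sqrt{x_i^2 + y_i^2}$ and $M = (K/N)\sum_i x_i$, by fixed-step
Euler-Maruyama (additive noise of one scale on both state variables;
deterministic Euler at noise 0). At `dt = 0.001` h a single oscillator
conserves its limit-cycle radius and period to well under 1%, and the
radial equation matches the closed-form logistic solution; `dt = 0.01` h is
the default for population work and `dt = 0.05` h is adequate for the
detection scans. The default population -- $N = 100$, $\tau_i \sim
\mathcal N(24, 1.5)$ h, $\gamma = 0.1$ h$^{-1}$, radii on the limit cycle,
phases uniform -- is a dephased dish whose mean field is flat until
coupling synchronizes it. The observable is the population mean of $x$
(three noisy replicates of it, in the detection scans), sampled over a 36 h
window at 3 h spacing after a 12 h transient.

`bfSensitivityScan()` maps median log10 BF over an (amplitude, coupling)
grid. The scan conditions used in the tests (amplitude 0.3, state noise
0.3, replicate noise 0.15, $K \in \{0, 0.15, 0.3\}$, 7 seeds per cell) were
chosen so that the uncoupled population is solidly undetectable and
synchronization emerges within the 48 h horizon; under them the median
log10 BF increases monotonically in $K$, and for large-amplitude noiseless
populations it is already high at small $K$ and flat thereafter.

## Numerical choices and degenerate inputs

* Covariances are factorized by Cholesky after the relative jitter; the
  exported `marginalLogLikelihood()` is plain R and is cross-checked in the
  tests against an eigendecomposition oracle and against the compiled
  (RcppArmadillo) evaluation used inside the optimizer, to $10^{-8}$.
* Optimization failures (all restarts non-finite) raise an error carrying
  the restart trace; individual failed restarts are recorded and skipped.
* `readTimeseries()` rejects non-numeric or missing times naming the row,
  all-missing columns naming the column, and records with fewer than 4
  distinct time points; all-missing time points are dropped.
* Z-scoring a zero-variance trace is refused with a pointer to `center`.
* Benchmark scoring records per-dataset failures and assigns them the worst
  observed score, keeping ROC denominators fixed.
* Ties in ROC scores are handled by threshold sweep over unique values,
  which makes the trapezoid AUC equal the Mann-Whitney rank statistic
  exactly (asserted to $10^{-12}$).

## Problem sizes used in the tests

The bundled checks run the full pipeline at reduced but honest sizes chosen
for a single-CPU session: ROC reproductions at 100+100 waves per class
(the Cosinor baseline at 500+500 in the acceptance script), calibration
properties over 50 seeded datasets, the coupling scan on a 1x3 grid with 7
seeds per cell, and single-oscillator integration checks at `dt = 0.001` h.

## Known limitations

* Evidence is type-II maximum likelihood, not full marginalization over
  hyperparameters; with 17-point records the residual optimism of the
  flexible kernel is what the pooled variance moderation keeps in check.
* No false-discovery-rate machinery: the $1/m$ prior odds is a global
  Bonferroni-style penalty, suitable for a handful of trajectories, not for
  genome-wide scans.
* One signal per dataset; batch analyses loop over files (the CLI does
  exactly that).
* Asymmetric waveforms (sawtooths) are not the alternative kernel's
  strength; rank-based methods are known to do better there, and the
  benchmark module exists partly to make such comparisons easy.
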