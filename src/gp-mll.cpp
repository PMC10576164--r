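// Fast marginal log-likelihood evaluations used by the hyperparameter
// optimizer. Formulae mirror the plain-R covMatrix/marginalLogLikelihood
// path exactly (including the relative jitter); tests assert agreement.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// piecewise-linear interpolation of anchor values at x, clamped outside the
// anchor span; returns exp(s(x))
static vec latent_exp(const vec& anchors, const vec& at, const vec& x) {
  const uword m = anchors.n_elem;
  vec out(x.n_elem);
  if (m == 1) {
    out.fill(std::exp(anchors[0]));
    return out;
  }
  for (uword i = 0; i < x.n_elem; ++i) {
    double xi = x[i];
    double s;
    if (xi <= at[0]) {
      s = anchors[0];
    } else if (xi >= at[m - 1]) {
      s = anchors[m - 1];
    } else {
      uword k = 0;
      while (k + 1 < m && at[k + 1] < xi) ++k;
      double f = (xi - at[k]) / (at[k + 1] - at[k]);
      s = anchors[k] + f * (anchors[k + 1] - anchors[k]);
    }
    out[i] = std::exp(s);
  }
  return out;
}

// Gaussian MLL via Cholesky with relative jitter; -inf if not factorizable
static double gauss_mll(mat& C, const vec& y) {
  const uword n = y.n_elem;
  double jitter = 1e-8 * mean(C.diag());
  C.diag() += jitter;
  mat L;
  if (!chol(L, C, "lower")) return -datum::inf;
  vec alpha = solve(trimatl(L), y);
  double quad = dot(alpha, alpha);
  double logdet = 2.0 * accu(log(L.diag()));
  return -0.5 * quad - 0.5 * logdet - 0.5 * n * LOG2PI;
}

// [[Rcpp::export(name = ".mll_diagonal_cpp")]]
double mll_diagonal_cpp(const arma::vec& y, const arma::vec& noise_var,
                        double log_eps) {
  double e2 = std::exp(2.0 * log_eps);
  vec v = noise_var + e2;
  double out = 0.0;
  for (uword i = 0; i < y.n_elem; ++i)
    out += -0.5 * y[i] * y[i] / v[i] - 0.5 * std::log(v[i]) - 0.5 * LOG2PI;
  return out;
}

// theta = (w_log[1..M], l_log[1..M], mu_log[1..M], log_eps)
// [[Rcpp::export(name = ".mll_nonstationary_cpp")]]
double mll_nonstationary_cpp(const arma::vec& times, const arma::vec& y,
                             const arma::vec& noise_var,
                             const arma::vec& theta,
                             const arma::vec& anchor_times) {
  const uword n = times.n_elem;
  const uword m = anchor_times.n_elem;
  if (theta.n_elem != 3 * m + 1) Rcpp::stop("theta must have length 3*M + 1");
  vec w = latent_exp(theta.subvec(0, m - 1), anchor_times, times);
  vec l = latent_exp(theta.subvec(m, 2 * m - 1), anchor_times, times);
  vec mu = latent_exp(theta.subvec(2 * m, 3 * m - 1), anchor_times, times);
  double eps2 = std::exp(2.0 * theta[3 * m]);

  mat C(n, n);
  for (uword i = 0; i < n; ++i) {
    C(i, i) = w[i] * w[i] + eps2 + noise_var[i];
    for (uword j = i + 1; j < n; ++j) {
      double s = l[i] * l[i] + l[j] * l[j];
      double d = times[i] - times[j];
      double gib = std::sqrt(2.0 * l[i] * l[j] / s) * std::exp(-d * d / s);
      double phase = 2.0 * M_PI * (times[i] * mu[i] - times[j] * mu[j]);
      double k = w[i] * w[j] * gib * std::cos(phase);
      C(i, j) = k;
      C(j, i) = k;
    }
  }
  return gauss_mll(C, y);
}

// theta = (log_w[1..Q], log_mu[1..Q], log_v[1..Q], log_eps)
// [[Rcpp::export(name = ".mll_spectral_mixture_cpp")]]
double mll_spectral_mixture_cpp(const arma::vec& times, const arma::vec& y,
                                const arma::vec& noise_var,
                                const arma::vec& theta, int Q) {
  const uword n = times.n_elem;
  if (theta.n_elem != (uword)(3 * Q + 1)) Rcpp::stop("theta must have length 3*Q + 1");
  vec wq = exp(theta.subvec(0, Q - 1));
  vec muq = exp(theta.subvec(Q, 2 * Q - 1));
  vec vq = exp(theta.subvec(2 * Q, 3 * Q - 1));
  double eps2 = std::exp(2.0 * theta[3 * Q]);

  mat C(n, n);
  for (uword i = 0; i < n; ++i) {
    C(i, i) = accu(wq) + eps2 + noise_var[i];
    for (uword j = i + 1; j < n; ++j) {
      double d = times[i] - times[j];
      double k = 0.0;
      for (int q = 0; q < Q; ++q)
        k += wq[q] * std::exp(-2.0 * M_PI * M_PI * d * d * vq[q]) *
             std::cos(2.0 * M_PI * muq[q] * d);
      C(i, j) = k;
      C(j, i) = k;
    }
  }
  return gauss_mll(C, y);
}
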