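#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over possibly many independent observation
// sequences sharing one parameter set. Emission log-likelihoods are
// precomputed (T x K); seq_starts are 1-based indices of the first
// position of each sequence. Returns per-position posteriors (gamma),
// summed transition expectations (xi), expected initial counts and the
// total log-likelihood.
// [[Rcpp::export]]
List fb_pass(NumericMatrix loglik, NumericMatrix transition,
             NumericVector initial, IntegerVector seq_starts) {
  const int T = loglik.nrow();
  const int K = loglik.ncol();
  const int S = seq_starts.size();

  NumericMatrix gamma(T, K);
  NumericMatrix xi(K, K);
  NumericVector init_counts(K);
  double total_ll = 0.0;

  std::vector<double> alpha(static_cast<size_t>(T) * K);
  std::vector<double> beta(static_cast<size_t>(T) * K);
  std::vector<double> cvec(T);
  std::vector<double> b(static_cast<size_t>(T) * K);
  std::vector<double> shift(T);

  for (int s = 0; s < S; ++s) {
    int t0 = seq_starts[s] - 1;
    int t1 = (s + 1 < S) ? seq_starts[s + 1] - 1 : T;

    // shifted emission probabilities: exp(loglik - rowmax); the shift is
    // absorbed into the scaling constants so the log-likelihood is exact
    for (int t = t0; t < t1; ++t) {
      double mx = loglik(t, 0);
      for (int k = 1; k < K; ++k) mx = std::max(mx, loglik(t, k));
      shift[t] = mx;
      for (int k = 0; k < K; ++k)
        b[static_cast<size_t>(t) * K + k] = std::exp(loglik(t, k) - mx);
    }

    // forward with per-position normalisation
    for (int t = t0; t < t1; ++t) {
      double norm = 0.0;
      if (t == t0) {
        for (int k = 0; k < K; ++k) {
          double v = initial[k] * b[static_cast<size_t>(t) * K + k];
          alpha[static_cast<size_t>(t) * K + k] = v;
          norm += v;
        }
      } else {
        for (int k = 0; k < K; ++k) {
          double acc = 0.0;
          for (int j = 0; j < K; ++j)
            acc += alpha[static_cast<size_t>(t - 1) * K + j] * transition(j, k);
          double v = acc * b[static_cast<size_t>(t) * K + k];
          alpha[static_cast<size_t>(t) * K + k] = v;
          norm += v;
        }
      }
      if (!(norm > 0.0) || !R_finite(norm))
        stop("forward pass underflow/NaN at position %d", t + 1);
      cvec[t] = norm;
      double inv = 1.0 / norm;
      for (int k = 0; k < K; ++k) alpha[static_cast<size_t>(t) * K + k] *= inv;
      total_ll += std::log(norm) + shift[t];
    }

    // backward, reusing the forward scaling constants
    for (int k = 0; k < K; ++k) beta[static_cast<size_t>(t1 - 1) * K + k] = 1.0;
    for (int t = t1 - 2; t >= t0; --t) {
      double inv = 1.0 / cvec[t + 1];
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j)
          acc += transition(k, j) * b[static_cast<size_t>(t + 1) * K + j] *
                 beta[static_cast<size_t>(t + 1) * K + j];
        beta[static_cast<size_t>(t) * K + k] = acc * inv;
      }
    }

    // posteriors and transition expectations
    for (int t = t0; t < t1; ++t) {
      double norm = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = alpha[static_cast<size_t>(t) * K + k] *
                   beta[static_cast<size_t>(t) * K + k];
        gamma(t, k) = g;
        norm += g;
      }
      double inv = 1.0 / norm;
      for (int k = 0; k < K; ++k) gamma(t, k) *= inv;
    }
    for (int k = 0; k < K; ++k) init_counts[k] += gamma(t0, k);
    for (int t = t0; t < t1 - 1; ++t) {
      double inv = 1.0 / cvec[t + 1];
      for (int j = 0; j < K; ++j) {
        double aj = alpha[static_cast<size_t>(t) * K + j];
        if (aj == 0.0) continue;
        for (int k = 0; k < K; ++k) {
          xi(j, k) += aj * transition(j, k) *
                      b[static_cast<size_t>(t + 1) * K + k] *
                      beta[static_cast<size_t>(t + 1) * K + k] * inv;
        }
      }
    }
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["init_counts"] = init_counts,
                      _["loglik"] = total_ll);
}

// Viterbi decoding in log space over multiple sequences; ties broken
// toward the lower state index.
// [[Rcpp::export]]
IntegerVector viterbi_path(NumericMatrix loglik, NumericMatrix transition,
                           NumericVector initial, IntegerVector seq_starts) {
  const int T = loglik.nrow();
  const int K = loglik.ncol();
  const int S = seq_starts.size();
  IntegerVector path(T);

  NumericMatrix logA(K, K);
  NumericVector logpi(K);
  for (int j = 0; j < K; ++j) {
    logpi[j] = std::log(initial[j]);
    for (int k = 0; k < K; ++k) logA(j, k) = std::log(transition(j, k));
  }

  std::vector<double> delta(static_cast<size_t>(T) * K);
  std::vector<int> psi(static_cast<size_t>(T) * K);

  for (int s = 0; s < S; ++s) {
    int t0 = seq_starts[s] - 1;
    int t1 = (s + 1 < S) ? seq_starts[s + 1] - 1 : T;
    for (int k = 0; k < K; ++k)
      delta[static_cast<size_t>(t0) * K + k] = logpi[k] + loglik(t0, k);
    for (int t = t0 + 1; t < t1; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta[static_cast<size_t>(t - 1) * K] + logA(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          double v = delta[static_cast<size_t>(t - 1) * K + j] + logA(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta[static_cast<size_t>(t) * K + k] = best + loglik(t, k);
        psi[static_cast<size_t>(t) * K + k] = arg;
      }
    }
    int last = t1 - 1;
    double best = delta[static_cast<size_t>(last) * K];
    int arg = 0;
    for (int k = 1; k < K; ++k) {
      double v = delta[static_cast<size_t>(last) * K + k];
      if (v > best) { best = v; arg = k; }
    }
    path[last] = arg + 1;
    for (int t = last; t > t0; --t) {
      arg = psi[static_cast<size_t>(t) * K + arg];
      path[t - 1] = arg + 1;
    }
  }
  return path;
}
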