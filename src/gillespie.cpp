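#include <Rcpp.h>
using namespace Rcpp;

// Exact continuous-time simulation of an ensemble of n independent two-state
// (closed <-> open) channels, simulated as the aggregate birth-death chain on
// the number of open channels. The aggregate chain is equal in law to n
// independent per-channel Gillespie simulations (superposition of independent
// two-state Markov chains) but costs one event loop instead of n.
//
// Returns the number of open channels at each sample instant t_i = i * dt.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerVector sim_ensemble_counts(int n, double k_open, double k_close,
                                  int n_samples, double dt, int init = -1) {
  IntegerVector out(n_samples);
  if (n <= 0) return out;
  double ksum = k_open + k_close;
  double p = ksum > 0.0 ? k_open / ksum : 0.0;
  int k = (init >= 0) ? init : (int) R::rbinom((double) n, p);
  double t = 0.0;
  int i = 0;
  while (i < n_samples) {
    double up = (n - k) * k_open;
    double down = k * k_close;
    double tot = up + down;
    if (tot <= 0.0) {
      for (; i < n_samples; ++i) out[i] = k;
      break;
    }
    double tnext = t + R::rexp(1.0 / tot); // R::rexp takes the scale
    while (i < n_samples && i * dt < tnext) out[i++] = k;
    t = tnext;
    if (R::unif_rand() * tot < up) ++k; else --k;
  }
  return out;
}

// Time-varying opening rate: k_open_t[i] applies on [i*dt, (i+1)*dt).
// Exact via thinning against the state-dependent bound
// (n - k) * max(k_open_t) + k * k_close, refreshed after every accepted jump
// (between jumps k is constant, so the bound stays valid).

// [[Rcpp::export]]
IntegerVector sim_ensemble_counts_tv(int n, NumericVector k_open_t,
                                     double k_close, double dt, int init) {
  int n_samples = k_open_t.size();
  IntegerVector out(n_samples);
  if (n <= 0) return out;
  double k_open_max = 0.0;
  for (int j = 0; j < n_samples; ++j)
    if (k_open_t[j] > k_open_max) k_open_max = k_open_t[j];
  int k = init;
  double t = 0.0;
  int i = 0;
  while (i < n_samples) {
    double bound = (n - k) * k_open_max + k * k_close;
    if (bound <= 0.0) {
      for (; i < n_samples; ++i) out[i] = k;
      break;
    }
    double tnext = t + R::rexp(1.0 / bound);
    while (i < n_samples && i * dt < tnext) out[i++] = k;
    if (i >= n_samples) break;
    t = tnext;
    int idx = (int) (t / dt);
    if (idx >= n_samples) idx = n_samples - 1;
    double up = (n - k) * k_open_t[idx];
    double down = k * k_close;
    double u = R::unif_rand() * bound;
    if (u < up) ++k;
    else if (u < up + down) --k;
    // else: thinned proposal, no jump
  }
  return out;
}
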