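#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Event-driven sweep of the coincidence-counting neuron on the simulation
// grid. The pooled excitatory window count C(t) (spikes in (t - W, t]) and
// the effective threshold theta + delta * (inhibitory spikes in
// (t - Delta, t]) are piecewise constant between input-spike arrivals and
// expiries, so evaluating the per-bin rule only at those change points
// reproduces the per-bin simulation exactly, for every dt that resolves the
// spike times. Per-bin rule: an output spike is emitted at any bin where
// C >= threshold and at least T has elapsed since the previous output
// spike; super-threshold bins inside the refractory period are discarded.

struct Ev {
  long long bin;
  int dc;      // change in excitatory window count
  double dthr; // change in effective threshold
};

// [[Rcpp::export(name = ".cc_counter")]]
List cc_counter(NumericVector exc, NumericVector inh, double duration,
                double dt, int theta, double W, double T_ref, double Delta,
                double delta) {
  const long long n_bins = (long long)std::llround(duration / dt);
  const long long w_bins = (long long)std::llround(W / dt);
  const long long t_bins = (long long)std::llround(T_ref / dt);
  const long long d_bins = (long long)std::llround(Delta / dt);
  if (w_bins < 1 || t_bins < 1 || d_bins < 1)
    stop("W, T and Delta must be at least one time step");

  std::vector<Ev> ev;
  ev.reserve(2 * (exc.size() + inh.size()));
  long long prev = -1;
  for (R_xlen_t i = 0; i < exc.size(); ++i) {
    if (exc[i] < 0 || exc[i] >= duration)
      stop("excitatory spike time outside [0, duration)");
    long long b = (long long)std::llround(exc[i] / dt);
    if (b < prev && i > 0)
      stop("excitatory spike times must be sorted");
    prev = b;
    ev.push_back({b, 1, 0.0});
    ev.push_back({b + w_bins, -1, 0.0});
  }
  prev = -1;
  for (R_xlen_t i = 0; i < inh.size(); ++i) {
    if (inh[i] < 0 || inh[i] >= duration)
      stop("inhibitory spike time outside [0, duration)");
    long long b = (long long)std::llround(inh[i] / dt);
    if (b < prev && i > 0)
      stop("inhibitory spike times must be sorted");
    prev = b;
    ev.push_back({b, 0, delta});
    ev.push_back({b + d_bins, 0, -delta});
  }
  std::sort(ev.begin(), ev.end(),
            [](const Ev& a, const Ev& b) { return a.bin < b.bin; });

  std::vector<long long> out;
  long long last = -4 * t_bins - 4; // effectively -infinity
  int C = 0;
  double thr = (double)theta;
  bool phi = false; // condition C >= thr on the interval since last event
  long long phi_since = 0; // bin at which phi last became true
  long long n_cand = 0;

  size_t i = 0;
  const size_t n_ev = ev.size();
  while (i < n_ev) {
    long long b = ev[i].bin;
    // Fire inside (prev event, b) if the condition has held through
    // refractory expiry: the per-bin rule emits at the first eligible bin
    // with phi true, then every t_bins while phi stays true.
    if (phi) {
      long long nb = std::max(last + t_bins, phi_since);
      while (nb < b && nb < n_bins) {
        out.push_back(nb);
        last = nb;
        nb = last + t_bins;
      }
    }
    bool phi_before = phi;
    while (i < n_ev && ev[i].bin == b) {
      C += ev[i].dc;
      thr += ev[i].dthr;
      ++i;
    }
    phi = (double)C >= thr - 1e-9;
    if (phi && !phi_before) {
      phi_since = b;
      if (b < n_bins) ++n_cand;
    }
    if (b >= n_bins) continue;
    if (phi && b >= last + t_bins) {
      out.push_back(b);
      last = b;
    }
  }

  NumericVector times(out.size());
  for (size_t j = 0; j < out.size(); ++j) times[j] = out[j] * dt;
  return List::create(_["spike_times"] = times,
                      _["n_candidates"] = (double)n_cand);
}

// Pure integrator: event-driven by construction. Inputs arriving strictly
// inside the refractory period (last, last + T) are discarded; counters
// accumulate from the end of the refractory period and reset at each output
// spike. All inputs sharing one arrival time are accumulated before the
// threshold test, matching the continuous-time definition
// N_e(t) - delta * N_i(t) >= theta.

// [[Rcpp::export(name = ".pure_integrator")]]
List pure_integrator(NumericVector exc, NumericVector inh, double duration,
                     int theta, double T_ref, double delta) {
  const R_xlen_t ne = exc.size(), ni = inh.size();
  for (R_xlen_t i = 1; i < ne; ++i)
    if (exc[i] < exc[i - 1]) stop("excitatory spike times must be sorted");
  for (R_xlen_t i = 1; i < ni; ++i)
    if (inh[i] < inh[i - 1]) stop("inhibitory spike times must be sorted");

  std::vector<double> out;
  double last = -2 * T_ref - 1; // no previous spike
  double Ne = 0, Ni = 0;
  R_xlen_t a = 0, b = 0;
  while (a < ne || b < ni) {
    double t;
    if (a < ne && (b >= ni || exc[a] <= inh[b])) t = exc[a];
    else t = inh[b];
    if (t < 0 || t >= duration) stop("spike time outside [0, duration)");
    bool refractory = (t > last) && (t < last + T_ref);
    // consume every input at this exact time
    while (a < ne && exc[a] == t) { if (!refractory) Ne += 1; ++a; }
    while (b < ni && inh[b] == t) { if (!refractory) Ni += 1; ++b; }
    if (refractory) continue;
    if (Ne - delta * Ni >= (double)theta - 1e-9) {
      out.push_back(t);
      last = t;
      Ne = 0;
      Ni = 0;
    }
  }
  return List::create(_["spike_times"] = NumericVector(out.begin(), out.end()),
                      _["n_candidates"] = NumericVector::get_na());
}
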