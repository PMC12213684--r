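#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-time stochastic LIF network with optional increase/depression
// synaptic plasticity.  One step:
//   1. X_i[t] ~ Bernoulli(P(V_i[t]))  with P = Gamma*(V-theta)/(1+Gamma*(V-theta))
//      when V - theta > 0, else p_spont;
//   2. V_i[t+1] = mu*V_i[t] + I + (1/k_i) * sum_j W_ij[t] X_j[t]  (non-fired i);
//   3. V_i[t+1] = 0 for fired i;
//   4. W_ij[t+1] = W_ij[t] + 1/tau - u*W_ij[t]*X_j[t]  on every existing edge.
//
// The uniform +1/tau drift is applied lazily: W[e] stores the value at step
// tlast[e] and the current value is W[e] + (t - tlast[e])/tau, materialised
// only when the source neuron fires.  The network-mean weight over edges whose
// target has in-degree >= 2 is maintained incrementally so recording it every
// step is O(1).
//
// Draws exactly n uniforms per step (one per neuron, in neuron order) from R's
// RNG stream, so traces are bitwise reproducible under set.seed() and can be
// checked against a pure-R reference.

// [[Rcpp::export]]
List sim_core(const int n,
              const IntegerVector& edge_src,   // 0-based
              const IntegerVector& edge_tgt,   // 0-based
              const IntegerVector& in_degree,  // length n
              const double w_init,
              const double mu, const double i_ext,
              const double gamma, const double theta, const double p_spont,
              const bool plast_on, const double tau, const double u,
              const int t_max,
              const LogicalVector& probe,      // length n
              const bool record_raster) {
  const int m = edge_src.size();

  // CSR adjacency by source neuron
  std::vector<int> off(n + 1, 0), eidx(m);
  for (int e = 0; e < m; ++e) off[edge_src[e] + 1]++;
  for (int i = 0; i < n; ++i) off[i + 1] += off[i];
  {
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int e = 0; e < m; ++e) eidx[pos[edge_src[e]]++] = e;
  }

  std::vector<double> V(n, 0.0), Vn(n, 0.0), W(m, w_init);
  std::vector<int> tlast(m, 0);
  std::vector<char> qual(m), X(n);
  long n_qual = 0;
  double S0 = 0.0;       // sum of stored W over qualifying edges
  double S1 = 0.0;       // sum of tlast over qualifying edges
  // weights whose presynaptic (source) neuron has in-degree < 2 grow almost
  // unchecked (the depression term depends on that neuron firing, which it
  // essentially never does) and are excluded from the recorded network mean
  for (int e = 0; e < m; ++e) {
    qual[e] = in_degree[edge_src[e]] >= 2;
    if (qual[e]) { ++n_qual; S0 += w_init; }
  }
  const double inv_tau = plast_on ? 1.0 / tau : 0.0;

  IntegerVector probe_counts(t_max);
  NumericVector mean_w(t_max);
  IntegerVector spikes_per_neuron(n);
  std::vector<int> ras_t, ras_i;
  std::vector<int> firing;
  firing.reserve(n);

  for (int t = 0; t < t_max; ++t) {
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
    firing.clear();
    int pc = 0;
    for (int i = 0; i < n; ++i) {
      const double d = V[i] - theta;
      const double p = (d > 0.0) ? (gamma * d) / (1.0 + gamma * d) : p_spont;
      if (unif_rand() < p) {
        X[i] = 1;
        firing.push_back(i);
        ++spikes_per_neuron[i];
        if (probe[i]) ++pc;
      } else {
        X[i] = 0;
      }
    }
    probe_counts[t] = pc;
    if (record_raster) {
      for (size_t f = 0; f < firing.size(); ++f) {
        ras_t.push_back(t + 1);
        ras_i.push_back(firing[f] + 1);
      }
    }

    // membrane update (uses W at time t, X at time t)
    for (int i = 0; i < n; ++i) Vn[i] = X[i] ? 0.0 : mu * V[i] + i_ext;
    for (size_t f = 0; f < firing.size(); ++f) {
      const int j = firing[f];
      for (int q = off[j]; q < off[j + 1]; ++q) {
        const int e = eidx[q];
        const int i = edge_tgt[e];
        if (!X[i]) {
          const double wcur = W[e] + (t - tlast[e]) * inv_tau;
          Vn[i] += wcur / in_degree[i];
        }
      }
    }

    // plasticity on edges whose source fired (the +1/tau drift on all other
    // edges is carried implicitly by tlast)
    if (plast_on) {
      for (size_t f = 0; f < firing.size(); ++f) {
        const int j = firing[f];
        for (int q = off[j]; q < off[j + 1]; ++q) {
          const int e = eidx[q];
          const double wcur = W[e] + (t - tlast[e]) * inv_tau;
          const double wnew = wcur + inv_tau - u * wcur;
          if (qual[e]) {
            S0 += wnew - W[e];
            S1 += (double)(t + 1) - tlast[e];
          }
          W[e] = wnew;
          tlast[e] = t + 1;
        }
      }
      mean_w[t] = (n_qual > 0)
        ? (S0 + ((double)(t + 1) * n_qual - S1) * inv_tau) / n_qual
        : NA_REAL;
    } else {
      mean_w[t] = (n_qual > 0) ? w_init : NA_REAL;
    }

    std::swap(V, Vn);
  }

  // materialise final weights at t = t_max
  NumericVector w_final(m);
  for (int e = 0; e < m; ++e) w_final[e] = W[e] + (t_max - tlast[e]) * inv_tau;

  List out = List::create(
    _["probe_counts"] = probe_counts,
    _["mean_w"] = mean_w,
    _["spikes_per_neuron"] = spikes_per_neuron,
    _["w_final"] = w_final,
    _["v_final"] = NumericVector(V.begin(), V.end()));
  if (record_raster) {
    out["raster_t"] = IntegerVector(ras_t.begin(), ras_t.end());
    out["raster_neuron"] = IntegerVector(ras_i.begin(), ras_i.end());
  }
  return out;
}
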