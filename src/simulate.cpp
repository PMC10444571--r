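// Time-stepped network integrator.
//
// Gates: exponential Euler with voltage-indexed lookup tables (0.01 mV grid,
// linear interpolation). Voltage: forward Euler drift + Euler-Maruyama noise
// (white-noise term held constant over the step, scaled by sqrt(dt)).
// Synapses: per-edge NMDA gating (nonlinear, forward Euler); the weighted
// AMPA drive per postsynaptic neuron is maintained as an aggregate since all
// AMPA open fractions share one decay factor. Delayed spike arrivals are
// delivered through a ring buffer; transmitted amounts carry the presynaptic
// short-term-depression resource sampled before its decrement.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct RateTables {
  // per 0.01 mV from v_lo to v_hi: gate steady states and exp-Euler factors
  double v_lo, v_hi, inv_step;
  int n;
  std::vector<double> m_inf, m_fac, h_inf, h_fac, n_inf, n_fac, u_mg;
};

inline double sing_ratio(double x, double s) {
  if (std::fabs(x) < 1e-9) return s;
  return x / (std::exp(x / s) - 1.0);
}

RateTables build_tables(double VT, double dt, const List& mod,
                        double a_mg, double mg_over_b) {
  const double sam = as<double>(mod["scale_alpha_m"]);
  const double sbm = as<double>(mod["scale_beta_m"]);
  const double sah = as<double>(mod["scale_alpha_h"]);
  const double sbh = as<double>(mod["scale_beta_h"]);
  const double sha = as<double>(mod["shift_activation"]);
  const double shi = as<double>(mod["shift_inactivation"]);

  RateTables t;
  t.v_lo = -200.0; t.v_hi = 150.0;
  const double step = 0.01;
  t.inv_step = 1.0 / step;
  t.n = (int)std::lround((t.v_hi - t.v_lo) / step) + 1;
  t.m_inf.resize(t.n); t.m_fac.resize(t.n);
  t.h_inf.resize(t.n); t.h_fac.resize(t.n);
  t.n_inf.resize(t.n); t.n_fac.resize(t.n); t.u_mg.resize(t.n);
  for (int i = 0; i < t.n; ++i) {
    const double v = t.v_lo + i * step;
    const double va = v - sha, vi = v - shi;
    const double am = sam * 0.32 * sing_ratio(-(va - VT - 13.0), 4.0);
    const double bm = sbm * 0.28 * sing_ratio(va - VT - 40.0, 5.0);
    const double ah = sah * 0.128 * std::exp(-(vi - VT - 17.0) / 18.0);
    const double bh = sbh * 4.0 / (1.0 + std::exp(-(vi - VT - 40.0) / 5.0));
    const double an = 0.032 * sing_ratio(-(v - VT - 15.0), 5.0);
    const double bn = 0.5 * std::exp(-(v - VT - 10.0) / 40.0);
    t.m_inf[i] = am / (am + bm); t.m_fac[i] = std::exp(-dt * (am + bm));
    t.h_inf[i] = ah / (ah + bh); t.h_fac[i] = std::exp(-dt * (ah + bh));
    t.n_inf[i] = an / (an + bn); t.n_fac[i] = std::exp(-dt * (an + bn));
    t.u_mg[i] = 1.0 / (1.0 + std::exp(-a_mg * v) * mg_over_b);
  }
  return t;
}

struct Arrival { int edge; double amt; };

// xoshiro256++ with splitmix64 seeding and Marsaglia-polar gaussians:
// fast, self-contained, identical stream on every platform
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

} // namespace

// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(List neuron, List synapse, List mod,
                          IntegerVector edge_from, IntegerVector edge_to,
                          NumericVector edge_weight,
                          IntegerVector edge_delay_steps,
                          NumericVector bias, NumericMatrix elec_w,
                          double dt, int n_steps, int transient_steps,
                          int record_stride,
                          double v_init, double m_init, double h_init,
                          double n_init,
                          double spike_threshold, int refractory_steps,
                          double rng_seed) {
  const int N = bias.size();
  const int nE = elec_w.nrow();
  const int n_edges = edge_from.size();

  // neuron parameters
  const double Cm = as<double>(neuron["Cm"]);
  const double gK = as<double>(neuron["gK_max"]);
  const double gNa = as<double>(neuron["gNa_max"]) *
    as<double>(mod["scale_gNa"]);
  const double gl = as<double>(neuron["gl"]);
  const double EK = as<double>(neuron["EK"]);
  const double ENa = as<double>(neuron["ENa"]);
  const double El = as<double>(neuron["El"]);
  const double VT = as<double>(neuron["VT"]);
  const double alphaCa = as<double>(neuron["alphaCa"]);
  const double tauAHP_ms = as<double>(neuron["tauAHP"]) * 1000.0;
  const double sigma = as<double>(neuron["sigma"]);
  const double area = as<double>(neuron["area"]);
  const double pa2dens = 1e-6 / area;  // pA -> uA/cm^2

  // synapse parameters
  const double gA = as<double>(synapse["gAMPA_max"]);
  const double gN = as<double>(synapse["gNMDA_max"]);
  const double EA = as<double>(synapse["EAMPA"]);
  const double EN = as<double>(synapse["ENMDA"]);
  const double aN = as<double>(synapse["alphaNMDA"]);
  const double tauA = as<double>(synapse["tauAMPA"]);
  const double tauNr = as<double>(synapse["tauNMDA_rise"]);
  const double tauNd = as<double>(synapse["tauNMDA_decay"]);
  const double mg = as<double>(synapse["mg_conc"]);
  const double a_mg = as<double>(synapse["a_mg"]);
  const double b_mg = as<double>(synapse["b_mg"]);
  const double tauD = as<double>(synapse["tauD"]);
  const double U = as<double>(synapse["U"]);
  const double Sscale = as<double>(synapse["S"]);

  const double fA = std::exp(-dt / tauA);
  const double fNr = std::exp(-dt / tauNr);
  const double fAHP = std::exp(-dt / tauAHP_ms);
  const double fD = std::exp(-dt / tauD);
  const double noise_amp = sigma * std::sqrt(2.0 * (gl / Cm) * dt);
  const double mg_over_b = mg / b_mg;

  RateTables tab = build_tables(VT, dt, mod, a_mg, mg_over_b);

  // CSR over outgoing edges
  std::vector<int> out_count(N, 0);
  for (int e = 0; e < n_edges; ++e) out_count[edge_from[e]]++;
  std::vector<int> out_start(N + 1, 0);
  for (int i = 0; i < N; ++i) out_start[i + 1] = out_start[i] + out_count[i];
  std::vector<int> out_edge(n_edges);
  {
    std::vector<int> cur(out_start.begin(), out_start.end() - 1);
    for (int e = 0; e < n_edges; ++e) out_edge[cur[edge_from[e]]++] = e;
  }
  std::vector<double> w_scaled(n_edges);
  for (int e = 0; e < n_edges; ++e) w_scaled[e] = edge_weight[e] * Sscale;

  int max_delay = 1;
  for (int e = 0; e < n_edges; ++e)
    if (edge_delay_steps[e] > max_delay) max_delay = edge_delay_steps[e];
  const int ring_len = max_delay + 1;
  std::vector<std::vector<Arrival>> ring(ring_len);

  // state
  std::vector<double> V(N, v_init), m(N, m_init), h(N, h_init),
      nn(N, n_init), gAHP(N, 0.0), x_std(N, 1.0);
  std::vector<int> refr(N, 0);
  std::vector<double> sumA(N, 0.0);             // aggregated weighted AMPA
  std::vector<double> s_nmda(n_edges, 0.0), x_nmda(n_edges, 0.0);
  std::vector<double> sumN(N, 0.0);
  // active-edge bookkeeping: only edges with non-decayed NMDA state are
  // swept each step (between bursts this list empties out)
  std::vector<int> active;
  active.reserve(n_edges);
  std::vector<char> is_active(n_edges, 0);

  // sparse electrode pickup lists (most weights are zero or negligible)
  std::vector<std::vector<std::pair<int, double>>> elec_nz(nE);
  for (int e = 0; e < nE; ++e)
    for (int i = 0; i < N; ++i)
      if (elec_w(e, i) > 0.0) elec_nz[e].push_back({i, elec_w(e, i)});

  const int n_rec = (n_steps - transient_steps + record_stride - 1) /
                    record_stride;
  NumericMatrix signals(nE, n_rec > 0 ? n_rec : 0);
  std::vector<int> spk_neuron;
  std::vector<int> spk_step;
  spk_neuron.reserve(1 << 16);
  spk_step.reserve(1 << 16);

  Rng rng((uint64_t)rng_seed);

  const double eps = 1e-9;   // NMDA gating below this contributes sub-fA currents
  int rec_i = 0;

  for (int t = 0; t < n_steps; ++t) {
    // deliver delayed arrivals
    std::vector<Arrival>& slot = ring[t % ring_len];
    for (const Arrival& a : slot) {
      sumA[edge_to[a.edge]] += w_scaled[a.edge] * a.amt;
      x_nmda[a.edge] += a.amt;
      if (!is_active[a.edge]) {
        is_active[a.edge] = 1;
        active.push_back(a.edge);
      }
    }
    slot.clear();

    // per-edge NMDA gating on active edges only
    for (size_t k = 0; k < active.size(); ) {
      const int e = active[k];
      double x = x_nmda[e] * fNr;
      double s = s_nmda[e];
      s += dt * (-s / tauNd + aN * x * (1.0 - s));
      if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;
      if (x <= eps) x = 0.0;
      if (s <= eps && x <= eps) {
        // fully decayed: drop from the active list (swap-pop)
        x_nmda[e] = 0.0; s_nmda[e] = 0.0;
        is_active[e] = 0;
        active[k] = active.back();
        active.pop_back();
        continue;
      }
      x_nmda[e] = x; s_nmda[e] = s;
      sumN[edge_to[e]] += w_scaled[e] * s;
      ++k;
    }

    for (int i = 0; i < N; ++i) {
      const double v_prev = V[i];
      // table lookup with linear interpolation
      double pos = (v_prev - tab.v_lo) * tab.inv_step;
      if (pos < 0) pos = 0;
      if (pos > tab.n - 1.001) pos = tab.n - 1.001;
      const int k = (int)pos;
      const double fr = pos - k;
      const double mi = tab.m_inf[k] + fr * (tab.m_inf[k + 1] - tab.m_inf[k]);
      const double mf = tab.m_fac[k] + fr * (tab.m_fac[k + 1] - tab.m_fac[k]);
      const double hi = tab.h_inf[k] + fr * (tab.h_inf[k + 1] - tab.h_inf[k]);
      const double hf = tab.h_fac[k] + fr * (tab.h_fac[k + 1] - tab.h_fac[k]);
      const double ni = tab.n_inf[k] + fr * (tab.n_inf[k + 1] - tab.n_inf[k]);
      const double nf = tab.n_fac[k] + fr * (tab.n_fac[k + 1] - tab.n_fac[k]);
      m[i] = mi + (m[i] - mi) * mf;
      h[i] = hi + (h[i] - hi) * hf;
      nn[i] = ni + (nn[i] - ni) * nf;

      const double u = tab.u_mg[k] + fr * (tab.u_mg[k + 1] - tab.u_mg[k]);
      const double I_pA = bias[i] - gAHP[i] * (v_prev - EK) +
        gA * sumA[i] * (EA - v_prev) + gN * u * sumN[i] * (EN - v_prev);
      const double n2 = nn[i] * nn[i];
      const double m2 = m[i] * m[i];
      const double drift =
        (-gK * n2 * n2 * (v_prev - EK) -
          gNa * m2 * m[i] * h[i] * (v_prev - ENa) -
          gl * (v_prev - El) + I_pA * pa2dens) / Cm;
      double v = v_prev + dt * drift;
      if (noise_amp > 0.0) v += noise_amp * rng.gauss();
      V[i] = v;

      gAHP[i] *= fAHP;
      x_std[i] = 1.0 + (x_std[i] - 1.0) * fD;

      if (refr[i] > 0) {
        refr[i]--;
      } else if (v >= spike_threshold && v_prev < spike_threshold) {
        spk_neuron.push_back(i + 1);
        spk_step.push_back(t);
        gAHP[i] += alphaCa;
        const double amt = x_std[i];      // resource before decrement
        x_std[i] -= U * amt;
        for (int q = out_start[i]; q < out_start[i + 1]; ++q) {
          const int e = out_edge[q];
          ring[(t + edge_delay_steps[e]) % ring_len].push_back({e, amt});
        }
        refr[i] = refractory_steps;
      }

      if (!std::isfinite(v) || std::fabs(v) > 200.0) {
        stop("numerical blow-up: |Vm| > 200 mV at neuron %d, step %d",
             i + 1, t);
      }
      sumN[i] = 0.0;
      sumA[i] *= fA;  // aggregated AMPA decays with the shared factor
    }

    if (t >= transient_steps && (t - transient_steps) % record_stride == 0) {
      for (int e = 0; e < nE; ++e) {
        double acc = 0.0;
        for (const auto& p : elec_nz[e]) acc += p.second * V[p.first];
        signals(e, rec_i) = acc;
      }
      rec_i++;
    }
  }

  return List::create(
    _["signals"] = signals,
    _["spike_neuron"] = IntegerVector(spk_neuron.begin(), spk_neuron.end()),
    _["spike_step"] = IntegerVector(spk_step.begin(), spk_step.end())
  );
}

// [[Rcpp::export(name = ".enforce_dead_time_cpp")]]
IntegerVector enforce_dead_time_cpp(IntegerVector idx, int min_gap) {
  // greedy: keep the first index, then the next one at least min_gap later
  std::vector<int> keep;
  keep.reserve(idx.size());
  long last = -2147483647L;
  for (int i = 0; i < idx.size(); ++i) {
    if ((long)idx[i] - last >= (long)min_gap) {
      keep.push_back(idx[i]);
      last = idx[i];
    }
  }
  return IntegerVector(keep.begin(), keep.end());
}
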