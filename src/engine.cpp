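#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Self-contained PCG32 generator so that simulations are reproducible from a
// single integer seed independently of R's RNG state.
namespace {

struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double unif() { return next() * (1.0 / 4294967296.0); }
};

inline double nmda_gate(double v) {
  double x = (v + 80.0) / 60.0;
  double x2 = x * x;
  return x2 / (1.0 + x2);
}

}  // namespace

//' @name engine_run
//' @noRd
// [[Rcpp::export(rng = false)]]
List engine_run(int n_neurons,
                NumericVector a, NumericVector b,
                NumericVector c, NumericVector d,
                NumericVector gain, NumericVector I_ext,
                NumericVector v0, NumericVector u0,
                NumericVector g0_ampa, NumericVector g0_nmda,
                NumericVector g0_gabaa, NumericVector g0_gabab,
                IntegerVector row_ptr,   // length n_units + 1, 0-based offsets
                IntegerVector col_idx,   // 0-based postsynaptic neuron ids
                NumericVector w,         // effective weights (modulation applied)
                IntegerVector chan,      // per synapse: 0 = AMPA+NMDA, 1 = GABAA+GABAB
                IntegerVector gen_group, // 0-based generator group per generator unit
                NumericMatrix rates,     // n_groups x T drive rates (Hz)
                int T,
                IntegerVector pop_of_unit, // 0-based population id per unit
                int n_pops,
                double seed,
                bool record_spikes,
                bool use_140_constant) {
  const int n_units = row_ptr.size() - 1;
  const int n_gen = n_units - n_neurons;
  if (n_gen < 0) stop("row_ptr shorter than the neuron count");
  if (gen_group.size() != n_gen) stop("gen_group length mismatch");
  if (pop_of_unit.size() != n_units) stop("pop_of_unit length mismatch");
  const int n_groups = rates.nrow();

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> gA(g0_ampa.begin(), g0_ampa.end());
  std::vector<double> gN(g0_nmda.begin(), g0_nmda.end());
  std::vector<double> gGA(g0_gabaa.begin(), g0_gabaa.end());
  std::vector<double> gGB(g0_gabab.begin(), g0_gabab.end());
  std::vector<double> incA(n_neurons, 0.0), incN(n_neurons, 0.0);
  std::vector<double> incGA(n_neurons, 0.0), incGB(n_neurons, 0.0);

  const double decA = std::exp(-1.0 / 5.0);
  const double decN = std::exp(-1.0 / 100.0);
  const double decGA = std::exp(-1.0 / 6.0);
  const double decGB = std::exp(-1.0 / 150.0);
  const double k140 = use_140_constant ? 140.0 : 0.0;

  IntegerMatrix pop_counts(n_pops, T);
  int* pc = INTEGER(pop_counts);

  std::vector<int> sp_unit, sp_t;
  std::vector<int> spikes_now;
  spikes_now.reserve(n_units);

  Pcg32 rng(static_cast<uint64_t>(seed));

  const int* rp = INTEGER(row_ptr);
  const int* ci = INTEGER(col_idx);
  const double* wp = REAL(w);
  const int* chp = INTEGER(chan);
  const int* pou = INTEGER(pop_of_unit);
  const double* ratep = REAL(rates);

  for (int t = 0; t < T; ++t) {
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
    // conductances: exponential decay, then arrivals from spikes at t-1
    for (int i = 0; i < n_neurons; ++i) {
      gA[i] = gA[i] * decA + incA[i];
      gN[i] = gN[i] * decN + incN[i];
      gGA[i] = gGA[i] * decGA + incGA[i];
      gGB[i] = gGB[i] * decGB + incGB[i];
      incA[i] = 0.0; incN[i] = 0.0; incGA[i] = 0.0; incGB[i] = 0.0;
    }
    spikes_now.clear();
    // neurons: spike check at step entry, then quadratic integrate-and-reset
    for (int i = 0; i < n_neurons; ++i) {
      double vi = v[i];
      if (vi >= 30.0) {
        spikes_now.push_back(i);
        v[i] = c[i];
        u[i] += d[i];
      } else {
        double I = I_ext[i] -
          (gA[i] * vi + gN[i] * nmda_gate(vi) * vi +
           gGA[i] * (vi + 70.0) + gGB[i] * (vi + 90.0));
        double Ieff = I * gain[i];
        double ui = u[i];
        double vv = vi;
        for (int s = 0; s < 2; ++s) {
          vv += 0.5 * (0.04 * vv * vv + 5.0 * vv + k140 - ui + Ieff);
          if (vv >= 30.0) { vv = 30.0; break; }
          // floor at the most negative synaptic reversal potential: below
          // -90 mV every driving force reverses sign, which is unphysical
          // and numerically unstable under explicit stepping
          if (vv < -90.0) vv = -90.0;
        }
        u[i] = ui + a[i] * (b[i] * vv - ui);
        v[i] = vv;
      }
    }
    // Poisson generator units: Bernoulli(rate * 1 ms)
    for (int gidx = 0; gidx < n_gen; ++gidx) {
      double r = ratep[gen_group[gidx] + (size_t)t * n_groups];
      if (r > 0.0 && rng.unif() < r * 0.001) spikes_now.push_back(n_neurons + gidx);
    }
    // deliver spikes (1 ms transmission delay: arrivals take effect at t+1)
    for (size_t si = 0; si < spikes_now.size(); ++si) {
      int s = spikes_now[si];
      for (int k = rp[s]; k < rp[s + 1]; ++k) {
        int post = ci[k];
        double wk = wp[k];
        if (chp[k] == 0) { incA[post] += wk; incN[post] += wk; }
        else             { incGA[post] += wk; incGB[post] += wk; }
      }
      pc[pou[s] + (size_t)t * n_pops] += 1;
      if (record_spikes) { sp_unit.push_back(s + 1); sp_t.push_back(t + 1); }
    }
  }

  for (int i = 0; i < n_neurons; ++i) {
    if (!R_finite(v[i]) || !R_finite(u[i]))
      stop("integration diverged (non-finite state in neuron %d); dt = 1 ms assumed", i + 1);
  }

  List out = List::create(
    _["pop_counts"] = pop_counts,
    _["v"] = NumericVector(v.begin(), v.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["g_ampa"] = NumericVector(gA.begin(), gA.end()),
    _["g_nmda"] = NumericVector(gN.begin(), gN.end()),
    _["g_gabaa"] = NumericVector(gGA.begin(), gGA.end()),
    _["g_gabab"] = NumericVector(gGB.begin(), gGB.end()));
  if (record_spikes) {
    out["spike_unit"] = IntegerVector(sp_unit.begin(), sp_unit.end());
    out["spike_time"] = IntegerVector(sp_t.begin(), sp_t.end());
  }
  return out;
}

// FNV-1a over a raw vector; used for config hashing.
// [[Rcpp::export(rng = false)]]
String fnv1a_hex(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= static_cast<uint64_t>(bytes[i]);
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", static_cast<unsigned long long>(h));
  return String(buf);
}
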