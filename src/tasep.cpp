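#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Deterministic, platform-independent RNG: splitmix64 seeding + xoshiro256**.
// We avoid std::exponential_distribution because its output is not specified
// bit-for-bit by the standard; uniforms are built from the top 53 bits.
namespace {

struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1]; never 0 so -log(u) is finite
  double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return 1.0 - u;
  }

  double rexp(double rate) { return -std::log(unif()) / rate; }
};

} // namespace

// Single-replicate event-driven simulation of the inhomogeneous l-TASEP.
//
// A ribosome's position is the codon it decodes; it covers [i, i + s - 1].
// Initiation places a ribosome at codon 1 at rate lambda0 when codons 1..s
// are all uncovered. A ribosome at i < n hops to i+1 at rate lambda[i-1]
// when codon i+s is uncovered (or i+s > n); the ribosome at n vacates the
// lattice at rate lambda[n-1] (termination).
//
// Burn-in runs until `burn_term` terminations or simulated time
// `burn_time_cap`, whichever first; measurement then runs until
// `measure_term` further terminations or absolute time `max_time`.
// [[Rcpp::export(name = ".tasep_run_cpp")]]
List tasep_run_cpp(NumericVector rates, double lambda0, int s,
                   double seed_hi, double seed_lo,
                   int burn_term, double burn_time_cap,
                   int measure_term, double max_time,
                   bool collect_occupancy, bool check_exclusion) {
  const int n = rates.size();
  if (n < s) stop("gene length must be >= footprint");

  uint64_t seed = (static_cast<uint64_t>(static_cast<uint32_t>(seed_hi)) << 32)
                | static_cast<uint64_t>(static_cast<uint32_t>(seed_lo));
  Xoshiro256 rng(seed);

  // positions sorted ascending: front() is the most recently initiated
  // ribosome (smallest codon index), back() the one closest to termination.
  std::deque<int> pos;

  double t = 0.0;
  bool measuring = false;
  double measure_start = 0.0;
  long term_burn = 0, term_meas = 0;
  long init_total = 0, term_total = 0, init_meas = 0;
  double rib_time = 0.0;
  std::vector<double> occ;
  if (collect_occupancy) occ.assign(n, 0.0);

  std::vector<double> enab_rates;
  enab_rates.reserve(64);
  std::vector<int> enab_who; // -1 = initiation, otherwise deque index
  enab_who.reserve(64);

  bool low_confidence = false;

  for (;;) {
    // enumerate enabled events
    enab_rates.clear();
    enab_who.clear();
    double total = 0.0;
    const int k = static_cast<int>(pos.size());

    if (pos.empty() || pos.front() > s) {
      enab_rates.push_back(lambda0);
      enab_who.push_back(-1);
      total += lambda0;
    }
    for (int j = 0; j < k; ++j) {
      const int i = pos[j];
      bool enabled;
      if (i == n) {
        enabled = true; // termination
      } else if (j == k - 1) {
        enabled = true; // leading ribosome: no one ahead, site i+s is free
      } else {
        enabled = (pos[j + 1] - i) > s;
      }
      if (enabled) {
        enab_rates.push_back(rates[i - 1]);
        enab_who.push_back(j);
        total += rates[i - 1];
      }
    }

    if (total <= 0.0) stop("no enabled events (all rates zero?)");

    const double dt_raw = rng.rexp(total);
    double t_next = t + dt_raw;

    // time caps
    bool capped = false;
    if (!measuring && t_next >= burn_time_cap && term_burn < burn_term) {
      // burn-in ends by time: start measuring at the cap instant
      t = burn_time_cap;
      measuring = true;
      measure_start = t;
      
      continue; // re-enumerate (state unchanged), draw a fresh waiting time
    }
    if (measuring && t_next >= max_time) {
      t_next = max_time;
      capped = true;
    }

    // accumulate time-weighted statistics over [t, t_next)
    if (measuring) {
      const double dt = t_next - t;
      rib_time += dt * k;
      if (collect_occupancy) {
        for (int j = 0; j < k; ++j) {
          const int lo = pos[j] - 1;
          const int hi = std::min(pos[j] + s - 1, n) - 1;
          for (int c = lo; c <= hi; ++c) occ[c] += dt;
        }
      }
    }
    t = t_next;

    if (capped) {
      low_confidence = true;
      break;
    }

    // pick the event
    double u = rng.unif() * total;
    int pick = 0;
    const int m = static_cast<int>(enab_rates.size());
    for (; pick < m - 1; ++pick) {
      u -= enab_rates[pick];
      if (u <= 0.0) break;
    }

    const int who = enab_who[pick];
    if (who == -1) {
      pos.push_front(1);
      ++init_total;
      if (measuring) ++init_meas;
    } else if (pos[who] == n) {
      pos.pop_back();
      ++term_total;
      if (measuring) {
        ++term_meas;
        if (term_meas >= measure_term) break;
      } else {
        ++term_burn;
        if (term_burn >= burn_term) {
          measuring = true;
          measure_start = t;
        }
      }
    } else {
      pos[who] += 1;
    }

    if (check_exclusion) {
      for (size_t j = 1; j < pos.size(); ++j) {
        if (pos[j] - pos[j - 1] < s)
          stop("exclusion violated: footprints overlap");
      }
      if (!pos.empty() && (pos.front() < 1 || pos.back() > n))
        stop("position out of lattice");
    }
  }

  const double measure_time = t - measure_start;
  const double tr = (measure_time > 0.0) ? term_meas / measure_time : NA_REAL;
  const double mean_rib =
      (measure_time > 0.0) ? rib_time / measure_time : NA_REAL;

  NumericVector occupancy;
  if (collect_occupancy) {
    occupancy = NumericVector(n);
    if (measure_time > 0.0)
      for (int c = 0; c < n; ++c) occupancy[c] = occ[c] / measure_time;
  }

  return List::create(
      _["tr"] = tr, _["mean_ribosomes"] = mean_rib,
      _["occupancy"] = occupancy, _["n_initiations"] = (double)init_meas,
      _["n_terminations"] = (double)term_meas,
      _["init_total"] = (double)init_total,
      _["term_total"] = (double)term_total,
      _["bound_at_end"] = (double)pos.size(),
      _["measure_time"] = measure_time,
      _["low_confidence"] = low_confidence);
}
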