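#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Depletion time of one resource within a phase: smallest t > 0 with
//   sum_k n_k * (exp(g_k * t) - 1) = c.
// The left side is strictly increasing in t.  Analytic bracket: all
// consumers growing at the fastest rate deplete no later than the true
// time (lower bound); each single consumer alone depletes by
// log1p(c/n_k)/g_k, so the minimum of those is an upper bound.  Using
// the per-consumer bound keeps every exponent g_j * t <= log1p(c/n_j),
// so the exponentials cannot overflow.  Safeguarded Newton inside the
// bracket.
static double phase_depletion_time(const std::vector<double> &n,
                                   const std::vector<double> &g,
                                   double c, double tol) {
  const size_t m = n.size();
  if (c <= 0.0) return 0.0;
  if (m == 1) return std::log1p(c / n[0]) / g[0];

  double ntot = 0.0, gmax = g[0], hi = R_PosInf;
  for (size_t k = 0; k < m; ++k) {
    ntot += n[k];
    if (g[k] > gmax) gmax = g[k];
    double tk = std::log1p(c / n[k]) / g[k];
    if (tk < hi) hi = tk;
  }
  double lo = std::log1p(c / ntot) / gmax;
  double t = 0.5 * (lo + hi);

  for (int it = 0; it < 200; ++it) {
    double f = -c, fp = 0.0;
    for (size_t k = 0; k < m; ++k) {
      double e = std::exp(g[k] * t);
      f += n[k] * (e - 1.0);
      fp += n[k] * g[k] * e;
    }
    if (f > 0.0) hi = t; else lo = t;
    double tn = t - f / fp;
    if (!(tn > lo && tn < hi)) tn = 0.5 * (lo + hi); // bisect on NaN or escape
    if (std::fabs(tn - t) < tol) return tn;
    t = tn;
  }
  return t;
}

// Event-driven serial-dilution simulation.
//
// g:      S x N growth-rate matrix (hr^-1)
// pref:   S x N preference matrix, pref(mu, k) = 1-based resource index of
//         species mu's rank-(k+1) preference
// n0:     initial biomasses
// supply: n_cycles x N supply fractions (each row sums to 1)
// record_cycles: sorted 1-based cycle indices whose end-of-cycle fractions
//         are stored
// detail_from: 1-based cycle from which time-on-preference is accumulated
//
// [[Rcpp::export(name = ".sim_serial_dilution_cpp")]]
List sim_serial_dilution_cpp(NumericMatrix g, IntegerMatrix pref,
                             NumericVector n0, NumericMatrix supply,
                             double mortality, double extinct_frac,
                             IntegerVector record_cycles, int detail_from,
                             double root_tol, double simul_tol) {
  const int S = g.nrow(), N = g.ncol();
  const int n_cycles = supply.nrow();
  if (supply.ncol() != N) stop("supply has wrong number of resources");
  if (pref.nrow() != S || pref.ncol() != N) stop("pref has wrong shape");
  if (n0.size() != S) stop("n0 has wrong length");

  // rank_of[mu][i]: 0-based preference rank of resource i for species mu
  std::vector<int> rank_of(S * N);
  for (int mu = 0; mu < S; ++mu)
    for (int k = 0; k < N; ++k)
      rank_of[mu * N + (pref(mu, k) - 1)] = k;

  std::vector<double> n(n0.begin(), n0.end());
  std::vector<int> active;
  for (int mu = 0; mu < S; ++mu) {
    if (n[mu] < 0) stop("negative initial biomass");
    if (n[mu] > 0) active.push_back(mu);
  }
  if (active.empty()) stop("no species present at inoculation");

  NumericMatrix frac_out(record_cycles.size(), S);
  NumericMatrix dep_times(n_cycles, N);
  NumericVector cycle_lengths(n_cycles);
  IntegerVector extinction_cycle(S, NA_INTEGER);
  NumericMatrix tau(S, N); // time on preference rank, summed over recorded cycles
  int tau_cycles = 0;
  int rec_ptr = 0;

  std::vector<double> c(N);
  std::vector<bool> depleted(N);
  std::vector<int> eater(S);

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    double stot = 0.0;
    int n_avail = 0;
    for (int i = 0; i < N; ++i) {
      c[i] = supply(cyc, i);
      if (c[i] < 0) stop("negative supply");
      stot += c[i];
      depleted[i] = (c[i] <= 0.0);
      dep_times(cyc, i) = depleted[i] ? 0.0 : NA_REAL;
      if (!depleted[i]) ++n_avail;
    }
    if (n_avail == 0) stop("supply is all zero on cycle %d", cyc + 1);

    double t = 0.0;
    double biomass_start = 0.0;
    for (int mu : active) biomass_start += n[mu];
    const bool detail = (cyc + 1) >= detail_from;

    while (n_avail > 0) {
      if (active.empty()) stop("dynamics stalled: no species left mid-cycle");
      // assign each species its top remaining preference
      std::vector<std::vector<int> > eaters(N);
      for (int mu : active) {
        int r = -1;
        for (int k = 0; k < N; ++k) {
          int cand = pref(mu, k) - 1;
          if (!depleted[cand]) { r = cand; break; }
        }
        eater[mu] = r;
        eaters[r].push_back(mu);
      }
      // earliest depletion among resources that are being eaten
      double dt_min = R_PosInf;
      std::vector<double> dt_i(N, R_PosInf);
      for (int i = 0; i < N; ++i) {
        if (depleted[i] || eaters[i].empty()) continue;
        std::vector<double> nn, gg;
        nn.reserve(eaters[i].size());
        gg.reserve(eaters[i].size());
        for (int mu : eaters[i]) { nn.push_back(n[mu]); gg.push_back(g(mu, i)); }
        dt_i[i] = phase_depletion_time(nn, gg, c[i], root_tol);
        if (dt_i[i] < dt_min) dt_min = dt_i[i];
      }
      if (!R_finite(dt_min))
        stop("dynamics stalled: remaining resources have no consumers");

      // advance populations and concentrations by dt_min
      for (int i = 0; i < N; ++i) {
        if (depleted[i] || eaters[i].empty()) continue;
        double eaten = 0.0;
        for (int mu : eaters[i]) eaten += n[mu] * std::expm1(g(mu, i) * dt_min);
        c[i] -= eaten;
      }
      for (int mu : active) {
        if (detail) tau(mu, rank_of[mu * N + eater[mu]]) += dt_min;
        n[mu] *= std::exp(g(mu, eater[mu]) * dt_min);
      }
      t += dt_min;
      // deplete every resource whose event time coincides (within tolerance)
      for (int i = 0; i < N; ++i) {
        if (depleted[i]) continue;
        bool hit = (dt_i[i] <= dt_min + simul_tol) || (c[i] <= simul_tol);
        if (c[i] < -1e-8) stop("concentration went negative beyond tolerance");
        if (hit) {
          depleted[i] = true;
          c[i] = 0.0;
          dep_times(cyc, i) = t;
          --n_avail;
        }
      }
    }
    cycle_lengths[cyc] = t;
    if (detail) ++tau_cycles;

    // mass balance: yield 1, so biomass gained must equal total supply
    double biomass_end = 0.0;
    for (int mu : active) biomass_end += n[mu];
    if (std::fabs((biomass_end - biomass_start) - stot) > 1e-6)
      stop("mass balance violated on cycle %d (error %g)", cyc + 1,
           (biomass_end - biomass_start) - stot);

    if (rec_ptr < record_cycles.size() && record_cycles[rec_ptr] == cyc + 1) {
      for (int mu = 0; mu < S; ++mu) frac_out(rec_ptr, mu) = n[mu] / biomass_end;
      ++rec_ptr;
    }

    // mortality, then extinction pruning on population fractions
    std::vector<int> still;
    still.reserve(active.size());
    for (int mu : active) {
      n[mu] /= mortality;
      if (n[mu] / (biomass_end / mortality) < extinct_frac) {
        n[mu] = 0.0;
        extinction_cycle[mu] = cyc + 1;
      } else {
        still.push_back(mu);
      }
    }
    active.swap(still);
    if (active.empty()) stop("all species went extinct on cycle %d", cyc + 1);
  }

  return List::create(
      _["fractions"] = frac_out,
      _["recorded_cycles"] = record_cycles,
      _["depletion_times"] = dep_times,
      _["cycle_lengths"] = cycle_lengths,
      _["extinction_cycle"] = extinction_cycle,
      _["populations"] = NumericVector(n.begin(), n.end()),
      _["tau"] = tau,
      _["tau_cycles"] = tau_cycles);
}
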