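// Event-driven core of the metacommunity model.
//
// One elementary event per time step (Gillespie-style discrete clock).
// Three dynamical modes share a single stepping kernel:
//   mode 0 "neutral": innovation (prob nu) or neutral migration-sweep.
//   mode 1 "sweep":   ordered pair (i, j); carrier -> non-carrier pairs
//                     trigger migration-sweep (prob p_m) or HGT-sweep
//                     (prob p_h); everything else is a no-op.
//   mode 2 "full":    innovation (prob nu, new species carries the gene
//                     with prob B/M), neutral migration among same-status
//                     pairs, selective migration/HGT on carrier ->
//                     non-carrier pairs.
//
// All randomness comes from R's generator (unif_rand), so a run is fully
// reproducible from set.seed(). The draw order is mirrored exactly by the
// R-level single-step functions; keep the two in sync.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Meta {
  int M;
  std::vector<int> species;
  std::vector<char> carrier;
  std::unordered_map<int, int> counts; // label -> number of patches
  int S;                               // distinct species (incremental)
  int B;                               // carrier patches (incremental)
  int next_label;

  void init(const IntegerVector& sp, const LogicalVector& ca, int nl) {
    M = sp.size();
    species.assign(sp.begin(), sp.end());
    carrier.assign(M, 0);
    B = 0;
    for (int k = 0; k < M; ++k) {
      carrier[k] = ca[k] ? 1 : 0;
      if (carrier[k]) ++B;
    }
    counts.clear();
    for (int k = 0; k < M; ++k) ++counts[species[k]];
    S = static_cast<int>(counts.size());
    next_label = nl;
  }

  // patch j's resident species becomes `lab`
  void replace_species(int j, int lab) {
    int old = species[j];
    if (old == lab) return;
    auto it = counts.find(old);
    if (--(it->second) == 0) { counts.erase(it); --S; }
    auto ins = counts.emplace(lab, 0);
    if (ins.second) ++S;
    ++ins.first->second;
    species[j] = lab;
  }

  void innovate(int i, bool flag) {
    replace_species(i, next_label++);
    if (carrier[i] && !flag) { carrier[i] = 0; --B; }
    else if (!carrier[i] && flag) { carrier[i] = 1; ++B; }
  }

  void gain_gene(int j) {
    if (!carrier[j]) { carrier[j] = 1; ++B; }
  }
};

inline int pick(int M) {
  int k = static_cast<int>(unif_rand() * M);
  return (k >= M) ? (M - 1) : k;
}

// uniform over the M-1 patches other than i
inline int pick_other(int i, int M) {
  int k = static_cast<int>(unif_rand() * (M - 1));
  if (k >= M - 1) k = M - 2;
  return k + (k >= i);
}

inline void do_step(Meta& st, int mode, double nu, double pm, double ph) {
  const int M = st.M;
  if (mode != 1) {
    if (unif_rand() < nu) {
      int i = pick(M);
      bool flag = false;
      // gene status of a brand-new species: Bernoulli(B/M); the draw is
      // skipped when it is forced (B = 0 or B = M) so that the no-gene
      // dynamics consumes the same random stream as the neutral model
      if (mode == 2 && st.B > 0) {
        flag = (st.B == M) ? true : (unif_rand() < static_cast<double>(st.B) / M);
      }
      st.innovate(i, flag);
      return;
    }
  }
  int i = pick(M);
  int j = pick_other(i, M);
  if (mode == 0) { st.replace_species(j, st.species[i]); return; }
  const bool ci = st.carrier[i] != 0, cj = st.carrier[j] != 0;
  if (mode == 2 && ci == cj) { st.replace_species(j, st.species[i]); return; }
  if (ci && !cj) {
    double u = unif_rand();
    if (u < pm) {                     // genome-wide (migration) sweep
      st.replace_species(j, st.species[i]);
      st.gain_gene(j);
    } else if (u < pm + ph) {         // gene-specific (HGT) sweep
      st.gain_gene(j);
    }
  }
  // non-carrier -> carrier pairs: no-op (selection protects carriers)
}

} // namespace

// Run the model for up to n_steps elementary events.
//
// arrival_steps: sorted elapsed-step indices (0-based, relative to this
// run) at which a new beneficial gene arrives: all carrier flags are
// cleared and one uniformly chosen patch seeds the new gene.  Episode
// summaries are produced per inter-arrival window.
//
// Returned S_min is the minimum during the sweep phase of the window
// (up to fixation, if reached); S_min_all is over the whole window.
// [[Rcpp::export]]
List cpp_run(IntegerVector patch_species, LogicalVector patch_carrier,
             int next_label, double start_step, int arrivals_seen,
             int mode, double nu, double pm, double ph,
             double n_steps, double record_every,
             NumericVector arrival_steps, bool stop_at_fixation) {
  Meta st;
  st.init(patch_species, patch_carrier, next_label);
  const int M = st.M;
  const int64_t nsteps = static_cast<int64_t>(n_steps);
  const int64_t rec = record_every > 0 ? static_cast<int64_t>(record_every) : 0;

  std::vector<int64_t> arr(arrival_steps.begin(), arrival_steps.end());
  size_t next_arr = 0;

  // trajectory
  std::vector<double> r_step; std::vector<int> r_S, r_B, r_A;
  int n_arr_seen = arrivals_seen;
  auto record = [&](int64_t t) {
    r_step.push_back(static_cast<double>(t));
    r_S.push_back(st.S); r_B.push_back(st.B); r_A.push_back(n_arr_seen);
  };

  // episode bookkeeping
  std::vector<double> e_start, e_end, e_fix;
  std::vector<int> e_Sstart, e_Smin, e_Sminall, e_Smax, e_Send, e_Sfix;
  std::vector<double> e_Smean;
  std::vector<int> e_trunc;
  int64_t ep_start = 0;
  int ep_Sstart = st.S, ep_Smin = st.S, ep_Sminall = st.S, ep_Smax = st.S;
  int ep_Sfix = NA_INTEGER;
  double ep_Ssum = 0.0;
  int64_t ep_n = 0, ep_fix = -1;

  auto open_episode = [&](int64_t t) {
    ep_start = t; ep_Sstart = st.S; ep_Smin = st.S; ep_Sminall = st.S;
    ep_Smax = st.S; ep_Ssum = 0.0; ep_n = 0; ep_fix = -1; ep_Sfix = NA_INTEGER;
  };
  auto close_episode = [&](int64_t t, bool truncated) {
    e_start.push_back(static_cast<double>(ep_start));
    e_end.push_back(static_cast<double>(t));
    e_Sstart.push_back(ep_Sstart);
    e_Smin.push_back(ep_Smin);
    e_Sminall.push_back(ep_Sminall);
    e_Smax.push_back(ep_Smax);
    e_Smean.push_back(ep_n > 0 ? ep_Ssum / ep_n : static_cast<double>(st.S));
    e_Send.push_back(st.S);
    e_fix.push_back(ep_fix >= 0 ? static_cast<double>(ep_fix) : NA_REAL);
    e_Sfix.push_back(ep_Sfix);
    e_trunc.push_back(truncated ? 1 : 0);
  };
  auto apply_arrival = [&](int64_t t) {
    if (t > ep_start || ep_n > 0) close_episode(t, false);
    std::fill(st.carrier.begin(), st.carrier.end(), 0);
    st.B = 0;
    st.gain_gene(pick(M));
    ++n_arr_seen;
    open_episode(t);
  };

  record(0);
  int64_t t = 0;
  bool fixated_stop = false;
  for (; t < nsteps; ++t) {
    while (next_arr < arr.size() && arr[next_arr] == t) {
      apply_arrival(t);
      ++next_arr;
    }
    do_step(st, mode, nu, pm, ph);
    ep_Ssum += st.S; ++ep_n;
    if (ep_fix < 0) {
      if (st.S < ep_Smin) ep_Smin = st.S;
      if (st.B == M) { ep_fix = t + 1; ep_Sfix = st.S; }
    }
    if (st.S < ep_Sminall) ep_Sminall = st.S;
    if (st.S > ep_Smax) ep_Smax = st.S;
    if (rec > 0 && (t + 1) % rec == 0) record(t + 1);
    if (stop_at_fixation && st.B == M) { fixated_stop = true; ++t; break; }
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (rec == 0 || r_step.back() != static_cast<double>(t)) record(t);
  (void)fixated_stop;
  close_episode(t, mode != 0 && ep_fix < 0 && st.B < M);

  return List::create(
    _["records"] = DataFrame::create(
      _["step"] = NumericVector(r_step.begin(), r_step.end()),
      _["S"] = IntegerVector(r_S.begin(), r_S.end()),
      _["B"] = IntegerVector(r_B.begin(), r_B.end()),
      _["arrivals_seen"] = IntegerVector(r_A.begin(), r_A.end())),
    _["episodes"] = DataFrame::create(
      _["start_step"] = NumericVector(e_start.begin(), e_start.end()),
      _["end_step"] = NumericVector(e_end.begin(), e_end.end()),
      _["S_start"] = IntegerVector(e_Sstart.begin(), e_Sstart.end()),
      _["S_min"] = IntegerVector(e_Smin.begin(), e_Smin.end()),
      _["S_min_all"] = IntegerVector(e_Sminall.begin(), e_Sminall.end()),
      _["S_max"] = IntegerVector(e_Smax.begin(), e_Smax.end()),
      _["S_mean"] = NumericVector(e_Smean.begin(), e_Smean.end()),
      _["S_end"] = IntegerVector(e_Send.begin(), e_Send.end()),
      _["S_fix"] = IntegerVector(e_Sfix.begin(), e_Sfix.end()),
      _["fixation_step"] = NumericVector(e_fix.begin(), e_fix.end()),
      _["truncated"] = IntegerVector(e_trunc.begin(), e_trunc.end())),
    _["species"] = IntegerVector(st.species.begin(), st.species.end()),
    _["carrier"] = LogicalVector(st.carrier.begin(), st.carrier.end()),
    _["next_label"] = st.next_label,
    _["S"] = st.S,
    _["B"] = st.B,
    _["step"] = start_step + static_cast<double>(t),
    _["arrivals_seen"] = n_arr_seen,
    _["steps_done"] = static_cast<double>(t));
}
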