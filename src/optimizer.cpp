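// Evolutionary + greedy local-search optimizer for the methyl assignment
// mapping. The state is the methyl -> HMQC-peak map (-1 = unassigned);
// NOESY/geminal expected peaks contribute via precomputed best-match
// tables indexed by ordered HMQC-peak pairs. Scores follow the Gaussian
// alignment + degeneracy-penalty form implemented in score_assignment();
// the R function is the reference, this file is the fast path.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// splitmix64: small, portable, deterministic across platforms
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return n > 0 ? (int)(next() % (uint64_t)n) : 0; }
};

struct Problem {
  int n = 0, nq = 0;
  std::vector<std::vector<int>> allowed;
  std::vector<std::vector<char>> allowed_mask;
  std::vector<int> e_a, e_b, e_mat;
  std::vector<double> e_prob;
  std::vector<double> hmqc_prob;            // per-methyl HMQC expected prob
  std::vector<std::vector<double>> mats;    // column-major nq x nq
  std::vector<double> H, C;
  double tol_h = 0.04, tol_c = 0.4, lambda = 0.5, mu = 0.0;
  std::vector<double> m_deg, q_deg;  // expected / measured NOE degrees
  std::vector<std::vector<int>> incident;   // non-HMQC expected rows per methyl
  // peaks whose 13C (1H) shift lies within the tolerance of each peak's
  // shift (strict inequality; includes the peak itself), with the
  // proximity weight (1 - delta/tol)^2 of each pair
  std::vector<std::vector<std::pair<int, double>>> cneigh, hneigh;

  inline double mat(int t, int qa, int qb) const {
    return mats[t][(size_t)qb * nq + qa];
  }
};

Problem unpack(const List& pk) {
  Problem p;
  p.n = as<int>(pk["n"]);
  p.nq = as<int>(pk["nq"]);
  List allowed = pk["allowed"];
  p.allowed.resize(p.n);
  p.allowed_mask.assign(p.n, std::vector<char>(p.nq, 0));
  for (int m = 0; m < p.n; ++m) {
    IntegerVector a = allowed[m];
    p.allowed[m].assign(a.begin(), a.end());
    for (int q : p.allowed[m]) p.allowed_mask[m][q] = 1;
  }
  IntegerVector ea = pk["e_a"], eb = pk["e_b"], em = pk["e_mat"];
  NumericVector ep = pk["e_prob"];
  p.e_a.assign(ea.begin(), ea.end());
  p.e_b.assign(eb.begin(), eb.end());
  p.e_mat.assign(em.begin(), em.end());
  p.e_prob.assign(ep.begin(), ep.end());
  List mats = pk["mats"];
  p.mats.resize(mats.size());
  for (int t = 0; t < mats.size(); ++t) {
    NumericMatrix M = mats[t];
    p.mats[t].assign(M.begin(), M.end());
  }
  NumericVector H = pk["H"], C = pk["C"];
  p.H.assign(H.begin(), H.end());
  p.C.assign(C.begin(), C.end());
  p.tol_h = as<double>(pk["tol_h"]);
  p.tol_c = as<double>(pk["tol_c"]);
  p.lambda = as<double>(pk["lambda"]);
  p.mu = as<double>(pk["mu"]);
  NumericVector md = pk["m_deg"], qd = pk["q_deg"];
  p.m_deg.assign(md.begin(), md.end());
  p.q_deg.assign(qd.begin(), qd.end());

  p.hmqc_prob.assign(p.n, 0.0);
  p.incident.resize(p.n);
  for (size_t e = 0; e < p.e_a.size(); ++e) {
    if (p.e_mat[e] < 0) {                    // HMQC expected peak
      if (p.e_a[e] >= 0) p.hmqc_prob[p.e_a[e]] += p.e_prob[e];
    } else {
      if (p.e_a[e] >= 0) p.incident[p.e_a[e]].push_back((int)e);
      if (p.e_b[e] >= 0 && p.e_b[e] != p.e_a[e])
        p.incident[p.e_b[e]].push_back((int)e);
    }
  }
  p.cneigh.resize(p.nq);
  p.hneigh.resize(p.nq);
  for (int u = 0; u < p.nq; ++u) {
    for (int v = 0; v < p.nq; ++v) {
      double dc = std::fabs(p.C[u] - p.C[v]) / p.tol_c;
      if (dc < 1.0) p.cneigh[u].push_back({v, (1 - dc) * (1 - dc)});
      double dh = std::fabs(p.H[u] - p.H[v]) / p.tol_h;
      if (dh < 1.0) p.hneigh[u].push_back({v, (1 - dh) * (1 - dh)});
    }
  }
  return p;
}

struct State {
  std::vector<int> q;      // -1 = unassigned
  std::vector<int> amult;  // # methyls assigned to each peak
  // degeneracy fields: degC[v] = sum over assigned methyls m of the 13C
  // proximity weight between peak v and peak q[m] (degH likewise)
  std::vector<double> degC, degH;
  double score = 0.0;
};

// rebuild amult and the degeneracy fields from q
void rebuild_aux(const Problem& p, State& st) {
  st.amult.assign(p.nq, 0);
  st.degC.assign(p.nq, 0.0);
  st.degH.assign(p.nq, 0.0);
  for (int v : st.q) {
    if (v < 0) continue;
    ++st.amult[v];
    for (const auto& uw : p.cneigh[v]) st.degC[uw.first] += uw.second;
    for (const auto& uw : p.hneigh[v]) st.degH[uw.first] += uw.second;
  }
}

// proximity weights between two peaks (1 at zero separation, 0 at the
// tolerance edge)
inline double wpair(const Problem& p, int u, int v) {
  double dc = std::fabs(p.C[u] - p.C[v]) / p.tol_c;
  double dh = std::fabs(p.H[u] - p.H[v]) / p.tol_h;
  double w = 0.0;
  if (dc < 1.0) w += (1 - dc) * (1 - dc);
  if (dh < 1.0) w += (1 - dh) * (1 - dh);
  return w;
}

double full_score(const Problem& p, const std::vector<int>& q) {
  double s = 0.0;
  for (int m = 0; m < p.n; ++m)
    if (q[m] >= 0) s += p.hmqc_prob[m];
  for (size_t e = 0; e < p.e_a.size(); ++e) {
    int t = p.e_mat[e];
    if (t < 0) continue;
    int qa = q[p.e_a[e]], qb = q[p.e_b[e]];
    if (qa >= 0 && qb >= 0) s += p.e_prob[e] * p.mat(t, qa, qb);
  }
  double deg = 0.0;
  for (int i = 0; i < p.n; ++i) {
    if (q[i] < 0) continue;
    for (int j = i + 1; j < p.n; ++j) {
      if (q[j] < 0) continue;
      double dc = std::fabs(p.C[q[i]] - p.C[q[j]]) / p.tol_c;
      if (dc < 1.0) deg += (1 - dc) * (1 - dc);
      double dh = std::fabs(p.H[q[i]] - p.H[q[j]]) / p.tol_h;
      if (dh < 1.0) deg += (1 - dh) * (1 - dh);
    }
  }
  std::vector<char> used(p.nq, 0);
  int n_used = 0;
  for (int v : q) {
    if (v >= 0 && !used[v]) { used[v] = 1; ++n_used; }
  }
  return s - p.lambda * deg - p.mu * (p.nq - n_used);
}

// score change of setting q[m] = v; does not modify the state
double delta_set(const Problem& p, State& st, int m, int v) {
  int old = st.q[m];
  if (old == v) return 0.0;
  double d = 0.0;
  if ((v >= 0) != (old >= 0)) d += (v >= 0 ? 1.0 : -1.0) * p.hmqc_prob[m];
  const std::vector<int>& q = st.q;
  for (int e : p.incident[m]) {
    int a = p.e_a[e], b = p.e_b[e], t = p.e_mat[e];
    double pr = p.e_prob[e];
    if (a == m && b == m) {
      if (old >= 0) d -= pr * p.mat(t, old, old);
      if (v >= 0) d += pr * p.mat(t, v, v);
    } else if (a == m) {
      int qp = q[b];
      if (qp < 0) continue;
      if (old >= 0) d -= pr * p.mat(t, old, qp);
      if (v >= 0) d += pr * p.mat(t, v, qp);
    } else {
      int qp = q[a];
      if (qp < 0) continue;
      if (old >= 0) d -= pr * p.mat(t, qp, old);
      if (v >= 0) d += pr * p.mat(t, qp, v);
    }
  }
  if (p.lambda != 0.0) {
    // degeneracy via the maintained fields, excluding m's own contribution
    double dd = 0.0;
    if (v >= 0) {
      dd += st.degC[v] + st.degH[v];
      if (old >= 0) dd -= wpair(p, v, old);
    }
    if (old >= 0) {
      dd -= st.degC[old] + st.degH[old] - wpair(p, old, old);
    }
    d -= p.lambda * dd;
  }
  if (p.mu != 0.0) {
    if (old >= 0 && st.amult[old] == 1) d -= p.mu; // old peak becomes unused
    if (v >= 0 && st.amult[v] == (old == v ? 1 : 0)) d += p.mu;
  }
  return d;
}

// apply q[m] = v with a precomputed score change
inline void apply_set(const Problem& p, State& st, int m, int v, double d) {
  int old = st.q[m];
  if (old >= 0) {
    --st.amult[old];
    for (const auto& uw : p.cneigh[old]) st.degC[uw.first] -= uw.second;
    for (const auto& uw : p.hneigh[old]) st.degH[uw.first] -= uw.second;
  }
  if (v >= 0) {
    ++st.amult[v];
    for (const auto& uw : p.cneigh[v]) st.degC[uw.first] += uw.second;
    for (const auto& uw : p.hneigh[v]) st.degH[uw.first] += uw.second;
  }
  st.q[m] = v;
  st.score += d;
}

const double kEps = 1e-12;

// steepest single-methyl insertion used during reconstruction
void steepest_insert(const Problem& p, State& st, int m) {
  int best_v = st.q[m];
  double best_d = 0.0;
  for (int v : p.allowed[m]) {
    if (v == st.q[m]) continue;
    double d = delta_set(p, st, m, v);
    if (d > best_d) { best_d = d; best_v = v; }
  }
  if (best_v != st.q[m]) apply_set(p, st, m, best_v, best_d);
}

// unrealized expected-peak probability mass around a methyl: incident
// expected peaks that are unmapped or poorly aligned in the current state
double deficit(const Problem& p, const State& st, int m) {
  if (st.q[m] < 0) return p.hmqc_prob[m];
  double d = 0.0;
  for (int e : p.incident[m]) {
    int a = p.e_a[e], b = p.e_b[e];
    int qa = st.q[a], qb = st.q[b];
    if (qa < 0 || qb < 0) {
      d += 0.5 * p.e_prob[e];
    } else {
      d += p.e_prob[e] * (1.0 - p.mat(p.e_mat[e], qa, qb));
    }
  }
  return d;
}

// ruin-and-recreate: unassign a methyl and its expected-peak neighbors,
// reinsert each greedily in random order; revert if the score drops.
// The seed methyl is the worst of three random candidates, measured by
// unrealized expected-peak mass.
void lns_move(const Problem& p, State& st, Rng& rng, int max_size) {
  int m0 = rng.below(p.n);
  for (int t = 0; t < 2; ++t) {
    int m2 = rng.below(p.n);
    if (deficit(p, st, m2) > deficit(p, st, m0)) m0 = m2;
  }
  std::vector<int> sel{m0};
  std::vector<char> in_sel(p.n, 0);
  in_sel[m0] = 1;
  for (int e : p.incident[m0]) {
    int other = (p.e_a[e] == m0) ? p.e_b[e] : p.e_a[e];
    if (other >= 0 && !in_sel[other]) {
      in_sel[other] = 1;
      sel.push_back(other);
      if ((int)sel.size() >= max_size) break;
    }
  }
  std::vector<int> saved(sel.size());
  double saved_score = st.score;
  for (size_t i = 0; i < sel.size(); ++i) saved[i] = st.q[sel[i]];
  for (int m : sel) {
    if (st.q[m] >= 0) apply_set(p, st, m, -1, delta_set(p, st, m, -1));
  }
  std::vector<int> order(sel);
  for (size_t i = order.size() - 1; i > 0; --i) {
    size_t j = rng.below((int)i + 1);
    std::swap(order[i], order[j]);
  }
  for (int m : order) steepest_insert(p, st, m);
  // second pass lets late insertions improve early ones
  for (int m : order) {
    if (st.q[m] >= 0) {
      double du = delta_set(p, st, m, -1);
      if (du > kEps) apply_set(p, st, m, -1, du);
    }
    steepest_insert(p, st, m);
  }
  if (st.score < saved_score - kEps) {
    for (size_t i = 0; i < sel.size(); ++i) {
      int m = sel[i];
      if (st.q[m] != saved[i])
        apply_set(p, st, m, saved[i], delta_set(p, st, m, saved[i]));
    }
    st.score = saved_score; // cancel accumulated rounding drift
  }
}

// ejection chain seeded at an unused measured peak: pull the best methyl
// onto the unused peak, then continue from the peak it freed; accept the
// chain only if the total change is non-negative
void ejection_move(const Problem& p, State& st, Rng& rng, int max_depth) {
  std::vector<int> unused;
  for (int v = 0; v < p.nq; ++v)
    if (st.amult[v] == 0) unused.push_back(v);
  if (unused.empty()) return;
  int u = unused[rng.below((int)unused.size())];
  std::vector<std::pair<int, int>> trail; // (methyl, previous peak)
  double total = 0.0;
  for (int depth = 0; depth < max_depth; ++depth) {
    int best_m = -1;
    double best_d = -1e18;
    for (int m = 0; m < p.n; ++m) {
      if (!p.allowed_mask[m][u] || st.q[m] == u) continue;
      double d = delta_set(p, st, m, u);
      if (d > best_d) { best_d = d; best_m = m; }
    }
    if (best_m < 0) break;
    int freed = st.q[best_m];
    trail.push_back({best_m, freed});
    apply_set(p, st, best_m, u, best_d);
    total += best_d;
    if (total >= kEps) break; // net gain already realized
    if (freed < 0 || st.amult[freed] != 0) break;
    u = freed;
  }
  if (total < -kEps) {
    for (size_t i = trail.size(); i > 0; --i) {
      int m = trail[i - 1].first, v = trail[i - 1].second;
      double d = delta_set(p, st, m, v);
      apply_set(p, st, m, v, d);
    }
  }
}

// one steepest-descent pass over all methyls in random order; returns the
// total score gain
double steepest_sweep(const Problem& p, State& st, Rng& rng) {
  std::vector<int> order(p.n);
  for (int i = 0; i < p.n; ++i) order[i] = i;
  for (int i = p.n - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(order[i], order[j]);
  }
  double gain = 0.0;
  for (int m : order) {
    int best_v = st.q[m];
    double best_d = 0.0;
    for (int v : p.allowed[m]) {
      if (v == st.q[m]) continue;
      double d = delta_set(p, st, m, v);
      if (d > best_d) { best_d = d; best_v = v; }
    }
    if (st.q[m] >= 0) {
      double du = delta_set(p, st, m, -1);
      if (du > best_d) { best_d = du; best_v = -1; }
    }
    if (best_v != st.q[m] && best_d > kEps) {
      apply_set(p, st, m, best_v, best_d);
      gain += best_d;
    }
  }
  return gain;
}

void sweep_to_convergence(const Problem& p, State& st, Rng& rng,
                          int max_sweeps) {
  for (int s = 0; s < max_sweeps; ++s) {
    if (steepest_sweep(p, st, rng) <= 1e-6) break;
  }
}

// greedy local search: steepest / ruin-recreate / reassign / unassign /
// swap proposals with greedy acceptance
void local_steps(const Problem& p, State& st, long iterations, Rng& rng) {
  for (long it = 0; it < iterations; ++it) {
    double r = rng.unif();
    if (r < 0.15) {
      int m = rng.below(p.n);
      const std::vector<int>& opts = p.allowed[m];
      if (opts.empty()) continue;
      int best_v = st.q[m];
      double best_d = 0.0;
      for (int v : opts) {
        if (v == st.q[m]) continue;
        double d = delta_set(p, st, m, v);
        if (d > best_d) { best_d = d; best_v = v; }
      }
      if (st.q[m] >= 0) {
        double du = delta_set(p, st, m, -1);
        if (du > best_d) { best_d = du; best_v = -1; }
      }
      if (best_v != st.q[m] && best_d >= -kEps) apply_set(p, st, m, best_v, best_d);
    } else if (r < 0.22) {
      lns_move(p, st, rng, 8);
    } else if (r < 0.28) {
      ejection_move(p, st, rng, 8);
    } else if (r < 0.5) {
      int m = rng.below(p.n);
      const std::vector<int>& opts = p.allowed[m];
      if (opts.empty()) continue;
      int v = opts[rng.below((int)opts.size())];
      if (v == st.q[m]) continue;
      double d = delta_set(p, st, m, v);
      if (d >= -kEps) apply_set(p, st, m, v, d);
    } else if (r < 0.6) {
      int m = rng.below(p.n);
      if (st.q[m] < 0) continue;
      double d = delta_set(p, st, m, -1);
      if (d >= -kEps) apply_set(p, st, m, -1, d);
    } else {
      if (p.n < 2) continue;
      int m1 = rng.below(p.n);
      int m2 = rng.below(p.n - 1);
      if (m2 >= m1) ++m2;
      int v1 = st.q[m2], v2 = st.q[m1];
      if (v1 == v2) continue;
      if (v1 >= 0 && !p.allowed_mask[m1][v1]) continue;
      if (v2 >= 0 && !p.allowed_mask[m2][v2]) continue;
      double d1 = delta_set(p, st, m1, v1);
      apply_set(p, st, m1, v1, d1);
      double d2 = delta_set(p, st, m2, v2);
      if (d1 + d2 >= -kEps) {
        apply_set(p, st, m2, v2, d2);
      } else {
        apply_set(p, st, m1, v2, -d1); // revert
      }
    }
  }
}

// random injective-where-possible start; with probability one half the
// start is degree-guided: methyls pick an unused allowed peak whose
// measured NOE degree resembles their expected degree (with noise),
// which places the search near plausible network embeddings
State random_state(const Problem& p, Rng& rng) {
  State st;
  st.q.assign(p.n, -1);
  std::vector<char> used(p.nq, 0);
  std::vector<int> order(p.n);
  for (int i = 0; i < p.n; ++i) order[i] = i;
  for (int i = p.n - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(order[i], order[j]);
  }
  bool guided = (rng.next() & 1) != 0;
  std::vector<int> opts;
  for (int m : order) {
    opts.clear();
    for (int q : p.allowed[m])
      if (!used[q]) opts.push_back(q);
    if (opts.empty()) continue;
    int v;
    if (guided) {
      double best = 1e18;
      v = opts[0];
      for (int q : opts) {
        double cost = std::fabs(p.q_deg[q] - p.m_deg[m]) +
          2.5 * rng.unif();
        if (cost < best) { best = cost; v = q; }
      }
    } else {
      v = opts[rng.below((int)opts.size())];
    }
    st.q[m] = v;
    used[v] = 1;
  }
  rebuild_aux(p, st);
  st.score = full_score(p, st.q);
  return st;
}

} // namespace

// [[Rcpp::export]]
List cpp_local_optimize(List pack, IntegerVector assign0, int iterations,
                        int seed) {
  Problem p = unpack(pack);
  State st;
  st.q.resize(p.n);
  for (int m = 0; m < p.n; ++m) st.q[m] = assign0[m] - 1; // 0 -> -1
  rebuild_aux(p, st);
  st.score = full_score(p, st.q);
  Rng rng((uint64_t)seed * 0x100000001B3ULL + 1442695040888963407ULL);
  local_steps(p, st, iterations, rng);
  st.score = full_score(p, st.q); // exact, drift-free
  IntegerVector out(p.n);
  for (int m = 0; m < p.n; ++m) out[m] = st.q[m] + 1;
  return List::create(_["assign"] = out, _["score"] = st.score);
}

// [[Rcpp::export]]
List cpp_evolve(List pack, int population, int generations, int stagnation,
                int local_iterations, double mutation_rate, int seed) {
  Problem p = unpack(pack);
  const double mu_full = p.mu;
  Rng rng((uint64_t)seed * 0x100000001B3ULL + 1442695040888963407ULL);
  long per_child = std::max(1L, (long)std::llround(
      (double)local_iterations / (double)generations));

  // the completeness penalty is annealed: search starts on the relaxed
  // landscape (mu = 0), where doubled peaks act as transit states, and
  // reaches the full penalty by mid-run
  auto mu_at = [&](int g) {
    if (generations <= 2) return mu_full;
    return mu_full * std::min(1.0, (double)g / (0.35 * generations));
  };

  p.mu = mu_at(0);
  std::vector<State> pop(population);
  for (int i = 0; i < population; ++i) {
    pop[i] = random_state(p, rng);
    sweep_to_convergence(p, pop[i], rng, 8);
    for (int t = 0; t < 2; ++t) ejection_move(p, pop[i], rng, 8);
  }

  // best-ever state, judged at the full penalty
  Problem pfull = p;
  pfull.mu = mu_full;
  State best = pop[0];
  best.score = full_score(pfull, best.q);
  for (int i = 1; i < population; ++i) {
    double fs = full_score(pfull, pop[i].q);
    if (fs > best.score) { best = pop[i]; best.score = fs; }
  }

  auto tournament = [&]() -> const State& {
    int a = rng.below(population), b = rng.below(population);
    return pop[a].score >= pop[b].score ? pop[a] : pop[b];
  };

  int since_improved = 0, gen = 0;
  for (gen = 1; gen <= generations; ++gen) {
    p.mu = mu_at(gen);
    std::vector<State> next(population);
    next[0] = best; // elitism
    next[0].score = full_score(p, next[0].q);
    sweep_to_convergence(p, next[0], rng, 20);
    for (int t = 0; t < 4; ++t) ejection_move(p, next[0], rng, 8);
    local_steps(p, next[0], per_child, rng);
    for (int i = 1; i < population; ++i) {
      State child;
      {
        const State& p1 = tournament();
        const State& p2 = tournament();
        child.q.resize(p.n);
        for (int m = 0; m < p.n; ++m)
          child.q[m] = (rng.next() & 1) ? p1.q[m] : p2.q[m];
        // clones of a converged pair get a much stronger shake
        double mr = (p1.q == p2.q) ? 4.0 * mutation_rate : mutation_rate;
        for (int m = 0; m < p.n; ++m) {
          if (rng.unif() < mr) {
            if (rng.unif() < 0.1 || p.allowed[m].empty()) {
              child.q[m] = -1;
            } else {
              child.q[m] = p.allowed[m][rng.below((int)p.allowed[m].size())];
            }
          }
        }
        rebuild_aux(p, child);
        child.score = full_score(p, child.q);
      }
      sweep_to_convergence(p, child, rng, 6);
      for (int t = 0; t < 4; ++t) ejection_move(p, child, rng, 8);
      local_steps(p, child, per_child, rng);
      next[i] = std::move(child);
    }
    pop = std::move(next);
    double prev_best = best.score;
    for (int i = 0; i < population; ++i) {
      double fs = full_score(pfull, pop[i].q);
      if (fs > best.score) { best = pop[i]; best.score = fs; }
    }
    if (best.score > prev_best + 1e-12) {
      since_improved = 0;
    } else if (p.mu >= mu_full && ++since_improved >= stagnation) {
      break;
    }
  }

  best.score = full_score(pfull, best.q); // exact, drift-free
  IntegerVector out(p.n);
  for (int m = 0; m < p.n; ++m) out[m] = best.q[m] + 1;
  return List::create(_["assign"] = out, _["score"] = best.score,
                      _["generations"] = std::min(gen, generations));
}
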