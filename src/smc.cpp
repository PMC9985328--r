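#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Neutral coalescent simulator with recombination along a chromosome,
// using the SMC' approximation: an initial genealogy is drawn at the left
// end under the (possibly structured, piecewise-constant) coalescent, and
// marginal trees along the sequence are updated at recombination
// breakpoints by detaching a lineage at a uniformly chosen point and
// re-coalescing it into the standing genealogy. Mutations are Poisson on
// branches under an infinite-sites model.
//
// Demography: epochs with start times (generations, ascending from 0) and
// per-epoch sizes of up to two demes in chromosomes (2N). A deme size of 0
// closes the deme: at the first epoch where deme 2 is closed, its lineages
// merge into deme 1. Migration is symmetric at the given per-lineage
// per-generation rate while both demes are open. All samples are taken
// from deme 1 at time 0.

namespace {

struct Demography {
  std::vector<double> t0, size1, size2, mig;
  int epoch_at(double t) const {
    int e = (int)t0.size() - 1;
    while (e > 0 && t < t0[e]) --e;
    return e;
  }
  double epoch_end(int e) const {
    return (e + 1 < (int)t0.size()) ? t0[e + 1] : R_PosInf;
  }
  bool two_demes(int e) const { return size2[e] > 0; }
};

struct MigEvent { double t; int deme; };

struct Tree {
  int k, n_nodes, root;
  std::vector<int> parent, child1, child2, deme0;
  std::vector<double> time;
  std::vector<std::vector<MigEvent>> migs;

  void init(int k_) {
    k = k_; n_nodes = 2 * k - 1;
    parent.assign(n_nodes, -1);
    child1.assign(n_nodes, -1);
    child2.assign(n_nodes, -1);
    deme0.assign(n_nodes, 0);
    time.assign(n_nodes, 0.0);
    migs.assign(n_nodes, {});
    root = -1;
  }
  int deme_at(int v, double t) const {
    int d = deme0[v];
    for (const auto& me : migs[v]) {
      if (me.t <= t) d = me.deme; else break;
    }
    return d;
  }
  double ptime(int v) const {
    return parent[v] >= 0 ? time[parent[v]] : R_PosInf;
  }
  bool alive_at(int v, double t) const {
    return time[v] <= t && t < ptime(v);
  }
  double total_length() const {
    double L = 0;
    for (int v = 0; v < n_nodes; ++v)
      if (parent[v] >= 0) L += time[parent[v]] - time[v];
    return L;
  }
  void replace_child(int p, int oldc, int newc) {
    if (child1[p] == oldc) child1[p] = newc;
    else if (child2[p] == oldc) child2[p] = newc;
    else stop("internal error: replace_child");
  }
  int leaves_under(int v, std::vector<int>& out) const {
    // iterative DFS collecting leaf indices
    out.clear();
    std::vector<int> st{v};
    while (!st.empty()) {
      int u = st.back(); st.pop_back();
      if (u < k) out.push_back(u);
      else { st.push_back(child1[u]); st.push_back(child2[u]); }
    }
    return (int)out.size();
  }
};

int pick_lineage(const std::vector<int>& act, const std::vector<int>& demes,
                 int want_deme, int n_in_deme) {
  int idx = (int)std::floor(R::unif_rand() * n_in_deme);
  if (idx >= n_in_deme) idx = n_in_deme - 1;
  for (size_t i = 0; i < act.size(); ++i) {
    if (demes[i] == want_deme) {
      if (idx == 0) return (int)i;
      --idx;
    }
  }
  stop("internal error: pick_lineage");
}

// Draw the genealogy at the left chromosome end.
void initial_tree(Tree& tr, const Demography& dem) {
  const int k = tr.k;
  std::vector<int> act(k), demes(k, 0);
  for (int i = 0; i < k; ++i) { act[i] = i; tr.time[i] = 0; tr.deme0[i] = 0; }
  int next_node = k;
  double t = 0;
  int n_act = k;
  while (n_act > 1) {
    int e = dem.epoch_at(t);
    double t_end = dem.epoch_end(e);
    // forced merge when deme 2 closes at this epoch's start
    if (!dem.two_demes(e)) {
      for (int i = 0; i < n_act; ++i) {
        if (demes[i] == 1) {
          demes[i] = 0;
          tr.migs[act[i]].push_back({t, 0});
        }
      }
    }
    int n1 = 0, n2 = 0;
    for (int i = 0; i < n_act; ++i) (demes[i] == 0 ? n1 : n2)++;
    double rc1 = 0.5 * n1 * (n1 - 1) / dem.size1[e];
    double rc2 = dem.two_demes(e) ? 0.5 * n2 * (n2 - 1) / dem.size2[e] : 0.0;
    double rm = dem.two_demes(e) ? dem.mig[e] * n_act : 0.0;
    double R = rc1 + rc2 + rm;
    if (R <= 0) { t = t_end; continue; }
    double dt = R::exp_rand() / R;
    if (t + dt >= t_end) { t = t_end; continue; }
    t += dt;
    double u = R::unif_rand() * R;
    if (u < rc1 + rc2) {
      int d = (u < rc1) ? 0 : 1;
      int ia = pick_lineage(act, demes, d, d == 0 ? n1 : n2);
      int ib;
      do { ib = pick_lineage(act, demes, d, d == 0 ? n1 : n2); } while (ib == ia);
      int p = next_node++;
      tr.time[p] = t; tr.deme0[p] = d;
      tr.child1[p] = act[ia]; tr.child2[p] = act[ib];
      tr.parent[act[ia]] = p; tr.parent[act[ib]] = p;
      act[ia] = p; demes[ia] = d;
      act[ib] = act[n_act - 1]; demes[ib] = demes[n_act - 1];
      --n_act;
    } else {
      int i = (int)std::floor(R::unif_rand() * n_act);
      if (i >= n_act) i = n_act - 1;
      demes[i] = 1 - demes[i];
      tr.migs[act[i]].push_back({t, demes[i]});
    }
  }
  tr.root = act[0];
}

// Re-coalesce a floating lineage starting at (time u, deme dm) into the
// standing tree (branch b above u remains a valid target: hitting it makes
// the recombination invisible; the root counts as a branch of infinite
// length). Returns target node c and time t_star; records the floating
// lineage's migration path in float_migs.
//
// Branch counts per deme are swept along a sorted event list (coalescences
// and recorded migration events above u), so each call is O(k log k).
// Fast path for unstructured demographies: branch counts follow directly
// from the sorted internal-node times (k lineages minus completed
// coalescences), so no event list is needed.
void recoalesce_single(const Tree& tr, const Demography& dem,
                       const std::vector<double>& itimes, double u,
                       double& t_star, int& c_out) {
  double t = u;
  size_t ie = std::upper_bound(itimes.begin(), itimes.end(), u) - itimes.begin();
  for (int guard = 0; guard < 100000000; ++guard) {
    int e = dem.epoch_at(t);
    double t_bp = dem.epoch_end(e);
    if (ie < itimes.size() && itimes[ie] < t_bp) t_bp = itimes[ie];
    int cnt = tr.k - (int)ie;
    if (cnt < 1) cnt = 1;  // above the root: the trunk lineage
    double R = cnt / dem.size1[e];
    double dt = (R > 0) ? R::exp_rand() / R : R_PosInf;
    if (t + dt >= t_bp) {
      t = t_bp;
      while (ie < itimes.size() && itimes[ie] <= t) ++ie;
      continue;
    }
    t_star = t + dt;
    int idx = (int)std::floor(R::unif_rand() * cnt);
    if (idx >= cnt) idx = cnt - 1;
    for (int v = 0; v < tr.n_nodes; ++v) {
      if (tr.alive_at(v, t_star)) {
        if (idx == 0) { c_out = v; return; }
        --idx;
      }
    }
    stop("internal error: coalescence target not found (single deme)");
  }
  stop("recoalesce_single: did not terminate");
}

void recoalesce(const Tree& tr, const Demography& dem, double u, int dm,
                double& t_star, int& c_out, std::vector<MigEvent>& float_migs) {
  float_migs.clear();
  // counts of alive branches per deme at time u
  int cnt[2] = {0, 0};
  for (int v = 0; v < tr.n_nodes; ++v)
    if (tr.alive_at(v, u)) cnt[tr.deme_at(v, u)]++;
  // events above u that change the per-deme counts
  struct Ev { double t; int d_from, d_to; };  // d_to = -1: coalescence
  std::vector<Ev> evs;
  evs.reserve(tr.n_nodes);
  for (int v = 0; v < tr.n_nodes; ++v) {
    if (v >= tr.k && tr.time[v] > u)
      evs.push_back({tr.time[v], tr.deme0[v], -1});
    int d = tr.deme0[v];
    for (const auto& me : tr.migs[v]) {
      if (me.t > u) evs.push_back({me.t, d, me.deme});
      d = me.deme;
    }
  }
  std::sort(evs.begin(), evs.end(),
            [](const Ev& a, const Ev& b) { return a.t < b.t; });
  size_t ie = 0;
  double t = u;
  for (int guard = 0; guard < 100000000; ++guard) {
    int e = dem.epoch_at(t);
    if (!dem.two_demes(e) && dm == 1) {
      dm = 0;
      float_migs.push_back({t, 0});
    }
    double t_bp = dem.epoch_end(e);
    if (ie < evs.size() && evs[ie].t < t_bp) t_bp = evs[ie].t;
    double size_d = dm == 0 ? dem.size1[e] : dem.size2[e];
    double rc = (size_d > 0) ? cnt[dm] / size_d : 0.0;
    double rm = dem.two_demes(e) ? dem.mig[e] : 0.0;
    double R = rc + rm;
    double dt = (R > 0) ? R::exp_rand() / R : R_PosInf;
    if (t + dt >= t_bp) {
      t = t_bp;
      while (ie < evs.size() && evs[ie].t <= t) {
        const Ev& ev = evs[ie++];
        if (ev.d_to < 0) cnt[ev.d_from]--;           // two branches -> one
        else { cnt[ev.d_from]--; cnt[ev.d_to]++; }   // migration
      }
      continue;
    }
    t += dt;
    if (R::unif_rand() * R < rc) {
      t_star = t;
      int n_same = cnt[dm];
      int idx = (int)std::floor(R::unif_rand() * n_same);
      if (idx >= n_same) idx = n_same - 1;
      for (int v = 0; v < tr.n_nodes; ++v) {
        if (tr.alive_at(v, t) && tr.deme_at(v, t) == dm) {
          if (idx == 0) { c_out = v; return; }
          --idx;
        }
      }
      stop("internal error: coalescence target not found");
    } else {
      dm = 1 - dm;
      float_migs.push_back({t, dm});
    }
  }
  stop("recoalesce: did not terminate");
}

void keep_migs_below(std::vector<MigEvent>& v, double t) {
  v.erase(std::remove_if(v.begin(), v.end(),
                         [t](const MigEvent& m) { return m.t > t; }),
          v.end());
}

} // namespace

// [[Rcpp::export]]
List smc_simulate_cpp(int n_samples, double L_bp, double r_bp, double mu_bp,
                      NumericVector epoch_start, NumericVector size1,
                      NumericVector size2, NumericVector mig,
                      double maf_min) {
  if (n_samples < 2) stop("smc_simulate_cpp: need at least 2 samples");
  Demography dem;
  dem.t0 = as<std::vector<double>>(epoch_start);
  dem.size1 = as<std::vector<double>>(size1);
  dem.size2 = as<std::vector<double>>(size2);
  dem.mig = as<std::vector<double>>(mig);
  if (dem.t0.empty() || dem.t0[0] != 0) stop("first epoch must start at 0");

  Tree tr;
  tr.init(n_samples);
  initial_tree(tr, dem);

  const int k = n_samples;
  bool structured = false;
  for (double s2 : dem.size2) if (s2 > 0) structured = true;
  std::vector<double> itimes;  // sorted internal node times (single-deme path)
  for (int v = k; v < tr.n_nodes; ++v) itimes.push_back(tr.time[v]);
  std::sort(itimes.begin(), itimes.end());
  std::vector<double> mut_pos;
  std::vector<uint8_t> mut_cols;  // column-major, k entries per mutation
  std::vector<int> leafbuf;

  double x = 0;
  double Ltree = tr.total_length();
  while (x < L_bp) {
    double step = (r_bp > 0 && Ltree > 0)
      ? R::exp_rand() / (r_bp * Ltree) : (L_bp - x);
    double x1 = std::min(x + step, L_bp);
    // mutations on the current tree over [x, x1)
    double lam = mu_bp * (x1 - x) * Ltree;
    int nm = (lam > 0) ? (int)R::rpois(lam) : 0;
    for (int m = 0; m < nm; ++m) {
      double target = R::unif_rand() * Ltree, acc = 0;
      int b = -1;
      for (int v = 0; v < tr.n_nodes; ++v) {
        if (tr.parent[v] < 0) continue;
        acc += tr.time[tr.parent[v]] - tr.time[v];
        if (acc >= target) { b = v; break; }
      }
      if (b < 0) b = tr.root == 0 ? 1 : 0;
      int cnt = tr.leaves_under(b, leafbuf);
      double af = (double)cnt / k;
      if (std::min(af, 1 - af) < maf_min) continue;
      mut_pos.push_back(x + R::unif_rand() * (x1 - x));
      size_t off = mut_cols.size();
      mut_cols.resize(off + k, 0);
      for (int lf : leafbuf) mut_cols[off + lf] = 1;
    }
    x = x1;
    if (x >= L_bp) break;

    // recombination: cut a uniform point on the tree
    double target = R::unif_rand() * Ltree, acc = 0;
    int b = -1;
    for (int v = 0; v < tr.n_nodes; ++v) {
      if (tr.parent[v] < 0) continue;
      acc += tr.time[tr.parent[v]] - tr.time[v];
      if (acc >= target) { b = v; break; }
    }
    if (b < 0) continue;
    double u = tr.time[tr.parent[b]] - (acc - target);

    double t_star; int c; std::vector<MigEvent> fmigs;
    if (structured) {
      int dm = tr.deme_at(b, u);
      recoalesce(tr, dem, u, dm, t_star, c, fmigs);
    } else {
      recoalesce_single(tr, dem, itimes, u, t_star, c);
    }
    if (c == b) continue;  // invisible: rejoined its own old branch

    int p = tr.parent[b];
    const double old_tp = tr.time[p];
    int sib = (tr.child1[p] == b) ? tr.child2[p] : tr.child1[p];
    int g = tr.parent[p];
    // splice out p: sib takes over p's branch (and its label changes)
    if (g >= 0) { tr.replace_child(g, p, sib); tr.parent[sib] = g; }
    else { tr.parent[sib] = -1; tr.root = sib; }
    for (const auto& me : tr.migs[p]) tr.migs[sib].push_back(me);
    tr.migs[p].clear();
    if (c == p) c = sib;

    // floating lineage keeps b's labels up to u, then its own path
    keep_migs_below(tr.migs[b], u);
    for (const auto& me : fmigs) tr.migs[b].push_back(me);

    int w = p;  // reuse node id
    if (tr.parent[c] < 0) {
      // coalesced with the root lineage: new root above
      tr.time[w] = t_star;
      tr.child1[w] = b; tr.child2[w] = c;
      tr.parent[b] = w; tr.parent[c] = w;
      tr.parent[w] = -1;
      tr.deme0[w] = tr.deme_at(c, t_star);
      tr.root = w;
    } else {
      int gc = tr.parent[c];
      tr.time[w] = t_star;
      tr.child1[w] = b; tr.child2[w] = c;
      tr.replace_child(gc, c, w);
      tr.parent[w] = gc;
      tr.parent[b] = w; tr.parent[c] = w;
      tr.deme0[w] = tr.deme_at(c, t_star);
      // w inherits c's label changes above t_star
      for (const auto& me : tr.migs[c])
        if (me.t > t_star) tr.migs[w].push_back(me);
      keep_migs_below(tr.migs[c], t_star);
    }
    // keep the sorted internal-time index in step (node p moved to t_star)
    itimes.erase(std::lower_bound(itimes.begin(), itimes.end(), old_tp));
    itimes.insert(std::upper_bound(itimes.begin(), itimes.end(), t_star),
                  t_star);
    Ltree = tr.total_length();
  }

  // order mutations by position, convert to unique integer bp
  const int S0 = (int)mut_pos.size();
  std::vector<int> ord(S0);
  for (int i = 0; i < S0; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return mut_pos[a] < mut_pos[b];
  });
  std::vector<int> pos_int; pos_int.reserve(S0);
  std::vector<int> keep; keep.reserve(S0);
  int prev = 0;
  for (int i = 0; i < S0; ++i) {
    int pi = (int)std::floor(mut_pos[ord[i]]) + 1;
    if (pi <= prev) pi = prev + 1;
    prev = pi;
    pos_int.push_back(pi);
    keep.push_back(ord[i]);
  }
  IntegerMatrix al(k, S0);
  for (int s = 0; s < S0; ++s) {
    size_t off = (size_t)keep[s] * k;
    for (int r = 0; r < k; ++r) al(r, s) = mut_cols[off + r];
  }
  return List::create(_["alleles"] = al,
                      _["pos_bp"] = IntegerVector(pos_int.begin(), pos_int.end()));
}
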