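// MCMC engine: maintains the genome structure and the sparse Poisson
// likelihood over "units" (the bins one pyramid level below the working
// level), and computes exact log-likelihood differences for candidate
// mutations of working-level bins.
//
// Distances are grid distances (unit ranks within a scaffold); the model
// tables lnlam[d] (log expected count at grid distance d) and F[S] (sum of
// expected counts over all intra pairs of a scaffold of S units) are
// supplied from R. A mutation moves a block of m contiguous units; pairs
// not involving the block only change through rank shifts across the
// removal/insertion cuts, which are accumulated exactly with one
// difference-array pass per affected scaffold.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <climits>
#include <map>
#include <set>
#include <vector>
using namespace Rcpp;

struct Engine {
  int U = 0, B = 0;
  // symmetric unit adjacency (diagonal excluded), CSR
  std::vector<int> aptr, apart;
  std::vector<double> acnt;
  // working bins -> units (forward order)
  std::vector<int> bptr, bunits, unit2bin;
  // structure
  std::vector<std::vector<int>> scafs;  // signed 1-based bin ids
  std::vector<int> bin_scaf, bin_pos;   // per bin
  std::vector<int> unit_rank;           // per unit, rank within scaffold
  std::vector<std::vector<int>> scaf_units;
  // model tables
  std::vector<double> lnlam;  // index d = 1..U-1
  std::vector<double> Fs;     // index S = 0..U
  double logdelta = 0.0, delta = 0.0;
  bool model_set = false;

  int bin_m(int b) const { return bptr[b + 1] - bptr[b]; }
  int bin_orient(int b) const {
    return scafs[bin_scaf[b]][bin_pos[b]] > 0 ? 1 : -1;
  }
  int uscaf(int u) const { return bin_scaf[unit2bin[u]]; }
  int bin_first_rank(int b) const {
    int r = INT_MAX;
    for (int t = bptr[b]; t < bptr[b + 1]; ++t)
      r = std::min(r, unit_rank[bunits[t]]);
    return r;
  }

  void rebuild() {
    scaf_units.assign(scafs.size(), {});
    for (size_t s = 0; s < scafs.size(); ++s) {
      int rank = 0;
      for (size_t p = 0; p < scafs[s].size(); ++p) {
        int v = scafs[s][p];
        int b = std::abs(v) - 1;
        bin_scaf[b] = (int)s;
        bin_pos[b] = (int)p;
        int m = bin_m(b);
        for (int t = 0; t < m; ++t) {
          int u = (v > 0) ? bunits[bptr[b] + t] : bunits[bptr[b] + m - 1 - t];
          unit_rank[u] = rank++;
          scaf_units[s].push_back(u);
        }
      }
    }
  }
};

static Engine* get(SEXP p) {
  Rcpp::XPtr<Engine> xp(p);
  return xp.get();
}

// [[Rcpp::export]]
SEXP eng_new(IntegerVector ui, IntegerVector uj, NumericVector ucnt, int U,
             IntegerVector bptr, IntegerVector bunits, List scaffolds) {
  Engine* e = new Engine();
  e->U = U;
  e->B = bptr.size() - 1;
  e->bptr.assign(bptr.begin(), bptr.end());
  e->bunits.assign(bunits.begin(), bunits.end());
  e->unit2bin.assign(U, -1);
  for (int b = 0; b < e->B; ++b)
    for (int t = e->bptr[b]; t < e->bptr[b + 1]; ++t)
      e->unit2bin[e->bunits[t]] = b;
  // adjacency
  std::vector<int> deg(U, 0);
  int nnz = ui.size();
  for (int k = 0; k < nnz; ++k)
    if (ui[k] != uj[k]) { deg[ui[k]]++; deg[uj[k]]++; }
  e->aptr.assign(U + 1, 0);
  for (int u = 0; u < U; ++u) e->aptr[u + 1] = e->aptr[u] + deg[u];
  e->apart.assign(e->aptr[U], 0);
  e->acnt.assign(e->aptr[U], 0.0);
  std::vector<int> fill(e->aptr.begin(), e->aptr.end() - 1);
  for (int k = 0; k < nnz; ++k) {
    if (ui[k] == uj[k]) continue;
    e->apart[fill[ui[k]]] = uj[k];
    e->acnt[fill[ui[k]]++] = ucnt[k];
    e->apart[fill[uj[k]]] = ui[k];
    e->acnt[fill[uj[k]]++] = ucnt[k];
  }
  // structure
  e->scafs.resize(scaffolds.size());
  for (int s = 0; s < scaffolds.size(); ++s) {
    IntegerVector v = scaffolds[s];
    e->scafs[s].assign(v.begin(), v.end());
  }
  e->bin_scaf.assign(e->B, -1);
  e->bin_pos.assign(e->B, -1);
  e->unit_rank.assign(U, -1);
  e->rebuild();
  Rcpp::XPtr<Engine> xp(e, true);
  return xp;
}

// [[Rcpp::export]]
void eng_set_model(SEXP p, NumericVector lam, double logdelta, double delta) {
  Engine* e = get(p);
  int n = lam.size();
  e->lnlam.assign(n + 1, R_NegInf);
  for (int d = 1; d <= n; ++d) e->lnlam[d] = std::log(lam[d - 1]);
  // F[S] = sum_{d=1}^{S-1} (S-d) lam[d]; F[S+1] = F[S] + cum[S]
  e->Fs.assign(e->U + 1, 0.0);
  double cum = 0.0;
  for (int S = 1; S <= e->U; ++S) {
    e->Fs[S] = e->Fs[S - 1] + cum;
    if (S <= n) cum += lam[S - 1];
  }
  e->logdelta = logdelta;
  e->delta = delta;
  e->model_set = true;
}

// [[Rcpp::export]]
List eng_structure(SEXP p) {
  Engine* e = get(p);
  List out(e->scafs.size());
  for (size_t s = 0; s < e->scafs.size(); ++s)
    out[s] = IntegerVector(e->scafs[s].begin(), e->scafs[s].end());
  return out;
}

// full log-likelihood over the engine's unit map (used for cross-checks)
// [[Rcpp::export]]
double eng_logl(SEXP p) {
  Engine* e = get(p);
  if (!e->model_set) stop("model not set");
  double nnzterm = 0.0;
  for (int u = 0; u < e->U; ++u) {
    for (int t = e->aptr[u]; t < e->aptr[u + 1]; ++t) {
      int v = e->apart[t];
      if (v <= u) continue;
      if (e->uscaf(u) == e->uscaf(v))
        nnzterm += e->acnt[t] *
                   e->lnlam[std::abs(e->unit_rank[u] - e->unit_rank[v])];
      else
        nnzterm += e->acnt[t] * e->logdelta;
    }
  }
  double sum_sq = 0.0, sum_F = 0.0;
  for (size_t s = 0; s < e->scaf_units.size(); ++s) {
    double S = (double)e->scaf_units[s].size();
    sum_sq += S * S;
    sum_F += e->Fs[(int)S];
  }
  double n_inter = ((double)e->U * e->U - sum_sq) / 2.0;
  return nnzterm - sum_F - e->delta * n_inter;
}

// ---------------------------------------------------------------------------
// delta machinery

struct ExtPair {       // external non-zero pair of a moved bin's unit
  int k;               // forward index of the unit within its bin
  int partner;         // partner unit
  double cnt;
};

struct TargetCtx {
  int b = -1, s0 = -1, m = 0, r0 = 0, S0 = 0;
  std::vector<ExtPair> ext;
  double cur_term = 0.0;    // current contribution of external pairs
  double rem_shift = 0.0;   // shift of s0 pairs across the removal cut
  bool rem_done = false;
  std::map<int, std::vector<double>> ins_cut;  // scaffold -> prefix by cut
};

// post-removal rank of a unit not in the target bin
static inline int post_rank(const Engine* e, const TargetCtx& c, int u) {
  int r = e->unit_rank[u];
  if (e->uscaf(u) == c.s0 && r >= c.r0 + c.m) r -= c.m;
  return r;
}

static void prep_target(const Engine* e, TargetCtx& c, int b) {
  c = TargetCtx();
  c.b = b;
  c.s0 = e->bin_scaf[b];
  c.m = e->bin_m(b);
  c.r0 = e->bin_first_rank(b);
  c.S0 = (int)e->scaf_units[c.s0].size();
  c.ext.clear();
  c.cur_term = 0.0;
  for (int t = e->bptr[b]; t < e->bptr[b + 1]; ++t) {
    int u = e->bunits[t];
    int k = t - e->bptr[b];
    for (int a = e->aptr[u]; a < e->aptr[u + 1]; ++a) {
      int v = e->apart[a];
      if (e->unit2bin[v] == b) continue;
      c.ext.push_back({k, v, e->acnt[a]});
      if (e->uscaf(v) == c.s0)
        c.cur_term += e->acnt[a] *
                      e->lnlam[std::abs(e->unit_rank[u] - e->unit_rank[v])];
      else
        c.cur_term += e->acnt[a] * e->logdelta;
    }
  }
}

// one pass over scaffold t: fills the insertion-cut prefix (post-removal
// coordinates) and, when t == s0, the removal-cut shift scalar.
static const std::vector<double>& scan_scaffold(const Engine* e, TargetCtx& c,
                                                int t) {
  auto it = c.ins_cut.find(t);
  if (it != c.ins_cut.end()) return it->second;
  int Stp = (int)e->scaf_units[t].size() - (t == c.s0 ? c.m : 0);
  std::vector<double> diff(Stp + 2, 0.0);
  bool do_rem = (t == c.s0 && !c.rem_done);
  double rem = 0.0;
  for (int u : e->scaf_units[t]) {
    if (e->unit2bin[u] == c.b) continue;
    int pru = post_rank(e, c, u);
    int ru = e->unit_rank[u];
    for (int a = e->aptr[u]; a < e->aptr[u + 1]; ++a) {
      int v = e->apart[a];
      if (v <= u) continue;
      if (e->unit2bin[v] == c.b) continue;
      if (e->uscaf(v) != t) continue;
      int prv = post_rank(e, c, v);
      int lo = std::min(pru, prv), hi = std::max(pru, prv);
      int dpost = hi - lo;
      double g = e->acnt[a] * (e->lnlam[dpost + c.m] - e->lnlam[dpost]);
      diff[lo + 1] += g;
      diff[hi + 1] -= g;
      if (do_rem) {
        int rv = e->unit_rank[v];
        int l2 = std::min(ru, rv), h2 = std::max(ru, rv);
        if (l2 < c.r0 && h2 >= c.r0 + c.m)
          rem += e->acnt[a] * (e->lnlam[h2 - l2 - c.m] - e->lnlam[h2 - l2]);
      }
    }
  }
  if (do_rem) { c.rem_shift = rem; c.rem_done = true; }
  std::vector<double> pre(Stp + 1, 0.0);
  double acc = 0.0;
  for (int q = 0; q <= Stp; ++q) { acc += diff[q]; pre[q] = acc; }
  auto res = c.ins_cut.emplace(t, std::move(pre));
  return res.first->second;
}

static void ensure_rem(const Engine* e, TargetCtx& c) {
  if (!c.rem_done) scan_scaffold(e, c, c.s0);
}

static double delta_flip(const Engine* e, const TargetCtx& c) {
  if (c.m == 1) return 0.0;
  double d = 0.0;
  for (const ExtPair& pr : c.ext) {
    if (e->uscaf(pr.partner) != c.s0) continue;
    int ru = e->unit_rank[e->bunits[e->bptr[c.b] + pr.k]];
    int nr = 2 * c.r0 + c.m - 1 - ru;  // rank after reflecting the block
    int rv = e->unit_rank[pr.partner];
    d += pr.cnt * (e->lnlam[std::abs(nr - rv)] - e->lnlam[std::abs(ru - rv)]);
  }
  return d;
}

static double size_terms(const Engine* e, int S0, int S0p, int S1, int S1p) {
  // change in -(sum lambda) when scaffold sizes change S0->S0p, S1->S1p
  double dF = e->Fs[S0p] + e->Fs[S1p] - e->Fs[S0] - e->Fs[S1];
  double dSq = (double)S0p * S0p + (double)S1p * S1p - (double)S0 * S0 -
               (double)S1 * S1;
  double dNinter = -dSq / 2.0;
  return -(dF + e->delta * dNinter);
}

static double delta_eject(const Engine* e, TargetCtx& c) {
  if (c.S0 == c.m) return 0.0;  // already a singleton scaffold
  ensure_rem(e, c);
  double new_term = 0.0;
  for (const ExtPair& pr : c.ext) new_term += pr.cnt * e->logdelta;
  return new_term - c.cur_term + c.rem_shift +
         size_terms(e, c.S0, c.S0 - c.m, 0, c.m);
}

static double delta_insert(const Engine* e, TargetCtx& c, int anchor,
                           bool before, bool flipped) {
  int t = e->bin_scaf[anchor];
  int ra = e->bin_first_rank(anchor);
  int ma = e->bin_m(anchor);
  int pa = ra;
  if (t == c.s0 && ra >= c.r0 + c.m) pa -= c.m;
  int q = before ? pa : pa + ma;
  ensure_rem(e, c);
  const std::vector<double>& cut = scan_scaffold(e, c, t);
  int ori = flipped ? -e->bin_orient(c.b) : e->bin_orient(c.b);
  double new_term = 0.0;
  for (const ExtPair& pr : c.ext) {
    int nr = (ori > 0) ? q + pr.k : q + c.m - 1 - pr.k;
    if (e->uscaf(pr.partner) == t) {
      int pv = post_rank(e, c, pr.partner);
      if (pv >= q) pv += c.m;
      new_term += pr.cnt * e->lnlam[std::abs(nr - pv)];
    } else {
      new_term += pr.cnt * e->logdelta;
    }
  }
  double d = new_term - c.cur_term + c.rem_shift + cut[q];
  if (t != c.s0) {
    int S1 = (int)e->scaf_units[t].size();
    d += size_terms(e, c.S0, c.S0 - c.m, S1, S1 + c.m);
  }
  return d;
}

static double delta_swap(const Engine* e, TargetCtx& c, int a) {
  int b = c.b;
  int s0 = c.s0, s1 = e->bin_scaf[a];
  int m = c.m, ma = e->bin_m(a);
  int r0 = c.r0, ra = e->bin_first_rank(a);
  // new first ranks after the swap
  int nb0, na0;  // first rank of b's block / a's block after swap
  if (s0 != s1) {
    nb0 = ra;  // b takes a's slot in s1
    na0 = r0;  // a takes b's slot in s0
  } else if (r0 < ra) {
    na0 = r0;
    nb0 = ra + (ma - m);
  } else {
    nb0 = ra;
    na0 = r0 + (m - ma);
  }
  int ob = e->bin_orient(b), oa = e->bin_orient(a);
  // post-swap rank of a unit not in b or a
  auto ps = [&](int u) -> int {
    int s = e->uscaf(u), r = e->unit_rank[u];
    if (s0 != s1) {
      if (s == s0 && r >= r0 + m) return r + (ma - m);
      if (s == s1 && r >= ra + ma) return r + (m - ma);
      return r;
    }
    if (s != s0) return r;
    int lo0 = std::min(r0, ra), him, k;
    if (r0 < ra) { him = ra; k = ma - m; }
    else { him = r0; k = m - ma; }
    int loend = lo0 + (r0 < ra ? m : ma);
    if (r >= loend && r < him) return r + k;
    return r;
  };
  auto new_scaf_of = [&](int u) -> int {
    int bb = e->unit2bin[u];
    if (bb == b) return s1;
    if (bb == a) return s0;
    return e->uscaf(u);
  };
  auto new_rank_of = [&](int u) -> int {
    int bb = e->unit2bin[u];
    if (bb == b) {
      int k = 0;
      for (int t = e->bptr[b]; t < e->bptr[b + 1]; ++t)
        if (e->bunits[t] == u) { k = t - e->bptr[b]; break; }
      return (ob > 0) ? nb0 + k : nb0 + m - 1 - k;
    }
    if (bb == a) {
      int k = 0;
      for (int t = e->bptr[a]; t < e->bptr[a + 1]; ++t)
        if (e->bunits[t] == u) { k = t - e->bptr[a]; break; }
      return (oa > 0) ? na0 + k : na0 + ma - 1 - k;
    }
    return ps(u);
  };
  // pair terms involving b or a units, before and after
  double before_t = 0.0, after_t = 0.0;
  for (int which = 0; which < 2; ++which) {
    int bb = which == 0 ? b : a;
    for (int t = e->bptr[bb]; t < e->bptr[bb + 1]; ++t) {
      int u = e->bunits[t];
      for (int x = e->aptr[u]; x < e->aptr[u + 1]; ++x) {
        int v = e->apart[x];
        int vb = e->unit2bin[v];
        if (vb == bb) continue;        // internal pair
        bool mutual = (vb == b || vb == a);
        if (mutual && v <= u) continue;  // count mutual pairs once
        double cnt = e->acnt[x];
        // before
        if (e->uscaf(v) == e->uscaf(u))
          before_t += cnt *
                      e->lnlam[std::abs(e->unit_rank[u] - e->unit_rank[v])];
        else
          before_t += cnt * e->logdelta;
        // after
        if (new_scaf_of(v) == new_scaf_of(u))
          after_t += cnt * e->lnlam[std::abs(new_rank_of(u) - new_rank_of(v))];
        else
          after_t += cnt * e->logdelta;
      }
    }
  }
  double d = after_t - before_t;
  // shift terms for pairs not involving b or a (only when sizes differ)
  if (m != ma) {
    if (s0 == s1) {
      // only pairs with an endpoint strictly between the two slots change
      // distance; iterate that (usually short) mid-region only
      int lo0 = std::min(r0, ra);
      int loend = lo0 + (r0 < ra ? m : ma);
      int him = std::max(r0, ra);
      const std::vector<int>& su = e->scaf_units[s0];
      for (int r = loend; r < him; ++r) {
        int u = su[r];
        int ub = e->unit2bin[u];
        if (ub == b || ub == a) continue;
        for (int x = e->aptr[u]; x < e->aptr[u + 1]; ++x) {
          int v = e->apart[x];
          int vb = e->unit2bin[v];
          if (vb == b || vb == a) continue;
          if (e->uscaf(v) != s0) continue;
          int rv = e->unit_rank[v];
          bool v_mid = (rv >= loend && rv < him);
          if (v_mid && v <= u) continue;  // both mid: count once
          if (!v_mid) {
            // both-outside pairs never reach here; mid-vs-outside shifts
          }
          int d0 = std::abs(e->unit_rank[u] - rv);
          int d1 = std::abs(ps(u) - ps(v));
          if (d1 != d0) d += e->acnt[x] * (e->lnlam[d1] - e->lnlam[d0]);
        }
      }
    } else {
      for (int s : {s0, s1}) {
        for (int u : e->scaf_units[s]) {
          int ub = e->unit2bin[u];
          if (ub == b || ub == a) continue;
          for (int x = e->aptr[u]; x < e->aptr[u + 1]; ++x) {
            int v = e->apart[x];
            if (v <= u) continue;
            int vb = e->unit2bin[v];
            if (vb == b || vb == a) continue;
            if (e->uscaf(v) != s) continue;
            int d0 = std::abs(e->unit_rank[u] - e->unit_rank[v]);
            int d1 = std::abs(ps(u) - ps(v));
            if (d1 != d0)
              d += e->acnt[x] * (e->lnlam[d1] - e->lnlam[d0]);
          }
        }
      }
      int S0 = c.S0, S1 = (int)e->scaf_units[s1].size();
      d += size_terms(e, S0, S0 - m + ma, S1, S1 - ma + m);
    }
  }
  return d;
}

// mutation codes: 0 stay, 1 flip, 2 eject, 3 insert_before, 4 insert_after,
// 5 swap; columns of `cands`: kind, target, anchor (-1 if none), flipped
// [[Rcpp::export]]
NumericVector eng_deltas(SEXP p, IntegerMatrix cands) {
  Engine* e = get(p);
  if (!e->model_set) stop("model not set");
  NumericVector out(cands.nrow());
  TargetCtx ctx;
  for (int r = 0; r < cands.nrow(); ++r) {
    int kind = cands(r, 0), target = cands(r, 1);
    int anchor = cands(r, 2);
    bool flipped = cands(r, 3) != 0;
    if (target < 0 || target >= e->B) stop("invalid target bin");
    if (kind >= 3 && (anchor < 0 || anchor >= e->B || anchor == target))
      stop("invalid anchor bin");
    if (ctx.b != target) prep_target(e, ctx, target);
    switch (kind) {
      case 0: out[r] = 0.0; break;
      case 1: out[r] = delta_flip(e, ctx); break;
      case 2: out[r] = delta_eject(e, ctx); break;
      case 3: out[r] = delta_insert(e, ctx, anchor, true, flipped); break;
      case 4: out[r] = delta_insert(e, ctx, anchor, false, flipped); break;
      case 5: out[r] = delta_swap(e, ctx, anchor); break;
      default: stop("unknown mutation kind");
    }
  }
  return out;
}

// [[Rcpp::export]]
void eng_apply(SEXP p, int kind, int target, int anchor, int flipped) {
  Engine* e = get(p);
  if (target < 0 || target >= e->B) stop("invalid target bin");
  int s0 = e->bin_scaf[target], p0 = e->bin_pos[target];
  int signed_t = e->scafs[s0][p0];
  if (kind == 0) return;
  if (kind == 1) {
    e->scafs[s0][p0] = -signed_t;
    e->rebuild();
    return;
  }
  if (kind == 2) {
    e->scafs[s0].erase(e->scafs[s0].begin() + p0);
    e->scafs.push_back({signed_t});
    e->scafs.erase(std::remove_if(e->scafs.begin(), e->scafs.end(),
                                  [](const std::vector<int>& v) {
                                    return v.empty();
                                  }),
                   e->scafs.end());
    e->rebuild();
    return;
  }
  if (anchor < 0 || anchor >= e->B || anchor == target)
    stop("invalid anchor bin");
  int sa = e->bin_scaf[anchor], pa = e->bin_pos[anchor];
  if (kind == 5) {
    int signed_a = e->scafs[sa][pa];
    e->scafs[s0][p0] = signed_a;
    e->scafs[sa][pa] = signed_t;
    e->rebuild();
    return;
  }
  // inserts
  e->scafs[s0].erase(e->scafs[s0].begin() + p0);
  if (sa == s0 && pa > p0) pa -= 1;
  int val = flipped ? -signed_t : signed_t;
  int at = (kind == 3) ? pa : pa + 1;
  e->scafs[sa].insert(e->scafs[sa].begin() + at, val);
  e->scafs.erase(std::remove_if(e->scafs.begin(), e->scafs.end(),
                                [](const std::vector<int>& v) {
                                  return v.empty();
                                }),
                 e->scafs.end());
  e->rebuild();
}

// candidate generation: stay, flip, eject (if not a singleton scaffold),
// inserts before/after x {keep, flip} for each of the top-k contact
// anchors, and a swap with each anchor; no-ops and duplicate insertion
// slots removed. Returns the integer matrix consumed by eng_deltas.
// [[Rcpp::export]]
IntegerMatrix eng_candidates(SEXP p, int target, int k) {
  Engine* e = get(p);
  if (target < 0 || target >= e->B) stop("invalid target bin");
  // contact totals with other bins
  std::map<int, double> tot;
  for (int t = e->bptr[target]; t < e->bptr[target + 1]; ++t) {
    int u = e->bunits[t];
    for (int a = e->aptr[u]; a < e->aptr[u + 1]; ++a) {
      int pb = e->unit2bin[e->apart[a]];
      if (pb != target) tot[pb] += e->acnt[a];
    }
  }
  std::vector<std::pair<double, int>> ranked;
  for (auto& kv : tot) ranked.push_back({kv.second, kv.first});
  std::sort(ranked.begin(), ranked.end(), [](const std::pair<double, int>& x,
                                             const std::pair<double, int>& y) {
    if (x.first != y.first) return x.first > y.first;
    return x.second < y.second;
  });
  int nk = std::min<int>(k, (int)ranked.size());

  int s0 = e->bin_scaf[target], p0 = e->bin_pos[target];
  bool singleton = e->scafs[s0].size() == 1;
  std::vector<std::array<int, 4>> rows;
  rows.push_back({0, target, -1, 0});
  rows.push_back({1, target, -1, 0});
  if (!singleton) rows.push_back({2, target, -1, 0});
  std::set<std::array<int, 3>> seen;  // (anchor scaffold, slot, signed ori)
  int cur_ori = e->scafs[s0][p0] > 0 ? 1 : -1;
  for (int z = 0; z < nk; ++z) {
    int a = ranked[z].second;
    int sa = e->bin_scaf[a];
    int pa = e->bin_pos[a];
    int pa_adj = pa;
    if (sa == s0 && pa > p0) pa_adj -= 1;
    for (int side = 0; side < 2; ++side) {  // 0 = before, 1 = after
      int slot = side == 0 ? pa_adj : pa_adj + 1;
      for (int fl = 0; fl < 2; ++fl) {
        int ori = fl ? -cur_ori : cur_ori;
        bool noop = (fl == 0) && sa == s0 &&
                    ((side == 0 && pa == p0 + 1) || (side == 1 && pa == p0 - 1));
        std::array<int, 3> key = {sa, slot, ori};
        if (!noop && seen.insert(key).second)
          rows.push_back({side == 0 ? 3 : 4, target, a, fl});
      }
    }
    rows.push_back({5, target, a, 0});
  }
  IntegerMatrix out((int)rows.size(), 4);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int cidx = 0; cidx < 4; ++cidx) out(r, cidx) = rows[r][cidx];
  return out;
}
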