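// Core numerics for the sliding-window bootstrap recombination scan:
// Kimura two-parameter distances, neighbor joining, and the per-window
// bootstrap vote. Bases are integer-coded 0=A, 1=C, 2=G, 3=T, -1=missing
// (N or gap). Transitions are A<->G and C<->T.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline bool is_base(int b) { return b >= 0; }
static inline bool is_transition(int a, int b) {
  return (a == 0 && b == 2) || (a == 2 && b == 0) ||
         (a == 1 && b == 3) || (a == 3 && b == 1);
}

// K80: d = -0.5 * log((1-2P-Q) * sqrt(1-2Q)); JC69 (model 1):
// d = -0.75 * log(1 - 4/3 (P+Q)). Saturation or zero comparable -> ceiling.
static double dist_from_counts(double P, double Q, double comp, double ceiling,
                               int model) {
  if (comp <= 0) return ceiling;
  double d;
  if (model == 1) {
    double p = (P + Q) / comp;
    double a = 1.0 - 4.0 * p / 3.0;
    if (a <= 0) return ceiling;
    d = -0.75 * std::log(a);
  } else {
    double p = P / comp, q = Q / comp;
    double a = 1.0 - 2.0 * p - q, b = 1.0 - 2.0 * q;
    if (a <= 0 || b <= 0) return ceiling;
    d = -0.5 * std::log(a * std::sqrt(b));
  }
  return d < 0 ? 0 : d;
}

// [[Rcpp::export]]
NumericMatrix cpp_k80_matrix(IntegerMatrix m, double ceiling, int model) {
  int n = m.nrow(), L = m.ncol();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double P = 0, Q = 0, comp = 0;
      for (int s = 0; s < L; ++s) {
        int a = m(i, s), b = m(j, s);
        if (!is_base(a) || !is_base(b)) continue;
        comp += 1;
        if (a == b) continue;
        if (is_transition(a, b)) P += 1; else Q += 1;
      }
      d(i, j) = d(j, i) = dist_from_counts(P, Q, comp, ceiling, model);
    }
  }
  return d;
}

// [[Rcpp::export]]
List cpp_k80_pair(IntegerVector a, IntegerVector b, double ceiling) {
  int L = a.size();
  double P = 0, Q = 0, comp = 0;
  for (int s = 0; s < L; ++s) {
    if (!is_base(a[s]) || !is_base(b[s])) continue;
    comp += 1;
    if (a[s] == b[s]) continue;
    if (is_transition(a[s], b[s])) P += 1; else Q += 1;
  }
  return List::create(_["distance"] = dist_from_counts(P, Q, comp, ceiling, 0),
                      _["comparable"] = comp,
                      _["P"] = comp > 0 ? P / comp : NA_REAL,
                      _["Q"] = comp > 0 ? Q / comp : NA_REAL);
}

// Neighbor joining (Saitou-Nei) on a full distance matrix held in a flat
// vector. Tips are 0..n-1; internal nodes n..2n-3, created in join order so
// the final 3-way center is node 2n-3. Ties in Q broken by smallest (i, j).
// Negative branch lengths clamped to zero. Fills eu/ev/el with 2n-3 edges.
static void nj_core(std::vector<double>& D, int n,
                    std::vector<int>& eu, std::vector<int>& ev,
                    std::vector<double>& el) {
  int total = 2 * n - 2;
  std::vector<int> active;
  for (int i = 0; i < n; ++i) active.push_back(i);
  std::vector<double> dist((size_t)total * total, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) dist[(size_t)i * total + j] = D[(size_t)i * n + j];
  int next_node = n;
  eu.clear(); ev.clear(); el.clear();
  while ((int)active.size() > 3) {
    int na = active.size();
    std::vector<double> r(na, 0.0);
    for (int i = 0; i < na; ++i)
      for (int j = 0; j < na; ++j)
        r[i] += dist[(size_t)active[i] * total + active[j]];
    double bestQ = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < na; ++i) {
      for (int j = i + 1; j < na; ++j) {
        double q = (na - 2) * dist[(size_t)active[i] * total + active[j]]
                   - r[i] - r[j];
        if (q < bestQ - 1e-12) { bestQ = q; bi = i; bj = j; }
      }
    }
    int u = active[bi], v = active[bj];
    double duv = dist[(size_t)u * total + v];
    double lu = 0.5 * duv + (r[bi] - r[bj]) / (2.0 * (na - 2));
    double lv = duv - lu;
    if (lu < 0) lu = 0;
    if (lv < 0) lv = 0;
    int k = next_node++;
    eu.push_back(k); ev.push_back(u); el.push_back(lu);
    eu.push_back(k); ev.push_back(v); el.push_back(lv);
    for (int m = 0; m < na; ++m) {
      if (m == bi || m == bj) continue;
      int w = active[m];
      double dw = 0.5 * (dist[(size_t)u * total + w] +
                         dist[(size_t)v * total + w] - duv);
      if (dw < 0) dw = 0;
      dist[(size_t)k * total + w] = dist[(size_t)w * total + k] = dw;
    }
    std::vector<int> na2;
    for (int m = 0; m < na; ++m) if (m != bi && m != bj) na2.push_back(active[m]);
    na2.push_back(k);
    active = na2;
  }
  if ((int)active.size() == 3) {
    int a = active[0], b = active[1], c = active[2];
    double dab = dist[(size_t)a * total + b], dac = dist[(size_t)a * total + c],
           dbc = dist[(size_t)b * total + c];
    int z = next_node++;
    double la = 0.5 * (dab + dac - dbc), lb = 0.5 * (dab + dbc - dac),
           lc = 0.5 * (dac + dbc - dab);
    if (la < 0) la = 0;
    if (lb < 0) lb = 0;
    if (lc < 0) lc = 0;
    eu.push_back(z); ev.push_back(a); el.push_back(la);
    eu.push_back(z); ev.push_back(b); el.push_back(lb);
    eu.push_back(z); ev.push_back(c); el.push_back(lc);
  } else if ((int)active.size() == 2) {
    eu.push_back(active[0]); ev.push_back(active[1]);
    el.push_back(dist[(size_t)active[0] * total + active[1]]);
  }
}

// [[Rcpp::export]]
List cpp_nj(NumericMatrix d) {
  int n = d.nrow();
  if (n < 2) stop("need at least 2 taxa");
  std::vector<double> D((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D[(size_t)i * n + j] = d(i, j);
  std::vector<int> eu, ev;
  std::vector<double> el;
  nj_core(D, n, eu, ev, el);
  int ne = eu.size();
  IntegerMatrix edge(ne, 2);
  NumericVector len(ne);
  for (int e = 0; e < ne; ++e) {
    edge(e, 0) = eu[e] + 1;
    edge(e, 1) = ev[e] + 1;
    len[e] = el[e];
  }
  return List::create(_["edge"] = edge, _["edge_length"] = len,
                      _["n_tip"] = n);
}

// Vote: on the unrooted tree, clades containing the query correspond to
// query-side components of single-edge removals. Find the smallest such
// component containing at least one parental; the parentals it contains share
// one vote equally (a unique parental takes the whole vote).
static void vote_tree(const std::vector<int>& eu, const std::vector<int>& ev,
                      int n, int qi, const std::vector<int>& par_of_tip,
                      int npar, std::vector<double>& votes) {
  int total = 2 * n - 2;
  if (n == 3) total = n + 1;  // single center node
  std::vector<std::vector<int> > adj(total);
  int ne = eu.size();
  for (int e = 0; e < ne; ++e) {
    adj[eu[e]].push_back(e);
    adj[ev[e]].push_back(e);
  }
  // DFS from query: for each edge directed away from the query, count tips
  // and parentals in the far-side subtree.
  std::vector<int> sub_tips(ne, 0), sub_par(ne, 0);
  std::vector<int> stack_node, stack_edge, order_edge;
  stack_node.push_back(qi); stack_edge.push_back(-1);
  std::vector<char> seen(total, 0);
  seen[qi] = 1;
  std::vector<int> far_node(ne, -1);
  while (!stack_node.empty()) {
    int u = stack_node.back(); stack_node.pop_back();
    int pe = stack_edge.back(); stack_edge.pop_back();
    for (size_t t = 0; t < adj[u].size(); ++t) {
      int e = adj[u][t];
      if (e == pe) continue;
      int w = (eu[e] == u) ? ev[e] : eu[e];
      if (seen[w]) continue;
      seen[w] = 1;
      far_node[e] = w;
      order_edge.push_back(e);
      stack_node.push_back(w); stack_edge.push_back(e);
    }
  }
  // accumulate subtree tip counts / parental masks in reverse discovery
  // order (children edges before their parent edge)
  std::vector<int> node_tips(total, 0), node_par(total, 0);
  for (int t = (int)order_edge.size() - 1; t >= 0; --t) {
    int e = order_edge[t];
    int w = far_node[e];
    int tips, par;
    if (w < n) {
      tips = 1;
      par = (par_of_tip[w] >= 0) ? (1 << par_of_tip[w]) : 0;
    } else {
      tips = node_tips[w];
      par = node_par[w];
    }
    sub_tips[e] = tips;
    sub_par[e] = par;
    int u = (eu[e] == far_node[e]) ? ev[e] : eu[e];
    node_tips[u] += tips;
    node_par[u] |= par;
  }
  int all_par_mask = 0;
  for (int i = 0; i < n; ++i)
    if (par_of_tip[i] >= 0) all_par_mask |= 1 << par_of_tip[i];
  int best_size = n + 1, best_mask = 0;
  for (int e = 0; e < ne; ++e) {
    if (far_node[e] < 0) continue;
    int qside_tips = n - sub_tips[e];
    int qside_par = all_par_mask & ~sub_par[e];
    if (qside_par == 0) continue;
    if (qside_tips < best_size) {
      best_size = qside_tips;
      best_mask = qside_par;
    } else if (qside_tips == best_size) {
      best_mask |= qside_par;
    }
  }
  if (best_mask == 0) return;
  int k = 0;
  for (int p = 0; p < npar; ++p) if (best_mask & (1 << p)) ++k;
  for (int p = 0; p < npar; ++p)
    if (best_mask & (1 << p)) votes[p] += 1.0 / k;
}

// [[Rcpp::export]]
NumericVector cpp_window_support(IntegerMatrix m, int qi, IntegerVector pidx,
                                 int reps, double ceiling, int model) {
  int n = m.nrow(), L = m.ncol();
  int npar = pidx.size();
  if (npar < 1 || npar > 31) stop("need between 1 and 31 parentals");
  if (n < 3) stop("need at least 3 taxa");
  std::vector<int> par_of_tip(n, -1);
  for (int p = 0; p < npar; ++p) par_of_tip[pidx[p]] = p;
  if (qi < 0 || qi >= n) stop("bad query index");

  // collapse identical columns into patterns; per pattern x pair, code the
  // contribution: -1 incomparable, 0 identical, 1 transition, 2 transversion
  std::map<std::vector<int>, int> pat_id;
  std::vector<int> col_pat(L);
  std::vector<std::vector<int> > pats;
  for (int s = 0; s < L; ++s) {
    std::vector<int> col(n);
    for (int i = 0; i < n; ++i) col[i] = m(i, s);
    std::map<std::vector<int>, int>::iterator it = pat_id.find(col);
    if (it == pat_id.end()) {
      int id = pats.size();
      pat_id[col] = id;
      pats.push_back(col);
      col_pat[s] = id;
    } else col_pat[s] = it->second;
  }
  int K = pats.size();
  int npairs = n * (n - 1) / 2;
  std::vector<signed char> code((size_t)K * npairs);
  bool any_variable = false;
  for (int k = 0; k < K; ++k) {
    int pr = 0;
    bool varies = false;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j, ++pr) {
        int a = pats[k][i], b = pats[k][j];
        signed char c;
        if (!is_base(a) || !is_base(b)) c = -1;
        else if (a == b) c = 0;
        else { c = is_transition(a, b) ? 1 : 2; varies = true; }
        code[(size_t)k * npairs + pr] = c;
      }
    }
    if (varies) any_variable = true;
  }
  NumericVector out(npar + 1);
  if (!any_variable) {
    out[npar] = 100.0;
    return out;
  }
  std::vector<double> votes(npar, 0.0);
  double unresolved = 0.0;
  std::vector<int> cnt(K);
  std::vector<double> P(npairs), Q(npairs), comp(npairs);
  std::vector<double> D((size_t)n * n);
  std::vector<int> eu, ev;
  std::vector<double> el;
  for (int rep = 0; rep < reps; ++rep) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int s = 0; s < L; ++s) {
      int j = (int)(unif_rand() * L);
      if (j == L) j = L - 1;
      cnt[col_pat[j]] += 1;
    }
    std::fill(P.begin(), P.end(), 0.0);
    std::fill(Q.begin(), Q.end(), 0.0);
    std::fill(comp.begin(), comp.end(), 0.0);
    bool varies = false;
    for (int k = 0; k < K; ++k) {
      if (!cnt[k]) continue;
      const signed char* row = &code[(size_t)k * npairs];
      for (int pr = 0; pr < npairs; ++pr) {
        signed char c = row[pr];
        if (c < 0) continue;
        comp[pr] += cnt[k];
        if (c == 1) { P[pr] += cnt[k]; varies = true; }
        else if (c == 2) { Q[pr] += cnt[k]; varies = true; }
      }
    }
    if (!varies) { unresolved += 1.0; continue; }
    int pr = 0;
    for (int i = 0; i < n; ++i) {
      D[(size_t)i * n + i] = 0.0;
      for (int j = i + 1; j < n; ++j, ++pr) {
        double d = dist_from_counts(P[pr], Q[pr], comp[pr], ceiling, model);
        D[(size_t)i * n + j] = D[(size_t)j * n + i] = d;
      }
    }
    nj_core(D, n, eu, ev, el);
    std::vector<double> v0(votes);
    vote_tree(eu, ev, n, qi, par_of_tip, npar, votes);
    bool voted = false;
    for (int p = 0; p < npar; ++p) if (votes[p] != v0[p]) voted = true;
    if (!voted) unresolved += 1.0;
  }
  for (int p = 0; p < npar; ++p) out[p] = 100.0 * votes[p] / reps;
  out[npar] = 100.0 * unresolved / reps;
  return out;
}
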