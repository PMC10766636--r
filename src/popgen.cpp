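#include <Rcpp.h>
using namespace Rcpp;

// Pairwise difference and comparable-site counts under pairwise deletion.
// seqs: n x L integer matrix, 1..4 = A,C,G,T; 0 = missing/ambiguous/gap.
// Columns that are complete (no missing) and constant contribute one
// comparable site to every pair and no differences, so only "active"
// columns (with missing data or variation) enter the pair loop.
// [[Rcpp::export]]
List diff_matrix_cpp(const IntegerMatrix& seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  std::vector<int> active;
  int base_comp = 0;
  for (int s = 0; s < L; ++s) {
    bool missing = false, varies = false;
    const int first = seqs(0, s);
    for (int i = 0; i < n; ++i) {
      const int v = seqs(i, s);
      if (v == 0) { missing = true; break; }
      if (v != first) varies = true;
    }
    if (missing || varies) active.push_back(s);
    else ++base_comp;
  }
  const int A = (int)active.size();
  // row-contiguous buffer of the active columns
  std::vector<int> buf((size_t)n * A);
  for (int t = 0; t < A; ++t) {
    const int s = active[t];
    for (int i = 0; i < n; ++i) buf[(size_t)i * A + t] = seqs(i, s);
  }
  IntegerMatrix diffs(n, n), comp(n, n);
  for (int i = 0; i < n; ++i) {
    const int* ri = &buf[(size_t)i * A];
    for (int j = i + 1; j < n; ++j) {
      const int* rj = &buf[(size_t)j * A];
      int d = 0, c = base_comp;
      for (int t = 0; t < A; ++t) {
        const int a = ri[t], b = rj[t];
        if (a > 0 && b > 0) {
          ++c;
          if (a != b) ++d;
        }
      }
      diffs(i, j) = diffs(j, i) = d;
      comp(i, j) = comp(j, i) = c;
    }
  }
  return List::create(_["diffs"] = diffs, _["comparable"] = comp);
}

// Hamming distances between all rows of a (haplotype) matrix, no missing.
// [[Rcpp::export]]
IntegerMatrix hamming_matrix_cpp(const IntegerMatrix& seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  IntegerMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int dd = 0;
      for (int s = 0; s < L; ++s)
        if (seqs(i, s) != seqs(j, s)) ++dd;
      d(i, j) = d(j, i) = dd;
    }
  return d;
}

// Per-column flag: at least two distinct non-missing states.
// [[Rcpp::export]]
LogicalVector seg_cols_cpp(const IntegerMatrix& seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  LogicalVector out(L);
  for (int s = 0; s < L; ++s) {
    int first = 0;
    bool seg = false;
    for (int i = 0; i < n; ++i) {
      const int v = seqs(i, s);
      if (v == 0) continue;
      if (first == 0) first = v;
      else if (v != first) { seg = true; break; }
    }
    out[s] = seg;
  }
  return out;
}

// Among-group Phi-statistic (FCT) from the pooled squared-distance summary.
// S: P x P matrix of summed squared distances over ordered pairs; np:
// population sizes; groups: 1-based group index per population; G: number
// of groups. Returns FCT (NaN when undefined).
// [[Rcpp::export]]
double fct_cpp(const NumericMatrix& S, const IntegerVector& np,
               const IntegerVector& groups, const int G) {
  const int P = np.size();
  double N = 0;
  for (int p = 0; p < P; ++p) N += np[p];
  double ssd_total = 0, ssd_wp = 0;
  for (int p = 0; p < P; ++p) {
    ssd_wp += S(p, p) / (2.0 * np[p]);
    for (int q = 0; q < P; ++q) ssd_total += S(p, q);
  }
  ssd_total /= 2.0 * N;
  double ssd_wg = 0, sum_np2_over_ng = 0, ng2 = 0, np2 = 0;
  for (int g = 1; g <= G; ++g) {
    double n_g = 0, s_g = 0, np2_g = 0;
    for (int p = 0; p < P; ++p) {
      if (groups[p] != g) continue;
      n_g += np[p];
      np2_g += (double)np[p] * np[p];
      for (int q = 0; q < P; ++q)
        if (groups[q] == g) s_g += S(p, q);
    }
    if (n_g == 0) return NA_REAL;
    ssd_wg += s_g / (2.0 * n_g);
    sum_np2_over_ng += np2_g / n_g;
    ng2 += n_g * n_g;
  }
  for (int p = 0; p < P; ++p) np2 += (double)np[p] * np[p];
  const double ssd_ap = ssd_wg - ssd_wp;
  const double ssd_ag = ssd_total - ssd_wg;
  const int df_a = G - 1, df_b = P - G;
  const double df_c = N - P;
  if (df_a <= 0 || df_c <= 0) return NA_REAL;
  const double sigma_c = ssd_wp / df_c;
  double sigma_b = 0;
  if (df_b > 0) {
    const double n_coef = (N - sum_np2_over_ng) / df_b;
    sigma_b = (ssd_ap / df_b - sigma_c) / n_coef;
  }
  const double n1 = (sum_np2_over_ng - np2 / N) / df_a;
  const double n2 = (N - ng2 / N) / df_a;
  const double sigma_a = (ssd_ag / df_a - sigma_c - n1 * sigma_b) / n2;
  const double tot = sigma_a + sigma_b + sigma_c;
  if (tot == 0) return NA_REAL;
  return sigma_a / tot;
}

// Simulated-annealing search over K-group partitions maximizing FCT.
// Geometric cooling; move = reassign one population to another group
// (rejected if it would empty a group). Uses R's RNG so results are
// reproducible under set.seed(). Returns the best grouping, its FCT and
// the per-restart best values.
// [[Rcpp::export]]
List samova_anneal_cpp(const NumericMatrix& S, const IntegerVector& np,
                       const int K, const int n_restarts, const double t0,
                       const double cooling, const int steps_per_temp,
                       const int n_temps) {
  const int P = np.size();
  IntegerVector best_g(P);
  double best_f = R_NegInf;
  NumericVector trace(n_restarts);
  IntegerVector g(P), g_rb(P);
  std::vector<int> cnt(K + 1);
  for (int r = 0; r < n_restarts; ++r) {
    // random init with all groups represented: first K slots 1..K, rest
    // uniform, then a Fisher-Yates shuffle
    for (int p = 0; p < P; ++p)
      g[p] = (p < K) ? p + 1 : 1 + (int)(unif_rand() * K);
    for (int p = P - 1; p > 0; --p) {
      int q = (int)(unif_rand() * (p + 1));
      std::swap(g[p], g[q]);
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int p = 0; p < P; ++p) ++cnt[g[p]];
    double f = fct_cpp(S, np, g, K);
    if (ISNAN(f)) f = R_NegInf;
    double f_rb = f;
    for (int p = 0; p < P; ++p) g_rb[p] = g[p];
    double temp = t0;
    for (int ti = 0; ti < n_temps; ++ti) {
      for (int s = 0; s < steps_per_temp; ++s) {
        const int i = (int)(unif_rand() * P);
        if (cnt[g[i]] == 1) continue;
        int ng = 1 + (int)(unif_rand() * (K - 1));
        if (ng >= g[i]) ++ng;
        const int old = g[i];
        g[i] = ng;
        double f2 = fct_cpp(S, np, g, K);
        if (ISNAN(f2)) f2 = R_NegInf;
        if (f2 >= f || unif_rand() < std::exp((f2 - f) / temp)) {
          f = f2;
          --cnt[old]; ++cnt[ng];
          if (f > f_rb) {
            f_rb = f;
            for (int p = 0; p < P; ++p) g_rb[p] = g[p];
          }
        } else {
          g[i] = old;
        }
      }
      temp *= cooling;
    }
    trace[r] = f_rb;
    if (f_rb > best_f) {
      best_f = f_rb;
      for (int p = 0; p < P; ++p) best_g[p] = g_rb[p];
    }
  }
  return List::create(_["groups"] = best_g, _["FCT"] = best_f,
                      _["trace"] = trace);
}

// Evolve sequences along a genealogy by uniformization of a normalized
// substitution chain. Edges must be ordered parent-before-child. Uses R's
// RNG (RNGScope added by the attribute wrapper), so results are
// reproducible under set.seed().
// edges: (2n-2) x 2, 1-based node ids; r: per-site rate multipliers;
// jump_cum: 4x4 row-wise cumulative jump probabilities; leave: leave rate
// per state (<= q_max); freq_cum: cumulative stationary frequencies.
// Returns the n_tip x L integer matrix of tip sequences (1..4).
// [[Rcpp::export]]
IntegerMatrix mutate_tree_cpp(const IntegerMatrix& edges,
                              const NumericVector& edge_length,
                              const int n_tip, const int root,
                              const NumericVector& r,
                              const double mu, const double q_max,
                              const NumericVector& leave,
                              const NumericMatrix& jump_cum,
                              const NumericVector& freq_cum) {
  const int L = r.size();
  const int n_nodes = 2 * n_tip - 1;
  std::vector<int> seqs((size_t)n_nodes * L);
  // cumulative site rates for sampling mutated sites proportional to r
  std::vector<double> cum_r(L);
  double sum_r = 0;
  for (int s = 0; s < L; ++s) { sum_r += r[s]; cum_r[s] = sum_r; }
  // root from stationary frequencies
  int* root_row = &seqs[(size_t)(root - 1) * L];
  for (int s = 0; s < L; ++s) {
    const double u = unif_rand();
    int st = 0;
    while (st < 3 && u > freq_cum[st]) ++st;
    root_row[s] = st + 1;
  }
  const int nE = edges.nrow();
  for (int e = 0; e < nE; ++e) {
    const int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    const int* pr = &seqs[(size_t)parent * L];
    int* ch = &seqs[(size_t)child * L];
    std::copy(pr, pr + L, ch);
    if (sum_r <= 0) continue;
    const int n_ev = (int)R::rpois(mu * q_max * sum_r * edge_length[e]);
    for (int k = 0; k < n_ev; ++k) {
      const double target = unif_rand() * sum_r;
      int lo = 0, hi = L - 1;
      while (lo < hi) {
        const int mid = (lo + hi) / 2;
        if (cum_r[mid] < target) lo = mid + 1; else hi = mid;
      }
      const int st = ch[lo];
      if (unif_rand() < leave[st - 1] / q_max) {
        const double u = unif_rand();
        int to = 0;
        while (to < 3 && u > jump_cum(st - 1, to)) ++to;
        ch[lo] = to + 1;
      }
    }
  }
  IntegerMatrix tips(n_tip, L);
  for (int i = 0; i < n_tip; ++i)
    for (int s = 0; s < L; ++s) tips(i, s) = seqs[(size_t)i * L + s];
  return tips;
}

// Structured coalescent with population split events. lin_pop: 1-based
// population index per sampled lineage; Npop: effective sizes; events
// (ev_t sorted ascending): at ev_t[i] population ev_d[i] merges into
// ev_a[i]. Uses R's RNG. Returns edge matrix (parent, child; appended in
// coalescence order so parents always come later), node times and root.
// [[Rcpp::export]]
List coalesce_cpp(const IntegerVector& lin_pop0, const NumericVector& Npop,
                  const NumericVector& ev_t, const IntegerVector& ev_d,
                  const IntegerVector& ev_a) {
  const int n_tip = lin_pop0.size();
  const int P = Npop.size();
  std::vector<int> lin_id(n_tip), lin_pop(n_tip);
  for (int i = 0; i < n_tip; ++i) {
    lin_id[i] = i + 1;
    lin_pop[i] = lin_pop0[i];
  }
  std::vector<int> k(P + 1, 0);
  for (int i = 0; i < n_tip; ++i) ++k[lin_pop[i]];
  IntegerMatrix edges(2 * (n_tip - 1), 2);
  NumericVector node_time(2 * n_tip - 1);
  int e_i = 0, next_node = n_tip + 1, ev_i = 0, n_act = n_tip;
  double t_now = 0;
  while (n_act > 1) {
    double total = 0;
    for (int p = 1; p <= P; ++p)
      total += k[p] * (k[p] - 1.0) / (2.0 * Npop[p - 1]);
    const double wait = total > 0 ? R::exp_rand() / total : R_PosInf;
    const double next_ev = ev_i < ev_t.size() ? ev_t[ev_i] : R_PosInf;
    if (t_now + wait < next_ev) {
      t_now += wait;
      // choose population proportional to its pair rate
      double u = unif_rand() * total, acc = 0;
      int p = 1;
      for (; p <= P; ++p) {
        acc += k[p] * (k[p] - 1.0) / (2.0 * Npop[p - 1]);
        if (u <= acc) break;
      }
      if (p > P) p = P;
      // pick two distinct lineages of population p
      const int kp = k[p];
      int i1 = (int)(unif_rand() * kp), i2 = (int)(unif_rand() * (kp - 1));
      if (i2 >= i1) ++i2;
      int a = -1, b = -1, seen = 0;
      for (int i = 0; i < n_act; ++i) {
        if (lin_pop[i] != p) continue;
        if (seen == i1) a = i;
        if (seen == i2) b = i;
        ++seen;
      }
      const int node = next_node++;
      node_time[node - 1] = t_now;
      edges(e_i, 0) = node; edges(e_i, 1) = lin_id[a]; ++e_i;
      edges(e_i, 0) = node; edges(e_i, 1) = lin_id[b]; ++e_i;
      lin_id[a] = node;
      lin_id[b] = lin_id[n_act - 1];
      lin_pop[b] = lin_pop[n_act - 1];
      --n_act;
      --k[p];
    } else {
      t_now = next_ev;
      k[ev_a[ev_i] ] += k[ev_d[ev_i]];
      k[ev_d[ev_i]] = 0;
      for (int i = 0; i < n_act; ++i)
        if (lin_pop[i] == ev_d[ev_i]) lin_pop[i] = ev_a[ev_i];
      ++ev_i;
    }
  }
  return List::create(_["edge"] = edges, _["node_time"] = node_time,
                      _["root"] = lin_id[0]);
}
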