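// Full MCMC sweeps for the connectivity-only model (no feature models):
// the per-entity assignment Gibbs scan with auxiliary classes, and the
// per-component slice-sampling scan. Both use R's RNG so chains are
// reproducible from R-level seeds. The R-level kernels dispatch here when
// no feature data is attached; the R implementations remain the reference
// path (and the only path when soma depths / synapse profiles are modeled).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double P_FLOOR2 = 1e-12;

static inline double clamp_prob2(double p) {
  if (p < P_FLOOR2) return P_FLOOR2;
  if (p > 1.0 - P_FLOOR2) return 1.0 - P_FLOOR2;
  return p;
}

static inline double pair_ll2(int kind, double obs, double d,
                              double p1, double p2,
                              double th1, double th2) {
  if (kind == 1) {
    double ps = 1.0 / (1.0 + std::exp((d - p1) / p2));
    double p = clamp_prob2(ps * (th1 - th2) + th2);
    return obs > 0.5 ? std::log(p) : std::log1p(-p);
  } else if (kind == 2) {
    double rs = 1.0 / (1.0 + std::exp((d - p1) / th1));
    double r = rs * (p2 - th2) + th2;
    if (r < 1e-10) r = 1e-10;
    return obs * std::log(r) - r - std::lgamma(obs + 1.0);
  } else {
    double ps = 1.0 / (1.0 + std::exp((d - p1) / th1));
    double p = clamp_prob2(ps * (p2 - th2) + th2);
    return obs > 0.5 ? std::log(p) : std::log1p(-p);
  }
}

// Square parameter table with grow/shrink by class, kept symmetric for
// undirected relations by construction (callers write both entries).
struct Table {
  int K;
  std::vector<double> v; // K x K row-major
  double at(int a, int b) const { return v[a * K + b]; }
  void set(int a, int b, double x) { v[a * K + b] = x; }
  void resize_to(int Kn) {
    std::vector<double> nv(Kn * Kn, 0.0);
    int m = std::min(K, Kn);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b) nv[a * Kn + b] = v[a * K + b];
    v.swap(nv); K = Kn;
  }
  void move_class(int from, int to) { // copy row/col `from` onto `to`
    for (int b = 0; b < K; ++b) set(to, b, at(from, b));
    for (int a = 0; a < K; ++a) set(a, to, at(a, from));
    set(to, to, at(from, from));
  }
  void drop_class(int k) {
    int Kn = K - 1;
    std::vector<double> nv(Kn * Kn);
    for (int a = 0, aa = 0; a < K; ++a) {
      if (a == k) continue;
      for (int b = 0, bb = 0; b < K; ++b) {
        if (b == k) continue;
        nv[aa * Kn + bb] = at(a, b);
        ++bb;
      }
      ++aa;
    }
    v.swap(nv); K = Kn;
  }
};

struct Rel {
  const double* R;
  const double* D;
  const int* mask; // LGLSXP storage
  int N;
  bool directed;
  int kind;
  double th1, th2;
  Table p1, p2;
  // prior: exponential means (and beta shapes for kind 3); fixed short-circuits
  double pa1, pa2, pa3, pa4;
  bool fixed;
  double fx1, fx2;
  void draw_prior(double& a, double& b) const {
    if (fixed) { a = fx1; b = fx2; return; }
    a = R::rexp(pa1);
    if (kind == 1) b = R::rexp(pa2);
    else if (kind == 2) b = th2 + R::rexp(pa2);
    else b = th2 + (1.0 - th2) * R::rbeta(pa3, pa4);
  }
  double prior_ll_p1(double x) const {
    if (fixed) return 0.0;
    return -std::log(pa1) - x / pa1;
  }
  double prior_ll_p2(double x) const {
    if (fixed) return 0.0;
    if (kind == 1) return -std::log(pa2) - x / pa2;
    if (kind == 2) {
      double y = x - th2;
      if (y <= 0) return R_NegInf;
      return -std::log(pa2) - y / pa2;
    }
    double u = (x - th2) / (1.0 - th2);
    if (u <= 0 || u >= 1) return R_NegInf;
    return R::dbeta(u, pa3, pa4, 1) - std::log1p(-th2);
  }
};

static std::vector<Rel> unpack_rels(List rels) {
  std::vector<Rel> out;
  for (int q = 0; q < rels.size(); ++q) {
    List rl = rels[q];
    Rel r;
    NumericMatrix Rm = rl["matrix"], Dm = rl["dmat"];
    LogicalMatrix Mm = rl["mask"];
    r.R = REAL(Rm); r.D = REAL(Dm); r.mask = LOGICAL(Mm);
    r.N = Rm.nrow();
    r.directed = as<bool>(rl["directed"]);
    r.kind = as<int>(rl["kind"]);
    NumericVector th = rl["theta"];
    r.th1 = th[0]; r.th2 = th[1];
    NumericMatrix P1 = rl["p1"], P2 = rl["p2"];
    int K = P1.nrow();
    r.p1.K = K; r.p1.v.assign(P1.begin(), P1.end());
    r.p2.K = K; r.p2.v.assign(P2.begin(), P2.end());
    // column-major to row-major is harmless: tables start symmetric for
    // undirected relations; for directed we transpose explicitly
    if (r.directed) {
      Table t1 = r.p1, t2 = r.p2;
      for (int a = 0; a < K; ++a)
        for (int b = 0; b < K; ++b) {
          r.p1.set(a, b, t1.at(b, a));
          r.p2.set(a, b, t2.at(b, a));
        }
    }
    NumericVector pp = rl["prior"];
    r.pa1 = pp[0]; r.pa2 = pp[1]; r.pa3 = pp[2]; r.pa4 = pp[3];
    r.fixed = as<bool>(rl["fixed"]);
    if (r.fixed) {
      NumericVector fx = rl["fx"];
      r.fx1 = fx[0]; r.fx2 = fx[1];
    } else { r.fx1 = r.fx2 = 0.0; }
    out.push_back(r);
  }
  return out;
}

static List pack_rels(const std::vector<Rel>& rels, int K) {
  List out(rels.size());
  for (size_t q = 0; q < rels.size(); ++q) {
    NumericMatrix P1(K, K), P2(K, K);
    for (int a = 0; a < K; ++a)
      for (int b = 0; b < K; ++b) {
        if (rels[q].directed) { // back to column-major orientation
          P1(a, b) = rels[q].p1.at(a, b);
          P2(a, b) = rels[q].p2.at(a, b);
        } else {
          P1(a, b) = rels[q].p1.at(a, b);
          P2(a, b) = rels[q].p2.at(a, b);
        }
      }
    out[q] = List::create(Named("p1") = P1, Named("p2") = P2);
  }
  return out;
}

// One full assignment Gibbs sweep (auxiliary-variable scheme, n_aux
// ephemeral classes per entity, singleton classes retained as the first
// auxiliary). Returns updated labels (1-based), K, and parameter tables.
// [[Rcpp::export]]
List cpp_sweep_assignments(IntegerVector labels_in, int K_in, List rels,
                           double alpha, double temperature, int n_aux) {
  std::vector<Rel> R = unpack_rels(rels);
  int N = labels_in.size();
  std::vector<int> lab(N);
  for (int i = 0; i < N; ++i) lab[i] = labels_in[i] - 1;
  int K = K_in;
  std::vector<int> counts(K, 0);
  for (int i = 0; i < N; ++i) counts[lab[i]]++;
  std::vector<double> ll, logw;
  for (int i = 0; i < N; ++i) {
    int k_old = lab[i];
    counts[k_old]--;
    bool singleton = counts[k_old] == 0;
    int n_fresh = singleton ? n_aux - 1 : n_aux;
    int Kt = K + n_fresh;
    // grow tables, fill fresh rows/cols from the prior
    for (auto& r : R) {
      r.p1.resize_to(Kt);
      r.p2.resize_to(Kt);
      for (int a = K; a < Kt; ++a)
        for (int b = 0; b <= (r.directed ? Kt - 1 : a); ++b) {
          double v1, v2;
          r.draw_prior(v1, v2);
          r.p1.set(a, b, v1); r.p2.set(a, b, v2);
          if (!r.directed) { r.p1.set(b, a, v1); r.p2.set(b, a, v2); }
          if (r.directed && b < K) { // fresh columns for old rows
            r.draw_prior(v1, v2);
            r.p1.set(b, a, v1); r.p2.set(b, a, v2);
          }
        }
    }
    ll.assign(Kt, 0.0);
    for (auto& r : R) {
      const int NN = r.N;
      for (int j = 0; j < NN; ++j) {
        if (j == i) continue;
        int cj = lab[j];
        double d = r.D[i + (size_t)NN * j];
        if (!r.directed) {
          if (!r.mask[i + (size_t)NN * j]) continue;
          double obs = r.R[i + (size_t)NN * j];
          for (int k = 0; k < Kt; ++k)
            ll[k] += pair_ll2(r.kind, obs, d, r.p1.at(k, cj), r.p2.at(k, cj),
                              r.th1, r.th2);
        } else {
          if (r.mask[i + (size_t)NN * j]) {
            double obs = r.R[i + (size_t)NN * j];
            for (int k = 0; k < Kt; ++k)
              ll[k] += pair_ll2(r.kind, obs, d, r.p1.at(k, cj), r.p2.at(k, cj),
                                r.th1, r.th2);
          }
          if (r.mask[j + (size_t)NN * i]) {
            double obs = r.R[j + (size_t)NN * i];
            for (int k = 0; k < Kt; ++k)
              ll[k] += pair_ll2(r.kind, obs, d, r.p1.at(cj, k), r.p2.at(cj, k),
                                r.th1, r.th2);
          }
        }
      }
    }
    logw.assign(Kt, 0.0);
    double la = std::log(alpha / n_aux);
    double mx = R_NegInf;
    for (int k = 0; k < Kt; ++k) {
      double w = ll[k] / temperature +
        ((k < K && counts[k] > 0) ? std::log((double)counts[k]) : la);
      logw[k] = w;
      if (w > mx) mx = w;
    }
    double tot = 0.0;
    for (int k = 0; k < Kt; ++k) { logw[k] = std::exp(logw[k] - mx); tot += logw[k]; }
    double u = unif_rand() * tot;
    int k_new = Kt - 1;
    double acc = 0.0;
    for (int k = 0; k < Kt; ++k) { acc += logw[k]; if (u <= acc) { k_new = k; break; } }
    if (k_new >= K) { // promote chosen ephemeral class to position K
      for (auto& r : R) { r.p1.move_class(k_new, K); r.p2.move_class(k_new, K); }
      k_new = K;
      K++;
      counts.push_back(0);
    }
    // shrink tables back to K real classes
    for (auto& r : R) { r.p1.resize_to(K); r.p2.resize_to(K); }
    lab[i] = k_new;
    counts[k_new]++;
    if (singleton && k_new != k_old) {
      for (auto& r : R) { r.p1.drop_class(k_old); r.p2.drop_class(k_old); }
      counts.erase(counts.begin() + k_old);
      K--;
      for (int j = 0; j < N; ++j) if (lab[j] > k_old) lab[j]--;
    }
  }
  IntegerVector lab_out(N);
  for (int i = 0; i < N; ++i) lab_out[i] = lab[i] + 1;
  return List::create(Named("labels") = lab_out, Named("K") = K,
                      Named("comps") = pack_rels(R, K));
}

// Univariate slice sampler (stepping out + shrinkage) on a tempered block
// conditional. logf closure is expressed via function pointers below.
struct BlockCtx {
  const Rel* r;
  const std::vector<int>* mi;
  const std::vector<int>* mj;
  bool within;       // m == n (undirected): unordered pairs within class
  double other;      // value of the parameter not being updated
  bool updating_p1;
  double temperature;
};

static double block_logf(const BlockCtx& c, double x) {
  double p1 = c.updating_p1 ? x : c.other;
  double p2 = c.updating_p1 ? c.other : x;
  const Rel& r = *c.r;
  double ll = 0.0;
  const int NN = r.N;
  if (c.within) {
    const std::vector<int>& m = *c.mi;
    for (size_t a = 0; a < m.size(); ++a)
      for (size_t b = a + 1; b < m.size(); ++b) {
        int i = m[a], j = m[b];
        if (!r.mask[i + (size_t)NN * j]) continue;
        ll += pair_ll2(r.kind, r.R[i + (size_t)NN * j], r.D[i + (size_t)NN * j],
                       p1, p2, r.th1, r.th2);
      }
  } else {
    for (int i : *c.mi)
      for (int j : *c.mj) {
        if (!r.mask[i + (size_t)NN * j]) continue;
        ll += pair_ll2(r.kind, r.R[i + (size_t)NN * j], r.D[i + (size_t)NN * j],
                       p1, p2, r.th1, r.th2);
      }
  }
  double pri = c.updating_p1 ? r.prior_ll_p1(x) : r.prior_ll_p2(x);
  return ll / c.temperature + pri;
}

static double slice1(const BlockCtx& c, double x0, double w, double lower,
                     double upper) {
  double f0 = block_logf(c, x0);
  if (!std::isfinite(f0)) return x0;
  double y = f0 - R::rexp(1.0);
  double L = x0 - w * unif_rand();
  double Rr = L + w;
  if (L < lower) L = lower;
  if (Rr > upper) Rr = upper;
  int steps = 16;
  while (steps-- > 0 && L > lower && block_logf(c, L) > y) {
    L -= w; if (L < lower) { L = lower; break; }
  }
  steps = 16;
  while (steps-- > 0 && Rr < upper && block_logf(c, Rr) > y) {
    Rr += w; if (Rr > upper) { Rr = upper; break; }
  }
  for (int it = 0; it < 100; ++it) {
    double x1 = L + unif_rand() * (Rr - L);
    if (block_logf(c, x1) >= y) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// One slice-sampling sweep over every component of every relation.
// widths: per-relation 2-vectors (initial slice widths for p1, p2);
// bounds: per-relation 4-vectors (lower1, upper1, lower2, upper2).
// [[Rcpp::export]]
List cpp_sweep_eta(IntegerVector labels, int K, List rels, double temperature,
                   List widths, List bounds) {
  std::vector<Rel> R = unpack_rels(rels);
  int N = labels.size();
  std::vector<std::vector<int> > members(K);
  for (int i = 0; i < N; ++i) members[labels[i] - 1].push_back(i);
  for (size_t q = 0; q < R.size(); ++q) {
    Rel& r = R[q];
    if (r.fixed) continue;
    NumericVector w = widths[q], bd = bounds[q];
    for (int m = 0; m < K; ++m) {
      int n_hi = r.directed ? K : m + 1;
      for (int n = (r.directed ? 0 : 0); n < (r.directed ? K : n_hi); ++n) {
        // undirected: n ranges 0..m (lower triangle incl diagonal)
        BlockCtx c;
        c.r = &r;
        c.temperature = temperature;
        c.within = (!r.directed) && (m == n);
        c.mi = &members[m];
        c.mj = &members[n];
        for (int par = 0; par < 2; ++par) {
          c.updating_p1 = (par == 0);
          c.other = c.updating_p1 ? r.p2.at(m, n) : r.p1.at(m, n);
          double x0 = c.updating_p1 ? r.p1.at(m, n) : r.p2.at(m, n);
          double x1 = slice1(c, x0, w[par], bd[2 * par], bd[2 * par + 1]);
          if (c.updating_p1) {
            r.p1.set(m, n, x1);
            if (!r.directed) r.p1.set(n, m, x1);
          } else {
            r.p2.set(m, n, x1);
            if (!r.directed) r.p2.set(n, m, x1);
          }
        }
      }
    }
  }
  return pack_rels(R, K);
}
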