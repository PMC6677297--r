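// Numerical core: Kabsch superposition, rectangular linear assignment
// (Jonker-Volgenant style shortest augmenting paths), the iterative
// superpose-assign refinement used by the non-sequential interface
// alignment, and the iterative superpose-DP loop used by the sequential
// TM-score comparison of whole domains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BIG = 1e30;

// Least-squares proper rotation mapping rows of X onto rows of Y.
// Returns R (3x3) and t (1x3) such that X %*% t(R) + t approximates Y.
static void kabsch_core(const mat& X, const mat& Y, mat& R, rowvec& t,
                        double& rmsd) {
  rowvec cx = mean(X, 0), cy = mean(Y, 0);
  mat Xc = X.each_row() - cx;
  mat Yc = Y.each_row() - cy;
  mat H = Xc.t() * Yc;
  mat U, V;
  vec s;
  if (!svd(U, s, V, H)) Rcpp::stop("SVD failure in Kabsch superposition");
  double d = det(V * U.t());
  mat D = eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = cy - cx * R.t();
  mat E = Xc * R.t() - Yc;
  rmsd = std::sqrt(accu(square(E)) / X.n_rows);
}

// [[Rcpp::export(name = ".kabsch_cpp")]]
Rcpp::List kabsch_cpp(const arma::mat& X, const arma::mat& Y) {
  mat R;
  rowvec t;
  double rmsd;
  kabsch_core(X, Y, R, t, rmsd);
  return Rcpp::List::create(Rcpp::Named("rotation") = R,
                            Rcpp::Named("translation") = t,
                            Rcpp::Named("rmsd") = rmsd);
}

// Rectangular LSAP, minimising total cost; requires n <= m.
// Returns, for each row, the assigned column (0-based).
static std::vector<int> lsap_min(const mat& cost) {
  const int n = cost.n_rows, m = cost.n_cols;
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, BIG);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = BIG;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  std::vector<int> ans(n, -1);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j - 1;
  return ans;
}

// [[Rcpp::export(name = ".lsap_cpp")]]
Rcpp::IntegerVector lsap_cpp(const arma::mat& cost) {
  // returns 1-based column index assigned to each row (rows <= cols),
  // minimising total cost
  bool flip = cost.n_rows > cost.n_cols;
  mat c = flip ? cost.t() : cost;
  std::vector<int> a = lsap_min(c);
  if (!flip) {
    Rcpp::IntegerVector out(cost.n_rows);
    for (size_t i = 0; i < a.size(); ++i) out[i] = a[i] + 1;
    return out;
  }
  Rcpp::IntegerVector out(cost.n_rows, NA_INTEGER);
  for (size_t j = 0; j < a.size(); ++j) out[a[j]] = (int)j + 1;
  return out;
}

// Solve one side's assignment between query rows idxq and template rows
// idxt of the transformed coordinates; appends matched index pairs.
static void match_side(const mat& Q, const mat& Tt, const uvec& idxq,
                       const uvec& idxt, double d0, double pair_cut,
                       std::vector<int>& qi, std::vector<int>& ti) {
  if (idxq.n_elem == 0 || idxt.n_elem == 0) return;
  const int n = idxq.n_elem, m = idxt.n_elem;
  mat cost(n, m);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < m; ++b) {
      double d2 = accu(square(Q.row(idxq[a]) - Tt.row(idxt[b])));
      // distance kernel shaped by the pairing cutoff: beyond pair_cut the
      // benefit is flattened so far-away pairs do not steer the assignment
      double ker = 1.0 / (1.0 + d2 / (d0 * d0));
      double cut2 = pair_cut * pair_cut;
      if (d2 > cut2) ker *= 0.25;
      cost(a, b) = -ker;
    }
  if (n <= m) {
    std::vector<int> a = lsap_min(cost);
    for (int r = 0; r < n; ++r) {
      qi.push_back(idxq[r]);
      ti.push_back(idxt[a[r]]);
    }
  } else {
    std::vector<int> a = lsap_min(cost.t());
    for (int c = 0; c < m; ++c) {
      qi.push_back(idxq[a[c]]);
      ti.push_back(idxt[c]);
    }
  }
}

// Iterative refinement of one alignment seed: alternate rectangular
// assignment per interface side with Kabsch superposition on the matched
// pairs, until the geometric score converges.
// side_q, side_t: 1/2 labels; pairing = 1 keeps sides, 2 swaps them.
// [[Rcpp::export(name = ".refine_seed_cpp")]]
Rcpp::List refine_seed_cpp(const arma::mat& Q, const arma::mat& T,
                           const arma::ivec& side_q, const arma::ivec& side_t,
                           int pairing, const arma::mat& R0,
                           const arma::rowvec& t0, double d0,
                           double pair_cut, int max_iter, double tol) {
  uvec q1 = find(side_q == 1), q2 = find(side_q == 2);
  uvec t1 = find(side_t == (pairing == 1 ? 1 : 2));
  uvec t2 = find(side_t == (pairing == 1 ? 2 : 1));
  mat R = R0;
  rowvec t = t0;
  double gprev = -1.0, rmsd = NA_REAL;
  std::vector<int> qi, ti;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    mat Tt = T * R.t();
    Tt.each_row() += t;
    qi.clear(); ti.clear();
    match_side(Q, Tt, q1, t1, d0, pair_cut, qi, ti);
    match_side(Q, Tt, q2, t2, d0, pair_cut, qi, ti);
    const int np = qi.size();
    if (np < 3) break;
    double g = 0.0;
    mat Xs(np, 3), Ys(np, 3);
    for (int k = 0; k < np; ++k) {
      Xs.row(k) = T.row(ti[k]);
      Ys.row(k) = Q.row(qi[k]);
      double d2 = accu(square(Q.row(qi[k]) - Tt.row(ti[k])));
      g += 1.0 / (1.0 + d2 / (d0 * d0));
    }
    kabsch_core(Xs, Ys, R, t, rmsd);
    if (std::fabs(g - gprev) < tol) break;
    gprev = g;
  }
  Rcpp::IntegerVector qout(qi.size()), tout(ti.size());
  for (size_t k = 0; k < qi.size(); ++k) {
    qout[k] = qi[k] + 1;
    tout[k] = ti[k] + 1;
  }
  return Rcpp::List::create(
      Rcpp::Named("qi") = qout, Rcpp::Named("ti") = tout,
      Rcpp::Named("rotation") = R, Rcpp::Named("translation") = t,
      Rcpp::Named("rmsd") = rmsd, Rcpp::Named("iterations") = it + 1);
}

// Global (Needleman-Wunsch, linear gap) DP over the distance-kernel score
// matrix; returns aligned index pairs (0-based) maximising the summed
// kernel with gap penalty gpen per gapped position.
static void dp_align(const mat& S, double gpen, std::vector<int>& ai,
                     std::vector<int>& bi) {
  const int n = S.n_rows, m = S.n_cols;
  mat F(n + 1, m + 1);
  Mat<int> P(n + 1, m + 1, fill::zeros);  // 1 diag, 2 up, 3 left
  F(0, 0) = 0;
  for (int i = 1; i <= n; ++i) { F(i, 0) = i * gpen; P(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { F(0, j) = j * gpen; P(0, j) = 3; }
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double diag = F(i - 1, j - 1) + S(i - 1, j - 1);
      double up = F(i - 1, j) + gpen;
      double left = F(i, j - 1) + gpen;
      if (diag >= up && diag >= left) { F(i, j) = diag; P(i, j) = 1; }
      else if (up >= left) { F(i, j) = up; P(i, j) = 2; }
      else { F(i, j) = left; P(i, j) = 3; }
    }
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = P(i, j);
    if (p == 1) { ai.push_back(i - 1); bi.push_back(j - 1); --i; --j; }
    else if (p == 2) --i;
    else --j;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
}

static double tm_of_pairs(const mat& A, const mat& B,
                          const std::vector<int>& ai,
                          const std::vector<int>& bi, double d0,
                          double Lnorm, mat& R, rowvec& t) {
  const int np = ai.size();
  if (np < 3) return 0.0;
  mat X(np, 3), Y(np, 3);
  for (int k = 0; k < np; ++k) {
    X.row(k) = B.row(bi[k]);
    Y.row(k) = A.row(ai[k]);
  }
  double rmsd;
  kabsch_core(X, Y, R, t, rmsd);
  mat Xt = X * R.t();
  Xt.each_row() += t;
  double s = 0.0;
  for (int k = 0; k < np; ++k)
    s += 1.0 / (1.0 + accu(square(Xt.row(k) - Y.row(k))) / (d0 * d0));
  return s / Lnorm;
}

// Sequential (order-preserving) structural alignment of two C-alpha traces
// by iterated fragment superposition + dynamic programming; returns the
// best TM-score found, normalised by Lnorm with the supplied d0.
// [[Rcpp::export(name = ".tm_align_cpp")]]
Rcpp::List tm_align_cpp(const arma::mat& A, const arma::mat& B, double d0,
                        double Lnorm, int max_iter) {
  const int n = A.n_rows, m = B.n_rows;
  const int lmin = std::min(std::min(n, m), 15);
  double best = 0.0;
  int best_len = 0;
  // gapless threading seeds
  int lo = -(m - lmin), hi = n - lmin;
  int stride = std::max(1, (hi - lo + 1) / 40);
  for (int off = lo; off <= hi; off += stride) {
    std::vector<int> ai, bi;
    for (int i = 0; i < n; ++i) {
      int j = i - off;
      if (j >= 0 && j < m) { ai.push_back(i); bi.push_back(j); }
    }
    if ((int)ai.size() < lmin) continue;
    std::vector<int> cai = ai, cbi = bi;
    for (int it = 0; it < max_iter; ++it) {
      mat R;
      rowvec t;
      double tm = tm_of_pairs(A, B, cai, cbi, d0, Lnorm, R, t);
      if (tm > best) { best = tm; best_len = cai.size(); }
      if (tm <= 0) break;
      mat Bt = B * R.t();
      Bt.each_row() += t;
      mat S(n, m);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j)
          S(i, j) =
              1.0 / (1.0 + accu(square(A.row(i) - Bt.row(j))) / (d0 * d0));
      std::vector<int> nai, nbi;
      dp_align(S, -0.6, nai, nbi);
      if (nai == cai && nbi == cbi) break;
      cai = nai; cbi = nbi;
    }
  }
  return Rcpp::List::create(Rcpp::Named("tm") = best,
                            Rcpp::Named("n_aligned") = best_len);
}

// Exact search over all per-side injective assignments between a query and
// a template interface (one fixed domain pairing): every full matching is
// scored as S = (1/LQ) sum f_i/(1+d_i^2/d0^2) under the Kabsch
// superposition of its own pairs. Returns the argmax matching.
// qa/qb, ta/tb: side coordinates; qcontacts: 0-based (ia, ib) pairs of the
// query contact map; tcon: logical matrix, tcon(i,j) = contact between
// template side-A row i and side-B row j; a_*: template per-residue
// contact counts; b_*: query per-residue contact counts.
static void injections_rec(int n, int k, std::vector<int>& cur,
                           std::vector<char>& used,
                           std::vector<std::vector<int>>& out) {
  if ((int)cur.size() == k) { out.push_back(cur); return; }
  for (int v = 0; v < n; ++v) {
    if (used[v]) continue;
    used[v] = 1; cur.push_back(v);
    injections_rec(n, k, cur, used, out);
    cur.pop_back(); used[v] = 0;
  }
}

// enumerate matchings of one side: rows (query) to cols (template),
// matching size min(nq, nt); each matching is a pair of index vectors
static std::vector<std::pair<std::vector<int>, std::vector<int>>>
side_matchings(int nq, int nt) {
  std::vector<std::pair<std::vector<int>, std::vector<int>>> res;
  std::vector<std::vector<int>> inj;
  std::vector<int> cur;
  if (nq <= nt) {
    std::vector<char> used(nt, 0);
    injections_rec(nt, nq, cur, used, inj);
    for (auto& j : inj) {
      std::vector<int> q(nq);
      for (int i = 0; i < nq; ++i) q[i] = i;
      res.push_back({q, j});
    }
  } else {
    std::vector<char> used(nq, 0);
    injections_rec(nq, nt, cur, used, inj);
    for (auto& j : inj) {
      std::vector<int> t(nt);
      for (int i = 0; i < nt; ++i) t[i] = i;
      res.push_back({j, t});
    }
  }
  return res;
}

// [[Rcpp::export(name = ".exact_enum_cpp")]]
Rcpp::List exact_enum_cpp(const arma::mat& qa, const arma::mat& qb,
                          const arma::mat& ta, const arma::mat& tb,
                          const arma::imat& qcontacts,
                          const arma::imat& tcon,
                          const arma::vec& a_a, const arma::vec& a_b,
                          const arma::vec& b_a, const arma::vec& b_b,
                          double d0, double LQ) {
  auto ma = side_matchings(qa.n_rows, ta.n_rows);
  auto mb = side_matchings(qb.n_rows, tb.n_rows);
  double best = -1.0;
  std::vector<int> bqa, bta, bqb, btb;
  const int nc = qcontacts.n_rows;
  for (auto& A : ma) {
    // map query side-A row -> template side-A row (or -1)
    std::vector<int> mapA(qa.n_rows, -1);
    for (size_t k = 0; k < A.first.size(); ++k)
      mapA[A.first[k]] = A.second[k];
    for (auto& B : mb) {
      std::vector<int> mapB(qb.n_rows, -1);
      for (size_t k = 0; k < B.first.size(); ++k)
        mapB[B.first[k]] = B.second[k];
      const int np = A.first.size() + B.first.size();
      if (np < 3) continue;
      mat X(np, 3), Y(np, 3);
      int r = 0;
      for (size_t k = 0; k < A.first.size(); ++k, ++r) {
        X.row(r) = ta.row(A.second[k]);
        Y.row(r) = qa.row(A.first[k]);
      }
      for (size_t k = 0; k < B.first.size(); ++k, ++r) {
        X.row(r) = tb.row(B.second[k]);
        Y.row(r) = qb.row(B.first[k]);
      }
      mat R;
      rowvec t;
      double rmsd;
      kabsch_core(X, Y, R, t, rmsd);
      mat Xt = X * R.t();
      Xt.each_row() += t;
      // overlap counts per aligned residue
      std::vector<double> cA(qa.n_rows, 0.0), cB(qb.n_rows, 0.0);
      for (int c = 0; c < nc; ++c) {
        int ia = qcontacts(c, 0), ib = qcontacts(c, 1);
        if (mapA[ia] >= 0 && mapB[ib] >= 0 && tcon(mapA[ia], mapB[ib])) {
          cA[ia] += 1.0;
          cB[ib] += 1.0;
        }
      }
      double S = 0.0;
      r = 0;
      for (size_t k = 0; k < A.first.size(); ++k, ++r) {
        double d2 = accu(square(Xt.row(r) - Y.row(r)));
        double f = (cA[A.first[k]] / a_a[A.second[k]] +
                    cA[A.first[k]] / b_a[A.first[k]]) / 2.0;
        S += f / (1.0 + d2 / (d0 * d0));
      }
      for (size_t k = 0; k < B.first.size(); ++k, ++r) {
        double d2 = accu(square(Xt.row(r) - Y.row(r)));
        double f = (cB[B.first[k]] / a_b[B.second[k]] +
                    cB[B.first[k]] / b_b[B.first[k]]) / 2.0;
        S += f / (1.0 + d2 / (d0 * d0));
      }
      S /= LQ;
      if (S > best) {
        best = S;
        bqa = A.first; bta = A.second;
        bqb = B.first; btb = B.second;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("S") = best,
      Rcpp::Named("qa") = Rcpp::wrap(bqa), Rcpp::Named("ta") = Rcpp::wrap(bta),
      Rcpp::Named("qb") = Rcpp::wrap(bqb), Rcpp::Named("tb") = Rcpp::wrap(btb));
}
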