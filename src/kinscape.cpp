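#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Sample a discrete Markov chain path from a row-stochastic matrix.
// Uses R's RNG so set.seed() gives reproducible paths. 1-based states.
// [[Rcpp::export]]
IntegerVector cpp_sample_chain(NumericMatrix T, int n_steps, int init) {
  int n = T.nrow();
  IntegerVector out(n_steps);
  // row-wise cumulative probabilities
  std::vector<double> cum(n * n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) { s += T(i, j); cum[i * n + j] = s; }
    cum[i * n + n - 1] = 1.0;
  }
  int s = init - 1;
  out[0] = s + 1;
  for (int t = 1; t < n_steps; ++t) {
    double u = unif_rand();
    const double* row = &cum[s * n];
    int j = 0;
    while (j < n - 1 && u > row[j]) ++j;
    s = j;
    out[t] = s + 1;
  }
  return out;
}

// Nearest-centre assignment: for each row of X, the index (1-based) of the
// closest row of centers in Euclidean distance.
// [[Rcpp::export]]
IntegerVector cpp_assign_centers(NumericMatrix X, NumericMatrix centers) {
  int n = X.nrow(), d = X.ncol(), k = centers.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - centers(j, c);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

static std::vector<double> stationary_of(const std::vector<double>& A, int K) {
  std::vector<double> p(K, 1.0 / K), q(K);
  for (int it = 0; it < 2000; ++it) {
    double diff = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += p[i] * A[i * K + j];
      q[j] = s;
    }
    double tot = 0.0;
    for (int j = 0; j < K; ++j) tot += q[j];
    for (int j = 0; j < K; ++j) { q[j] /= tot; diff += std::fabs(q[j] - p[j]); }
    p = q;
    if (diff < 1e-14) break;
  }
  return p;
}

// Baum-Welch EM for a hidden Markov model with discrete emissions over M
// observed symbols.  dtrajs: list of integer vectors with 0-based symbols.
// The initial state distribution is tied to the stationary distribution of
// the current transition matrix (equilibrium HMM).  Returns the refined
// transition matrix A (K x K), emission matrix B (K x M), log-likelihood
// trace, and convergence flag.
// [[Rcpp::export]]
List cpp_hmm_em(List dtrajs, int K, int M, NumericMatrix A0, NumericMatrix B0,
                int max_iter, double tol) {
  int S = dtrajs.size();
  std::vector<std::vector<int> > obs(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector v = dtrajs[s];
    obs[s].assign(v.begin(), v.end());
  }
  std::vector<double> A(K * K), B(K * M);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A[i * K + j] = A0(i, j);
  for (int i = 0; i < K; ++i)
    for (int m = 0; m < M; ++m) B[i * M + m] = B0(i, m);

  double prev_ll = R_NegInf, ll = R_NegInf;
  std::vector<double> ll_trace;
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    std::vector<double> Anum(K * K, 0.0), Bnum(K * M, 0.0);
    ll = 0.0;
    std::vector<double> pi0 = stationary_of(A, K);
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& o = obs[s];
      int Tn = (int)o.size();
      if (Tn < 2) continue;
      std::vector<double> alpha(Tn * K), beta(Tn * K), cvec(Tn);
      // forward with scaling
      double c0 = 0.0;
      for (int i = 0; i < K; ++i) {
        alpha[i] = pi0[i] * B[i * M + o[0]];
        c0 += alpha[i];
      }
      if (c0 <= 0) c0 = 1e-300;
      cvec[0] = c0;
      for (int i = 0; i < K; ++i) alpha[i] /= c0;
      for (int t = 1; t < Tn; ++t) {
        double ct = 0.0;
        for (int j = 0; j < K; ++j) {
          double a = 0.0;
          for (int i = 0; i < K; ++i) a += alpha[(t - 1) * K + i] * A[i * K + j];
          a *= B[j * M + o[t]];
          alpha[t * K + j] = a;
          ct += a;
        }
        if (ct <= 0) ct = 1e-300;
        cvec[t] = ct;
        for (int j = 0; j < K; ++j) alpha[t * K + j] /= ct;
      }
      // backward with same scaling
      for (int i = 0; i < K; ++i) beta[(Tn - 1) * K + i] = 1.0;
      for (int t = Tn - 2; t >= 0; --t) {
        for (int i = 0; i < K; ++i) {
          double b = 0.0;
          for (int j = 0; j < K; ++j)
            b += A[i * K + j] * B[j * M + o[t + 1]] * beta[(t + 1) * K + j];
          beta[t * K + i] = b / cvec[t + 1];
        }
      }
      for (int t = 0; t < Tn; ++t) ll += std::log(cvec[t]);
      // accumulate expected counts
      for (int t = 0; t < Tn; ++t)
        for (int i = 0; i < K; ++i)
          Bnum[i * M + o[t]] += alpha[t * K + i] * beta[t * K + i];
      for (int t = 0; t < Tn - 1; ++t) {
        for (int i = 0; i < K; ++i) {
          double ai = alpha[t * K + i];
          if (ai <= 0) continue;
          for (int j = 0; j < K; ++j) {
            double x = ai * A[i * K + j] * B[j * M + o[t + 1]] *
              beta[(t + 1) * K + j] / cvec[t + 1];
            Anum[i * K + j] += x;
          }
        }
      }
    }
    // M-step
    for (int i = 0; i < K; ++i) {
      double rs = 0.0;
      for (int j = 0; j < K; ++j) rs += Anum[i * K + j];
      if (rs > 0) for (int j = 0; j < K; ++j) A[i * K + j] = Anum[i * K + j] / rs;
      double bs = 0.0;
      for (int m = 0; m < M; ++m) bs += Bnum[i * M + m];
      if (bs > 0) for (int m = 0; m < M; ++m) B[i * M + m] = Bnum[i * M + m] / bs;
    }
    ll_trace.push_back(ll);
    if (iter > 0 && std::fabs(ll - prev_ll) < tol * (1.0 + std::fabs(ll))) {
      converged = true;
      ++iter;
      break;
    }
    prev_ll = ll;
  }
  NumericMatrix Aout(K, K), Bout(K, M);
  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < K; ++j) Aout(i, j) = A[i * K + j];
    for (int m = 0; m < M; ++m) Bout(i, m) = B[i * M + m];
  }
  return List::create(_["A"] = Aout, _["B"] = Bout,
                      _["loglik"] = wrap(ll_trace),
                      _["n_iter"] = iter, _["converged"] = converged);
}

// Metropolis-Hastings sampler over reversible transition matrices given a
// count matrix C.  Parameterization: symmetric edge weights x_ij >= 0 with
// T_ij = x_ij / x_i, x_i = sum_j x_ij; posterior density
// prod_ij (x_ij / x_i)^{c_ij} with scale-invariant 1/x_ij prior on edges
// (the prior Jacobian cancels the log-normal proposal correction, so the
// acceptance ratio is the likelihood ratio alone).  Returns an array of
// sampled transition matrices (k x k x n_samples).  Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_sample_reversible(NumericMatrix C, int n_samples,
                                    int thin, int burnin, double step) {
  int k = C.nrow();
  std::vector<double> crow(k, 0.0);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) crow[i] += C(i, j);
  // edges with symmetric counts > 0 (upper triangle incl. diagonal)
  std::vector<int> ei, ej;
  std::vector<double> csym;
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      double cs = C(i, j) + (j > i ? C(j, i) : 0.0);
      if (cs > 0) { ei.push_back(i); ej.push_back(j); csym.push_back(cs); }
    }
  int ne = (int)ei.size();
  // init x at symmetrized counts, normalised
  std::vector<double> x(ne), xr(k, 0.0);
  double tot = 0.0;
  for (int e = 0; e < ne; ++e) { x[e] = csym[e]; tot += csym[e]; }
  for (int e = 0; e < ne; ++e) {
    x[e] /= tot;
    xr[ei[e]] += x[e];
    if (ej[e] != ei[e]) xr[ej[e]] += x[e];
  }
  NumericVector out(Dimension(k, k, n_samples));
  int kept = 0;
  long sweeps = 0;
  while (kept < n_samples) {
    // one sweep: propose a log-normal multiplicative update of every edge
    for (int e = 0; e < ne; ++e) {
      double xo = x[e];
      double xn = xo * std::exp(step * norm_rand());
      int i = ei[e], j = ej[e];
      double xri_n = xr[i] - xo + xn;
      double dlog = csym[e] * (std::log(xn) - std::log(xo))
        - crow[i] * (std::log(xri_n) - std::log(xr[i]));
      double xrj_n = xr[j];
      if (j != i) {
        xrj_n = xr[j] - xo + xn;
        dlog -= crow[j] * (std::log(xrj_n) - std::log(xr[j]));
      }
      if (dlog >= 0.0 || unif_rand() < std::exp(dlog)) {
        x[e] = xn;
        xr[i] = xri_n;
        if (j != i) xr[j] = xrj_n;
      }
    }
    ++sweeps;
    if (sweeps > burnin && ((sweeps - burnin) % thin == 0)) {
      // emit T from current x
      double* slab = &out[(R_xlen_t)kept * k * k];
      for (int e = 0; e < ne; ++e) {
        int i = ei[e], j = ej[e];
        slab[i + k * j] = 0.0;
        slab[j + k * i] = 0.0;
      }
      for (int e = 0; e < ne; ++e) {
        int i = ei[e], j = ej[e];
        slab[i + k * j] += x[e] / xr[i];
        if (j != i) slab[j + k * i] += x[e] / xr[j];
      }
      ++kept;
    }
  }
  return out;
}

// ---------------- 3-D Delaunay triangulation (Bowyer-Watson) -------------

struct Tet {
  int v[4];
  double cx, cy, cz, r2; // circumsphere
  bool alive;
};

static bool circumsphere(const std::vector<double>& px,
                         const std::vector<double>& py,
                         const std::vector<double>& pz,
                         int a, int b, int c, int d,
                         double& cx, double& cy, double& cz, double& r2) {
  // solve 2 (p_i - p_a) . x = |p_i|^2 - |p_a|^2, i in {b,c,d}
  double ax = px[a], ay = py[a], az = pz[a];
  double m[3][3], rhs[3];
  int vv[3] = {b, c, d};
  for (int r = 0; r < 3; ++r) {
    int i = vv[r];
    m[r][0] = 2.0 * (px[i] - ax);
    m[r][1] = 2.0 * (py[i] - ay);
    m[r][2] = 2.0 * (pz[i] - az);
    rhs[r] = (px[i] * px[i] + py[i] * py[i] + pz[i] * pz[i]) -
             (ax * ax + ay * ay + az * az);
  }
  double det =
    m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
    m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
    m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::fabs(det) < 1e-14) return false;
  double inv[3][3];
  inv[0][0] = (m[1][1] * m[2][2] - m[1][2] * m[2][1]) / det;
  inv[0][1] = (m[0][2] * m[2][1] - m[0][1] * m[2][2]) / det;
  inv[0][2] = (m[0][1] * m[1][2] - m[0][2] * m[1][1]) / det;
  inv[1][0] = (m[1][2] * m[2][0] - m[1][0] * m[2][2]) / det;
  inv[1][1] = (m[0][0] * m[2][2] - m[0][2] * m[2][0]) / det;
  inv[1][2] = (m[0][2] * m[1][0] - m[0][0] * m[1][2]) / det;
  inv[2][0] = (m[1][0] * m[2][1] - m[1][1] * m[2][0]) / det;
  inv[2][1] = (m[0][1] * m[2][0] - m[0][0] * m[2][1]) / det;
  inv[2][2] = (m[0][0] * m[1][1] - m[0][1] * m[1][0]) / det;
  cx = inv[0][0] * rhs[0] + inv[0][1] * rhs[1] + inv[0][2] * rhs[2];
  cy = inv[1][0] * rhs[0] + inv[1][1] * rhs[1] + inv[1][2] * rhs[2];
  cz = inv[2][0] * rhs[0] + inv[2][1] * rhs[1] + inv[2][2] * rhs[2];
  double dx = cx - ax, dy = cy - ay, dz = cz - az;
  r2 = dx * dx + dy * dy + dz * dz;
  return true;
}

// Delaunay tetrahedralization of pts (n x 3).  Returns an n_tet x 4 matrix
// of 1-based point indices.  Incremental Bowyer-Watson with a super-
// tetrahedron; points are expected to be jittered out of exact degeneracy
// by the caller.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay3d(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<double> px(n + 4), py(n + 4), pz(n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    double v[3] = {px[i], py[i], pz[i]};
    for (int c = 0; c < 3; ++c) {
      if (v[c] < lo[c]) lo[c] = v[c];
      if (v[c] > hi[c]) hi[c] = v[c];
    }
  }
  double cx = (lo[0] + hi[0]) / 2, cy = (lo[1] + hi[1]) / 2, cz = (lo[2] + hi[2]) / 2;
  double span = std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
  if (span <= 0) span = 1.0;
  double L = 100.0 * span;
  // super-tetrahedron vertices at indices n..n+3
  px[n] = cx - L;       py[n] = cy - L;       pz[n] = cz - L;
  px[n + 1] = cx + 3*L; py[n + 1] = cy - L;   pz[n + 1] = cz - L;
  px[n + 2] = cx;       py[n + 2] = cy + 3*L; pz[n + 2] = cz - L;
  px[n + 3] = cx;       py[n + 3] = cy;       pz[n + 3] = cz + 3*L;
  std::vector<Tet> tets;
  {
    Tet t; t.v[0] = n; t.v[1] = n + 1; t.v[2] = n + 2; t.v[3] = n + 3;
    t.alive = circumsphere(px, py, pz, t.v[0], t.v[1], t.v[2], t.v[3],
                           t.cx, t.cy, t.cz, t.r2);
    if (!t.alive) stop("degenerate super-tetrahedron");
    tets.push_back(t);
  }
  double eps2 = 1e-12 * span * span;
  std::vector<int> bad;
  typedef std::map<std::vector<int>, int> FaceMap;
  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      double dx = px[p] - tets[t].cx, dy = py[p] - tets[t].cy,
             dz = pz[p] - tets[t].cz;
      if (dx * dx + dy * dy + dz * dz < tets[t].r2 - eps2)
        bad.push_back((int)t);
    }
    if (bad.empty()) {
      // numerically marginal: fall back to the tet whose circumsphere the
      // point is closest to entering
      double best = R_PosInf; int bt = -1;
      for (size_t t = 0; t < tets.size(); ++t) {
        if (!tets[t].alive) continue;
        double dx = px[p] - tets[t].cx, dy = py[p] - tets[t].cy,
               dz = pz[p] - tets[t].cz;
        double excess = dx * dx + dy * dy + dz * dz - tets[t].r2;
        if (excess < best) { best = excess; bt = (int)t; }
      }
      if (bt < 0) stop("triangulation failure");
      bad.push_back(bt);
    }
    FaceMap faces;
    for (size_t b = 0; b < bad.size(); ++b) {
      Tet& t = tets[bad[b]];
      t.alive = false;
      static const int fidx[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
      for (int f = 0; f < 4; ++f) {
        std::vector<int> key(3);
        key[0] = t.v[fidx[f][0]]; key[1] = t.v[fidx[f][1]]; key[2] = t.v[fidx[f][2]];
        std::sort(key.begin(), key.end());
        faces[key] += 1;
      }
    }
    for (FaceMap::iterator it = faces.begin(); it != faces.end(); ++it) {
      if (it->second != 1) continue; // interior face of the cavity
      Tet t;
      t.v[0] = it->first[0]; t.v[1] = it->first[1]; t.v[2] = it->first[2];
      t.v[3] = p;
      t.alive = circumsphere(px, py, pz, t.v[0], t.v[1], t.v[2], t.v[3],
                             t.cx, t.cy, t.cz, t.r2);
      if (t.alive) tets.push_back(t);
    }
  }
  // collect tets not touching the super-tetrahedron
  std::vector<int> keep;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool ok = true;
    for (int c = 0; c < 4; ++c) if (tets[t].v[c] >= n) { ok = false; break; }
    if (ok) keep.push_back((int)t);
  }
  IntegerMatrix out((int)keep.size(), 4);
  for (size_t r = 0; r < keep.size(); ++r)
    for (int c = 0; c < 4; ++c)
      out((int)r, c) = tets[keep[r]].v[c] + 1;
  return out;
}

// Count apolar-apolar overlaps: for each apolar sphere, the number of other
// apolar spheres whose centre distance is below the sum of radii.
// [[Rcpp::export]]
IntegerVector cpp_overlap_counts(NumericMatrix centers, NumericVector radii,
                                 LogicalVector apolar) {
  int n = centers.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!apolar[i]) continue;
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i || !apolar[j]) continue;
      double dx = centers(i,0) - centers(j,0);
      double dy = centers(i,1) - centers(j,1);
      double dz = centers(i,2) - centers(j,2);
      double rs = radii[i] + radii[j];
      if (dx*dx + dy*dy + dz*dz < rs*rs) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}
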