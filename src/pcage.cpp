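// Hot numerical kernels: the face-deformation quality functional, the
// Metropolis node optimizer, and the Moller triangle-triangle test.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

struct Topo {
  int N, P, NN, M;
  std::vector<int> faces;   // N*P node ids (0-based), row-major by face
  std::vector<int> shared;  // M*4: f1, s1, f2, s2 (0-based)
};

static Topo make_topo(const IntegerMatrix& faces, const IntegerMatrix& shared, int NN) {
  Topo t;
  t.N = faces.nrow(); t.P = faces.ncol(); t.NN = NN; t.M = shared.nrow();
  t.faces.resize((size_t)t.N * t.P);
  for (int f = 0; f < t.N; ++f)
    for (int i = 0; i < t.P; ++i) t.faces[(size_t)f * t.P + i] = faces(f, i) - 1;
  t.shared.resize((size_t)t.M * 4);
  for (int m = 0; m < t.M; ++m)
    for (int k = 0; k < 4; ++k) t.shared[(size_t)m * 4 + k] = shared(m, k) - 1;
  return t;
}

// Full quality breakdown; out must have room for 8 doubles:
// qlen, qang, qplan, qcf, qcp, total, delta_l, delta_a
static void quality(const Topo& t, const double* X, const double* w,
                    int variant, double* out) {
  const int N = t.N, P = t.P, NN = t.NN;
  const double cl = w[0], ca = w[1], cp = w[2], ccf = w[3], ccp = w[4], Lf = w[5];
  const double a0 = M_PI * (1.0 - 2.0 / P);
  double O[3] = {0, 0, 0};
  for (int n = 0; n < NN; ++n)
    for (int k = 0; k < 3; ++k) O[k] += X[3 * n + k];
  for (int k = 0; k < 3; ++k) O[k] /= NN;

  double qlen = 0, qang = 0, qplan = 0;
  double qcf = 0, qcp = 0, dl = 0, da = 0;
  std::vector<double> Cf((size_t)N * 3), Wn((size_t)N * 3);

  std::vector<double> s((size_t)P * 3), wv((size_t)P * 3), len(P);
  for (int f = 0; f < N; ++f) {
    const int* fn = &t.faces[(size_t)f * P];
    double C[3] = {0, 0, 0};
    for (int i = 0; i < P; ++i)
      for (int k = 0; k < 3; ++k) C[k] += X[3 * fn[i] + k];
    for (int k = 0; k < 3; ++k) C[k] /= P;
    for (int k = 0; k < 3; ++k) Cf[(size_t)f * 3 + k] = C[k];
    for (int i = 0; i < P; ++i) {
      int j = (i + 1) % P;
      for (int k = 0; k < 3; ++k)
        s[(size_t)i * 3 + k] = X[3 * fn[j] + k] - X[3 * fn[i] + k];
      len[i] = norm3(&s[(size_t)i * 3]);
      double d = len[i] - Lf;
      qlen += (d / Lf) * (d / Lf);
      if (std::fabs(d) > dl) dl = std::fabs(d);
    }
    // corner angles from consecutive edge pairs
    for (int i = 0; i < P; ++i) {
      int j = (i + 1) % P;
      double c = -dot3(&s[(size_t)i * 3], &s[(size_t)j * 3]) / (len[i] * len[j]);
      if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
      double alpha = std::acos(c);
      qang += (alpha - a0) * (alpha - a0);
      double rel = std::fabs(alpha - a0) / a0;
      if (rel > da) da = rel;
    }
    // facelets and area vector
    double W[3] = {0, 0, 0};
    for (int i = 0; i < P; ++i) {
      int j = (i + 1) % P;
      double nu1[3], nu2[3];
      for (int k = 0; k < 3; ++k) {
        nu1[k] = X[3 * fn[i] + k] - C[k];
        nu2[k] = X[3 * fn[j] + k] - C[k];
      }
      double* wf = &wv[(size_t)i * 3];
      cross3(nu1, nu2, wf);
      for (int k = 0; k < 3; ++k) { wf[k] *= 0.5; W[k] += wf[k]; }
    }
    double Wn0 = norm3(W);
    double Wh[3] = {0, 0, 0};
    if (Wn0 > 0) for (int k = 0; k < 3; ++k) Wh[k] = W[k] / Wn0;
    for (int k = 0; k < 3; ++k) Wn[(size_t)f * 3 + k] = Wh[k];
    for (int i = 0; i < P; ++i) {
      const double* wf = &wv[(size_t)i * 3];
      double proj = dot3(wf, Wh);
      qplan += dot3(wf, wf) - proj * proj;
    }
    // face convexity: consecutive edges must turn consistently outward
    double Ff[3];
    for (int k = 0; k < 3; ++k) Ff[k] = C[k] - O[k];
    for (int i = 0; i < P; ++i) {
      int j = (i + 1) % P;
      double cr[3];
      cross3(&s[(size_t)i * 3], &s[(size_t)j * 3], cr);
      if (dot3(cr, Ff) < -1e-12) qcf += 1.0;
    }
  }
  // cage convexity over shared edges
  for (int m = 0; m < t.M; ++m) {
    int f1 = t.shared[(size_t)m * 4 + 0], s1 = t.shared[(size_t)m * 4 + 1];
    int f2 = t.shared[(size_t)m * 4 + 2], s2 = t.shared[(size_t)m * 4 + 3];
    if (variant == 1) {
      const int* fn1 = &t.faces[(size_t)f1 * P];
      const int* fn2 = &t.faces[(size_t)f2 * P];
      int a1 = fn1[s1], b1 = fn1[(s1 + 1) % P];
      int a2 = fn2[s2], b2 = fn2[(s2 + 1) % P];
      double M1[3], d1[3], d2[3];
      for (int k = 0; k < 3; ++k) {
        M1[k] = 0.5 * (X[3 * a1 + k] + X[3 * b1 + k]);
        double M2 = 0.5 * (X[3 * a2 + k] + X[3 * b2 + k]);
        d1[k] = M1[k] - Cf[(size_t)f1 * 3 + k];
        d2[k] = M2 - Cf[(size_t)f2 * 3 + k];
      }
      double n1 = norm3(d1), n2 = norm3(d2);
      double u[3], r[3];
      for (int k = 0; k < 3; ++k) {
        u[k] = d1[k] / n1 + d2[k] / n2;
        r[k] = M1[k] - O[k];
      }
      if (dot3(u, r) < -1e-12) qcp += 1.0;
    } else {
      double base = 0, tip = 0;
      for (int k = 0; k < 3; ++k) {
        double db = Cf[(size_t)f1 * 3 + k] - Cf[(size_t)f2 * 3 + k];
        double dt = db + Wn[(size_t)f1 * 3 + k] - Wn[(size_t)f2 * 3 + k];
        base += db * db; tip += dt * dt;
      }
      if (std::sqrt(base) - std::sqrt(tip) > 1e-12) qcp += 1.0;
    }
  }
  out[0] = qlen; out[1] = qang; out[2] = qplan; out[3] = qcf; out[4] = qcp;
  out[5] = cl * qlen + ca * qang + cp * qplan + ccf * qcf + ccp * qcp;
  out[6] = dl; out[7] = da;
}

// [[Rcpp::export]]
NumericVector pc_quality_cpp(NumericMatrix coords, IntegerMatrix faces,
                             IntegerMatrix shared, NumericVector weights,
                             int variant) {
  Topo t = make_topo(faces, shared, coords.nrow());
  std::vector<double> X((size_t)t.NN * 3);
  for (int n = 0; n < t.NN; ++n)
    for (int k = 0; k < 3; ++k) X[3 * n + k] = coords(n, k);
  double out[8];
  quality(t, X.data(), REAL(weights), variant, out);
  NumericVector res(8);
  for (int k = 0; k < 8; ++k) res[k] = out[k];
  res.names() = CharacterVector::create("q_length", "q_angle", "q_planar",
                                        "q_conv_face", "q_conv_cage", "total",
                                        "delta_l", "delta_a");
  return res;
}

// Metropolis optimization of the node positions.  Geometric cooling from
// temp0 by factor cool per sweep; per-node Gaussian proposals whose step
// adapts towards target acceptance; at temperatures below temp_floor only
// improving moves are accepted (zero-temperature refinement).  Uses the R
// RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List pc_metropolis_cpp(NumericMatrix coords, IntegerMatrix faces,
                       IntegerMatrix shared, NumericVector weights,
                       int variant, int sweeps, double temp0, double cool,
                       double step0, double target_acc, double step_min,
                       double temp_floor) {
  Topo t = make_topo(faces, shared, coords.nrow());
  const int NN = t.NN;
  std::vector<double> X((size_t)NN * 3), best;
  for (int n = 0; n < NN; ++n)
    for (int k = 0; k < 3; ++k) X[3 * n + k] = coords(n, k);
  double out[8];
  quality(t, X.data(), REAL(weights), variant, out);
  double q = out[5], bestq = q;
  best = X;
  double T = temp0, step = step0;
  RNGScope scope;
  for (int sw = 0; sw < sweeps; ++sw) {
    int acc = 0;
    for (int n = 0; n < NN; ++n) {
      double old[3];
      for (int k = 0; k < 3; ++k) {
        old[k] = X[3 * n + k];
        X[3 * n + k] = old[k] + step * norm_rand();
      }
      quality(t, X.data(), REAL(weights), variant, out);
      double qn = out[5];
      bool ok = qn <= q;
      if (!ok && T > temp_floor) ok = unif_rand() < std::exp(-(qn - q) / T);
      if (ok) {
        q = qn; ++acc;
        if (q < bestq) { bestq = q; best = X; }
      } else {
        for (int k = 0; k < 3; ++k) X[3 * n + k] = old[k];
      }
    }
    double rate = (double)acc / NN;
    step *= (rate > target_acc) ? 1.15 : 0.85;
    if (step < step_min) step = step_min;
    if (step > 1.0) step = 1.0;
    T *= cool;
  }
  NumericMatrix res(NN, 3);
  for (int n = 0; n < NN; ++n)
    for (int k = 0; k < 3; ++k) res(n, k) = best[3 * n + k];
  quality(t, best.data(), REAL(weights), variant, out);
  return List::create(_["coords"] = res, _["total"] = out[5],
                      _["delta_l"] = out[6], _["delta_a"] = out[7],
                      _["step"] = step);
}

// Deterministic coordinate pattern search: cyclically probe +/- step moves of
// every node coordinate, halving the step whenever a full pass brings no
// improvement.  Converges deeply (used to polish after the Metropolis stage).
// [[Rcpp::export]]
List pc_pattern_cpp(NumericMatrix coords, IntegerMatrix faces,
                    IntegerMatrix shared, NumericVector weights, int variant,
                    double step0, double step_min, int max_passes) {
  Topo t = make_topo(faces, shared, coords.nrow());
  const int NN = t.NN;
  std::vector<double> X((size_t)NN * 3);
  for (int n = 0; n < NN; ++n)
    for (int k = 0; k < 3; ++k) X[3 * n + k] = coords(n, k);
  double out[8];
  quality(t, X.data(), REAL(weights), variant, out);
  double q = out[5];
  double step = step0;
  for (int pass = 0; pass < max_passes && step >= step_min; ++pass) {
    bool improved = false;
    for (int n = 0; n < NN; ++n) {
      for (int k = 0; k < 3; ++k) {
        double orig = X[3 * n + k];
        for (int dir = 0; dir < 2; ++dir) {
          X[3 * n + k] = orig + (dir ? -step : step);
          quality(t, X.data(), REAL(weights), variant, out);
          if (out[5] < q) { q = out[5]; orig = X[3 * n + k]; improved = true; break; }
          X[3 * n + k] = orig;
        }
      }
    }
    if (!improved) step *= 0.5;
  }
  NumericMatrix res(NN, 3);
  for (int n = 0; n < NN; ++n)
    for (int k = 0; k < 3; ++k) res(n, k) = X[3 * n + k];
  quality(t, X.data(), REAL(weights), variant, out);
  return List::create(_["coords"] = res, _["total"] = out[5],
                      _["delta_l"] = out[6], _["delta_a"] = out[7]);
}

// Gradient descent with Barzilai-Borwein steps on a central-difference
// gradient.  The Heaviside convexity counts are locally constant, so inside
// a convex basin the functional is smooth and this converges much deeper
// than stochastic search; a backtracking safeguard keeps it monotone enough.
// [[Rcpp::export]]
List pc_descend_cpp(NumericMatrix coords, IntegerMatrix faces,
                    IntegerMatrix shared, NumericVector weights, int variant,
                    int maxit, double h, double tol, double rel_tol) {
  Topo t = make_topo(faces, shared, coords.nrow());
  const int D = t.NN * 3;
  std::vector<double> X(D), G(D), Gprev(D), Xprev(D), best(D);
  for (int n = 0; n < t.NN; ++n)
    for (int k = 0; k < 3; ++k) X[3 * n + k] = coords(n, k);
  double out[8];
  const double* w = REAL(weights);
  quality(t, X.data(), w, variant, out);
  double q = out[5], bestq = q;
  best = X;
  auto grad = [&](std::vector<double>& x, std::vector<double>& g) {
    for (int i = 0; i < D; ++i) {
      double orig = x[i];
      x[i] = orig + h; quality(t, x.data(), w, variant, out); double qp = out[5];
      x[i] = orig - h; quality(t, x.data(), w, variant, out); double qm = out[5];
      x[i] = orig;
      g[i] = (qp - qm) / (2 * h);
    }
  };
  grad(X, G);
  double alpha = 1e-3;
  double q_window = q;
  for (int it = 0; it < maxit; ++it) {
    if (it % 10 == 9) {
      if (q_window - q < 1e-14 + rel_tol * std::fabs(q)) break;
      q_window = q;
    }
    Xprev = X; Gprev = G;
    double qtrial;
    for (int bt = 0; ; ++bt) {
      for (int i = 0; i < D; ++i) X[i] = Xprev[i] - alpha * Gprev[i];
      quality(t, X.data(), w, variant, out);
      qtrial = out[5];
      if (qtrial <= q + 1e-12 || bt >= 30) break;
      alpha *= 0.5;
    }
    q = qtrial;
    if (q < bestq) { bestq = q; best = X; }
    grad(X, G);
    double sy = 0, ss = 0, gn = 0;
    for (int i = 0; i < D; ++i) {
      double s = X[i] - Xprev[i], y = G[i] - Gprev[i];
      sy += s * y; ss += s * s; gn += G[i] * G[i];
    }
    if (gn < tol * tol) break;
    if (sy > 1e-16) alpha = ss / sy; else alpha = 1e-3;
    if (alpha > 10.0) alpha = 10.0;
    if (alpha < 1e-12) alpha = 1e-12;
  }
  NumericMatrix res(t.NN, 3);
  for (int n = 0; n < t.NN; ++n)
    for (int k = 0; k < 3; ++k) res(n, k) = best[3 * n + k];
  quality(t, best.data(), w, variant, out);
  return List::create(_["coords"] = res, _["total"] = out[5],
                      _["delta_l"] = out[6], _["delta_a"] = out[7]);
}

// L-BFGS (two-loop recursion, memory 10) on a central-difference gradient
// with Armijo backtracking.  The quality functional is smooth inside a
// convex basin, where this reaches the local optimum to near machine
// precision at C++ evaluation cost.
// [[Rcpp::export]]
List pc_lbfgs_cpp(NumericMatrix coords, IntegerMatrix faces,
                  IntegerMatrix shared, NumericVector weights, int variant,
                  int maxit, double h, double rel_tol) {
  Topo t = make_topo(faces, shared, coords.nrow());
  const int D = t.NN * 3;
  const int M = 10;
  std::vector<double> X(D), G(D), Xn(D), Gn(D), dir(D), best(D);
  std::vector<std::vector<double>> Svec, Yvec;
  std::vector<double> rho;
  for (int n = 0; n < t.NN; ++n)
    for (int k = 0; k < 3; ++k) X[3 * n + k] = coords(n, k);
  double out[8];
  const double* w = REAL(weights);
  auto f = [&](std::vector<double>& x) {
    quality(t, x.data(), w, variant, out);
    return out[5];
  };
  auto grad = [&](std::vector<double>& x, std::vector<double>& g) {
    for (int i = 0; i < D; ++i) {
      double orig = x[i];
      x[i] = orig + h; double qp = f(x);
      x[i] = orig - h; double qm = f(x);
      x[i] = orig;
      g[i] = (qp - qm) / (2 * h);
    }
  };
  double q = f(X), bestq = q;
  best = X;
  grad(X, G);
  double q_window = q;
  for (int it = 0; it < maxit; ++it) {
    if (it % 10 == 9) {
      if (q_window - q < 1e-16 + rel_tol * std::fabs(q)) break;
      q_window = q;
    }
    // two-loop recursion
    dir = G;
    int mm = (int)Svec.size();
    std::vector<double> alpha_i(mm);
    for (int i = mm - 1; i >= 0; --i) {
      double a = 0;
      for (int k = 0; k < D; ++k) a += Svec[i][k] * dir[k];
      a *= rho[i];
      alpha_i[i] = a;
      for (int k = 0; k < D; ++k) dir[k] -= a * Yvec[i][k];
    }
    double gamma = 1e-3;
    if (mm > 0) {
      double sy = 0, yy = 0;
      for (int k = 0; k < D; ++k) {
        sy += Svec[mm - 1][k] * Yvec[mm - 1][k];
        yy += Yvec[mm - 1][k] * Yvec[mm - 1][k];
      }
      if (yy > 0) gamma = sy / yy;
    }
    for (int k = 0; k < D; ++k) dir[k] *= gamma;
    for (int i = 0; i < mm; ++i) {
      double b = 0;
      for (int k = 0; k < D; ++k) b += Yvec[i][k] * dir[k];
      b *= rho[i];
      for (int k = 0; k < D; ++k) dir[k] += Svec[i][k] * (alpha_i[i] - b);
    }
    // dir is an ascent-scaled gradient direction; step along -dir
    double gd = 0;
    for (int k = 0; k < D; ++k) gd += G[k] * dir[k];
    if (gd <= 0) {  // not a descent direction: fall back to -G
      dir = G;
      gd = 0;
      for (int k = 0; k < D; ++k) gd += G[k] * G[k];
      for (int k = 0; k < D; ++k) dir[k] *= 1e-3;
      gd *= 1e-3;
    }
    double step = 1.0, qn = q;
    bool ok = false;
    for (int bt = 0; bt < 40; ++bt) {
      for (int k = 0; k < D; ++k) Xn[k] = X[k] - step * dir[k];
      qn = f(Xn);
      if (qn <= q - 1e-4 * step * gd) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) break;
    grad(Xn, Gn);
    std::vector<double> s(D), y(D);
    double sy = 0;
    for (int k = 0; k < D; ++k) {
      s[k] = Xn[k] - X[k];
      y[k] = Gn[k] - G[k];
      sy += s[k] * y[k];
    }
    if (sy > 1e-14) {
      Svec.push_back(s); Yvec.push_back(y); rho.push_back(1.0 / sy);
      if ((int)Svec.size() > M) {
        Svec.erase(Svec.begin()); Yvec.erase(Yvec.begin()); rho.erase(rho.begin());
      }
    }
    X = Xn; G = Gn; q = qn;
    if (q < bestq) { bestq = q; best = X; }
  }
  NumericMatrix res(t.NN, 3);
  for (int n = 0; n < t.NN; ++n)
    for (int k = 0; k < 3; ++k) res(n, k) = best[3 * n + k];
  quality(t, best.data(), w, variant, out);
  return List::create(_["coords"] = res, _["total"] = out[5],
                      _["delta_l"] = out[6], _["delta_a"] = out[7]);
}

// ---- Moller triangle-triangle intersection --------------------------------

static const double EPS = 1e-9;

static bool edge_edge_2d(const double* a, const double* b,
                         const double* c, const double* d) {
  double r[2] = {b[0] - a[0], b[1] - a[1]};
  double s[2] = {d[0] - c[0], d[1] - c[1]};
  double denom = r[0] * s[1] - r[1] * s[0];
  double qp[2] = {c[0] - a[0], c[1] - a[1]};
  double qpxr = qp[0] * r[1] - qp[1] * r[0];
  if (std::fabs(denom) < EPS) {
    if (std::fabs(qpxr) > EPS) return false;  // parallel, non-collinear
    // collinear: project on r
    double rr = r[0] * r[0] + r[1] * r[1];
    if (rr < EPS * EPS) return false;
    double t0 = (qp[0] * r[0] + qp[1] * r[1]) / rr;
    double t1 = t0 + (s[0] * r[0] + s[1] * r[1]) / rr;
    if (t0 > t1) std::swap(t0, t1);
    return t1 >= -EPS && t0 <= 1 + EPS;
  }
  double u = qpxr / denom;
  double qpxs = qp[0] * s[1] - qp[1] * s[0];
  double tpar = qpxs / denom;
  return tpar >= -EPS && tpar <= 1 + EPS && u >= -EPS && u <= 1 + EPS;
}

static bool point_in_tri_2d(const double* p, const double* a,
                            const double* b, const double* c) {
  double d1 = (p[0] - b[0]) * (a[1] - b[1]) - (a[0] - b[0]) * (p[1] - b[1]);
  double d2 = (p[0] - c[0]) * (b[1] - c[1]) - (b[0] - c[0]) * (p[1] - c[1]);
  double d3 = (p[0] - a[0]) * (c[1] - a[1]) - (c[0] - a[0]) * (p[1] - a[1]);
  bool neg = (d1 < -EPS) || (d2 < -EPS) || (d3 < -EPS);
  bool pos = (d1 > EPS) || (d2 > EPS) || (d3 > EPS);
  return !(neg && pos);
}

static bool coplanar_tri_tri(const double* n, const double V[3][3],
                             const double U[3][3]) {
  // project to the dominant axis plane
  int i0, i1;
  double a[3] = {std::fabs(n[0]), std::fabs(n[1]), std::fabs(n[2])};
  if (a[0] > a[1] && a[0] > a[2]) { i0 = 1; i1 = 2; }
  else if (a[1] > a[2]) { i0 = 0; i1 = 2; }
  else { i0 = 0; i1 = 1; }
  double v[3][2], u[3][2];
  for (int i = 0; i < 3; ++i) {
    v[i][0] = V[i][i0]; v[i][1] = V[i][i1];
    u[i][0] = U[i][i0]; u[i][1] = U[i][i1];
  }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (edge_edge_2d(v[i], v[(i + 1) % 3], u[j], u[(j + 1) % 3])) return true;
  if (point_in_tri_2d(v[0], u[0], u[1], u[2])) return true;
  if (point_in_tri_2d(u[0], v[0], v[1], v[2])) return true;
  return false;
}

static bool compute_intervals(double p0, double p1, double p2,
                              double d0, double d1, double d2,
                              double* t1, double* t2) {
  // projections p, signed distances d; the triangle crosses the plane
  if (d0 * d1 > 0) {
    // d2 on the other side
    *t1 = p2 + (p0 - p2) * d2 / (d2 - d0);
    *t2 = p2 + (p1 - p2) * d2 / (d2 - d1);
  } else if (d0 * d2 > 0) {
    *t1 = p1 + (p0 - p1) * d1 / (d1 - d0);
    *t2 = p1 + (p2 - p1) * d1 / (d1 - d2);
  } else if (d1 * d2 > 0 || d0 != 0) {
    *t1 = p0 + (p1 - p0) * d0 / (d0 - d1);
    *t2 = p0 + (p2 - p0) * d0 / (d0 - d2);
  } else if (d1 != 0) {
    *t1 = p1 + (p0 - p1) * d1 / (d1 - d0);
    *t2 = p1 + (p2 - p1) * d1 / (d1 - d2);
  } else if (d2 != 0) {
    *t1 = p2 + (p0 - p2) * d2 / (d2 - d0);
    *t2 = p2 + (p1 - p2) * d2 / (d2 - d1);
  } else {
    return false;  // coplanar
  }
  return true;
}

static bool tri_tri(const double V[3][3], const double U[3][3]) {
  double e1[3], e2[3], n1[3], n2[3];
  for (int k = 0; k < 3; ++k) { e1[k] = V[1][k] - V[0][k]; e2[k] = V[2][k] - V[0][k]; }
  cross3(e1, e2, n1);
  double d1c = -dot3(n1, V[0]);
  double du[3];
  for (int i = 0; i < 3; ++i) {
    du[i] = dot3(n1, U[i]) + d1c;
    if (std::fabs(du[i]) < EPS) du[i] = 0;
  }
  if (du[0] * du[1] > 0 && du[0] * du[2] > 0) return false;
  for (int k = 0; k < 3; ++k) { e1[k] = U[1][k] - U[0][k]; e2[k] = U[2][k] - U[0][k]; }
  cross3(e1, e2, n2);
  double d2c = -dot3(n2, U[0]);
  double dv[3];
  for (int i = 0; i < 3; ++i) {
    dv[i] = dot3(n2, V[i]) + d2c;
    if (std::fabs(dv[i]) < EPS) dv[i] = 0;
  }
  if (dv[0] * dv[1] > 0 && dv[0] * dv[2] > 0) return false;
  if (du[0] == 0 && du[1] == 0 && du[2] == 0)
    return coplanar_tri_tri(n1, V, U);
  // direction of the intersection line
  double D[3];
  cross3(n1, n2, D);
  double a[3] = {std::fabs(D[0]), std::fabs(D[1]), std::fabs(D[2])};
  int axis = (a[0] >= a[1] && a[0] >= a[2]) ? 0 : (a[1] >= a[2] ? 1 : 2);
  double vp[3] = {V[0][axis], V[1][axis], V[2][axis]};
  double up[3] = {U[0][axis], U[1][axis], U[2][axis]};
  double s1, s2, t1, t2;
  if (!compute_intervals(vp[0], vp[1], vp[2], dv[0], dv[1], dv[2], &s1, &s2))
    return coplanar_tri_tri(n1, V, U);
  if (!compute_intervals(up[0], up[1], up[2], du[0], du[1], du[2], &t1, &t2))
    return coplanar_tri_tri(n1, V, U);
  if (s1 > s2) std::swap(s1, s2);
  if (t1 > t2) std::swap(t1, t2);
  return !(s2 < t1 - EPS || t2 < s1 - EPS);
}

// [[Rcpp::export]]
bool pc_tri_tri_cpp(NumericMatrix t1, NumericMatrix t2) {
  double V[3][3], U[3][3];
  for (int i = 0; i < 3; ++i)
    for (int k = 0; k < 3; ++k) { V[i][k] = t1(i, k); U[i][k] = t2(i, k); }
  return tri_tri(V, U);
}

// Self-intersection over facelet triangles (face centre, node i, node i+1).
// Facelet pairs from the same face, or whose triangles share a cage node,
// are skipped (contact along shared edges and hole corners is structural).
// [[Rcpp::export]]
List pc_cage_intersections_cpp(NumericMatrix coords, IntegerMatrix faces) {
  int N = faces.nrow(), P = faces.ncol();
  int NF = N * P;
  std::vector<double> tri((size_t)NF * 9);
  std::vector<int> na(NF), nb(NF), fid(NF);
  std::vector<double> lo((size_t)NF * 3), hi((size_t)NF * 3);
  std::vector<double> C((size_t)N * 3, 0.0);
  for (int f = 0; f < N; ++f) {
    for (int i = 0; i < P; ++i) {
      int nd = faces(f, i) - 1;
      for (int k = 0; k < 3; ++k) C[(size_t)f * 3 + k] += coords(nd, k);
    }
    for (int k = 0; k < 3; ++k) C[(size_t)f * 3 + k] /= P;
  }
  int idx = 0;
  for (int f = 0; f < N; ++f) {
    for (int i = 0; i < P; ++i, ++idx) {
      int A = faces(f, i) - 1, B = faces(f, (i + 1) % P) - 1;
      na[idx] = A; nb[idx] = B; fid[idx] = f;
      for (int k = 0; k < 3; ++k) {
        double c0 = C[(size_t)f * 3 + k];
        double pa = coords(A, k), pb = coords(B, k);
        tri[(size_t)idx * 9 + k] = c0;
        tri[(size_t)idx * 9 + 3 + k] = pa;
        tri[(size_t)idx * 9 + 6 + k] = pb;
        lo[(size_t)idx * 3 + k] = std::min(c0, std::min(pa, pb));
        hi[(size_t)idx * 3 + k] = std::max(c0, std::max(pa, pb));
      }
    }
  }
  std::vector<int> pf, pg;
  for (int i = 0; i < NF; ++i) {
    for (int j = i + 1; j < NF; ++j) {
      if (fid[i] == fid[j]) continue;
      if (na[i] == na[j] || na[i] == nb[j] || nb[i] == na[j] || nb[i] == nb[j])
        continue;
      bool sep = false;
      for (int k = 0; k < 3; ++k)
        if (lo[(size_t)i * 3 + k] > hi[(size_t)j * 3 + k] + EPS ||
            lo[(size_t)j * 3 + k] > hi[(size_t)i * 3 + k] + EPS) { sep = true; break; }
      if (sep) continue;
      double V[3][3], U[3][3];
      for (int r = 0; r < 3; ++r)
        for (int k = 0; k < 3; ++k) {
          V[r][k] = tri[(size_t)i * 9 + 3 * r + k];
          U[r][k] = tri[(size_t)j * 9 + 3 * r + k];
        }
      if (tri_tri(V, U)) {
        pf.push_back(fid[i] + 1);
        pg.push_back(fid[j] + 1);
      }
    }
  }
  return List::create(_["intersects"] = (int)pf.size() > 0,
                      _["face1"] = wrap(pf), _["face2"] = wrap(pg));
}
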