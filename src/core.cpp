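// Explicit dynamic-relaxation core for the morphoelastic tet model.
// Nodal forces follow the traction recipe: for each tet the Cauchy stress is
// constant; the traction on each deformed face (area-weighted outward normal)
// is distributed equally to the three face vertices.  For linear tetrahedra
// this equals minus the gradient of the total elastic energy.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double det3(const double* F) {
  return F[0] * (F[4] * F[8] - F[7] * F[5])
       - F[3] * (F[1] * F[8] - F[7] * F[2])
       + F[6] * (F[1] * F[5] - F[4] * F[2]);
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Assemble nodal forces and total elastic energy at nodal positions x.
// Returns -1 on success, else the (0-based) index of the first tet with
// non-positive or non-finite J.
static int assemble_core(int M, const int* tets, const double* Binv,
                         const double* mu, const double* K, const double* volg,
                         const double* x, double* f, double* Etot) {
  double E = 0.0;
  for (int t = 0; t < M; ++t) {
    const int n0 = tets[4 * t], n1 = tets[4 * t + 1],
              n2 = tets[4 * t + 2], n3 = tets[4 * t + 3];
    const double* p0 = x + 3 * n0;
    const double* p1 = x + 3 * n1;
    const double* p2 = x + 3 * n2;
    const double* p3 = x + 3 * n3;
    // deformed shape matrix A = [p1-p0 p2-p0 p3-p0] (column-major)
    double A[9];
    for (int r = 0; r < 3; ++r) {
      A[r]     = p1[r] - p0[r];
      A[3 + r] = p2[r] - p0[r];
      A[6 + r] = p3[r] - p0[r];
    }
    const double* B = Binv + 9 * t;  // (G * Ahat)^{-1}, column-major
    double F[9];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        F[3 * c + r] = A[r] * B[3 * c] + A[3 + r] * B[3 * c + 1] + A[6 + r] * B[3 * c + 2];
    const double J = det3(F);
    if (!(J > 0.0) || !std::isfinite(J)) return t;
    // left Cauchy-Green b = F F^T (symmetric)
    const double b00 = F[0] * F[0] + F[3] * F[3] + F[6] * F[6];
    const double b11 = F[1] * F[1] + F[4] * F[4] + F[7] * F[7];
    const double b22 = F[2] * F[2] + F[5] * F[5] + F[8] * F[8];
    const double b01 = F[0] * F[1] + F[3] * F[4] + F[6] * F[7];
    const double b02 = F[0] * F[2] + F[3] * F[5] + F[6] * F[8];
    const double b12 = F[1] * F[2] + F[4] * F[5] + F[7] * F[8];
    const double trb = b00 + b11 + b22;
    const double cbrtJ = std::cbrt(J);
    const double Jm23 = 1.0 / (cbrtJ * cbrtJ);
    E += (0.5 * mu[t] * (trb * Jm23 - 3.0) + 0.5 * K[t] * (J - 1.0) * (J - 1.0)) * volg[t];
    // sigma = mu J^{-5/3} dev(b) + K (J-1) I
    const double c1 = mu[t] * Jm23 / J;
    const double p = K[t] * (J - 1.0);
    const double s00 = c1 * (b00 - trb / 3.0) + p;
    const double s11 = c1 * (b11 - trb / 3.0) + p;
    const double s22 = c1 * (b22 - trb / 3.0) + p;
    const double s01 = c1 * b01, s02 = c1 * b02, s12 = c1 * b12;
    // outward area-weighted normals of the deformed faces (face i opposite
    // vertex i of a positively oriented tet)
    double e1[3], e2[3], e3[3], d12[3], d13[3];
    for (int r = 0; r < 3; ++r) {
      e1[r] = A[r]; e2[r] = A[3 + r]; e3[r] = A[6 + r];
      d12[r] = e2[r] - e1[r]; d13[r] = e3[r] - e1[r];
    }
    double nf[4][3], tmp[3];
    cross3(d12, d13, tmp); for (int r = 0; r < 3; ++r) nf[0][r] = 0.5 * tmp[r];
    cross3(e3, e2, tmp);   for (int r = 0; r < 3; ++r) nf[1][r] = 0.5 * tmp[r];
    cross3(e1, e3, tmp);   for (int r = 0; r < 3; ++r) nf[2][r] = 0.5 * tmp[r];
    cross3(e2, e1, tmp);   for (int r = 0; r < 3; ++r) nf[3][r] = 0.5 * tmp[r];
    // traction s_i = -sigma n_i, one third to each vertex of face i
    const int face[4][3] = {{n1, n2, n3}, {n0, n2, n3}, {n0, n1, n3}, {n0, n1, n2}};
    for (int i = 0; i < 4; ++i) {
      const double sx = -(s00 * nf[i][0] + s01 * nf[i][1] + s02 * nf[i][2]) / 3.0;
      const double sy = -(s01 * nf[i][0] + s11 * nf[i][1] + s12 * nf[i][2]) / 3.0;
      const double sz = -(s02 * nf[i][0] + s12 * nf[i][1] + s22 * nf[i][2]) / 3.0;
      for (int v = 0; v < 3; ++v) {
        double* fv = f + 3 * face[i][v];
        fv[0] += sx; fv[1] += sy; fv[2] += sz;
      }
    }
  }
  *Etot = E;
  return -1;
}

// codes: 0 free, 1 fixed, 2 move only along cdir, 3 zero component along cnorm
static inline void project_vec(int code, const double* cdir, const double* cnorm,
                               double* w) {
  if (code == 1) {
    w[0] = w[1] = w[2] = 0.0;
  } else if (code == 2) {
    const double d = w[0] * cdir[0] + w[1] * cdir[1] + w[2] * cdir[2];
    w[0] = d * cdir[0]; w[1] = d * cdir[1]; w[2] = d * cdir[2];
  } else if (code == 3) {
    const double d = w[0] * cnorm[0] + w[1] * cnorm[1] + w[2] * cnorm[2];
    w[0] -= d * cnorm[0]; w[1] -= d * cnorm[1]; w[2] -= d * cnorm[2];
  }
}

// [[Rcpp::export(name = ".forces_energy_cpp")]]
List forces_energy_cpp(NumericMatrix x, IntegerMatrix tets, NumericMatrix Binv,
                       NumericVector mu, NumericVector K, NumericVector volg) {
  const int N = x.nrow(), M = tets.nrow();
  std::vector<double> xv(3 * N), fv(3 * N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int r = 0; r < 3; ++r) xv[3 * i + r] = x(i, r);
  std::vector<int> tv(4 * M);
  for (int t = 0; t < M; ++t)
    for (int c = 0; c < 4; ++c) tv[4 * t + c] = tets(t, c) - 1;
  std::vector<double> Bv(9 * M);
  for (int t = 0; t < M; ++t)
    for (int c = 0; c < 9; ++c) Bv[9 * t + c] = Binv(t, c);
  double E = 0.0;
  int bad = assemble_core(M, tv.data(), Bv.data(), REAL(mu), REAL(K), REAL(volg),
                          xv.data(), fv.data(), &E);
  NumericMatrix f(N, 3);
  for (int i = 0; i < N; ++i)
    for (int r = 0; r < 3; ++r) f(i, r) = fv[3 * i + r];
  return List::create(_["forces"] = f, _["energy"] = E,
                      _["inverted_tet"] = bad < 0 ? R_NilValue : wrap(bad + 1));
}

// [[Rcpp::export(name = ".relax_cpp")]]
List relax_cpp(NumericMatrix x0, NumericMatrix v0, IntegerMatrix tets,
               NumericMatrix Binv, NumericVector mu, NumericVector K,
               NumericVector volg, IntegerVector code, NumericVector cdir,
               NumericVector cnorm, double dt, double mass, double gamma0,
               double gamma_floor, int window, double e_rel_tol,
               double disp_tol_abs, int max_iter, int check_every) {
  const int N = x0.nrow(), M = tets.nrow();
  std::vector<double> x(3 * N), v(3 * N), f(3 * N), xckpt(3 * N), vckpt(3 * N);
  for (int i = 0; i < N; ++i)
    for (int r = 0; r < 3; ++r) {
      x[3 * i + r] = x0(i, r);
      v[3 * i + r] = v0(i, r);
    }
  std::vector<int> tv(4 * M);
  for (int t = 0; t < M; ++t)
    for (int c = 0; c < 4; ++c) tv[4 * t + c] = tets(t, c) - 1;
  std::vector<double> Bv(9 * M);
  for (int t = 0; t < M; ++t)
    for (int c = 0; c < 9; ++c) Bv[9 * t + c] = Binv(t, c);
  const double cd[3] = {cdir[0], cdir[1], cdir[2]};
  const double cn[3] = {cnorm[0], cnorm[1], cnorm[2]};

  double gamma = gamma0, Etot = 0.0, maxdisp = R_PosInf;
  std::vector<double> hist_iter, hist_E, hist_disp;
  // ring buffer of energies sampled every check_every, spanning one window
  const int span = std::max(1, window / std::max(1, check_every));
  std::vector<double> ring;
  double E_prev_window = NA_REAL;
  bool converged = false;
  int it = 0, nhalve = 0;
  xckpt = x; vckpt = v;

  while (it < max_iter) {
    ++it;
    std::fill(f.begin(), f.end(), 0.0);
    int bad = assemble_core(M, tv.data(), Bv.data(), REAL(mu), REAL(K),
                            REAL(volg), x.data(), f.data(), &Etot);
    if (bad >= 0 || !std::isfinite(Etot)) {
      // inverted element or numerical blow-up: halve the step, restart from
      // the last good checkpoint with zero velocity
      x = xckpt;
      std::fill(v.begin(), v.end(), 0.0);
      dt *= 0.5;
      ring.clear();
      if (++nhalve > 30)
        stop("dynamic relaxation blew up at iteration %d (tet %d): step halving exhausted",
             it, bad + 1);
      continue;
    }
    maxdisp = 0.0;
    const double idt = dt / mass;
    for (int i = 0; i < N; ++i) {
      double* fi = f.data() + 3 * i;
      double* vi = v.data() + 3 * i;
      project_vec(code[i], cd, cn, fi);
      for (int r = 0; r < 3; ++r) vi[r] += (fi[r] - gamma * vi[r]) * idt;
      project_vec(code[i], cd, cn, vi);
      const double step = std::sqrt(vi[0] * vi[0] + vi[1] * vi[1] + vi[2] * vi[2]) * dt;
      if (step > maxdisp) maxdisp = step;
      double* xi = x.data() + 3 * i;
      for (int r = 0; r < 3; ++r) xi[r] += vi[r] * dt;
    }
    if (it % check_every == 0) {
      hist_iter.push_back(it);
      hist_E.push_back(Etot);
      hist_disp.push_back(maxdisp);
      ring.push_back(Etot);
      if ((int)ring.size() > span) ring.erase(ring.begin());
      // convergence is only accepted once the damping schedule has reached
      // its floor: while the system is overdamped a slowly growing unstable
      // mode can masquerade as a steady state
      if ((int)ring.size() == span && gamma <= gamma_floor * 1.000001) {
        const double Eref = ring.front();
        const double denom = std::max(std::fabs(Eref), 1e-300);
        const double rel = std::fabs(Etot - Eref) / denom;
        if ((rel < e_rel_tol || std::fabs(Etot) < 1e-300) && maxdisp < disp_tol_abs) {
          converged = true;
          break;
        }
      }
      if (it % window == 0) {
        // damping is reduced progressively: halved at the end of every
        // window in which the energy failed to drop by half, floored
        if (R_finite(E_prev_window)) {
          const double denom = std::max(std::fabs(E_prev_window), 1e-300);
          const double decrease = (E_prev_window - Etot) / denom;
          if (decrease < 0.5) gamma = std::max(gamma / 2.0, gamma_floor);
        } else {
          gamma = std::max(gamma / 2.0, gamma_floor);
        }
        E_prev_window = Etot;
        xckpt = x; vckpt = v;
      }
    }
  }

  NumericMatrix xout(N, 3), vout(N, 3);
  for (int i = 0; i < N; ++i)
    for (int r = 0; r < 3; ++r) {
      xout(i, r) = x[3 * i + r];
      vout(i, r) = v[3 * i + r];
    }
  return List::create(
      _["x"] = xout, _["v"] = vout, _["converged"] = converged,
      _["iterations"] = it, _["energy"] = Etot, _["max_step"] = maxdisp,
      _["dt_final"] = dt, _["gamma_final"] = gamma,
      _["history"] = DataFrame::create(_["iteration"] = hist_iter,
                                       _["energy"] = hist_E,
                                       _["max_step"] = hist_disp));
}

// Exact minimum distance from a point to a triangle (Ericson-style clamping).
static double point_tri_dist(const double* p, const double* a, const double* b,
                             const double* c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int r = 0; r < 3; ++r) {
    ab[r] = b[r] - a[r]; ac[r] = c[r] - a[r]; ap[r] = p[r] - a[r];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto dist_to = [&](double qx, double qy, double qz) {
    const double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  if (d1 <= 0.0 && d2 <= 0.0) return dist_to(a[0], a[1], a[2]);
  for (int r = 0; r < 3; ++r) bp[r] = p[r] - b[r];
  const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) return dist_to(b[0], b[1], b[2]);
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double t = d1 / (d1 - d3);
    return dist_to(a[0] + t * ab[0], a[1] + t * ab[1], a[2] + t * ab[2]);
  }
  for (int r = 0; r < 3; ++r) cp[r] = p[r] - c[r];
  const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) return dist_to(c[0], c[1], c[2]);
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double t = d2 / (d2 - d6);
    return dist_to(a[0] + t * ac[0], a[1] + t * ac[1], a[2] + t * ac[2]);
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist_to(b[0] + t * (c[0] - b[0]), b[1] + t * (c[1] - b[1]),
                   b[2] + t * (c[2] - b[2]));
  }
  const double denom = 1.0 / (va + vb + vc);
  const double sv = vb * denom, tv = vc * denom;
  return dist_to(a[0] + sv * ab[0] + tv * ac[0], a[1] + sv * ab[1] + tv * ac[1],
                 a[2] + sv * ab[2] + tv * ac[2]);
}

// [[Rcpp::export(name = ".point_tri_min_dist_cpp")]]
NumericVector point_tri_min_dist_cpp(NumericMatrix points, NumericMatrix verts,
                                     IntegerMatrix tris) {
  const int P = points.nrow(), S = tris.nrow();
  NumericVector out(P);
  std::vector<double> pv(3 * P), vv(3 * verts.nrow());
  for (int i = 0; i < P; ++i)
    for (int r = 0; r < 3; ++r) pv[3 * i + r] = points(i, r);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int r = 0; r < 3; ++r) vv[3 * i + r] = verts(i, r);
  for (int i = 0; i < P; ++i) {
    double best = R_PosInf;
    for (int s = 0; s < S; ++s) {
      const double d = point_tri_dist(pv.data() + 3 * i,
                                      vv.data() + 3 * (tris(s, 0) - 1),
                                      vv.data() + 3 * (tris(s, 1) - 1),
                                      vv.data() + 3 * (tris(s, 2) - 1));
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}
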