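#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Chaotic maps
//
// map ids: 1 logistic, 2 singer, 3 sinusoidal, 4 tent, 5 zaslavskii
// pars: logistic/sinusoidal alpha, singer mu, tent none, zaslavskii (v, r, a)
// ---------------------------------------------------------------------------

// floor-based modulo (avoids libm's versioned fmod)
static inline double mod_pos(double a, double m) {
  return a - std::floor(a / m) * m;
}

static inline void map_step(int map, double &x, double &y, const double *p) {
  switch (map) {
  case 1: x = p[0] * x * (1.0 - x); break;
  case 2: x = p[0] * (7.86 * x - 23.31 * x * x + 28.75 * x * x * x -
                      13.302875 * x * x * x * x); break;
  case 3: x = p[0] * x * x * std::sin(M_PI * x); break;
  case 4: x = (x < 0.7) ? x / 0.7 : (10.0 / 3.0) * (1.0 - x); break;
  case 5: {
    // auxiliary state first, then the wrapped coordinate
    double yn = std::cos(2.0 * M_PI * x) + std::exp(-p[1]) * y;
    double xn = mod_pos(x + p[0] + p[2] * yn, 1.0);
    if (xn >= 1.0) xn = 0.0;
    x = xn; y = yn;
  } break;
  default: stop("unknown map id");
  }
}

// Park-Miller minimal standard generator; state in [1, 2147483646].
// Streams carry their own state so re-seeding never touches R's RNG.
static inline double lcg_next(double &state) {
  state = mod_pos(16807.0 * state, 2147483647.0);
  return state / 2147483647.0;
}

static double admissible_start(int map, double &state) {
  double u;
  switch (map) {
  case 1:
    do { u = lcg_next(state); }
    while (u <= 1e-6 || u >= 1.0 - 1e-6 ||
           std::fabs(u - 0.25) < 1e-9 || std::fabs(u - 0.5) < 1e-9 ||
           std::fabs(u - 0.75) < 1e-9);
    return u;
  case 3:
    u = lcg_next(state);
    return 0.45 + 0.47 * u;
  default:
    do { u = lcg_next(state); } while (u <= 1e-6 || u >= 1.0 - 1e-6);
    return u;
  }
}

// A state is usable if the next next_unit() call can proceed: strictly inside
// (0,1) and not numerically on a fixed point / fixed cycle of the map.
static bool valid_state(int map, double x) {
  if (!(x > 1e-12 && x < 1.0 - 1e-12)) return false;
  if (map == 1) {
    if (std::fabs(x - 0.25) < 1e-12 || std::fabs(x - 0.5) < 1e-12 ||
        std::fabs(x - 0.75) < 1e-12) return false;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_admissible_start(int map, double lcg_state) {
  double x = admissible_start(map, lcg_state);
  return List::create(_["x"] = x, _["lcg_state"] = lcg_state);
}

// Raw trajectory of the dynamical system (no degeneracy handling).
// [[Rcpp::export]]
List cpp_chaos_trajectory(int map, int n, double x0, double y0,
                          NumericVector pars) {
  NumericVector xs(n), ys(map == 5 ? n : 0);
  double x = x0, y = y0, p[3] = {0, 0, 0};
  for (int i = 0; i < pars.size() && i < 3; ++i) p[i] = pars[i];
  for (int i = 0; i < n; ++i) {
    map_step(map, x, y, p);
    xs[i] = x;
    if (map == 5) ys[i] = y;
  }
  return List::create(_["x"] = xs, _["y"] = ys);
}

// Stream semantics: advance one step; if the new state is out of (0,1) or on
// a fixed point, transparently re-seed from the admissible start set (using
// the stream's own LCG) and step again.
// [[Rcpp::export]]
List cpp_chaos_sequence(int map, int n, double x, double y,
                        NumericVector pars, double lcg_state) {
  NumericVector out(n);
  double p[3] = {0, 0, 0};
  for (int i = 0; i < pars.size() && i < 3; ++i) p[i] = pars[i];
  for (int i = 0; i < n; ++i) {
    double xn = x, yn = y;
    int tries = 0;
    for (;;) {
      map_step(map, xn, yn, p);
      if (valid_state(map, xn)) break;
      if (++tries > 100) stop("chaotic stream stuck in a degenerate state");
      xn = admissible_start(map, lcg_state);
      if (map == 5) yn = 0.0;
    }
    x = xn; y = yn;
    out[i] = x;
  }
  return List::create(_["values"] = out, _["x"] = x, _["y"] = y,
                      _["lcg_state"] = lcg_state);
}

// ---------------------------------------------------------------------------
// Conformation -> Cartesian coordinates
// ---------------------------------------------------------------------------

static void quat_to_mat(const double q[4], double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z);
  R[0][1] = 2 * (x * y - w * z);
  R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z);
  R[1][1] = 1 - 2 * (x * x + z * z);
  R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y);
  R[2][1] = 2 * (y * z + w * x);
  R[2][2] = 1 - 2 * (x * x + y * y);
}

// coords: working matrix (n x 3, column-major via pointer triplets)
// Branches are applied in reverse file order (innermost first); a later
// (outer) rotation then moves the whole inner assembly rigidly, which
// composes correctly for nested BRANCH records.
static void apply_conf_impl(const NumericMatrix &ref,
                            const double *root_center,
                            const double *quat_raw,
                            const NumericVector &torsions,
                            const IntegerVector &br_parent,
                            const IntegerVector &br_child,
                            const std::vector<std::vector<int> > &moved,
                            const double *position,
                            NumericMatrix &out) {
  int n = ref.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = ref(i, j);

  int nb = br_parent.size();
  for (int b = nb - 1; b >= 0; --b) {
    double th = torsions[b];
    if (th == 0.0) continue;
    int ip = br_parent[b] - 1, ic = br_child[b] - 1;
    double a[3] = {out(ip, 0), out(ip, 1), out(ip, 2)};
    double u[3] = {out(ic, 0) - a[0], out(ic, 1) - a[1], out(ic, 2) - a[2]};
    double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    if (nu < 1e-12) continue;
    for (int k = 0; k < 3; ++k) u[k] /= nu;
    double ct = std::cos(th), st = std::sin(th);
    const std::vector<int> &mv = moved[b];
    for (size_t m = 0; m < mv.size(); ++m) {
      int ia = mv[m] - 1;
      double r[3] = {out(ia, 0) - a[0], out(ia, 1) - a[1], out(ia, 2) - a[2]};
      double ur = u[0] * r[0] + u[1] * r[1] + u[2] * r[2];
      double cx[3] = {u[1] * r[2] - u[2] * r[1],
                      u[2] * r[0] - u[0] * r[2],
                      u[0] * r[1] - u[1] * r[0]};
      for (int k = 0; k < 3; ++k)
        out(ia, k) = a[k] + ct * r[k] + st * cx[k] + (1 - ct) * ur * u[k];
    }
  }

  double q[4] = {quat_raw[0], quat_raw[1], quat_raw[2], quat_raw[3]};
  double nq = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  if (nq < 1e-12) { q[0] = 1; q[1] = q[2] = q[3] = 0; }
  else for (int k = 0; k < 4; ++k) q[k] /= nq;
  double R[3][3];
  quat_to_mat(q, R);
  for (int i = 0; i < n; ++i) {
    double v[3] = {out(i, 0) - root_center[0], out(i, 1) - root_center[1],
                   out(i, 2) - root_center[2]};
    for (int k = 0; k < 3; ++k)
      out(i, k) = R[k][0] * v[0] + R[k][1] * v[1] + R[k][2] * v[2] +
                  position[k];
  }
}

static std::vector<std::vector<int> > as_moved(const List &br_moved) {
  std::vector<std::vector<int> > moved(br_moved.size());
  for (int b = 0; b < br_moved.size(); ++b) {
    IntegerVector mv = br_moved[b];
    moved[b].assign(mv.begin(), mv.end());
  }
  return moved;
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_conformation(NumericMatrix ref,
                                     NumericVector root_center,
                                     NumericVector quat,
                                     NumericVector torsions,
                                     IntegerVector br_parent,
                                     IntegerVector br_child,
                                     List br_moved,
                                     NumericVector position) {
  NumericMatrix out(ref.nrow(), 3);
  std::vector<std::vector<int> > moved = as_moved(br_moved);
  apply_conf_impl(ref, REAL(root_center), REAL(quat), torsions,
                  br_parent, br_child, moved, REAL(position), out);
  return out;
}

// ---------------------------------------------------------------------------
// Vina-style empirical scoring
//
// weights: gauss1, gauss2, repulsion, hydrophobic, hbond
// d is the surface distance r - R_i - R_j.
// ---------------------------------------------------------------------------

static inline double pair_e(double d, bool hyd, bool hb, const double *w,
                            double *dE) {
  double e = 0.0, g = 0.0;
  double t1 = d / 0.5, e1 = std::exp(-t1 * t1);
  e += w[0] * e1; g += w[0] * e1 * (-2.0 * t1 / 0.5);
  double t2 = (d - 3.0) / 2.0, e2 = std::exp(-t2 * t2);
  e += w[1] * e2; g += w[1] * e2 * (-2.0 * t2 / 2.0);
  if (d < 0.0) { e += w[2] * d * d; g += w[2] * 2.0 * d; }
  if (hyd) {
    if (d < 0.5) e += w[3];
    else if (d < 1.5) { e += w[3] * (1.5 - d); g -= w[3]; }
  }
  if (hb) {
    if (d < -0.7) e += w[4];
    else if (d < 0.0) { e += w[4] * (-d / 0.7); g -= w[4] / 0.7; }
  }
  if (dE) *dE = g;
  return e;
}

struct CellList {
  double cell;
  std::unordered_map<long long, std::vector<int> > cells;
  static long long key(int ix, int iy, int iz) {
    return ((long long)(ix + 4096) * 8192 + (iy + 4096)) * 8192 + (iz + 4096);
  }
  void build(const NumericMatrix &xyz, const LogicalVector &use, double c) {
    cell = c;
    for (int i = 0; i < xyz.nrow(); ++i) {
      if (!use[i]) continue;
      int ix = (int)std::floor(xyz(i, 0) / cell);
      int iy = (int)std::floor(xyz(i, 1) / cell);
      int iz = (int)std::floor(xyz(i, 2) / cell);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
};

// Intermolecular + intramolecular energy; optional d(E)/d(ligand atom).
static void score_impl(const NumericMatrix &lig, const NumericVector &lrad,
                       const LogicalVector &lhyd, const LogicalVector &ldon,
                       const LogicalVector &lacc, const LogicalVector &lheavy,
                       const NumericMatrix &rec, const NumericVector &rrad,
                       const LogicalVector &rhyd, const LogicalVector &rdon,
                       const LogicalVector &racc, const LogicalVector &rheavy,
                       const IntegerMatrix &intra_pairs,
                       const double *w, double cutoff, bool use_cells,
                       bool want_grad, double &inter, double &intra,
                       NumericMatrix *grad) {
  inter = 0.0; intra = 0.0;
  int nl = lig.nrow(), nr = rec.nrow();
  double cut2 = cutoff * cutoff;

  CellList cl;
  if (use_cells) cl.build(rec, rheavy, cutoff);

  for (int i = 0; i < nl; ++i) {
    if (!lheavy[i]) continue;
    double xi = lig(i, 0), yi = lig(i, 1), zi = lig(i, 2);
    std::vector<int> const *bucket;
    std::vector<int> near;
    if (use_cells) {
      int cx = (int)std::floor(xi / cl.cell);
      int cy = (int)std::floor(yi / cl.cell);
      int cz = (int)std::floor(zi / cl.cell);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            std::unordered_map<long long, std::vector<int> >::const_iterator
              it = cl.cells.find(CellList::key(cx + dx, cy + dy, cz + dz));
            if (it != cl.cells.end())
              near.insert(near.end(), it->second.begin(), it->second.end());
          }
      bucket = &near;
    } else {
      near.reserve(nr);
      for (int j = 0; j < nr; ++j) if (rheavy[j]) near.push_back(j);
      bucket = &near;
    }
    for (size_t bj = 0; bj < bucket->size(); ++bj) {
      int j = (*bucket)[bj];
      double dx = xi - rec(j, 0), dy = yi - rec(j, 1), dz = zi - rec(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      double r = std::sqrt(r2);
      double d = r - lrad[i] - rrad[j];
      bool hyd = lhyd[i] && rhyd[j];
      bool hb = (ldon[i] && racc[j]) || (lacc[i] && rdon[j]);
      double dE;
      inter += pair_e(d, hyd, hb, w, want_grad ? &dE : 0);
      if (want_grad && r > 1e-12) {
        double s = dE / r;
        (*grad)(i, 0) += s * dx;
        (*grad)(i, 1) += s * dy;
        (*grad)(i, 2) += s * dz;
      }
    }
  }

  for (int p = 0; p < intra_pairs.nrow(); ++p) {
    int i = intra_pairs(p, 0) - 1, j = intra_pairs(p, 1) - 1;
    double dx = lig(i, 0) - lig(j, 0), dy = lig(i, 1) - lig(j, 1),
           dz = lig(i, 2) - lig(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut2) continue;
    double r = std::sqrt(r2);
    double d = r - lrad[i] - lrad[j];
    bool hyd = lhyd[i] && lhyd[j];
    bool hb = (ldon[i] && lacc[j]) || (lacc[i] && ldon[j]);
    double dE;
    intra += pair_e(d, hyd, hb, w, want_grad ? &dE : 0);
    if (want_grad && r > 1e-12) {
      double s = dE / r;
      (*grad)(i, 0) += s * dx; (*grad)(i, 1) += s * dy; (*grad)(i, 2) += s * dz;
      (*grad)(j, 0) -= s * dx; (*grad)(j, 1) -= s * dy; (*grad)(j, 2) -= s * dz;
    }
  }
}

// [[Rcpp::export]]
List cpp_score_system(NumericMatrix lig, NumericVector lrad,
                      LogicalVector lhyd, LogicalVector ldon,
                      LogicalVector lacc, LogicalVector lheavy,
                      NumericMatrix rec, NumericVector rrad,
                      LogicalVector rhyd, LogicalVector rdon,
                      LogicalVector racc, LogicalVector rheavy,
                      IntegerMatrix intra_pairs, NumericVector weights,
                      double cutoff, bool use_cells, bool want_grad) {
  double inter, intra;
  NumericMatrix grad(want_grad ? lig.nrow() : 0, 3);
  score_impl(lig, lrad, lhyd, ldon, lacc, lheavy,
             rec, rrad, rhyd, rdon, racc, rheavy,
             intra_pairs, REAL(weights), cutoff, use_cells, want_grad,
             inter, intra, want_grad ? &grad : 0);
  return List::create(_["inter"] = inter, _["intra"] = intra,
                      _["grad"] = want_grad ? (SEXP)grad : R_NilValue);
}

// ---------------------------------------------------------------------------
// Full docking objective over the search vector
// X = (position[3], quaternion[4], torsions[nt]); value = (inter+intra)/div.
// Gradient blocks: translation, quaternion (pullback of the rigid-rotation
// torque through the normalized quaternion), torsions (per-branch torque
// about the rotated bond axis).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_dock_eval(NumericVector X, NumericMatrix ref,
                   NumericVector root_center,
                   IntegerVector br_parent, IntegerVector br_child,
                   List br_moved,
                   NumericVector lrad, LogicalVector lhyd, LogicalVector ldon,
                   LogicalVector lacc, LogicalVector lheavy,
                   NumericMatrix rec, NumericVector rrad, LogicalVector rhyd,
                   LogicalVector rdon, LogicalVector racc,
                   LogicalVector rheavy,
                   IntegerMatrix intra_pairs, NumericVector weights,
                   double cutoff, double divisor, bool use_cells,
                   bool want_grad) {
  int nt = br_parent.size();
  int n = ref.nrow();
  if (X.size() != 7 + nt) stop("conformation vector has wrong dimension");
  double pos[3] = {X[0], X[1], X[2]};
  double qraw[4] = {X[3], X[4], X[5], X[6]};
  NumericVector tors(nt);
  for (int b = 0; b < nt; ++b) tors[b] = X[7 + b];

  NumericMatrix coords(n, 3);
  std::vector<std::vector<int> > moved = as_moved(br_moved);
  apply_conf_impl(ref, REAL(root_center), qraw, tors, br_parent, br_child,
                  moved, pos, coords);

  double inter, intra;
  NumericMatrix G(want_grad ? n : 0, 3);
  score_impl(coords, lrad, lhyd, ldon, lacc, lheavy,
             rec, rrad, rhyd, rdon, racc, rheavy,
             intra_pairs, REAL(weights), cutoff, use_cells, want_grad,
             inter, intra, want_grad ? &G : 0);
  double value = (inter + intra) / divisor;

  if (!want_grad)
    return List::create(_["value"] = value, _["inter"] = inter,
                        _["intra"] = intra, _["gradient"] = R_NilValue);

  NumericVector g(7 + nt);
  double tau[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) {
    g[0] += G(i, 0); g[1] += G(i, 1); g[2] += G(i, 2);
    double rx = coords(i, 0) - pos[0], ry = coords(i, 1) - pos[1],
           rz = coords(i, 2) - pos[2];
    tau[0] += ry * G(i, 2) - rz * G(i, 1);
    tau[1] += rz * G(i, 0) - rx * G(i, 2);
    tau[2] += rx * G(i, 1) - ry * G(i, 0);
  }

  // quaternion block: dE/dq_k = tau . 2 vec(e_k (x) u*) / |q_raw|
  double nq = std::sqrt(qraw[0] * qraw[0] + qraw[1] * qraw[1] +
                        qraw[2] * qraw[2] + qraw[3] * qraw[3]);
  double u[4];
  if (nq < 1e-12) { u[0] = 1; u[1] = u[2] = u[3] = 0; nq = 1.0; }
  else for (int k = 0; k < 4; ++k) u[k] = qraw[k] / nq;
  double uc[4] = {u[0], -u[1], -u[2], -u[3]};  // conjugate
  for (int k = 0; k < 4; ++k) {
    double e[4] = {0, 0, 0, 0};
    e[k] = 1.0;
    // vector part of e (x) uc
    double vx = e[0] * uc[1] + e[1] * uc[0] + e[2] * uc[3] - e[3] * uc[2];
    double vy = e[0] * uc[2] - e[1] * uc[3] + e[2] * uc[0] + e[3] * uc[1];
    double vz = e[0] * uc[3] + e[1] * uc[2] - e[2] * uc[1] + e[3] * uc[0];
    g[3 + k] = 2.0 * (tau[0] * vx + tau[1] * vy + tau[2] * vz) / nq;
  }

  for (int b = 0; b < nt; ++b) {
    int ip = br_parent[b] - 1, ic = br_child[b] - 1;
    double a[3] = {coords(ip, 0), coords(ip, 1), coords(ip, 2)};
    double ax[3] = {coords(ic, 0) - a[0], coords(ic, 1) - a[1],
                    coords(ic, 2) - a[2]};
    double na = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    if (na < 1e-12) { g[7 + b] = 0.0; continue; }
    for (int k = 0; k < 3; ++k) ax[k] /= na;
    double gt = 0.0;
    const std::vector<int> &mv = moved[b];
    for (size_t m = 0; m < mv.size(); ++m) {
      int i = mv[m] - 1;
      double rx = coords(i, 0) - a[0], ry = coords(i, 1) - a[1],
             rz = coords(i, 2) - a[2];
      // (u x r) . G_i
      gt += (ax[1] * rz - ax[2] * ry) * G(i, 0) +
            (ax[2] * rx - ax[0] * rz) * G(i, 1) +
            (ax[0] * ry - ax[1] * rx) * G(i, 2);
    }
    g[7 + b] = gt;
  }

  for (int k = 0; k < 7 + nt; ++k) g[k] /= divisor;
  return List::create(_["value"] = value, _["inter"] = inter,
                      _["intra"] = intra, _["gradient"] = g);
}
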