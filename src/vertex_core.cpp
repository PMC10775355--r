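// Core numerics for the periodic 2D vertex model: polygon geometry under
// minimum-image convention, the area/perimeter elastic energy and its
// analytic gradient, a FIRE minimizer with optional short-edge (T1)
// detection, and a winding union-find for wrapping percolation.
#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// Unwrap a cell cycle: coordinates relative to the first vertex, built by
// accumulating minimum-image displacements along the cycle.
struct CellScratch {
  std::vector<double> x, y;
};

static void unwrap_cell(const double* vx, const double* vy,
                        const int* verts, int m, double Lx, double Ly,
                        CellScratch& sc) {
  sc.x.resize(m);
  sc.y.resize(m);
  sc.x[0] = vx[verts[0]];
  sc.y[0] = vy[verts[0]];
  for (int k = 1; k < m; ++k) {
    sc.x[k] = sc.x[k - 1] + min_image(vx[verts[k]] - vx[verts[k - 1]], Lx);
    sc.y[k] = sc.y[k - 1] + min_image(vy[verts[k]] - vy[verts[k - 1]], Ly);
  }
}

static void cell_area_perim(const CellScratch& sc, double& A, double& P) {
  const int m = (int)sc.x.size();
  A = 0.0;
  P = 0.0;
  for (int k = 0; k < m; ++k) {
    int k1 = (k + 1) % m;
    A += sc.x[k] * sc.y[k1] - sc.x[k1] * sc.y[k];
    double ex = sc.x[k1] - sc.x[k], ey = sc.y[k1] - sc.y[k];
    P += std::sqrt(ex * ex + ey * ey);
  }
  A *= 0.5;
}

// [[Rcpp::export]]
List vm_geometry(NumericMatrix verts, IntegerVector cell_starts,
                 IntegerVector cell_verts, double Lx, double Ly) {
  const int F = cell_starts.size() - 1;
  NumericVector area(F), perim(F);
  const double* vx = &verts(0, 0);
  const double* vy = &verts(0, 1);
  CellScratch sc;
  for (int c = 0; c < F; ++c) {
    int s = cell_starts[c], m = cell_starts[c + 1] - s;
    unwrap_cell(vx, vy, &cell_verts[s], m, Lx, Ly, sc);
    double A, P;
    cell_area_perim(sc, A, P);
    area[c] = A;
    perim[c] = P;
  }
  return List::create(_["area"] = area, _["perimeter"] = perim);
}

static double energy_and_forces(const double* vx, const double* vy,
                                const int* cell_starts, const int* cell_verts,
                                int F, const double* p0, double a0,
                                double ka, double kp, double Lx, double Ly,
                                double* fx, double* fy, int nv,
                                CellScratch& sc) {
  double E = 0.0;
  if (fx) {
    std::fill(fx, fx + nv, 0.0);
    std::fill(fy, fy + nv, 0.0);
  }
  for (int c = 0; c < F; ++c) {
    int s = cell_starts[c], m = cell_starts[c + 1] - s;
    const int* vid = &cell_verts[s];
    unwrap_cell(vx, vy, vid, m, Lx, Ly, sc);
    double A, P;
    cell_area_perim(sc, A, P);
    double cA = ka * (A - a0);
    double cP = kp * (P - p0[c]);
    E += 0.5 * cA * (A - a0) + 0.5 * cP * (P - p0[c]);
    if (!fx) continue;
    for (int k = 0; k < m; ++k) {
      int km = (k + m - 1) % m, kp1 = (k + 1) % m;
      // area gradient: dA/dx_k = 0.5 (y_{k+1} - y_{k-1}); dA/dy_k = 0.5 (x_{k-1} - x_{k+1})
      double gax = 0.5 * (sc.y[kp1] - sc.y[km]);
      double gay = 0.5 * (sc.x[km] - sc.x[kp1]);
      // perimeter gradient: u_{k-1} - u_k with u_j the unit vector along edge j -> j+1
      double e1x = sc.x[k] - sc.x[km], e1y = sc.y[k] - sc.y[km];
      double e2x = sc.x[kp1] - sc.x[k], e2y = sc.y[kp1] - sc.y[k];
      double l1 = std::sqrt(e1x * e1x + e1y * e1y);
      double l2 = std::sqrt(e2x * e2x + e2y * e2y);
      double gpx = 0.0, gpy = 0.0;
      if (l1 > 0) { gpx += e1x / l1; gpy += e1y / l1; }
      if (l2 > 0) { gpx -= e2x / l2; gpy -= e2y / l2; }
      int v = vid[k];
      fx[v] -= cA * gax + cP * gpx;
      fy[v] -= cA * gay + cP * gpy;
    }
  }
  return E;
}

// [[Rcpp::export]]
double vm_energy(NumericMatrix verts, IntegerVector cell_starts,
                 IntegerVector cell_verts, NumericVector p0, double a0,
                 double ka, double kp, double Lx, double Ly) {
  CellScratch sc;
  return energy_and_forces(&verts(0, 0), &verts(0, 1), &cell_starts[0],
                           &cell_verts[0], cell_starts.size() - 1, &p0[0], a0,
                           ka, kp, Lx, Ly, nullptr, nullptr, verts.nrow(), sc);
}

// [[Rcpp::export]]
NumericMatrix vm_forces(NumericMatrix verts, IntegerVector cell_starts,
                        IntegerVector cell_verts, NumericVector p0, double a0,
                        double ka, double kp, double Lx, double Ly) {
  const int nv = verts.nrow();
  NumericMatrix f(nv, 2);
  CellScratch sc;
  energy_and_forces(&verts(0, 0), &verts(0, 1), &cell_starts[0], &cell_verts[0],
                    cell_starts.size() - 1, &p0[0], a0, ka, kp, Lx, Ly,
                    &f(0, 0), &f(0, 1), nv, sc);
  return f;
}

// Net-force residual over vertex clusters joined by near-zero edges: at a
// tension-pinned short edge (stable higher-order vertex / rosette) the
// energy minimum sits at zero edge length where the plain gradient does not
// vanish; force balance there means the *summed* force on the coincident
// vertices vanishes (KKT condition for the length >= 0 constraint).
static double cluster_residual(const std::vector<double>& fx,
                               const std::vector<double>& fy, int nv,
                               const double* px, const double* py,
                               IntegerMatrix& edges, double cusp_len,
                               double Lx, double Ly) {
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int v) {
    while (parent[v] != v) v = parent[v] = parent[parent[v]];
    return v;
  };
  const int ne = edges.nrow();
  for (int e = 0; e < ne; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    double dx = min_image(px[v] - px[u], Lx);
    double dy = min_image(py[v] - py[u], Ly);
    if (std::sqrt(dx * dx + dy * dy) < cusp_len) {
      int ru = find(u), rv = find(v);
      if (ru != rv) parent[ru] = rv;
    }
  }
  std::vector<double> sx(nv, 0.0), sy(nv, 0.0);
  for (int i = 0; i < nv; ++i) {
    int r = find(i);
    sx[r] += fx[i];
    sy[r] += fy[i];
  }
  double res = 0.0;
  for (int i = 0; i < nv; ++i) {
    if (find(i) != i) continue;
    double f2 = sx[i] * sx[i] + sy[i] * sy[i];
    if (f2 > res) res = f2;
  }
  return std::sqrt(res);
}

// FIRE minimizer (semi-implicit Euler with velocity mixing). Runs until the
// force residual drops below `tol` (per-vertex max force, or the clustered
// residual when tension-pinned near-zero edges are present), `maxit`
// iterations are spent, or (when `t1_len` > 0) a flippable edge shorter
// than `t1_len` is detected at one of the periodic checks, in which case
// the offending edges are returned for the caller to reconnect. Status: 0
// converged, 1 iteration budget exhausted, 2 short edges found.
// [[Rcpp::export]]
List vm_fire(NumericMatrix verts, IntegerVector cell_starts,
             IntegerVector cell_verts, NumericVector p0, double a0, double ka,
             double kp, double Lx, double Ly, double tol, int maxit,
             double dt0, double dt_max, double alpha0, double f_inc,
             double f_dec, double f_alpha, int n_min,
             IntegerMatrix edges, LogicalVector flippable, double t1_len,
             int check_every, double cusp_len, double t1_res_gate) {
  const int nv = verts.nrow();
  const int F = cell_starts.size() - 1;
  NumericMatrix pos = clone(verts);
  double* px = &pos(0, 0);
  double* py = &pos(0, 1);
  std::vector<double> fx(nv), fy(nv), vxv(nv, 0.0), vyv(nv, 0.0);
  std::vector<int> uf(nv), cnt(nv, 1), cusp_pairs;
  std::vector<double> mfx(nv), mfy(nv);
  std::vector<bool> frozen(edges.nrow(), false);
  CellScratch sc;
  double dt = dt0, alpha = alpha0;
  int npos = 0, it = 0, status = 1, n_uphill = 0;
  double E = 0.0, res = R_PosInf;
  const int ne = edges.nrow();
  std::vector<int> short_edges;
  const double dmax = 0.1 * std::sqrt(a0);  // displacement clip per step

  for (it = 0; it < maxit; ++it) {
    E = energy_and_forces(px, py, &cell_starts[0], &cell_verts[0], F, &p0[0],
                          a0, ka, kp, Lx, Ly, fx.data(), fy.data(), nv, sc);
    // rosette handling: vertices joined by near-zero (tension-pinned) edges
    // move as one unit -- every member of such a cluster gets the cluster
    // mean force, so the cusp cannot destabilize the integrator while the
    // rest of the tissue relaxes
    if (cusp_len > 0) {
      cusp_pairs.clear();
      for (int e = 0; e < ne; ++e) {
        int u = edges(e, 0), v = edges(e, 1);
        double dx = min_image(px[v] - px[u], Lx);
        double dy = min_image(py[v] - py[u], Ly);
        double len = std::sqrt(dx * dx + dy * dy);
        // hysteresis band: pin below cusp_len, release only after the
        // edge has clearly reopened (avoids flicker at the band edge
        // without pinning edges that escape)
        if (!frozen[e] && len < cusp_len) frozen[e] = true;
        else if (frozen[e] && len > 5 * cusp_len) frozen[e] = false;
        if (frozen[e]) {
          cusp_pairs.push_back(u);
          cusp_pairs.push_back(v);
        }
      }
      if (!cusp_pairs.empty()) {
        for (int i = 0; i < nv; ++i) uf[i] = i;
        auto uf_find = [&](int v) {
          while (uf[v] != v) v = uf[v] = uf[uf[v]];
          return v;
        };
        for (size_t k = 0; k < cusp_pairs.size(); k += 2) {
          int ru = uf_find(cusp_pairs[k]), rv = uf_find(cusp_pairs[k + 1]);
          if (ru != rv) uf[ru] = rv;
        }
        for (size_t k = 0; k < cusp_pairs.size(); ++k) {
          int v = cusp_pairs[k], r = uf_find(v);
          if (r != v && cnt[v] > 0) {
            fx[r] += fx[v];
            fy[r] += fy[v];
            cnt[r] += cnt[v];
            fx[v] = fy[v] = 0.0;
            cnt[v] = 0;
          }
        }
        for (size_t k = 0; k < cusp_pairs.size(); ++k) {
          int r = uf_find(cusp_pairs[k]);
          mfx[r] = fx[r] / cnt[r];
          mfy[r] = fy[r] / cnt[r];
        }
        for (size_t k = 0; k < cusp_pairs.size(); ++k) {
          int v = cusp_pairs[k], r = uf_find(v);
          fx[v] = mfx[r];
          fy[v] = mfy[r];
        }
        // restore counts for the next iteration
        for (size_t k = 0; k < cusp_pairs.size(); ++k) cnt[cusp_pairs[k]] = 1;
      }
    }
    res = 0.0;
    for (int i = 0; i < nv; ++i) {
      double f2 = fx[i] * fx[i] + fy[i] * fy[i];
      if (f2 > res) res = f2;
    }
    res = std::sqrt(res);
    if (res < tol) { status = 0; break; }
    // clustered (rosette-aware) convergence check, every check_every iters
    if (ne > 0 && cusp_len > 0 && it % check_every == 0 && res < 1.0) {
      bool any_cusp = false;
      for (int e = 0; e < ne && !any_cusp; ++e) {
        double dx = min_image(px[edges(e, 1)] - px[edges(e, 0)], Lx);
        double dy = min_image(py[edges(e, 1)] - py[edges(e, 0)], Ly);
        if (std::sqrt(dx * dx + dy * dy) < cusp_len) any_cusp = true;
      }
      if (any_cusp) {
        double cres = cluster_residual(fx, fy, nv, px, py, edges, cusp_len,
                                       Lx, Ly);
        if (cres < tol) { res = cres; status = 0; break; }
      }
    }

    // scan for collapsing junctions only near force balance: transient
    // dips during the descent that follows a deformation step do not mark
    // topology changes of the approached minimum
    if (t1_len > 0 && ne > 0 && it > 0 && it % check_every == 0 &&
        res < t1_res_gate) {
      for (int e = 0; e < ne; ++e) {
        if (!flippable[e]) continue;
        double dx = min_image(px[edges(e, 1)] - px[edges(e, 0)], Lx);
        double dy = min_image(py[edges(e, 1)] - py[edges(e, 0)], Ly);
        if (std::sqrt(dx * dx + dy * dy) < t1_len) short_edges.push_back(e + 1);
      }
      if (!short_edges.empty()) { status = 2; break; }
    }

    double Pfv = 0.0;
    for (int i = 0; i < nv; ++i) Pfv += fx[i] * vxv[i] + fy[i] * vyv[i];
    if (Pfv > 0) {
      if (++npos > n_min) {
        dt = std::min(dt * f_inc, dt_max);
        alpha *= f_alpha;
      }
    } else {
      npos = 0;
      ++n_uphill;
      // uphill: retract half the last step, zero velocities, cool down
      for (int i = 0; i < nv; ++i) {
        px[i] -= 0.5 * dt * vxv[i];
        py[i] -= 0.5 * dt * vyv[i];
        px[i] -= Lx * std::floor(px[i] / Lx);
        py[i] -= Ly * std::floor(py[i] / Ly);
      }
      dt *= f_dec;
      alpha = alpha0;
      std::fill(vxv.begin(), vxv.end(), 0.0);
      std::fill(vyv.begin(), vyv.end(), 0.0);
    }

    double vnorm = 0.0, fnorm = 0.0;
    for (int i = 0; i < nv; ++i) {
      vxv[i] += dt * fx[i];
      vyv[i] += dt * fy[i];
      vnorm += vxv[i] * vxv[i] + vyv[i] * vyv[i];
      fnorm += fx[i] * fx[i] + fy[i] * fy[i];
    }
    vnorm = std::sqrt(vnorm);
    fnorm = std::sqrt(fnorm);
    if (fnorm > 0) {
      double mix = alpha * vnorm / fnorm;
      for (int i = 0; i < nv; ++i) {
        vxv[i] = (1 - alpha) * vxv[i] + mix * fx[i];
        vyv[i] = (1 - alpha) * vyv[i] + mix * fy[i];
      }
    }
    double vmax = 0.0;
    for (int i = 0; i < nv; ++i) {
      double v2 = vxv[i] * vxv[i] + vyv[i] * vyv[i];
      if (v2 > vmax) vmax = v2;
    }
    vmax = std::sqrt(vmax) * dt;
    if (vmax > dmax) {  // cap the step by rescaling the velocities themselves
      double scale = dmax / vmax;
      for (int i = 0; i < nv; ++i) {
        vxv[i] *= scale;
        vyv[i] *= scale;
      }
    }
    for (int i = 0; i < nv; ++i) {
      px[i] += dt * vxv[i];
      py[i] += dt * vyv[i];
      px[i] -= Lx * std::floor(px[i] / Lx);
      py[i] -= Ly * std::floor(py[i] / Ly);
    }
  }
  int imax = 0;
  double fmax = -1.0;
  for (int i = 0; i < nv; ++i) {
    double f2 = fx[i] * fx[i] + fy[i] * fy[i];
    if (f2 > fmax) { fmax = f2; imax = i; }
  }
  return List::create(_["vertices"] = pos, _["energy"] = E,
                      _["residual"] = res, _["iterations"] = it,
                      _["status"] = status,
                      _["short_edges"] = IntegerVector(short_edges.begin(),
                                                       short_edges.end()),
                      _["dt"] = dt, _["n_uphill"] = n_uphill,
                      _["max_force_vertex"] = imax + 1);
}

// Winding union-find: does the subgraph given by `edges` (1-based vertex
// ids) with per-edge minimum-image displacements wrap around the periodic
// box in x and/or y?
// [[Rcpp::export]]
List vm_percolate(int n_vertices, IntegerMatrix edges, NumericMatrix disp,
                  double Lx, double Ly) {
  std::vector<int> parent(n_vertices), sz(n_vertices, 1);
  std::vector<double> offx(n_vertices, 0.0), offy(n_vertices, 0.0);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  bool wx = false, wy = false;

  // iterative find with full path compression, accumulating offsets to root
  std::vector<int> stack;
  auto find = [&](int v) {
    stack.clear();
    while (parent[v] != v) {
      stack.push_back(v);
      v = parent[v];
    }
    double ax = 0.0, ay = 0.0;
    for (int i = (int)stack.size() - 1; i >= 0; --i) {
      int u = stack[i];
      ax += offx[u];
      ay += offy[u];
      parent[u] = v;
      offx[u] = ax;
      offy[u] = ay;
    }
    return v;
  };

  const int ne = edges.nrow();
  for (int e = 0; e < ne; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    double dx = disp(e, 0), dy = disp(e, 1);
    int ru = find(u), rv = find(v);
    if (ru == rv) {
      double mx = offx[u] + dx - offx[v];
      double my = offy[u] + dy - offy[v];
      if (std::lround(mx / Lx) != 0) wx = true;
      if (std::lround(my / Ly) != 0) wy = true;
    } else {
      if (sz[ru] < sz[rv]) {
        std::swap(ru, rv);
        std::swap(u, v);
        dx = -dx;
        dy = -dy;
      }
      parent[rv] = ru;
      offx[rv] = offx[u] + dx - offx[v];
      offy[rv] = offy[u] + dy - offy[v];
      sz[ru] += sz[rv];
    }
    if (wx && wy) break;
  }
  return List::create(_["wraps_x"] = wx, _["wraps_y"] = wy);
}

// Incremental bond-percolation threshold on one graph realization: edges are
// added in the supplied order; returns the 1-based count of edges added when
// the cluster first wraps in both periodic directions (0 if never).
// [[Rcpp::export]]
int vm_percolation_onset(int n_vertices, IntegerMatrix edges,
                         NumericMatrix disp, double Lx, double Ly) {
  std::vector<int> parent(n_vertices), sz(n_vertices, 1);
  std::vector<double> offx(n_vertices, 0.0), offy(n_vertices, 0.0);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  bool wx = false, wy = false;
  std::vector<int> stack;
  auto find = [&](int v) {
    stack.clear();
    while (parent[v] != v) {
      stack.push_back(v);
      v = parent[v];
    }
    double ax = 0.0, ay = 0.0;
    for (int i = (int)stack.size() - 1; i >= 0; --i) {
      int u = stack[i];
      ax += offx[u];
      ay += offy[u];
      parent[u] = v;
      offx[u] = ax;
      offy[u] = ay;
    }
    return v;
  };
  const int ne = edges.nrow();
  for (int e = 0; e < ne; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    double dx = disp(e, 0), dy = disp(e, 1);
    int ru = find(u), rv = find(v);
    if (ru == rv) {
      double mx = offx[u] + dx - offx[v];
      double my = offy[u] + dy - offy[v];
      if (std::lround(mx / Lx) != 0) wx = true;
      if (std::lround(my / Ly) != 0) wy = true;
    } else {
      if (sz[ru] < sz[rv]) {
        std::swap(ru, rv);
        std::swap(u, v);
        dx = -dx;
        dy = -dy;
      }
      parent[rv] = ru;
      offx[rv] = offx[u] + dx - offx[v];
      offy[rv] = offy[u] + dy - offy[v];
      sz[ru] += sz[rv];
    }
    if (wx && wy) return e + 1;
  }
  return 0;
}
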