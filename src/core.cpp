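#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Delaunay / Voronoi adjacency.
//
// An edge (i, j) belongs to a Delaunay triangulation iff some circumcircle
// through i, j and a third point k contains no other point. N is small
// (tens of individuals), so the brute-force test with early exit is fast
// enough to run every integration step. Exact cocircular ties (e.g. a
// perfect square lattice) are broken deterministically by a tiny
// index-dependent jitter applied only inside this test; it is far below
// any physical scale of the model.
// ---------------------------------------------------------------------------

static void jittered_copy(const double* x, const double* y, int n,
                          std::vector<double>& jx, std::vector<double>& jy) {
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    scale = std::max(scale, std::fabs(x[i]));
    scale = std::max(scale, std::fabs(y[i]));
  }
  if (scale <= 0.0) scale = 1.0;
  const double eps = 1e-9 * scale;
  jx.resize(n); jy.resize(n);
  for (int i = 0; i < n; ++i) {
    // deterministic pseudo-random offsets from the index only
    double a = std::sin(12.9898 * (i + 1)) * 43758.5453;
    double b = std::sin(78.2330 * (i + 1)) * 24634.6345;
    jx[i] = x[i] + eps * (a - std::floor(a) - 0.5);
    jy[i] = y[i] + eps * (b - std::floor(b) - 0.5);
  }
}

// adjacency for n >= 3 general-position points; fills symmetric logical matrix
static void delaunay_adjacency(const double* x0, const double* y0, int n,
                               std::vector<unsigned char>& adj) {
  adj.assign((size_t)n * n, 0);
  if (n == 1) return;
  if (n == 2) { adj[1] = adj[n] = 1; return; }

  // reject duplicate points: zero distances break both weights and circles
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x0[i] - x0[j], dy = y0[i] - y0[j];
      if (dx * dx + dy * dy < 1e-20)
        stop("duplicate positions: individuals %d and %d coincide", i + 1, j + 1);
    }

  std::vector<double> x, y;
  jittered_copy(x0, y0, n, x, y);

  // collinearity check (degenerate Voronoi diagram)
  bool collinear = true;
  for (int k = 2; k < n && collinear; ++k) {
    double cr = (x[1] - x[0]) * (y[k] - y[0]) - (y[1] - y[0]) * (x[k] - x[0]);
    double L = std::hypot(x[1] - x[0], y[1] - y[0]) *
               std::hypot(x[k] - x[0], y[k] - y[0]);
    if (std::fabs(cr) > 1e-7 * std::max(L, 1.0)) collinear = false;
  }
  if (collinear)
    stop("degenerate configuration: all positions are collinear");

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool edge = false;
      for (int k = 0; k < n && !edge; ++k) {
        if (k == i || k == j) continue;
        // circumcenter of (i, j, k)
        double ax = x[i], ay = y[i], bx = x[j], by = y[j],
               cx = x[k], cy = y[k];
        double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
        if (std::fabs(d) < 1e-14) continue;  // (near-)collinear triple
        double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
               c2 = cx * cx + cy * cy;
        double ux = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
        double uy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
        double r2 = (ax - ux) * (ax - ux) + (ay - uy) * (ay - uy);
        bool empty = true;
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j || m == k) continue;
          double dm = (x[m] - ux) * (x[m] - ux) + (y[m] - uy) * (y[m] - uy);
          if (dm < r2) { empty = false; break; }
        }
        if (empty) edge = true;
      }
      if (edge) {
        adj[(size_t)i * n + j] = 1;
        adj[(size_t)j * n + i] = 1;
      }
    }
  }
}

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
LogicalMatrix delaunay_edges_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (y.size() != n) stop("x and y lengths differ");
  std::vector<unsigned char> adj;
  delaunay_adjacency(REAL(x), REAL(y), n, adj);
  LogicalMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = adj[(size_t)i * n + j] != 0;
  return out;
}

static int nearest_of(const double* x, const double* y, int n, int i) {
  int best = -1;
  double bd = R_PosInf;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double d = (x[i] - x[j]) * (x[i] - x[j]) + (y[i] - y[j]) * (y[i] - y[j]);
    if (d < bd) { bd = d; best = j; }
  }
  return best;
}

// nearest-neighbor index (1-based) for every frame and individual
// [[Rcpp::export(name = ".nn_indices_cpp")]]
IntegerMatrix nn_indices_cpp(NumericMatrix X, NumericMatrix Y) {
  int T = X.nrow(), n = X.ncol();
  if (n < 2) stop("need at least 2 individuals");
  IntegerMatrix out(T, n);
  std::vector<double> x(n), y(n);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) { x[i] = X(t, i); y[i] = Y(t, i); }
    for (int i = 0; i < n; ++i) out(t, i) = nearest_of(x.data(), y.data(), n, i) + 1;
  }
  return out;
}

// Durations (in frames) of maximal runs of Voronoi adjacency per unordered
// pair; strictly contiguous, runs reaching the final frame are emitted.
// [[Rcpp::export(name = ".contact_runs_cpp")]]
NumericVector contact_runs_cpp(NumericMatrix X, NumericMatrix Y) {
  int T = X.nrow(), n = X.ncol();
  std::vector<int> run((size_t)n * n, 0);
  std::vector<unsigned char> adj;
  std::vector<double> durations;
  std::vector<double> x(n), y(n);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) { x[i] = X(t, i); y[i] = Y(t, i); }
    delaunay_adjacency(x.data(), y.data(), n, adj);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        size_t p = (size_t)i * n + j;
        if (adj[p]) {
          run[p] += 1;
        } else if (run[p] > 0) {
          durations.push_back(run[p]);
          run[p] = 0;
        }
      }
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      size_t p = (size_t)i * n + j;
      if (run[p] > 0) durations.push_back(run[p]);
    }
  return wrap(durations);
}

// ---------------------------------------------------------------------------
// Euler-Maruyama integrator.
//
// Velocity update is explicit in the forces evaluated at the current state;
// position uses the updated velocity (semi-implicit ordering). Noise enters
// with sqrt(dt) scaling, consistent with sigma units of cm s^{-3/2}.
// Recorded accelerations are deterministic force + realized noise
// increment / dt, i.e. what a tracking pipeline would measure.
// ---------------------------------------------------------------------------

struct Field {
  bool present = false;
  int nx = 0, ny = 0;
  double x0 = 0, x1 = 0, y0 = 0, y1 = 0;
  const double* fx = nullptr;
  const double* fy = nullptr;
  // bilinear interpolation on cell centers, clamped at the boundary
  void eval(double qx, double qy, double& ox, double& oy) const {
    double hx = (x1 - x0) / nx, hy = (y1 - y0) / ny;
    double gx = (qx - x0) / hx - 0.5, gy = (qy - y0) / hy - 0.5;
    gx = std::min(std::max(gx, 0.0), (double)(nx - 1));
    gy = std::min(std::max(gy, 0.0), (double)(ny - 1));
    int i0 = std::min((int)std::floor(gx), nx - 2);
    int j0 = std::min((int)std::floor(gy), ny - 2);
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    double tx = gx - i0, ty = gy - j0;
    tx = std::min(std::max(tx, 0.0), 1.0);
    ty = std::min(std::max(ty, 0.0), 1.0);
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1);
    double w00 = (1 - tx) * (1 - ty), w10 = tx * (1 - ty),
           w01 = (1 - tx) * ty, w11 = tx * ty;
    ox = w00 * fx[i0 + nx * j0] + w10 * fx[i1 + nx * j0] +
         w01 * fx[i0 + nx * j1] + w11 * fx[i1 + nx * j1];
    oy = w00 * fy[i0 + nx * j0] + w10 * fy[i1 + nx * j0] +
         w01 * fy[i0 + nx * j1] + w11 * fy[i1 + nx * j1];
  }
};

// variant codes: 0 standard, 1 selective, 2 explicit antialignment,
//                3 persistent random force, 4 nearest-neighbor-only
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericVector x_init, NumericVector y_init,
                  NumericVector vx_init, NumericVector vy_init,
                  List par, int n_frames, int n_transient) {
  const int n = x_init.size();
  const double k_rep = par["k_rep"], k_att = par["k_att"], d0 = par["d0"],
               mu = par["mu"], v0 = par["v0"], tau_v = par["tau_v"],
               sigma_v = par["sigma_v"], sigma_phi = par["sigma_phi"],
               dt = par["dt"];
  const int variant = par["variant_code"];
  // 0: unnormalized 1/d sum; 1: normalized over the interacting set;
  // 2: normalized over all Voronoi neighbors, summed over the set
  const int wmode = par["weight_mode"];
  double pr_r = 0, pr_A = 0, pr_tau = 0;
  if (variant == 3) {
    pr_r = par["pr_rate"]; pr_A = par["pr_amplitude"]; pr_tau = par["pr_duration"];
  }
  Field field;
  NumericMatrix ffx, ffy;
  if (variant == 2) {
    List fl = par["field"];
    ffx = as<NumericMatrix>(fl["fx"]);
    ffy = as<NumericMatrix>(fl["fy"]);
    field.present = true;
    field.nx = ffx.nrow(); field.ny = ffx.ncol();
    field.x0 = fl["xmin"]; field.x1 = fl["xmax"];
    field.y0 = fl["ymin"]; field.y1 = fl["ymax"];
    field.fx = REAL(ffx); field.fy = REAL(ffy);
  }

  const double sq_dt = std::sqrt(dt);
  const int total = n_frames + n_transient;

  std::vector<double> x(x_init.begin(), x_init.end()),
      y(y_init.begin(), y_init.end()),
      vx(vx_init.begin(), vx_init.end()),
      vy(vy_init.begin(), vy_init.end());
  std::vector<double> fx(n), fy(n), speed(n);
  std::vector<unsigned char> adj;
  std::vector<double> w(n);

  // persistent-random-force registers
  std::vector<double> reg_dx(n, 0), reg_dy(n, 0), reg_rem(n, 0);
  std::vector<unsigned char> reg_on(n, 0);

  NumericMatrix X(n_frames, n), Y(n_frames, n), VX(n_frames, n),
      VY(n_frames, n), AX(n_frames, n), AY(n_frames, n);

  for (int step = 0; step < total; ++step) {
    for (int i = 0; i < n; ++i) {
      speed[i] = std::hypot(vx[i], vy[i]);
      if (speed[i] < 1e-9)
        stop("degenerate state: individual %d has (near-)zero speed, heading undefined",
             i + 1);
    }

    if (variant == 3) {
      for (int i = 0; i < n; ++i) {
        if (reg_on[i] && reg_rem[i] <= 0) reg_on[i] = 0;
        if (!reg_on[i] && unif_rand() < pr_r * dt) {
          double th = 2.0 * M_PI * unif_rand();
          reg_dx[i] = std::cos(th); reg_dy[i] = std::sin(th);
          reg_rem[i] = pr_tau; reg_on[i] = 1;
        }
      }
    }

    if (n >= 2) delaunay_adjacency(x.data(), y.data(), n, adj);

    for (int i = 0; i < n; ++i) {
      double sfx = 0, sfy = 0;
      if (variant == 3 && reg_on[i]) {
        sfx = pr_A * reg_dx[i];
        sfy = pr_A * reg_dy[i];
      } else if (n >= 2) {
        // interacting set and weights
        double wsum = 0, wsum_all = 0;
        for (int j = 0; j < n; ++j) {
          w[j] = 0;
          if (j == i) continue;
          bool vor = adj[(size_t)i * n + j] != 0;
          double dx = x[i] - x[j], dy = y[i] - y[j];
          double d = std::hypot(dx, dy);
          if (vor) wsum_all += 1.0 / d;
          bool use = vor;
          if (variant == 1 && use) use = speed[j] > speed[i];
          if (variant == 4 && use) use = false;  // resolved after loop
          if (use) { w[j] = 1.0 / d; wsum += w[j]; }
        }
        if (variant == 4) {
          int gnn = nearest_of(x.data(), y.data(), n, i);
          w[gnn] = 1.0; wsum = 1.0; wsum_all = 1.0;
        }
        double wden = (wmode == 0) ? 1.0 : (wmode == 1 ? wsum : wsum_all);
        if (wsum > 0) {
          for (int j = 0; j < n; ++j) {
            if (w[j] == 0) continue;
            double wij = w[j] / wden;
            double dx = x[i] - x[j], dy = y[i] - y[j];
            double d = std::hypot(dx, dy);
            double k = (d <= d0) ? k_rep : k_att;
            double fr = -k * (d - d0) / d;
            double pfx = fr * dx, pfy = fr * dy;
            if (variant != 2) {
              pfx += -mu * (vx[i] - vx[j]);
              pfy += -mu * (vy[i] - vy[j]);
            }
            sfx += wij * pfx; sfy += wij * pfy;
          }
        }
        if (variant == 2 && field.present) {
          // tabulated (anti)alignment force at the relative velocity with
          // the nearest neighbor, evaluated in the focal frame of i
          int gnn = nearest_of(x.data(), y.data(), n, i);
          double hvx = vx[i] / speed[i], hvy = vy[i] / speed[i];
          double rxx = hvy, rxy = -hvx;  // focal x-axis (right of heading)
          double dvx = vx[i] - vx[gnn], dvy = vy[i] - vy[gnn];
          double qx = dvx * rxx + dvy * rxy;   // focal-frame components
          double qy = dvx * hvx + dvy * hvy;
          double gx, gy;
          field.eval(qx, qy, gx, gy);
          sfx += gx * rxx + gy * hvx;          // rotate back to lab frame
          sfy += gx * rxy + gy * hvy;
        }
      }
      double hx = vx[i] / speed[i], hy = vy[i] / speed[i];
      double ffric = R_finite(tau_v) ? -(speed[i] - v0) / tau_v : 0.0;
      double detx = sfx + ffric * hx, dety = sfy + ffric * hy;
      double xi_v = norm_rand(), xi_p = norm_rand();
      double nx_ = sigma_v * xi_v * hx + sigma_phi * xi_p * (-hy);
      double ny_ = sigma_v * xi_v * hy + sigma_phi * xi_p * hx;
      fx[i] = detx * dt + nx_ * sq_dt;  // velocity increment
      fy[i] = dety * dt + ny_ * sq_dt;
      if (step >= n_transient) {
        int t = step - n_transient;
        X(t, i) = x[i]; Y(t, i) = y[i];
        VX(t, i) = vx[i]; VY(t, i) = vy[i];
        AX(t, i) = detx + nx_ / sq_dt;
        AY(t, i) = dety + ny_ / sq_dt;
      }
    }

    for (int i = 0; i < n; ++i) {
      vx[i] += fx[i]; vy[i] += fy[i];
      x[i] += vx[i] * dt; y[i] += vy[i] * dt;
      if (variant == 3 && reg_on[i]) reg_rem[i] -= dt;
    }
  }

  return List::create(_["x"] = X, _["y"] = Y, _["vx"] = VX, _["vy"] = VY,
                      _["ax"] = AX, _["ay"] = AY);
}
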