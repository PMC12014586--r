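// Simulation core: dual-timescale loop over mechanics (voxel selection,
// ECM degradation, persistence-driven direction resampling, centre-based
// velocities, forward-Euler move) and phenotype (division, volume growth).
// Mirrors the plain-R reference step in R/mechanics.R; randomness comes
// from R's RNG so runs are reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double cbrt_radius(double V) {
  return std::cbrt(3.0 * V / (4.0 * M_PI));
}

// nearest-centre axis index (0-based); ties go to the smaller index
static inline int axis_idx(double coord, double orig, double h, int n) {
  double u = (coord - orig) / h;
  double fi = std::floor(u);
  int i = static_cast<int>(fi);
  if (u == fi && i > 0) i -= 1;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// uniform-bin spatial index for neighbour queries
struct Bins {
  double lo, w;
  int nb;
  std::vector<int> head, nxt;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             double lo_, double hi_, double binw) {
    lo = lo_;
    w = binw;
    nb = std::max(1, static_cast<int>(std::ceil((hi_ - lo_) / binw)));
    head.assign(static_cast<size_t>(nb) * nb, -1);
    size_t n = x.size();
    nxt.assign(n, -1);
    for (size_t i = 0; i < n; ++i) {
      int bx = std::min(nb - 1, std::max(0, static_cast<int>((x[i] - lo) / w)));
      int by = std::min(nb - 1, std::max(0, static_cast<int>((y[i] - lo) / w)));
      int b = by * nb + bx;
      nxt[i] = head[b];
      head[b] = static_cast<int>(i);
    }
  }
};

// [[Rcpp::export]]
List sim_run_cpp(NumericVector x0, NumericVector y0, NumericVector vol0,
                 NumericVector dirx0, NumericVector diry0,
                 NumericMatrix rho0, List par) {
  RNGScope scope;

  // parameters
  const double ox = as<double>(par["ox"]), oy = as<double>(par["oy"]);
  const double h = as<double>(par["voxel_size"]);
  const int nx = as<int>(par["nx"]), ny = as<int>(par["ny"]);
  const double dt = as<double>(par["dt_mech"]);
  const int n_steps = as<int>(par["n_steps"]);
  const int steps_per_cell = as<int>(par["steps_per_cell"]);
  const int record_every = as<int>(par["record_every_steps"]);
  const double rdeg = as<double>(par["rdeg"]);
  const double Srib = as<double>(par["Srib"]);
  const double Tper = as<double>(par["Tper"]);
  const double rdiv = as<double>(par["rdiv"]);
  const int Nmax = as<int>(par["Nmax"]);
  const double ccca = as<double>(par["ccca"]);
  const double cccr = as<double>(par["cccr"]);
  const double mult = as<double>(par["adhesion_radius_multiple"]);
  const double kgrow = as<double>(par["growth_rate_k"]);
  const double Vmax = as<double>(par["cell_volume_max"]);
  const double hw = as<double>(par["domain_half_width"]);

  const double dt_cell = dt * steps_per_cell;
  if (rdiv * dt_cell > 1.0)
    stop("`rdiv * dt_cell` exceeds 1: division probability ill-defined");
  const double presample = (Tper == R_PosInf) ? 0.0 : dt / Tper;
  if (presample > 1.0) stop("`dt_mech` must be <= `Tper`");
  const double decay = std::exp(-rdeg * dt);

  // state
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> vol(vol0.begin(), vol0.end());
  std::vector<double> dx(dirx0.begin(), dirx0.end());
  std::vector<double> dy(diry0.begin(), diry0.end());
  size_t n = x.size();
  std::vector<double> rad(n), spd(n, 0.0);
  std::vector<int> id(n);
  for (size_t i = 0; i < n; ++i) {
    rad[i] = cbrt_radius(vol[i]);
    id[i] = static_cast<int>(i) + 1;
  }
  int next_id = static_cast<int>(n);

  std::vector<double> rho(rho0.begin(), rho0.end()); // column-major: ix + iy*nx

  long n_divisions = 0, n_clamped = 0, n_coincident = 0;

  // snapshots of (time, x, y, radius) at the recording cadence
  List snap_times, snap_x, snap_y, snap_r;
  auto record = [&](double t) {
    snap_times.push_back(t);
    snap_x.push_back(NumericVector(x.begin(), x.end()));
    snap_y.push_back(NumericVector(y.begin(), y.end()));
    snap_r.push_back(NumericVector(rad.begin(), rad.end()));
  };
  record(0.0);

  Bins bins;
  // bin width: largest possible interaction distance
  const double binw = 2.0 * mult * cbrt_radius(Vmax) + 1e-9;

  std::vector<int> sel;
  std::vector<double> vx, vy;
  std::vector<int> nbr;

  for (int step = 1; step <= n_steps; ++step) {
    // (1) per-cell interaction voxel (front voxel when moving)
    sel.resize(n);
    for (size_t i = 0; i < n; ++i) {
      double px = x[i], py = y[i];
      double nd = std::sqrt(dx[i] * dx[i] + dy[i] * dy[i]);
      if (nd > 0) {
        px += rad[i] * dx[i] / nd;
        py += rad[i] * dy[i] / nd;
        double cx = std::min(std::max(px, -hw), hw);
        double cy = std::min(std::max(py, -hw), hw);
        if (cx != px || cy != py) ++n_clamped;
        px = cx; py = cy;
      }
      sel[i] = axis_idx(py, oy, h, ny) * nx + axis_idx(px, ox, h, nx);
    }
    // (2) degradation, once per cell in cell order (updates commute)
    if (rdeg > 0) {
      for (size_t i = 0; i < n; ++i) rho[sel[i]] *= decay;
    }
    // (3) direction resampling
    if (presample > 0) {
      for (size_t i = 0; i < n; ++i) {
        if (unif_rand() < presample) {
          double ang = unif_rand() * 2.0 * M_PI;
          dx[i] = std::cos(ang);
          dy[i] = std::sin(ang);
        }
      }
    }
    // (4) velocities from pre-step positions (synchronous update)
    bins.build(x, y, -hw, hw, binw);
    vx.assign(n, 0.0);
    vy.assign(n, 0.0);
    for (size_t i = 0; i < n; ++i) {
      double vccx = 0.0, vccy = 0.0;
      int bx = std::min(bins.nb - 1, std::max(0, static_cast<int>((x[i] + hw) / bins.w)));
      int by = std::min(bins.nb - 1, std::max(0, static_cast<int>((y[i] + hw) / bins.w)));
      for (int gy = std::max(0, by - 1); gy <= std::min(bins.nb - 1, by + 1); ++gy) {
        for (int gx = std::max(0, bx - 1); gx <= std::min(bins.nb - 1, bx + 1); ++gx) {
          for (int j = bins.head[gy * bins.nb + gx]; j >= 0; j = bins.nxt[j]) {
            if (static_cast<size_t>(j) == i) continue;
            double dxv = x[i] - x[j], dyv = y[i] - y[j];
            double d = std::sqrt(dxv * dxv + dyv * dyv);
            double lim_a = mult * (rad[i] + rad[j]);
            if (d >= lim_a) continue;
            double ux, uy;
            if (d == 0.0) {
              ux = (i < static_cast<size_t>(j)) ? 1.0 : -1.0;
              uy = 0.0;
              ++n_coincident;
            } else {
              ux = dxv / d;
              uy = dyv / d;
            }
            double om = 1.0 - d / lim_a;
            double f = -ccca * om * om;
            double lim_r = rad[i] + rad[j];
            if (d < lim_r) {
              double omr = 1.0 - d / lim_r;
              f += cccr * omr * omr;
            }
            vccx += f * ux;
            vccy += f * uy;
          }
        }
      }
      double rho_i = rho[sel[i]];
      double s_cma = 4.0 * Srib * rho_i;
      double tx = vccx + s_cma * dx[i];
      double ty = vccy + s_cma * dy[i];
      vx[i] = tx * (1.0 - rho_i);
      vy[i] = ty * (1.0 - rho_i);
      spd[i] = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
    }
    // (5) move
    for (size_t i = 0; i < n; ++i) {
      x[i] += vx[i] * dt;
      y[i] += vy[i] * dt;
      if (!R_finite(x[i]) || !R_finite(y[i]) ||
          std::fabs(x[i]) > hw || std::fabs(y[i]) > hw) {
        stop("cell %d left the domain at step %d; increase `domain_half_width`",
             id[i], step);
      }
    }

    // phenotype: division then volume growth
    if (step % steps_per_cell == 0) {
      if (rdiv > 0) {
        bins.build(x, y, -hw, hw, binw);
        size_t n_now = n;
        nbr.assign(n_now, 0);
        for (size_t i = 0; i < n_now; ++i) {
          int bx = std::min(bins.nb - 1, std::max(0, static_cast<int>((x[i] + hw) / bins.w)));
          int by = std::min(bins.nb - 1, std::max(0, static_cast<int>((y[i] + hw) / bins.w)));
          int cnt = 0;
          for (int gy = std::max(0, by - 1); gy <= std::min(bins.nb - 1, by + 1); ++gy) {
            for (int gx = std::max(0, bx - 1); gx <= std::min(bins.nb - 1, bx + 1); ++gx) {
              for (int j = bins.head[gy * bins.nb + gx]; j >= 0; j = bins.nxt[j]) {
                if (static_cast<size_t>(j) == i) continue;
                double dxv = x[i] - x[j], dyv = y[i] - y[j];
                double d = std::sqrt(dxv * dxv + dyv * dyv);
                if (d < mult * (rad[i] + rad[j])) ++cnt;
              }
            }
          }
          nbr[i] = cnt;
        }
        for (size_t i = 0; i < n_now; ++i) {
          double u = unif_rand();
          double fip;
          if (nbr[i] >= Nmax) {
            fip = 0.0;
          } else {
            int v = axis_idx(y[i], oy, h, ny) * nx + axis_idx(x[i], ox, h, nx);
            fip = 1.0 - rho[v];
          }
          if (u < rdiv * fip * dt_cell) {
            double ang = unif_rand() * 2.0 * M_PI;
            double off = rad[i] / 2.0;
            double ux = std::cos(ang), uy = std::sin(ang);
            // parent becomes one daughter, the other is appended
            x.push_back(x[i] - off * ux);
            y.push_back(y[i] - off * uy);
            vol[i] *= 0.5;
            vol.push_back(vol[i]);
            rad[i] = cbrt_radius(vol[i]);
            rad.push_back(rad[i]);
            dx.push_back(dx[i]);
            dy.push_back(dy[i]);
            spd.push_back(spd[i]);
            id.push_back(++next_id);
            x[i] += off * ux;
            y[i] += off * uy;
            ++n_divisions;
            ++n;
          }
        }
      }
      if (kgrow > 0) {
        double g = std::exp(-kgrow * dt_cell);
        for (size_t i = 0; i < n; ++i) {
          vol[i] = Vmax - (Vmax - vol[i]) * g;
          rad[i] = cbrt_radius(vol[i]);
        }
      }
    }

    if (step % record_every == 0) record(step * dt);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix rho_out(nx, ny);
  std::copy(rho.begin(), rho.end(), rho_out.begin());

  DataFrame cells = DataFrame::create(
      _["id"] = IntegerVector(id.begin(), id.end()),
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["volume"] = NumericVector(vol.begin(), vol.end()),
      _["radius"] = NumericVector(rad.begin(), rad.end()),
      _["dir_x"] = NumericVector(dx.begin(), dx.end()),
      _["dir_y"] = NumericVector(dy.begin(), dy.end()),
      _["speed"] = NumericVector(spd.begin(), spd.end()));

  return List::create(
      _["cells"] = cells,
      _["rho"] = rho_out,
      _["snap_time"] = snap_times,
      _["snap_x"] = snap_x,
      _["snap_y"] = snap_y,
      _["snap_r"] = snap_r,
      _["n_divisions"] = static_cast<double>(n_divisions),
      _["n_clamped_fronts"] = static_cast<double>(n_clamped),
      _["n_coincident"] = static_cast<double>(n_coincident));
}

// Union-of-disks area on an n x n raster of the square [lo, hi]^2.
// A grid element counts as covered when its centre lies inside or on the
// boundary of at least one disk; overlaps count once.
// [[Rcpp::export]]
double raster_area_cpp(NumericVector x, NumericVector y, NumericVector r,
                       double lo, double hi, int n) {
  if (n < 1) stop("`n` must be >= 1");
  const double stepw = (hi - lo) / n;
  std::vector<unsigned char> cov(static_cast<size_t>(n) * n, 0);
  const int ncell = x.size();
  for (int k = 0; k < ncell; ++k) {
    double rk = r[k];
    if (rk <= 0) continue;
    int i0 = std::max(0, static_cast<int>(std::floor((x[k] - rk - lo) / stepw)) - 1);
    int i1 = std::min(n - 1, static_cast<int>(std::ceil((x[k] + rk - lo) / stepw)) + 1);
    int j0 = std::max(0, static_cast<int>(std::floor((y[k] - rk - lo) / stepw)) - 1);
    int j1 = std::min(n - 1, static_cast<int>(std::ceil((y[k] + rk - lo) / stepw)) + 1);
    double r2 = rk * rk;
    for (int j = j0; j <= j1; ++j) {
      double cy = lo + (j + 0.5) * stepw - y[k];
      double cy2 = cy * cy;
      if (cy2 > r2) continue;
      for (int i = i0; i <= i1; ++i) {
        double cx = lo + (i + 0.5) * stepw - x[k];
        if (cx * cx + cy2 <= r2) cov[static_cast<size_t>(j) * n + i] = 1;
      }
    }
  }
  size_t covered = 0;
  for (size_t i = 0; i < cov.size(); ++i) covered += cov[i];
  double dom = (hi - lo);
  return covered * dom * dom / (static_cast<double>(n) * n);
}
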