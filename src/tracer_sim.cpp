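#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Periodic minimum-image difference on [0, box)
static inline double min_image(double d, double box) {
  d -= box * std::nearbyint(d / box);
  return d;
}

// Cell-list over obstacle centers for O(1) neighbourhood queries.
// Cell edge >= interaction radius so a 3x3 stencil is sufficient.
struct ObstacleGrid {
  int ncell;
  double cell, box;
  std::vector<int> start;   // CSR offsets, length ncell*ncell+1
  std::vector<int> idx;     // obstacle indices sorted by cell
  const double *ox, *oy;
  int n;

  ObstacleGrid(const NumericVector& x, const NumericVector& y,
               double box_, double r_int)
      : box(box_), ox(x.begin()), oy(y.begin()), n(x.size()) {
    ncell = std::max(1, (int)std::floor(box / std::max(r_int, 1e-9)));
    ncell = std::min(ncell, 4096);
    cell = box / ncell;
    std::vector<int> count(ncell * ncell, 0);
    std::vector<int> ci(n);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(ox[i] / cell); if (cx >= ncell) cx = ncell - 1;
      int cy = (int)std::floor(oy[i] / cell); if (cy >= ncell) cy = ncell - 1;
      ci[i] = cy * ncell + cx;
      count[ci[i]]++;
    }
    start.assign(ncell * ncell + 1, 0);
    for (int c = 0; c < ncell * ncell; ++c) start[c + 1] = start[c] + count[c];
    idx.resize(n);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) idx[fill[ci[i]]++] = i;
  }

  // squared distance to nearest obstacle centre within the 3x3 stencil
  inline double nearest_sq(double x, double y) const {
    if (n == 0) return R_PosInf;
    int cx = (int)std::floor(x / cell); if (cx >= ncell) cx = ncell - 1;
    int cy = (int)std::floor(y / cell); if (cy >= ncell) cy = ncell - 1;
    double best = R_PosInf;
    for (int dy = -1; dy <= 1; ++dy) {
      int gy = (cy + dy + ncell) % ncell;
      for (int dx = -1; dx <= 1; ++dx) {
        int gx = (cx + dx + ncell) % ncell;
        int c = gy * ncell + gx;
        for (int k = start[c]; k < start[c + 1]; ++k) {
          int i = idx[k];
          double ddx = min_image(x - ox[i], box);
          double ddy = min_image(y - oy[i], box);
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 < best) best = d2;
        }
      }
    }
    return best;
  }
};

// Brownian tracers among reflecting disc obstacles with optional
// reduced-diffusivity annuli, motion blur and localization noise.
// Coordinates in um, times in s. Returns unwrapped frame positions.
// [[Rcpp::export]]
List cpp_simulate_tracers(NumericVector ox, NumericVector oy,
                          double core_r, double nerd_w, double nerd_f,
                          double box, double D, double dt,
                          int steps_per_frame, int blur_steps,
                          int n_frames, int n_tracers, double sigma) {
  if (blur_steps < 1) blur_steps = 1;
  if (blur_steps > steps_per_frame) blur_steps = steps_per_frame;
  double r_int = core_r + nerd_w;
  ObstacleGrid grid(ox, oy, box, std::max(r_int, box / 64.0));
  double sl = std::sqrt(2.0 * D * dt);
  double core2 = core_r * core_r;
  double ann2 = r_int * r_int;
  double sf = std::sqrt(std::max(0.0, nerd_f));

  NumericMatrix X(n_frames, n_tracers), Y(n_frames, n_tracers);
  NumericMatrix Xr(n_frames, n_tracers), Yr(n_frames, n_tracers);
  RNGScope scope;

  for (int tr = 0; tr < n_tracers; ++tr) {
    // start uniformly in free (non-core) space
    double xw = 0, yw = 0;
    bool placed = false;
    for (int tries = 0; tries < 10000; ++tries) {
      xw = unif_rand() * box;
      yw = unif_rand() * box;
      if (grid.nearest_sq(xw, yw) >= core2) { placed = true; break; }
    }
    if (!placed) stop("could not place tracer in free space; coverage too high");
    double xu = xw, yu = yw;  // unwrapped

    for (int f = 0; f < n_frames; ++f) {
      double bx = 0, by = 0;
      for (int s = 0; s < steps_per_frame; ++s) {
        if (s < blur_steps) { bx += xu; by += yu; }
        double scale = 1.0;
        if (nerd_w > 0) {
          double d2 = grid.nearest_sq(xw, yw);
          if (d2 <= ann2) scale = sf;  // position is never inside a core
        }
        double dx = scale * sl * norm_rand();
        double dy = scale * sl * norm_rand();
        double px = xw + dx, py = yw + dy;
        px -= box * std::floor(px / box);
        py -= box * std::floor(py / box);
        if (grid.nearest_sq(px, py) >= core2) {
          xw = px; yw = py; xu += dx; yu += dy;
        }
      }
      double mx = bx / blur_steps, my = by / blur_steps;
      Xr(f, tr) = mx; Yr(f, tr) = my;
      X(f, tr) = mx + (sigma > 0 ? sigma * norm_rand() : 0.0);
      Y(f, tr) = my + (sigma > 0 ? sigma * norm_rand() : 0.0);
    }
  }
  return List::create(_["x"] = X, _["y"] = Y,
                      _["x_raw"] = Xr, _["y_raw"] = Yr);
}

// Spanning test for overlapping discs of radius r in a [0,L]^2 box
// (free boundaries). Union-find over the disc overlap graph; a replicate
// spans if one cluster touches both the left and right edge, or both the
// bottom and top edge.
// [[Rcpp::export]]
bool cpp_discs_span(NumericVector x, NumericVector y, double r, double L) {
  int n = x.size();
  if (n == 0) return false;
  std::vector<int> parent(n), rank_(n, 0);
  std::vector<unsigned char> flag(n, 0);  // bits: 1=left 2=right 4=bottom 8=top
  for (int i = 0; i < n; ++i) {
    parent[i] = i;
    unsigned char fl = 0;
    if (x[i] - r <= 0) fl |= 1;
    if (x[i] + r >= L) fl |= 2;
    if (y[i] - r <= 0) fl |= 4;
    if (y[i] + r >= L) fl |= 8;
    flag[i] = fl;
  }
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  bool spans = false;
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    flag[a] |= flag[b];
    if (rank_[a] == rank_[b]) rank_[a]++;
    if (((flag[a] & 1) && (flag[a] & 2)) || ((flag[a] & 4) && (flag[a] & 8)))
      spans = true;
  };
  for (int i = 0; i < n; ++i) {
    int a = find(i);
    if (((flag[a] & 1) && (flag[a] & 2)) || ((flag[a] & 4) && (flag[a] & 8)))
      return true;
  }

  // grid with cell = 2r; overlap iff centre distance <= 2r
  double cell = 2.0 * r;
  int ncell = std::max(1, (int)std::floor(L / cell));
  ncell = std::min(ncell, 4096);
  cell = L / ncell;
  std::vector<std::vector<int>> bins(ncell * ncell);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncell - 1, (int)std::floor(x[i] / cell));
    int cy = std::min(ncell - 1, (int)std::floor(y[i] / cell));
    bins[cy * ncell + cx].push_back(i);
  }
  double r2 = 4.0 * r * r;
  for (int cy = 0; cy < ncell && !spans; ++cy) {
    for (int cx = 0; cx < ncell && !spans; ++cx) {
      const std::vector<int>& b = bins[cy * ncell + cx];
      for (size_t u = 0; u < b.size(); ++u) {
        int i = b[u];
        for (size_t v = u + 1; v < b.size(); ++v) {
          int j = b[v];
          double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy <= r2) unite(i, j);
        }
        // forward half-stencil of neighbour cells (no periodic wrap)
        static const int offs[4][2] = {{1, 0}, {-1, 1}, {0, 1}, {1, 1}};
        for (int k = 0; k < 4; ++k) {
          int gx = cx + offs[k][0], gy = cy + offs[k][1];
          if (gx < 0 || gx >= ncell || gy < 0 || gy >= ncell) continue;
          const std::vector<int>& nb = bins[gy * ncell + gx];
          for (size_t v = 0; v < nb.size(); ++v) {
            int j = nb[v];
            double dx = x[i] - x[j], dy = y[i] - y[j];
            if (dx * dx + dy * dy <= r2) unite(i, j);
          }
        }
        if (spans) break;
      }
    }
  }
  return spans;
}

static inline double model_ratio(double rho, double R, double cp) {
  double z = rho * M_PI * R * R * 1e-6 / cp;   // R in nm, rho in um^-2
  double inner = 1.0 - std::exp(-z);
  if (inner < 0) inner = 0;
  return 1.0 - std::sqrt(inner);
}

static double ssr_radius(const double* rho, const double* ratio, int n,
                         double R, double cp) {
  double s = 0;
  for (int i = 0; i < n; ++i) {
    double d = ratio[i] - model_ratio(rho[i], R, cp);
    s += d * d;
  }
  return s;
}

// Single-parameter least squares for the combined radius: coarse log-grid
// bracket followed by golden-section refinement.
static double fit_radius_one(const double* rho, const double* ratio, int n,
                             double cp, double lo, double hi) {
  const int ngrid = 60;
  double best = lo, bssr = R_PosInf;
  double llo = std::log(lo), lhi = std::log(hi);
  int bi = 0;
  for (int i = 0; i < ngrid; ++i) {
    double R = std::exp(llo + (lhi - llo) * i / (ngrid - 1.0));
    double s = ssr_radius(rho, ratio, n, R, cp);
    if (s < bssr) { bssr = s; best = R; bi = i; }
  }
  double a = std::exp(llo + (lhi - llo) * std::max(0, bi - 1) / (ngrid - 1.0));
  double b = std::exp(llo + (lhi - llo) * std::min(ngrid - 1, bi + 1) / (ngrid - 1.0));
  const double gr = 0.6180339887498949;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = ssr_radius(rho, ratio, n, x1, cp);
  double f2 = ssr_radius(rho, ratio, n, x2, cp);
  for (int it = 0; it < 70 && (b - a) > 1e-10; ++it) {
    if (f1 < f2) { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = ssr_radius(rho, ratio, n, x1, cp); }
    else { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = ssr_radius(rho, ratio, n, x2, cp); }
  }
  (void)best;
  return 0.5 * (a + b);
}

// [[Rcpp::export]]
List cpp_fit_radius(NumericVector rho, NumericVector ratio, double cp,
                    double lo, double hi) {
  int n = rho.size();
  double R = fit_radius_one(rho.begin(), ratio.begin(), n, cp, lo, hi);
  double s = ssr_radius(rho.begin(), ratio.begin(), n, R, cp);
  return List::create(_["R"] = R, _["ssr"] = s);
}

// Column-wise radius fits over many datasets (rows = cells, cols = datasets).
// [[Rcpp::export]]
NumericVector cpp_fit_radius_many(NumericMatrix rho, NumericMatrix ratio,
                                  double cp, double lo, double hi) {
  int n = rho.nrow(), m = rho.ncol();
  NumericVector out(m);
  std::vector<double> rr(n), yy(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) { rr[i] = rho(i, j); yy[i] = ratio(i, j); }
    out[j] = fit_radius_one(rr.data(), yy.data(), n, cp, lo, hi);
  }
  return out;
}
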