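#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement along one axis.
static inline double min_image(double dx, double box, bool periodic) {
  if (periodic) dx -= box * std::nearbyint(dx / box);
  return dx;
}

// Count particle centers inside a probe volume under the minimum-image
// convention.  shape: 0 = sphere (strict <), 1 = axis-aligned cuboid with
// half-open membership [-dim/2, dim/2) per axis.
static int count_probe(const NumericMatrix& coords,
                       const NumericVector& box,
                       const LogicalVector& periodic,
                       double cx, double cy, double cz,
                       int shape, double R,
                       const NumericVector& dims) {
  const int n = coords.nrow();
  int count = 0;
  const double R2 = R * R;
  for (int i = 0; i < n; ++i) {
    double dx = min_image(coords(i, 0) - cx, box[0], periodic[0]);
    double dy = min_image(coords(i, 1) - cy, box[1], periodic[1]);
    double dz = min_image(coords(i, 2) - cz, box[2], periodic[2]);
    if (shape == 0) {
      if (dx * dx + dy * dy + dz * dz < R2) ++count;
    } else {
      if (dx >= -dims[0] / 2 && dx < dims[0] / 2 &&
          dy >= -dims[1] / 2 && dy < dims[1] / 2 &&
          dz >= -dims[2] / 2 && dz < dims[2] / 2) ++count;
    }
  }
  return count;
}

// [[Rcpp::export]]
int cpp_count_occupancy(NumericMatrix coords, NumericVector box,
                        LogicalVector periodic, NumericVector center,
                        int shape, double R, NumericVector dims) {
  return count_probe(coords, box, periodic,
                     center[0], center[1], center[2], shape, R, dims);
}

// Random probe insertions into one configuration.  Centers are uniform in
// the box; when fixed_z is true the z coordinate is pinned to z_center
// (cuboid placement at a set distance from a surface).  Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_sample_config(NumericMatrix coords, NumericVector box,
                                LogicalVector periodic, int shape, double R,
                                NumericVector dims, int n_insert,
                                bool fixed_z, double z_center) {
  IntegerVector out(n_insert);
  for (int k = 0; k < n_insert; ++k) {
    double cx = unif_rand() * box[0];
    double cy = unif_rand() * box[1];
    double cz = fixed_z ? z_center : unif_rand() * box[2];
    out[k] = count_probe(coords, box, periodic, cx, cy, cz, shape, R, dims);
  }
  return out;
}

// Monte Carlo estimate of the pair-overlap probability inside a sphere:
// two independent uniform points in a sphere of radius R, count pairs with
// separation < d.  Brute-force oracle for the fluctuation integral with a
// step pair correlation function.
// [[Rcpp::export]]
double cpp_pair_dist_lt(double R, double d, int n_samples) {
  const double d2 = d * d, R2 = R * R;
  long hits = 0;
  double p[6];
  for (int k = 0; k < n_samples; ++k) {
    for (int j = 0; j < 2; ++j) {  // rejection-sample a point in the sphere
      for (;;) {
        double x = (2 * unif_rand() - 1) * R;
        double y = (2 * unif_rand() - 1) * R;
        double z = (2 * unif_rand() - 1) * R;
        if (x * x + y * y + z * z < R2) {
          p[3 * j] = x; p[3 * j + 1] = y; p[3 * j + 2] = z;
          break;
        }
      }
    }
    double dx = p[0] - p[3], dy = p[1] - p[4], dz = p[2] - p[5];
    if (dx * dx + dy * dy + dz * dz < d2) ++hits;
  }
  return (double)hits;
}

// Overlap test for particle i at trial position (x, y, z) against all other
// particles, hard-core diameter 1, cubic periodic box of edge L.
static bool overlaps(const NumericMatrix& x, int i, double xi, double yi,
                     double zi, double L, int N) {
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    double dx = xi - x(j, 0); dx -= L * std::nearbyint(dx / L);
    double dy = yi - x(j, 1); dy -= L * std::nearbyint(dy / L);
    double dz = zi - x(j, 2); dz -= L * std::nearbyint(dz / L);
    if (dx * dx + dy * dy + dz * dz < 1.0) return true;
  }
  return false;
}

// Metropolis hard-sphere fluid (diameter 1) in a cubic periodic box.
// Starts from an fcc lattice, auto-tunes the displacement step toward the
// target acceptance during equilibration only, then freezes it.  Emits
// n_configs configurations spaced by sweeps_between sweeps.
// [[Rcpp::export]]
List cpp_hs_mc(int N, double L, int n_configs, int n_equil,
               int sweeps_between, double step0, double target_acc) {
  // fcc initialization: m^3 cells, 4 sites each
  int m = (int)std::ceil(std::cbrt(N / 4.0));
  double a = L / m;
  NumericMatrix x(N, 3);
  {
    int idx = 0;
    const double basis[4][3] = {{0.25, 0.25, 0.25}, {0.75, 0.75, 0.25},
                                {0.75, 0.25, 0.75}, {0.25, 0.75, 0.75}};
    for (int i = 0; i < m && idx < N; ++i)
      for (int j = 0; j < m && idx < N; ++j)
        for (int k = 0; k < m && idx < N; ++k)
          for (int b = 0; b < 4 && idx < N; ++b) {
            x(idx, 0) = (i + basis[b][0]) * a;
            x(idx, 1) = (j + basis[b][1]) * a;
            x(idx, 2) = (k + basis[b][2]) * a;
            ++idx;
          }
  }
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = x(i,0)-x(j,0); dx -= L * std::nearbyint(dx / L);
      double dy = x(i,1)-x(j,1); dy -= L * std::nearbyint(dy / L);
      double dz = x(i,2)-x(j,2); dz -= L * std::nearbyint(dz / L);
      if (dx*dx + dy*dy + dz*dz < 1.0)
        stop("hs_monte_carlo: fcc initialization overlaps; eta too high");
    }

  double step = step0;
  long acc = 0, tot = 0;
  List configs(n_configs);
  int emitted = 0;
  long total_sweeps = (long)n_equil + (long)n_configs * sweeps_between;
  for (long sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int mv = 0; mv < N; ++mv) {
      int i = (int)(unif_rand() * N);
      if (i == N) i = N - 1;
      double xi = x(i, 0) + (unif_rand() - 0.5) * step;
      double yi = x(i, 1) + (unif_rand() - 0.5) * step;
      double zi = x(i, 2) + (unif_rand() - 0.5) * step;
      xi -= L * std::floor(xi / L);
      yi -= L * std::floor(yi / L);
      zi -= L * std::floor(zi / L);
      ++tot;
      if (!overlaps(x, i, xi, yi, zi, L, N)) {
        x(i, 0) = xi; x(i, 1) = yi; x(i, 2) = zi;
        ++acc;
      }
    }
    // step auto-tune during equilibration only, every 50 sweeps:
    // multiplicative update by the clipped acceptance ratio
    if (sweep < n_equil && (sweep + 1) % 50 == 0) {
      double r = (double)acc / (double)tot;
      double f = r / target_acc;
      if (f < 0.5) f = 0.5;
      if (f > 2.0) f = 2.0;
      step = std::min(step * f, L / 2);
      acc = 0; tot = 0;
    }
    if (sweep == n_equil - 1) { acc = 0; tot = 0; }  // reset for production
    if (sweep >= n_equil &&
        ((sweep - n_equil + 1) % sweeps_between == 0) && emitted < n_configs) {
      configs[emitted++] = clone(x);
    }
  }
  double acc_ratio = tot > 0 ? (double)acc / (double)tot : NA_REAL;
  return List::create(_["configs"] = configs, _["step"] = step,
                      _["acceptance"] = acc_ratio);
}

// Exhaustive minimum pair distance under the minimum-image convention.
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix coords, NumericVector box,
                         LogicalVector periodic) {
  const int n = coords.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(coords(i,0) - coords(j,0), box[0], periodic[0]);
      double dy = min_image(coords(i,1) - coords(j,1), box[1], periodic[1]);
      double dz = min_image(coords(i,2) - coords(j,2), box[2], periodic[2]);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < best) best = d;
    }
  return best;
}
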