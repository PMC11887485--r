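#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// Test points on each atom's expanded sphere (r_i + probe) are placed on a
// Fibonacci lattice; a point is accessible if it lies outside every other
// atom's expanded sphere. SASA_i = accessible fraction * 4*pi*(r_i+probe)^2.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // Fibonacci sphere directions
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    sx[k] = rho * std::cos(th);
    sy[k] = rho * std::sin(th);
    sz[k] = z;
  }

  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> nb;
  nb.reserve(n);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = er[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double lim = ri + er[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + ri * sx[k], py = yi + ri * sy[k], pz = zi + ri * sz[k];
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        double dx = px - coords(j, 0), dy = py - coords(j, 1),
               dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * (double)acc / n_points;
  }
  return out;
}
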