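#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.  Each atom sphere of
// radius r_i + probe is sampled at n_points quasi-uniform points (Fibonacci
// lattice); a point is accessible when it lies outside every other atom's
// probe-expanded sphere.  ASA_i = 4*pi*(r_i+probe)^2 * accessible/n_points.
//
// `coords`/`radii` are the atoms whose ASA is reported; `occ_coords`/
// `occ_radii` are additional occluders (e.g. the other chains of a complex)
// that block solvent but get no ASA of their own.

// [[Rcpp::export]]
NumericVector shrake_rupley_cpp(NumericMatrix coords, NumericVector radii,
                                NumericMatrix occ_coords,
                                NumericVector occ_radii, double probe,
                                int n_points) {
  int n = coords.nrow();
  int n_occ = occ_coords.nrow();
  NumericVector asa(n);

  // Fibonacci sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rr = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    px[k] = std::cos(phi) * rr;
    py[k] = std::sin(phi) * rr;
    pz[k] = z;
  }

  int n_all = n + n_occ;
  std::vector<double> ax(n_all), ay(n_all), az(n_all), ar(n_all);
  for (int i = 0; i < n; ++i) {
    ax[i] = coords(i, 0); ay[i] = coords(i, 1); az[i] = coords(i, 2);
    ar[i] = radii[i];
  }
  for (int i = 0; i < n_occ; ++i) {
    ax[n + i] = occ_coords(i, 0); ay[n + i] = occ_coords(i, 1);
    az[n + i] = occ_coords(i, 2); ar[n + i] = occ_radii[i];
  }

  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    double Ri = radii[i] + probe;
    nb.clear();
    for (int j = 0; j < n_all; ++j) {
      if (j == i) continue;
      double dx = ax[j] - ax[i], dy = ay[j] - ay[i], dz = az[j] - az[i];
      double cut = Ri + ar[j] + probe;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double sx = ax[i] + Ri * px[k];
      double sy = ay[i] + Ri * py[k];
      double sz = az[i] + Ri * pz[k];
      bool blocked = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        double dx = sx - ax[j], dy = sy - ay[j], dz = sz - az[j];
        double Rj = ar[j] + probe;
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) {
          blocked = true;
          break;
        }
      }
      if (!blocked) ++acc;
    }
    asa[i] = 4.0 * M_PI * Ri * Ri * (double)acc / n_points;
  }
  return asa;
}
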