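// Pharmacophore voxelization: occupancy of voxel center v for an atom at
// distance r with van der Waals radius rvdw is 1 - exp(-(rvdw/r)^12),
// aggregated per channel by the maximum over the atoms carrying that flag.
// Contributions below 1e-13 are skipped; because channels aggregate by
// maximum (not sum), the result differs from a naive per-voxel / per-atom
// double loop by at most 1e-13 per voxel.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector voxelize_cpp(NumericMatrix coords, NumericVector radii,
                           LogicalMatrix flags, NumericVector origin,
                           int edge_voxels, double resolution) {
  const int natoms = coords.nrow();
  const int nchan = flags.ncol();
  const int E = edge_voxels;
  NumericVector out(nchan * E * E * E);  // index c + C*(x + E*(y + E*z))
  std::vector<double> centers(E);
  for (int i = 0; i < E; ++i) centers[i] = (i + 0.5) * resolution;

  for (int a = 0; a < natoms; ++a) {
    const double ax = coords(a, 0) - origin[0];
    const double ay = coords(a, 1) - origin[1];
    const double az = coords(a, 2) - origin[2];
    const double rv = radii[a];
    // occupancy < 1e-13 beyond this squared distance: (rv^2/r^2)^6 < 1e-13
    const double cut2 = rv * rv * std::pow(1e-13, -1.0 / 6.0);
    std::vector<int> chans;
    for (int c = 0; c < nchan; ++c) if (flags(a, c)) chans.push_back(c);
    if (chans.empty()) continue;
    for (int z = 0; z < E; ++z) {
      const double dz = centers[z] - az;
      for (int y = 0; y < E; ++y) {
        const double dy = centers[y] - ay;
        const double d2yz = dy * dy + dz * dz;
        for (int x = 0; x < E; ++x) {
          const double dx = centers[x] - ax;
          const double r2 = dx * dx + d2yz;
          if (r2 > cut2) continue;
          double occ;
          if (r2 == 0.0) {
            occ = 1.0;  // limit of 1 - exp(-(rvdw/r)^12) as r -> 0
          } else {
            const double t2 = rv * rv / r2;
            const double t6 = t2 * t2 * t2;
            occ = 1.0 - std::exp(-(t6 * t6));
          }
          const int base = nchan * (x + E * (y + E * z));
          for (size_t ci = 0; ci < chans.size(); ++ci) {
            double& cur = out[base + chans[ci]];
            if (occ > cur) cur = occ;
          }
        }
      }
    }
  }
  return out;
}
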