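// Mass-averaged SAR by cube growing on a rectilinear grid.
//
// For every tissue cell the smallest centred cube (in physical mm, measured
// by per-axis distance between cell centres) whose enclosed tissue mass
// reaches the target is found by expanding index ranges one step at a time,
// always extending towards the nearest not-yet-included cell-centre plane.
// Enclosed mass/power are O(1) queries on 3D prefix sums.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cube_avg_sar_cpp")]]
List cube_avg_sar_cpp(IntegerVector dims,
                      NumericVector cx, NumericVector cy, NumericVector cz,
                      NumericVector mass, NumericVector power,
                      IntegerVector tissue, double target_mass) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  auto id = [&](int i, int j, int k) { return (size_t)i + (size_t)nx * (j + (size_t)ny * k); };

  // inclusive 3D prefix sums, padded by one plane of zeros
  const int px = nx + 1, py = ny + 1, pz = nz + 1;
  std::vector<double> Pm((size_t)px * py * pz, 0.0), Pw((size_t)px * py * pz, 0.0);
  auto pid = [&](int i, int j, int k) { return (size_t)i + (size_t)px * (j + (size_t)py * k); };
  for (int k = 1; k < pz; ++k)
    for (int j = 1; j < py; ++j)
      for (int i = 1; i < px; ++i) {
        size_t c = id(i - 1, j - 1, k - 1);
        Pm[pid(i,j,k)] = mass[c] + Pm[pid(i-1,j,k)] + Pm[pid(i,j-1,k)] + Pm[pid(i,j,k-1)]
          - Pm[pid(i-1,j-1,k)] - Pm[pid(i-1,j,k-1)] - Pm[pid(i,j-1,k-1)] + Pm[pid(i-1,j-1,k-1)];
        Pw[pid(i,j,k)] = power[c] + Pw[pid(i-1,j,k)] + Pw[pid(i,j-1,k)] + Pw[pid(i,j,k-1)]
          - Pw[pid(i-1,j-1,k)] - Pw[pid(i-1,j,k-1)] - Pw[pid(i,j-1,k-1)] + Pw[pid(i-1,j-1,k-1)];
      }
  auto boxsum = [&](const std::vector<double> &P, int i0, int i1, int j0, int j1, int k0, int k1) {
    return P[pid(i1+1,j1+1,k1+1)] - P[pid(i0,j1+1,k1+1)] - P[pid(i1+1,j0,k1+1)] - P[pid(i1+1,j1+1,k0)]
         + P[pid(i0,j0,k1+1)] + P[pid(i0,j1+1,k0)] + P[pid(i1+1,j0,k0)] - P[pid(i0,j0,k0)];
  };

  NumericVector avg(n, NA_REAL);
  LogicalVector valid(n, false);
  for (int k0 = 0; k0 < nz; ++k0)
    for (int j0 = 0; j0 < ny; ++j0)
      for (int i0 = 0; i0 < nx; ++i0) {
        size_t c = id(i0, j0, k0);
        if (!tissue[c]) continue;
        int ilo = i0, ihi = i0, jlo = j0, jhi = j0, klo = k0, khi = k0;
        double m = boxsum(Pm, ilo, ihi, jlo, jhi, klo, khi);
        const double x0 = cx[i0], y0 = cy[j0], z0 = cz[k0];
        while (m < target_mass) {
          // candidate expansion distances (centre-to-centre, per axis)
          double dbest = R_PosInf; int which = -1;
          if (ilo > 0     && x0 - cx[ilo-1] < dbest) { dbest = x0 - cx[ilo-1]; which = 0; }
          if (ihi < nx-1  && cx[ihi+1] - x0 < dbest) { dbest = cx[ihi+1] - x0; which = 1; }
          if (jlo > 0     && y0 - cy[jlo-1] < dbest) { dbest = y0 - cy[jlo-1]; which = 2; }
          if (jhi < ny-1  && cy[jhi+1] - y0 < dbest) { dbest = cy[jhi+1] - y0; which = 3; }
          if (klo > 0     && z0 - cz[klo-1] < dbest) { dbest = z0 - cz[klo-1]; which = 4; }
          if (khi < nz-1  && cz[khi+1] - z0 < dbest) { dbest = cz[khi+1] - z0; which = 5; }
          if (which < 0) break; // cube covers the whole grid
          // include every cell whose centre lies within dbest on any axis
          // (ties expand symmetrically so the region stays a centred cube)
          const double eps = dbest * (1.0 + 1e-12);
          while (ilo > 0    && x0 - cx[ilo-1] <= eps) --ilo;
          while (ihi < nx-1 && cx[ihi+1] - x0 <= eps) ++ihi;
          while (jlo > 0    && y0 - cy[jlo-1] <= eps) --jlo;
          while (jhi < ny-1 && cy[jhi+1] - y0 <= eps) ++jhi;
          while (klo > 0    && z0 - cz[klo-1] <= eps) --klo;
          while (khi < nz-1 && cz[khi+1] - z0 <= eps) ++khi;
          m = boxsum(Pm, ilo, ihi, jlo, jhi, klo, khi);
        }
        if (m >= target_mass && m > 0) {
          double w = boxsum(Pw, ilo, ihi, jlo, jhi, klo, khi);
          avg[c] = w / m;
          valid[c] = true;
        }
      }
  return List::create(_["avg"] = avg, _["valid"] = valid);
}
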