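#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Neighbour-count tabulation for the Strauss interaction integral.
//
// The integral of gamma^t(u) over the window decomposes as
//   |W| + sum_i int_{disk_i cap W} (gamma^t(u) - 1) / t(u) du,
// because the region where t(u) = k is covered by exactly k of the radius-r
// disks centred on the data points. Each disk is sampled at fixed unit-disk
// locations v_m scaled by r: u = x_i + r v_m. For such a moving sample,
// "x_j lies within r of u" holds for all r beyond a single entry radius
// (the positive root of a quadratic in r), and the sample stays inside the
// window up to a single exit radius, so the neighbour count along the whole
// radius grid is a cheap sweep over sorted entry radii.
//
// Returns a K x (Tmax + 1) matrix km: km(k, t) = number of in-window
// samples with neighbour count exactly t at radius r_grid[k] (t >= 1 since
// a sample in disk_i always has x_i within r).
// [[Rcpp::export]]
NumericMatrix strauss_disk_counts_cpp(NumericMatrix pts, NumericVector vx,
                                      NumericVector vy, double wx, double wy,
                                      NumericVector r_grid) {
  const int n = pts.nrow(), M = vx.size(), K = r_grid.size();
  const double rmax = r_grid[K - 1];
  int tcap = 8;  // grown on demand
  std::vector<double> counts((size_t)K * (tcap + 1), 0.0);

  std::vector<double> entries;
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1);
    for (int m = 0; m < M; ++m) {
      const double vxm = vx[m], vym = vy[m];
      const double c = vxm * vxm + vym * vym;  // |v|^2 < 1
      // exit radius: u = x_i + r v leaves the window
      double r_exit = rmax + 1.0;
      if (vxm > 0) r_exit = std::min(r_exit, (wx - xi) / vxm);
      if (vxm < 0) r_exit = std::min(r_exit, -xi / vxm);
      if (vym > 0) r_exit = std::min(r_exit, (wy - yi) / vym);
      if (vym < 0) r_exit = std::min(r_exit, -yi / vym);
      // grid indices with r < r_exit
      int kend = (int)(std::lower_bound(r_grid.begin(), r_grid.end(), r_exit) -
                       r_grid.begin());
      if (kend == 0) continue;
      entries.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dx = xi - pts(j, 0), dy = yi - pts(j, 1);
        const double w2 = dx * dx + dy * dy;
        if (w2 >= 4.0 * rmax * rmax) continue;  // cannot enter within grid
        const double b = dx * vxm + dy * vym;
        const double rstar = (b + std::sqrt(b * b + (1.0 - c) * w2)) / (1.0 - c);
        if (rstar < rmax) entries.push_back(rstar);
      }
      std::sort(entries.begin(), entries.end());
      int ei = 0;
      const int ne = (int)entries.size();
      for (int k = 0; k < kend; ++k) {
        const double rk = r_grid[k];
        while (ei < ne && entries[ei] < rk) ++ei;
        const int t = 1 + ei;
        if (t > tcap) {
          const int newcap = std::max(t, 2 * tcap);
          std::vector<double> bigger((size_t)K * (newcap + 1), 0.0);
          for (int kk = 0; kk < K; ++kk)
            for (int tt = 0; tt <= tcap; ++tt)
              bigger[(size_t)kk * (newcap + 1) + tt] =
                  counts[(size_t)kk * (tcap + 1) + tt];
          counts.swap(bigger);
          tcap = newcap;
        }
        counts[(size_t)k * (tcap + 1) + t] += 1.0;
      }
    }
  }

  NumericMatrix out(K, tcap + 1);
  for (int k = 0; k < K; ++k)
    for (int t = 0; t <= tcap; ++t)
      out(k, t) = counts[(size_t)k * (tcap + 1) + t];
  return out;
}
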