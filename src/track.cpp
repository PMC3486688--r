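#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Probabilistic streamline propagation on a voxel grid. Positions are in
// continuous voxel units (0-based corners); the voxel containing p is
// floor(p). Uses R's RNG so results are reproducible via set.seed().

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 normalize(const Vec3& v) {
  double n = std::sqrt(v.x * v.x + v.y * v.y + v.z * v.z);
  Vec3 o = {0, 0, 0};
  if (n > 0) {
    o.x = v.x / n;
    o.y = v.y / n;
    o.z = v.z / n;
  }
  return o;
}

inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// orthonormal basis perpendicular to u
inline void perp_basis(const Vec3& u, Vec3& a, Vec3& b) {
  Vec3 t = std::fabs(u.x) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
  a = {u.y * t.z - u.z * t.y, u.z * t.x - u.x * t.z, u.x * t.y - u.y * t.x};
  a = normalize(a);
  b = {u.y * a.z - u.z * a.y, u.z * a.x - u.x * a.z, u.x * a.y - u.y * a.x};
}

}  // namespace

// [[Rcpp::export]]
List track_cpp(IntegerVector dims, NumericMatrix e1, NumericVector fa,
               NumericMatrix dir2, NumericVector frac2, IntegerVector seed_idx,
               List waypoints, List exclusions, int samples_per_voxel,
               double step_vox, int max_steps, double cos_curv, double kappa,
               double fa_stop) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long V = (long long)nx * ny * nz;
  const bool has2 = dir2.nrow() > 0 && frac2.size() == V;

  std::vector<LogicalVector> wps, exs;
  for (int i = 0; i < waypoints.size(); ++i)
    wps.push_back(as<LogicalVector>(waypoints[i]));
  for (int i = 0; i < exclusions.size(); ++i)
    exs.push_back(as<LogicalVector>(exclusions[i]));

  NumericVector counts(V);
  std::vector<int> stamp(V, -1);
  std::vector<long long> visited;
  visited.reserve(4 * max_steps);

  long long n_ret = 0, n_exc = 0, n_way = 0, n_launched = 0;
  RNGScope scope;

  for (int si = 0; si < seed_idx.size(); ++si) {
    long long sv = seed_idx[si];
    int sx = (int)(sv % nx), sy = (int)((sv / nx) % ny), sz = (int)(sv / ((long long)nx * ny));
    for (int s = 0; s < samples_per_voxel; ++s) {
      ++n_launched;
      int id = (int)(n_launched % 2147483647);
      visited.clear();
      Vec3 p0 = {sx + unif_rand(), sy + unif_rand(), sz + unif_rand()};
      if (stamp[sv] != id) {
        stamp[sv] = id;
        visited.push_back(sv);
      }
      Vec3 ax0 = {e1(sv, 0), e1(sv, 1), e1(sv, 2)};
      for (int halfdir = 0; halfdir < 2; ++halfdir) {
        Vec3 prev = halfdir == 0 ? ax0 : Vec3{-ax0.x, -ax0.y, -ax0.z};
        Vec3 p = p0;
        for (int st = 0; st < max_steps; ++st) {
          int vx = (int)std::floor(p.x), vy = (int)std::floor(p.y),
              vz = (int)std::floor(p.z);
          if (vx < 0 || vy < 0 || vz < 0 || vx >= nx || vy >= ny || vz >= nz)
            break;
          long long v = vx + (long long)nx * (vy + (long long)ny * vz);
          if (fa[v] < fa_stop) break;
          Vec3 axis;
          if (has2 && frac2[v] > 0 && unif_rand() < frac2[v]) {
            axis = {dir2(v, 0), dir2(v, 1), dir2(v, 2)};
          } else {
            axis = {e1(v, 0), e1(v, 1), e1(v, 2)};
          }
          if (dot(axis, prev) < 0) {
            axis.x = -axis.x;
            axis.y = -axis.y;
            axis.z = -axis.z;
          }
          Vec3 dir = axis;
          if (kappa > 0) {
            double keff = kappa * std::max(fa[v], 0.05);
            double sigma = 1.0 / std::sqrt(keff);
            Vec3 a, b;
            perp_basis(axis, a, b);
            double g1 = norm_rand() * sigma, g2 = norm_rand() * sigma;
            dir = {axis.x + g1 * a.x + g2 * b.x, axis.y + g1 * a.y + g2 * b.y,
                   axis.z + g1 * a.z + g2 * b.z};
            dir = normalize(dir);
          }
          if (dot(dir, prev) < cos_curv) break;
          p.x += dir.x * step_vox;
          p.y += dir.y * step_vox;
          p.z += dir.z * step_vox;
          prev = dir;
          int wx = (int)std::floor(p.x), wy = (int)std::floor(p.y),
              wz = (int)std::floor(p.z);
          if (wx < 0 || wy < 0 || wz < 0 || wx >= nx || wy >= ny || wz >= nz)
            break;
          long long w = wx + (long long)nx * (wy + (long long)ny * wz);
          if (stamp[w] != id) {
            stamp[w] = id;
            visited.push_back(w);
          }
        }
      }
      bool excluded = false;
      for (size_t e = 0; e < exs.size() && !excluded; ++e)
        for (size_t j = 0; j < visited.size(); ++j)
          if (exs[e][visited[j]]) {
            excluded = true;
            break;
          }
      if (excluded) {
        ++n_exc;
        continue;
      }
      bool all_wp = true;
      for (size_t wpi = 0; wpi < wps.size() && all_wp; ++wpi) {
        bool hit = false;
        for (size_t j = 0; j < visited.size(); ++j)
          if (wps[wpi][visited[j]]) {
            hit = true;
            break;
          }
        if (!hit) all_wp = false;
      }
      if (!all_wp) {
        ++n_way;
        continue;
      }
      ++n_ret;
      for (size_t j = 0; j < visited.size(); ++j) counts[visited[j]] += 1.0;
    }
  }
  return List::create(Named("counts") = counts, Named("n_launched") = (double)n_launched,
                      Named("n_retained") = (double)n_ret,
                      Named("n_rejected_exclusion") = (double)n_exc,
                      Named("n_failed_waypoint") = (double)n_way);
}
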