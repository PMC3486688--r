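#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Threshold-free cluster enhancement over an arbitrary voxel subset.
// coords are 0-based (n x 3); connectivity is the 26-neighborhood
// restricted to the supplied voxels (which is the natural skeleton
// neighborhood when the subset is a skeleton).
// [[Rcpp::export]]
NumericVector tfce_enhance_cpp(NumericVector values, IntegerMatrix coords,
                               IntegerVector dims, double H, double E,
                               double dh) {
  const int n = values.size();
  NumericVector out(n);
  if (n == 0) return out;
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) if (values[i] > hmax) hmax = values[i];
  if (hmax <= 0.0 || dh <= 0.0) return out;

  const long long nx = dims[0], ny = dims[1];
  std::unordered_map<long long, int> vox;
  vox.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    long long key = coords(i, 0) + nx * (coords(i, 1) + ny * (long long)coords(i, 2));
    vox[key] = i;
  }
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          long long x = coords(i, 0) + dx, y = coords(i, 1) + dy,
                    z = coords(i, 2) + dz;
          if (x < 0 || y < 0 || z < 0 || x >= dims[0] || y >= dims[1] ||
              z >= dims[2])
            continue;
          std::unordered_map<long long, int>::iterator it =
              vox.find(x + nx * (y + ny * z));
          if (it != vox.end()) nb[i].push_back(it->second);
        }
  }

  std::vector<int> comp(n), stack;
  std::vector<int> members;
  for (double h = dh; h <= hmax + 1e-12; h += dh) {
    std::fill(comp.begin(), comp.end(), -1);
    for (int s = 0; s < n; ++s) {
      if (values[s] < h || comp[s] >= 0) continue;
      // flood fill one component
      members.clear();
      stack.clear();
      stack.push_back(s);
      comp[s] = s;
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        members.push_back(v);
        const std::vector<int>& nbr = nb[v];
        for (size_t j = 0; j < nbr.size(); ++j) {
          int w = nbr[j];
          if (values[w] >= h && comp[w] < 0) {
            comp[w] = s;
            stack.push_back(w);
          }
        }
      }
      double add = std::pow(h, H) * std::pow((double)members.size(), E) * dh;
      for (size_t j = 0; j < members.size(); ++j) out[members[j]] += add;
    }
  }
  return out;
}
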