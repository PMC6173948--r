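// Connected-component labelling of a 3D integer label volume under
// 6/18/26-connectivity, one label at a time (components never bridge labels).
#include <Rcpp.h>
#include <vector>

// [[Rcpp::export(name = ".label_components_cpp")]]
Rcpp::IntegerVector label_components_cpp(Rcpp::IntegerVector vol,
                                         Rcpp::IntegerVector dims,
                                         int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ntot = nx * ny * nz;

  // neighbourhood offsets: 6 = faces, 18 = + edges, 26 = + corners
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  Rcpp::IntegerVector comp(ntot, 0);
  int next_id = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < ntot; ++idx) {
    if (vol[idx] == 0 || comp[idx] != 0) continue;
    const int lab = vol[idx];
    comp[idx] = ++next_id;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur / (nx * ny);
      int cy = (cur - cz * nx * ny) / nx;
      int cx = cur - cz * nx * ny - cy * nx;
      for (const auto& o : offs) {
        int x = cx + o[0], y = cy + o[1], z = cz + o[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int nidx = x + nx * (y + ny * z);
        if (vol[nidx] == lab && comp[nidx] == 0) {
          comp[nidx] = next_id;
          stack.push_back(nidx);
        }
      }
    }
  }
  return comp;
}
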