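#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected flood fill seeded from every boundary voxel, restricted to
// voxels flagged fillable. Used to separate external air (reachable from the
// volume boundary) from enclosed cavities, which must stay untouched.
// [[Rcpp::export]]
LogicalVector flood_from_boundary(LogicalVector fillable, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (fillable.size() != n) stop("fillable length does not match dims");
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1 << 16);
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
  };
  auto push = [&](int i, int j, int k) {
    R_xlen_t id = idx(i, j, k);
    if (!seen[id] && fillable[id]) { seen[id] = 1; stack.push_back(id); }
  };
  for (int j = 0; j < ny; ++j)
    for (int k = 0; k < nz; ++k) { push(0, j, k); push(nx - 1, j, k); }
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) { push(i, 0, k); push(i, ny - 1, k); }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) { push(i, j, 0); push(i, j, nz - 1); }
  while (!stack.empty()) {
    R_xlen_t id = stack.back();
    stack.pop_back();
    int i = (int)(id % nx);
    R_xlen_t r = id / nx;
    int j = (int)(r % ny);
    int k = (int)(r / ny);
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = seen[t] != 0;
  return out;
}
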