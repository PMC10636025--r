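#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdlib>
using namespace Rcpp;

// Connected-component labeling of a 3-D logical grid by iterative BFS.
// Labels are assigned in first-encounter (column-major) order, starting at 1.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const R_xlen_t nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        std::array<int, 3> o = {{dx, dy, dz}};
        offs.push_back(o);
      }

  std::vector<R_xlen_t> stack;
  int lab = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == NA_LOGICAL) stop("mask contains NA");
    if (!mask[i] || labels[i]) continue;
    ++lab;
    labels[i] = lab;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      R_xlen_t x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
      for (size_t k = 0; k < offs.size(); ++k) {
        R_xlen_t X = x + offs[k][0], Y = y + offs[k][1], Z = z + offs[k][2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t j = Z * nx * ny + Y * nx + X;
        if (mask[j] && !labels[j]) {
          labels[j] = lab;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = lab;
  return labels;
}
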