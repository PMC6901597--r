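#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical mask by iterative flood fill.
// Pixels are scanned in raster order (top-left origin, row by row), so
// component k's first-visited pixel is the k-th anchor pixel in raster
// order; labels are therefore already numbered the way downstream object
// tables expect.  An explicit stack replaces recursion so arbitrarily
// large blobs cannot overflow the call stack.
//
// `mask` is a logical matrix (nrow = height, ncol = width, column-major).
// Returns an integer matrix of the same shape: 0 = background, 1..n
// component ids.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int dy4[4] = {-1, 0, 0, 1};
  const int *dx = connectivity == 8 ? dx8 : dx4;
  const int *dy = connectivity == 8 ? dy8 : dy4;
  const int nn = connectivity;
  std::vector<int> stack;
  int next = 0;
  for (int y = 0; y < h; ++y) {       // raster order: y outer, x inner
    for (int x = 0; x < w; ++x) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      stack.clear();
      stack.push_back(y + x * h);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cy = idx % h, cx = idx / h;
        for (int k = 0; k < nn; ++k) {
          int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          if (mask(ny, nx) && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back(ny + nx * h);
          }
        }
      }
    }
  }
  return lab;
}
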