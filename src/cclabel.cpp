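// Connected-component labelling of binary masks with selectable
// 4- or 8-connectivity (EBImage::bwlabel is fixed at 4).

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dh4[] = {-1, 1, 0, 0};
  const int dw4[] = {0, 0, -1, 1};
  const int dh8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dw8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dh = (connectivity == 4) ? dh4 : dh8;
  const int* dw = (connectivity == 4) ? dw4 : dw8;
  const int nd = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w)) continue;
      lab(h, w) = ++next;
      q.push(std::make_pair(h, w));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < nd; ++d) {
          const int hh = p.first + dh[d], ww = p.second + dw[d];
          if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
          if (!mask(hh, ww) || lab(hh, ww)) continue;
          lab(hh, ww) = next;
          q.push(std::make_pair(hh, ww));
        }
      }
    }
  return lab;
}
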