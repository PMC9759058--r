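#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a binary mask plus, per component, its
// pixel count, centroid and external boundary traced clockwise (Moore
// neighbor tracing with Jacob's stopping criterion). Coordinates in the
// returned structures are 0-based with x = column, y = row.
// [[Rcpp::export]]
List label_components_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> areas;
  std::vector<double> cxs, cys;

  // BFS labeling, 8-connectivity
  std::vector<std::pair<int, int> > stack;
  int nlab = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != 0 && labels(r, c) == 0) {
        ++nlab;
        int area = 0;
        double sx = 0.0, sy = 0.0;
        stack.clear();
        stack.push_back(std::make_pair(r, c));
        labels(r, c) = nlab;
        while (!stack.empty()) {
          const int pr = stack.back().first, pc = stack.back().second;
          stack.pop_back();
          ++area;
          sx += pc;
          sy += pr;
          for (int dy = -1; dy <= 1; ++dy) {
            for (int dx = -1; dx <= 1; ++dx) {
              if (dy == 0 && dx == 0) continue;
              const int qr = pr + dy, qc = pc + dx;
              if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
              if (mask(qr, qc) != 0 && labels(qr, qc) == 0) {
                labels(qr, qc) = nlab;
                stack.push_back(std::make_pair(qr, qc));
              }
            }
          }
        }
        areas.push_back(area);
        cxs.push_back(sx / area);
        cys.push_back(sy / area);
      }
    }
  }

  // external boundary per component, clockwise in screen coordinates
  // (y down): neighbor order E, SE, S, SW, W, NW, N, NE
  const int dyv[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dxv[8] = {1, 1, 0, -1, -1, -1, 0, 1};

  // start pixel per component: smallest row, then smallest column
  std::vector<int> sr(nlab, -1), sc(nlab, -1);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      const int l = labels(r, c);
      if (l > 0 && sr[l - 1] < 0) { sr[l - 1] = r; sc[l - 1] = c; }
    }

  List polys(nlab);
  for (int l = 0; l < nlab; ++l) {
    const int r0 = sr[l], c0 = sc[l];
    std::vector<int> px, py;
    px.push_back(c0);
    py.push_back(r0);
    if (areas[l] > 1) {
      // backtrack starts W of the start pixel (background by scan order)
      int cr = r0, cc = c0, br = r0, bc = c0 - 1;
      const int fbr = br, fbc = bc;
      const long maxIter = 4L * static_cast<long>(areas[l]) + 16L;
      for (long it = 0; it < maxIter; ++it) {
        // direction index of backtrack relative to current
        int db = 0;
        for (int k = 0; k < 8; ++k)
          if (cr + dyv[k] == br && cc + dxv[k] == bc) { db = k; break; }
        int found = -1;
        for (int k = 1; k <= 8; ++k) {
          const int d = (db + k) % 8;
          const int qr = cr + dyv[d], qc = cc + dxv[d];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (labels(qr, qc) == l + 1) { found = k; break; }
        }
        if (found < 0) break; // isolated pixel (cannot happen when area > 1)
        const int d = (db + found) % 8;
        const int pd = (db + found - 1) % 8;
        br = cr + dyv[pd];
        bc = cc + dxv[pd];
        cr = cr + dyv[d];
        cc = cc + dxv[d];
        if (cr == r0 && cc == c0 && br == fbr && bc == fbc) break;
        px.push_back(cc);
        py.push_back(cr);
      }
    }
    IntegerMatrix poly(px.size(), 2);
    for (size_t i = 0; i < px.size(); ++i) {
      poly(i, 0) = px[i];
      poly(i, 1) = py[i];
    }
    colnames(poly) = CharacterVector::create("x", "y");
    polys[l] = poly;
  }

  return List::create(
    _["labels"] = labels,
    _["area"] = wrap(areas),
    _["cx"] = wrap(cxs),
    _["cy"] = wrap(cys),
    _["polygon"] = polys);
}
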