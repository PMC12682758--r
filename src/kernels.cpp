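#include <Rcpp.h>
using namespace Rcpp;

// Sum of squared RGB differences between the known pixels of the patch at
// (pr, pc) and each candidate patch. 0-based row/col indices; candidates
// are patch centers whose full (2r+1)^2 patch lies inside the image and
// contains no unknown pixel (the caller guarantees this). Offsets of the
// target patch falling outside the image are skipped.
// [[Rcpp::export]]
NumericVector ssd_scan(NumericVector img, LogicalMatrix known,
                       int pr, int pc, int radius,
                       IntegerVector cand_r, IntegerVector cand_c) {
  IntegerVector dims = img.attr("dim");
  int H = dims[0], W = dims[1];
  int n = cand_r.size();
  NumericVector out(n);

  // collect known in-bounds offsets of the target patch once
  std::vector<int> offr, offc;
  std::vector<double> tval0, tval1, tval2;
  for (int dr = -radius; dr <= radius; ++dr) {
    for (int dc = -radius; dc <= radius; ++dc) {
      int r = pr + dr, c = pc + dc;
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      if (!known(r, c)) continue;
      int plane = H * W;
      offr.push_back(dr);
      offc.push_back(dc);
      tval0.push_back(img[r + H * c]);
      tval1.push_back(img[r + H * c + plane]);
      tval2.push_back(img[r + H * c + 2 * plane]);
    }
  }
  int m = offr.size();
  int plane = H * W;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    int qr = cand_r[i], qc = cand_c[i];
    for (int j = 0; j < m; ++j) {
      int idx = (qr + offr[j]) + H * (qc + offc[j]);
      double d0 = img[idx] - tval0[j];
      double d1 = img[idx + plane] - tval1[j];
      double d2 = img[idx + 2 * plane] - tval2[j];
      s += d0 * d0 + d1 * d1 + d2 * d2;
    }
    out[i] = s;
  }
  return out;
}

// 4-connected component labeling of a logical mask. Labels start at 1 in
// row-major discovery order; 0 marks background.
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
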