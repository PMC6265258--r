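#include <Rcpp.h>
using namespace Rcpp;

// Neighbourhood competition index: for each query point, sum over trees
// within `radius` of height_j / max(dist_j, dist_floor). Trees at exactly the
// query point (distance 0) are excluded, which also removes a tree from its
// own neighbourhood when trees are queried at their own coordinates.
// A uniform cell grid keeps the scan local; worst case degrades gracefully to
// the all-pairs sum.
// [[Rcpp::export]]
NumericVector cpp_nci(NumericVector tx, NumericVector ty, NumericVector th,
                      NumericVector qx, NumericVector qy,
                      double radius, double dist_floor) {
  const int nt = tx.size(), nq = qx.size();
  NumericVector out(nq);
  if (nt == 0 || nq == 0) return out;
  if (radius <= 0) stop("radius must be > 0");

  double xmin = tx[0], xmax = tx[0], ymin = ty[0], ymax = ty[0];
  for (int i = 1; i < nt; ++i) {
    if (tx[i] < xmin) xmin = tx[i];
    if (tx[i] > xmax) xmax = tx[i];
    if (ty[i] < ymin) ymin = ty[i];
    if (ty[i] > ymax) ymax = ty[i];
  }
  const double cell = radius;
  const int ncx = std::max(1, (int)((xmax - xmin) / cell) + 1);
  const int ncy = std::max(1, (int)((ymax - ymin) / cell) + 1);
  std::vector<std::vector<int> > bins((size_t)ncx * ncy);
  for (int i = 0; i < nt; ++i) {
    int cx = std::min(ncx - 1, (int)((tx[i] - xmin) / cell));
    int cy = std::min(ncy - 1, (int)((ty[i] - ymin) / cell));
    bins[(size_t)cx * ncy + cy].push_back(i);
  }
  const double r2 = radius * radius;
  for (int q = 0; q < nq; ++q) {
    double s = 0.0;
    int cx0 = (int)((qx[q] - xmin) / cell), cy0 = (int)((qy[q] - ymin) / cell);
    for (int cx = std::max(0, cx0 - 1); cx <= std::min(ncx - 1, cx0 + 1); ++cx)
      for (int cy = std::max(0, cy0 - 1); cy <= std::min(ncy - 1, cy0 + 1); ++cy) {
        const std::vector<int>& b = bins[(size_t)cx * ncy + cy];
        for (size_t k = 0; k < b.size(); ++k) {
          const int j = b[k];
          const double dx = tx[j] - qx[q], dy = ty[j] - qy[q];
          const double d2 = dx * dx + dy * dy;
          if (d2 == 0.0 || d2 > r2) continue;
          const double d = std::sqrt(d2);
          s += th[j] / std::max(d, dist_floor);
        }
      }
    out[q] = s;
  }
  return out;
}
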