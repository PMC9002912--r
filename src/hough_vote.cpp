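#include <Rcpp.h>
using namespace Rcpp;

// Accumulate circle-Hough votes for one radius: every edge pixel (ex, ey)
// votes for the centres (ex + dx, ey + dy) over the perimeter offset set.
// Coordinates are 0-based; the returned vector has nx * ny bins indexed
// cy * nx + cx.
// [[Rcpp::export(name = ".hough_vote")]]
IntegerVector hough_vote(IntegerVector ex, IntegerVector ey,
                         IntegerVector dx, IntegerVector dy,
                         int nx, int ny) {
  IntegerVector acc(nx * ny);
  const int ne = ex.size(), no = dx.size();
  for (int j = 0; j < no; ++j) {
    const int ox = dx[j], oy = dy[j];
    for (int i = 0; i < ne; ++i) {
      const int cx = ex[i] + ox;
      const int cy = ey[i] + oy;
      if (cx >= 0 && cx < nx && cy >= 0 && cy < ny)
        ++acc[cy * nx + cx];
    }
  }
  return acc;
}
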