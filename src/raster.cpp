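// Raster utilities: connected-component labeling and plateau-aware local
// maxima. Coordinates returned to R are 0-based (y, x).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

inline void neighbor_offsets(int connectivity, std::vector<int> &dy,
                             std::vector<int> &dx) {
  if (connectivity == 4) {
    dy = {-1, 1, 0, 0};
    dx = {0, 0, -1, 1};
  } else {
    dy = {-1, -1, -1, 0, 0, 1, 1, 1};
    dx = {-1, 0, 1, -1, 1, -1, 0, 1};
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix m, int connectivity) {
  int h = m.nrow(), w = m.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> dy, dx;
  neighbor_offsets(connectivity, dy, dx);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (!m(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      stack.clear();
      stack.push_back(y + x * h);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        int cy = v % h, cx = v / h;
        for (size_t k = 0; k < dy.size(); ++k) {
          int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          if (m(ny, nx) && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back(ny + nx * h);
          }
        }
      }
    }
  }
  return lab;
}

// Plateau-aware strict local maxima. A plateau is a connected component of
// equal-valued pixels; it is a maximum iff every neighboring pixel outside
// it has a strictly lower value (image borders contribute only existing
// neighbors). Each maximal plateau is reported once at its rounded
// centroid, falling back to its first row-major member if the rounded
// centroid lies off-plateau. Rows are (y, x, value), 0-based, sorted
// row-major by the reported pixel.
// [[Rcpp::export]]
NumericMatrix plateau_maxima(NumericMatrix img, int connectivity) {
  int h = img.nrow(), w = img.ncol();
  IntegerMatrix lab(h, w); // 0 = unvisited
  std::vector<int> dy, dx;
  neighbor_offsets(connectivity, dy, dx);
  std::vector<double> out; // triples
  std::vector<int> stack, members;
  int next = 0;
  // row-major scan: first plateau member encountered is its top-left one
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (lab(y, x) != 0) continue;
      ++next;
      double v = img(y, x);
      bool is_max = true;
      stack.clear();
      members.clear();
      lab(y, x) = next;
      stack.push_back(y + x * h);
      members.push_back(y + x * h);
      double sum_y = 0, sum_x = 0;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int cy = p % h, cx = p / h;
        sum_y += cy;
        sum_x += cx;
        for (size_t k = 0; k < dy.size(); ++k) {
          int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          double nv = img(ny, nx);
          if (nv > v) is_max = false;
          else if (nv == v && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back(ny + nx * h);
            members.push_back(ny + nx * h);
          }
        }
      }
      if (!is_max) continue;
      int n = (int)members.size();
      int cy = (int)std::floor(sum_y / n + 0.5);
      int cx = (int)std::floor(sum_x / n + 0.5);
      if (cy < 0 || cy >= h || cx < 0 || cx >= w || lab(cy, cx) != next) {
        int first = members.front(); // seed = top-left member
        cy = first % h;
        cx = first / h;
      }
      out.push_back(cy);
      out.push_back(cx);
      out.push_back(v);
    }
  }
  int n_max = (int)out.size() / 3;
  // sort row-major by reported (y, x)
  std::vector<int> ord(n_max);
  for (int i = 0; i < n_max; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (out[3 * a] != out[3 * b]) return out[3 * a] < out[3 * b];
    return out[3 * a + 1] < out[3 * b + 1];
  });
  NumericMatrix res(n_max, 3);
  for (int i = 0; i < n_max; ++i) {
    res(i, 0) = out[3 * ord[i]];
    res(i, 1) = out[3 * ord[i] + 1];
    res(i, 2) = out[3 * ord[i] + 2];
  }
  colnames(res) = CharacterVector::create("y", "x", "value");
  return res;
}
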