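// Connected-component labeling (selectable 4/8-connectivity) and
// Moore-neighbour outer-contour tracing for binary masks.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Labels assigned in raster-scan order of first encounter, so component k's
// first pixel is the leftmost pixel of its topmost row: deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int dr4[] = {-1, 0, 0, 1};
  int dc4[] = {0, -1, 1, 0};
  int *dr = (connectivity == 4) ? dr4 : dr8;
  int *dc = (connectivity == 4) ? dc4 : dc8;
  int nd = (connectivity == 4) ? 4 : 8;
  int next_label = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next_label;
      lab(r, c) = next_label;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < nd; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next_label;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour tracing of the outer boundary of the (single) foreground
// component containing the raster-first foreground pixel.  Steps weigh 1
// axially and sqrt(2) diagonally; an isolated pixel gets perimeter 4
// (its unit-square boundary) by convention.
// [[Rcpp::export]]
List cpp_trace_contour(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c) != 0) { sr = r; sc = c; break; }
  if (sr < 0)
    return List::create(_["coords"] = IntegerMatrix(0, 2),
                        _["chain_length"] = 0.0,
                        _["n_axial"] = 0, _["n_diagonal"] = 0, _["n_corner"] = 0);

  // clockwise from W (screen coordinates: rows grow downward)
  int dr[] = {0, -1, -1, -1, 0, 1, 1, 1};
  int dc[] = {-1, -1, 0, 1, 1, 1, 0, -1};
  double steplen[] = {1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2};

  bool isolated = true;
  for (int k = 0; k < 8; ++k) {
    int rr = sr + dr[k], cc = sc + dc[k];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && mask(rr, cc) != 0)
      { isolated = false; break; }
  }
  if (isolated) {
    IntegerMatrix co(1, 2);
    co(0, 0) = sr + 1; co(0, 1) = sc + 1;
    return List::create(_["coords"] = co, _["chain_length"] = 4.0,
                        _["n_axial"] = 0, _["n_diagonal"] = 0, _["n_corner"] = 0);
  }

  std::vector<int> crs, ccs;
  crs.push_back(sr); ccs.push_back(sc);
  int cur_r = sr, cur_c = sc;
  int back_dir = 0;   // backtrack cell is W of the start (background: start is raster-first)
  double perim = 0.0;
  int n_axial = 0, n_diagonal = 0, n_corner = 0;
  int prev_move = -1;
  int first_move = -1;
  long max_iter = 4L * nr * nc + 16;
  for (long iter = 0; iter < max_iter; ++iter) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (back_dir + k) % 8;
      int rr = cur_r + dr[d], cc = cur_c + dc[d];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && mask(rr, cc) != 0) {
        found = d;
        back_dir = (back_dir + k - 1) % 8;  // last background cell examined
        break;
      }
    }
    if (found < 0) break;  // cannot happen for non-isolated pixel
    if (first_move < 0) {
      first_move = found;
    } else if (cur_r == sr && cur_c == sc && found == first_move) {
      break;  // closed the loop (Jacob's stopping criterion)
    }
    perim += steplen[found];
    if (found % 2 == 0) ++n_axial; else ++n_diagonal;
    if (prev_move >= 0 && found != prev_move) ++n_corner;
    prev_move = found;
    cur_r += dr[found];
    cur_c += dc[found];
    // re-anchor backtrack relative to the new current pixel: the cell we
    // stored is adjacent to both old and new current; express its direction
    int br = (cur_r - dr[found]) + dr[back_dir] - cur_r;
    int bc = (cur_c - dc[found]) + dc[back_dir] - cur_c;
    for (int k = 0; k < 8; ++k)
      if (dr[k] == br && dc[k] == bc) { back_dir = k; break; }
    if (!(cur_r == sr && cur_c == sc)) {
      crs.push_back(cur_r); ccs.push_back(cur_c);
    }
  }
  // the closing step back to the first move is a potential corner too
  if (prev_move >= 0 && first_move >= 0 && prev_move != first_move) ++n_corner;
  IntegerMatrix co(crs.size(), 2);
  for (size_t i = 0; i < crs.size(); ++i) {
    co(i, 0) = crs[i] + 1;
    co(i, 1) = ccs[i] + 1;
  }
  return List::create(_["coords"] = co, _["chain_length"] = perim,
                      _["n_axial"] = n_axial, _["n_diagonal"] = n_diagonal,
                      _["n_corner"] = n_corner);
}
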