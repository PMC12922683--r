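// Low-level raster operations used by the segmentation and feature pipelines.
// All matrices are column-major (R layout); linear index = row + col * nrow.
// Boundary handling for convolutions is edge replication, which preserves
// constants under a normalized kernel (required so that difference-of-Gaussians
// exactly removes additive offsets).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(NumericMatrix img, NumericVector kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int klen = kernel.size();
  const int kr = (klen - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical direction within each column)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -kr; t <= kr; ++t) {
        int ii = clampi(i + t, 0, nr - 1);
        acc += img(ii, j) * kernel[t + kr];
      }
      tmp(i, j) = acc;
    }
  }
  // along columns (horizontal direction within each row)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -kr; t <= kr; ++t) {
        int jj = clampi(j + t, 0, nc - 1);
        acc += tmp(i, jj) * kernel[t + kr];
      }
      out(i, j) = acc;
    }
  }
  return out;
}

static std::vector<std::pair<int,int> > disc_offsets(double radius) {
  std::vector<std::pair<int,int> > off;
  int r = (int)std::floor(radius + 1e-9);
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if ((double)di * di + (double)dj * dj <= radius * radius + 1e-9)
        off.push_back(std::make_pair(di, dj));
  return off;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<int,int> > off = disc_offsets(radius);
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(off.size());
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (size_t k = 0; k < off.size(); ++k) {
        int ii = i + off[k].first, jj = j + off[k].second;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) buf.push_back(img(ii, jj));
      }
      size_t n = buf.size();
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix grey_erode_cpp(NumericMatrix img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<int,int> > off = disc_offsets(radius);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = std::numeric_limits<double>::infinity();
      for (size_t k = 0; k < off.size(); ++k) {
        int ii = i + off[k].first, jj = j + off[k].second;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) {
          double v = img(ii, jj);
          if (v < m) m = v;
        }
      }
      out(i, j) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix grey_dilate_cpp(NumericMatrix img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<int,int> > off = disc_offsets(radius);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = -std::numeric_limits<double>::infinity();
      for (size_t k = 0; k < off.size(); ++k) {
        int ii = i + off[k].first, jj = j + off[k].second;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) {
          double v = img(ii, jj);
          if (v > m) m = v;
        }
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Grayscale reconstruction by dilation (Vincent 1993 hybrid algorithm,
// 8-connectivity). marker must be <= mask everywhere.
// [[Rcpp::export]]
NumericMatrix reconstruct_dilate_cpp(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // raster scan (N+ : neighbours already visited in raster order)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = J(i, j);
      for (int k = 0; k < 8; ++k) {
        int ii = i + di8[k], jj = j + dj8[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (jj < j || (jj == j && ii < i)) {
          if (J(ii, jj) > m) m = J(ii, jj);
        }
      }
      J(i, j) = std::min(m, mask(i, j));
    }
  }
  // anti-raster scan + queue initialization
  std::queue<int> fifo;
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      double m = J(i, j);
      for (int k = 0; k < 8; ++k) {
        int ii = i + di8[k], jj = j + dj8[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (jj > j || (jj == j && ii > i)) {
          if (J(ii, jj) > m) m = J(ii, jj);
        }
      }
      J(i, j) = std::min(m, mask(i, j));
      for (int k = 0; k < 8; ++k) {
        int ii = i + di8[k], jj = j + dj8[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (jj > j || (jj == j && ii > i)) {
          if (J(ii, jj) < J(i, j) && J(ii, jj) < mask(ii, jj)) {
            fifo.push(i + j * nr);
            break;
          }
        }
      }
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int i = p % nr, j = p / nr;
    for (int k = 0; k < 8; ++k) {
      int ii = i + di8[k], jj = j + dj8[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (J(ii, jj) < J(i, j) && mask(ii, jj) != J(ii, jj)) {
        double v = std::min(J(i, j), mask(ii, jj));
        if (v > J(ii, jj)) {
          J(ii, jj) = v;
          fifo.push(ii + jj * nr);
        }
      }
    }
  }
  return J;
}

// Connected-component labelling (BFS), conn = 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int conn) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (conn == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int ii = pi + di8[k], jj = pj + dj8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) to the
// nearest TRUE pixel of `feature`, with the linear (1-based) index of that
// pixel returned alongside.  Distances are in pixel units.
// [[Rcpp::export]]
List edt_cpp(LogicalMatrix feature) {
  const int nr = feature.nrow(), nc = feature.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d1(nr, nc);       // per-column vertical distance
  IntegerMatrix rowidx(nr, nc);   // row of nearest feature in this column
  for (int j = 0; j < nc; ++j) {
    double d = INF; int src = -1;
    for (int i = 0; i < nr; ++i) {
      if (feature(i, j)) { d = 0; src = i; } else if (d < INF) { d += 1; }
      d1(i, j) = d; rowidx(i, j) = src;
    }
    d = INF; src = -1;
    for (int i = nr - 1; i >= 0; --i) {
      if (feature(i, j)) { d = 0; src = i; } else if (d < INF) { d += 1; }
      if (d < d1(i, j)) { d1(i, j) = d; rowidx(i, j) = src; }
    }
  }
  NumericMatrix dist(nr, nc);
  IntegerMatrix nearest(nr, nc); // 1-based linear index, 0 when no feature
  std::vector<int> v(nc);
  std::vector<double> z(nc + 1), f(nc);
  for (int i = 0; i < nr; ++i) {
    int k = 0;
    bool any = false;
    for (int j = 0; j < nc; ++j) {
      f[j] = d1(i, j) == INF ? INF : d1(i, j) * d1(i, j);
      if (f[j] < INF) any = true;
    }
    if (!any) {
      for (int j = 0; j < nc; ++j) { dist(i, j) = INF; nearest(i, j) = 0; }
      continue;
    }
    // lower envelope of parabolas f[q] + (x - q)^2 over columns with finite f
    v[0] = -1; // sentinel: first finite column goes in below
    k = -1;
    for (int q = 0; q < nc; ++q) {
      if (f[q] == INF) continue;
      if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
      double s;
      while (true) {
        int p = v[k];
        s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
        if (s <= z[k]) { --k; if (k < 0) break; } else break;
      }
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
      if (k == 0) z[0] = -INF;
    }
    int kk = 0;
    for (int j = 0; j < nc; ++j) {
      while (z[kk + 1] < (double)j) ++kk;
      int q = v[kk];
      double dd = (double)(j - q) * (j - q) + f[q];
      dist(i, j) = std::sqrt(dd);
      nearest(i, j) = rowidx(i, q) + q * nr + 1;
    }
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}

// Regional maxima of img within mask: plateaus (8-connected, equal value)
// none of whose in-mask neighbours has a strictly greater value.
// [[Rcpp::export]]
LogicalMatrix regional_maxima_cpp(NumericMatrix img, LogicalMatrix mask) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  IntegerMatrix seen(nr, nc);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> plateau, stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || seen(i, j)) continue;
      double v = img(i, j);
      bool is_max = true;
      plateau.clear(); stack.clear();
      stack.push_back(i + j * nr);
      seen(i, j) = 1;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        plateau.push_back(p);
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 8; ++k) {
          int ii = pi + di8[k], jj = pj + dj8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (!mask(ii, jj)) continue;
          double w = img(ii, jj);
          if (w > v) is_max = false;
          else if (w == v && !seen(ii, jj)) {
            seen(ii, jj) = 1;
            stack.push_back(ii + jj * nr);
          }
        }
      }
      if (is_max)
        for (size_t t = 0; t < plateau.size(); ++t)
          out[plateau[t]] = true;
    }
  }
  return out;
}

// Meyer's seeded watershed flooding within mask. `surface` is flooded from
// low to high values starting at seed labels; ties broken by insertion order
// (deterministic).  Unreached masked pixels keep label 0.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix surface, IntegerMatrix seeds,
                            LogicalMatrix mask) {
  const int nr = surface.nrow(), nc = surface.ncol();
  IntegerMatrix lab = clone(seeds);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  typedef std::pair<double, std::pair<long long, int> > QE; // (prio, (order, idx))
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  long long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0 && mask(i, j))
        for (int k = 0; k < 8; ++k) {
          int ii = i + di8[k], jj = j + dj8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            pq.push(QE(surface(ii, jj), std::make_pair(order++, ii + jj * nr)));
          }
        }
  std::vector<char> queued(nr * nc, 0);
  while (!pq.empty()) {
    int p = pq.top().second.second; pq.pop();
    int i = p % nr, j = p / nr;
    if (lab(i, j) != 0) continue;
    // label of any labelled neighbour (first found in fixed order)
    int l = 0;
    for (int k = 0; k < 8; ++k) {
      int ii = i + di8[k], jj = j + dj8[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (lab(ii, jj) > 0) { l = lab(ii, jj); break; }
    }
    if (l == 0) continue;
    lab(i, j) = l;
    for (int k = 0; k < 8; ++k) {
      int ii = i + di8[k], jj = j + dj8[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (mask(ii, jj) && lab(ii, jj) == 0 && !queued[ii + jj * nr]) {
        queued[ii + jj * nr] = 1;
        pq.push(QE(surface(ii, jj), std::make_pair(order++, ii + jj * nr)));
      }
    }
  }
  return lab;
}
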