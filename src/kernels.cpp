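#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected-component labelling (iterative flood fill).
// Components are numbered 1..K in row-major discovery order, so label 1's
// first pixel is the topmost-then-leftmost pixel of the first component.
// connectivity is 4 or 8.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = connectivity;
  int next_label = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(r * nc + c);
      lab(r, c) = next_label;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int pr = idx / nc, pc = idx % nc;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next_label;
            stack.push_back(qr * nc + qc);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next_label;
  return lab;
}

// ---------------------------------------------------------------------------
// Fill holes: background components (4-connected) not touching the image
// border become foreground.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> stack;
  auto push_if_bg = [&](int r, int c) {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return;
    size_t idx = (size_t)r * nc + c;
    if (!mask(r, c) && !outside[idx]) {
      outside[idx] = 1;
      stack.push_back(r * nc + c);
    }
  };
  for (int c = 0; c < nc; ++c) { push_if_bg(0, c); push_if_bg(nr - 1, c); }
  for (int r = 0; r < nr; ++r) { push_if_bg(r, 0); push_if_bg(r, nc - 1); }
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int r = idx / nc, c = idx % nc;
    push_if_bg(r - 1, c); push_if_bg(r + 1, c);
    push_if_bg(r, c - 1); push_if_bg(r, c + 1);
  }
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = mask(r, c) || !outside[(size_t)r * nc + c];
  return out;
}

// ---------------------------------------------------------------------------
// Per-component area, centroid (1-based row/col), and perimeter.
// Perimeter: Moore-neighbour contour traversal; orthogonal steps count 1,
// diagonal steps sqrt(2). Isolated single pixels get perimeter 1 by
// convention (the traversal makes no steps).
// ---------------------------------------------------------------------------

static double trace_perimeter(const IntegerMatrix& lab, int target,
                              int sr, int sc) {
  const int nr = lab.nrow(), nc = lab.ncol();
  // clockwise directions starting East
  static const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  static const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  static const double len[8] = {1.0, M_SQRT2, 1.0, M_SQRT2,
                                1.0, M_SQRT2, 1.0, M_SQRT2};
  auto at = [&](int r, int c) {
    return r >= 0 && r < nr && c >= 0 && c < nc && lab(r, c) == target;
  };
  int pr = sr, pc = sc;
  int back = 4;  // start pixel entered "from the West"
  int first_dir = -1, first_qr = -1, first_qc = -1;
  double total = 0.0;
  long cap = 8L * nr * nc + 16L;
  for (long it = 0; it < cap; ++it) {
    int d = -1, qr = 0, qc = 0;
    for (int k = 1; k <= 8; ++k) {
      int cand = (back + k) % 8;
      int rr = pr + dr[cand], cc = pc + dc[cand];
      if (at(rr, cc)) { d = cand; qr = rr; qc = cc; break; }
    }
    if (d < 0) return 1.0;  // isolated pixel
    if (first_dir < 0) {
      first_dir = d; first_qr = qr; first_qc = qc;
    } else if (pr == sr && pc == sc && d == first_dir &&
               qr == first_qr && qc == first_qc) {
      break;  // about to repeat the initial move: contour closed
    }
    total += len[d];
    back = (d + 4) % 8;
    pr = qr; pc = qc;
  }
  return total;
}

// [[Rcpp::export]]
List cpp_component_stats(const IntegerMatrix& lab, int n_labels) {
  const int nr = lab.nrow(), nc = lab.ncol();
  IntegerVector area(n_labels);
  NumericVector sum_r(n_labels), sum_c(n_labels);
  IntegerVector start_r(n_labels, -1), start_c(n_labels, -1);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int l = lab(r, c);
      if (l <= 0) continue;
      int i = l - 1;
      area[i] += 1;
      sum_r[i] += r + 1;  // 1-based
      sum_c[i] += c + 1;
      if (start_r[i] < 0) { start_r[i] = r; start_c[i] = c; }
    }
  }
  NumericVector cen_r(n_labels), cen_c(n_labels), per(n_labels);
  for (int i = 0; i < n_labels; ++i) {
    cen_r[i] = sum_r[i] / area[i];
    cen_c[i] = sum_c[i] / area[i];
    per[i] = trace_perimeter(lab, i + 1, start_r[i], start_c[i]);
  }
  return List::create(_["area"] = area, _["perimeter"] = per,
                      _["centroid_row"] = cen_r, _["centroid_col"] = cen_c);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance from every pixel to the nearest TRUE pixel of the mask.
// Used as the fast path for mask-to-mask Hausdorff distances; agrees exactly
// with brute force on integer grids because all arithmetic is on integers
// represented in doubles.
// ---------------------------------------------------------------------------

static void dt_1d(std::vector<double>& f, std::vector<double>& d, int n,
                  std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), dd(std::max(nr, nc));
  std::vector<int> v(std::max(nr, nc));
  std::vector<double> z(std::max(nr, nc) + 1);
  // transform along columns (over rows)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 0.0 : INF;
    dt_1d(f, dd, nr, v, z);
    for (int r = 0; r < nr; ++r) d(r, c) = dd[r];
  }
  // then along rows (over columns)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt_1d(f, dd, nc, v, z);
    for (int c = 0; c < nc; ++c) d(r, c) = dd[c];
  }
  return d;
}

// Symmetric Hausdorff distance (pixels) between the foregrounds of two
// binary masks of identical size. Either mask empty -> NA.

// [[Rcpp::export]]
double cpp_hausdorff_masks(const LogicalMatrix& a, const LogicalMatrix& b) {
  const int nr = a.nrow(), nc = a.ncol();
  bool any_a = false, any_b = false;
  for (int r = 0; r < nr && !(any_a && any_b); ++r)
    for (int c = 0; c < nc; ++c) {
      any_a = any_a || a(r, c);
      any_b = any_b || b(r, c);
    }
  if (!any_a || !any_b) return NA_REAL;
  NumericMatrix db = cpp_edt_sq(b), da = cpp_edt_sq(a);
  double m = 0.0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (a(r, c) && db(r, c) > m) m = db(r, c);
      if (b(r, c) && da(r, c) > m) m = da(r, c);
    }
  return std::sqrt(m);
}

// ---------------------------------------------------------------------------
// Directed Hausdorff distance between explicit point sets (rows = points,
// two columns). Exact; early-break on the inner scan.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_directed_hausdorff(const NumericMatrix& A, const NumericMatrix& B) {
  const int na = A.nrow(), nb = B.nrow();
  double cmax = 0.0;
  for (int i = 0; i < na; ++i) {
    double cmin = std::numeric_limits<double>::infinity();
    const double ax = A(i, 0), ay = A(i, 1);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1);
      double d = dx * dx + dy * dy;
      if (d < cmin) {
        cmin = d;
        if (cmin <= cmax) break;  // cannot raise the running max
      }
    }
    if (cmin > cmax) cmax = cmin;
  }
  return std::sqrt(cmax);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with symmetric (mirror) boundary handling.
// Kernel radius ceil(3*sigma), normalised to sum 1; conserves total
// intensity up to floating point.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * rad + 1);
  double s = 0.0;
  for (int k = -rad; k <= rad; ++k) {
    w[k + rad] = std::exp(-(double)k * k / (2.0 * sigma * sigma));
    s += w[k + rad];
  }
  for (double& x : w) x /= s;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - 1 - i;
    }
    return i;
  };
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)  // vertical pass
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int k = -rad; k <= rad; ++k)
        acc += w[k + rad] * img(reflect(r + k, nr), c);
      tmp(r, c) = acc;
    }
  for (int r = 0; r < nr; ++r)  // horizontal pass
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int k = -rad; k <= rad; ++k)
        acc += w[k + rad] * tmp(r, reflect(c + k, nc));
      out(r, c) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Row-wise median of a pixels x frames matrix (temporal median background).
// Even counts average the two central order statistics, matching
// stats::median.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_median_stack(const NumericMatrix& x) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) buf[j] = x(i, j);
    int h = m / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (m % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = 0.5 * (med + lo);
    }
    out[i] = med;
  }
  return out;
}
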