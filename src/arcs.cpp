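// Wave-front arc detection on binarized activity frames: sample triples of
// suprathreshold pixels, fit the unique circle through them, rasterize a
// one-pixel-wide mask and accept the arc when the fraction of mask pixels
// present in the frame exceeds min_support.  Accepted arcs consume their
// supporting pixels; search stops after max_trials consecutive rejections
// or when fewer than three pixels remain.
#include <Rcpp.h>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Circle {
  double cr, cc, r;
  bool collinear;
};

inline double det3(double a1, double a2, double a3,
                   double b1, double b2, double b3,
                   double c1, double c2, double c3) {
  return a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
         a3 * (b1 * c2 - b2 * c1);
}

// x^2 + y^2 + A x + B y + C = 0 through three points; Cramer's rule.
Circle fit_circle(double x1, double y1, double x2, double y2,
                  double x3, double y3) {
  Circle out{0, 0, 0, false};
  double D = det3(x1, y1, 1, x2, y2, 1, x3, y3, 1);
  if (std::fabs(D) < 1e-12) {
    out.collinear = true;
    return out;
  }
  double b1 = -(x1 * x1 + y1 * y1);
  double b2 = -(x2 * x2 + y2 * y2);
  double b3 = -(x3 * x3 + y3 * y3);
  double A = det3(b1, y1, 1, b2, y2, 1, b3, y3, 1) / D;
  double B = det3(x1, b1, 1, x2, b2, 1, x3, b3, 1) / D;
  double C = det3(x1, y1, b1, x2, y2, b2, x3, y3, b3) / D;
  out.cr = -A / 2.0; // x plays the role of the row coordinate
  out.cc = -B / 2.0;
  double rad2 = A * A / 4.0 + B * B / 4.0 - C;
  out.r = rad2 > 0 ? std::sqrt(rad2) : 0.0;
  return out;
}

// One-pixel-wide raster of a circle with continuous center, clipped to the
// frame; midpoint-style scan along both axes keeps the ring 8-connected.
std::vector<std::pair<int, int>> raster_circle(double cr, double cc, double r,
                                               int rows, int cols) {
  std::set<std::pair<int, int>> pts;
  int lo = (int)std::ceil(cr - r), hi = (int)std::floor(cr + r);
  for (int ir = lo; ir <= hi; ++ir) {
    double d2 = r * r - (ir - cr) * (ir - cr);
    if (d2 < 0) continue;
    double s = std::sqrt(d2);
    pts.insert({ir, (int)std::lround(cc - s)});
    pts.insert({ir, (int)std::lround(cc + s)});
  }
  lo = (int)std::ceil(cc - r);
  hi = (int)std::floor(cc + r);
  for (int ic = lo; ic <= hi; ++ic) {
    double d2 = r * r - (ic - cc) * (ic - cc);
    if (d2 < 0) continue;
    double s = std::sqrt(d2);
    pts.insert({(int)std::lround(cr - s), ic});
    pts.insert({(int)std::lround(cr + s), ic});
  }
  std::vector<std::pair<int, int>> out;
  out.reserve(pts.size());
  for (const auto& p : pts)
    if (p.first >= 0 && p.first < rows && p.second >= 0 && p.second < cols)
      out.push_back(p);
  return out;
}

// algebraic least-squares (Kasa) circle fit through a pixel set
bool kasa_fit(const std::vector<std::pair<int, int>>& pts, Circle& out) {
  const size_t n = pts.size();
  if (n < 3) return false;
  double Sx = 0, Sy = 0, Sxx = 0, Syy = 0, Sxy = 0, Sz = 0, Sxz = 0, Syz = 0;
  for (const auto& p : pts) {
    double x = p.first, y = p.second, z = x * x + y * y;
    Sx += x; Sy += y; Sxx += x * x; Syy += y * y; Sxy += x * y;
    Sz += z; Sxz += x * z; Syz += y * z;
  }
  // normal equations for x^2 + y^2 + A x + B y + C = 0
  double M[3][3] = {{Sxx, Sxy, Sx}, {Sxy, Syy, Sy}, {Sx, Sy, (double)n}};
  double rhsv[3] = {-Sxz, -Syz, -Sz};
  double D = det3(M[0][0], M[0][1], M[0][2], M[1][0], M[1][1], M[1][2],
                  M[2][0], M[2][1], M[2][2]);
  if (std::fabs(D) < 1e-9) return false;
  double A = det3(rhsv[0], M[0][1], M[0][2], rhsv[1], M[1][1], M[1][2],
                  rhsv[2], M[2][1], M[2][2]) / D;
  double B = det3(M[0][0], rhsv[0], M[0][2], M[1][0], rhsv[1], M[1][2],
                  M[2][0], rhsv[2], M[2][2]) / D;
  double C = det3(M[0][0], M[0][1], rhsv[0], M[1][0], M[1][1], rhsv[1],
                  M[2][0], M[2][1], rhsv[2]) / D;
  double rad2 = A * A / 4.0 + B * B / 4.0 - C;
  if (rad2 <= 0) return false;
  out.cr = -A / 2.0;
  out.cc = -B / 2.0;
  out.r = std::sqrt(rad2);
  out.collinear = false;
  return true;
}

} // namespace

// [[Rcpp::export(name = ".raster_circle_cpp")]]
IntegerMatrix raster_circle_cpp(double center_row, double center_col,
                                double radius, int rows, int cols) {
  auto pts = raster_circle(center_row - 1.0, center_col - 1.0, radius,
                           rows, cols);
  IntegerMatrix out(pts.size(), 2);
  for (size_t i = 0; i < pts.size(); ++i) {
    out(i, 0) = pts[i].first + 1;
    out(i, 1) = pts[i].second + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".detect_arcs_cpp")]]
List detect_arcs_cpp(LogicalMatrix frame, double min_support, int max_trials,
                     double min_radius, double max_radius, int min_hits,
                     double remove_band) {
  const int rows = frame.nrow(), cols = frame.ncol();
  std::vector<char> F((size_t)rows * cols, 0);
  std::vector<std::pair<int, int>> edge;
  for (int ir = 0; ir < rows; ++ir)
    for (int ic = 0; ic < cols; ++ic)
      if (frame(ir, ic)) {
        F[(size_t)ir * cols + ic] = 1;
        edge.push_back({ir, ic});
      }

  std::vector<double> a_cr, a_cc, a_r, a_sup;
  std::vector<int> a_hits, a_mask;
  std::vector<IntegerMatrix> a_pix;

  auto support_of = [&](const Circle& c, int& hits, int& msize) {
    auto mask = raster_circle(c.cr, c.cc, c.r, rows, cols);
    msize = (int)mask.size();
    hits = 0;
    if (msize < 4) return 0.0;
    for (const auto& p : mask)
      if (F[(size_t)p.first * cols + p.second]) ++hits;
    return (double)hits / (double)msize;
  };

  // least-squares refinement over the supporting annulus; keeps the refined
  // circle only while the mask support improves
  auto refine = [&](Circle c, double support, int hits, int msize) {
    for (int it = 0; it < 3; ++it) {
      std::vector<std::pair<int, int>> inl;
      for (const auto& p : edge) {
        double dr = p.first - c.cr, dc = p.second - c.cc;
        if (std::fabs(std::sqrt(dr * dr + dc * dc) - c.r) <= remove_band)
          inl.push_back(p);
      }
      Circle c2;
      if (!kasa_fit(inl, c2) || c2.r < min_radius || c2.r > max_radius)
        break;
      int hits2, msize2;
      double support2 = support_of(c2, hits2, msize2);
      if (support2 <= support || hits2 < min_hits) break;
      c = c2;
      support = support2;
      hits = hits2;
      msize = msize2;
    }
    struct { Circle c; double support; int hits, msize; } out{
      c, support, hits, msize};
    return out;
  };

  // each round spends up to max_trials random triples and accepts the
  // best-supported circle above the acceptance bar; rounds repeat until no
  // candidate passes or fewer than three pixels remain
  while ((int)edge.size() >= 3) {
    const int n = (int)edge.size();
    Circle best{0, 0, 0, true};
    double best_sup = 0;
    int best_hits = 0, best_mask = 0;
    for (int trial = 0; trial < max_trials; ++trial) {
      int i1 = (int)(unif_rand() * n);
      int i2 = (int)(unif_rand() * n);
      int i3 = (int)(unif_rand() * n);
      if (i1 >= n) i1 = n - 1;
      if (i2 >= n) i2 = n - 1;
      if (i3 >= n) i3 = n - 1;
      if (i1 == i2 || i1 == i3 || i2 == i3) continue;
      Circle c = fit_circle(edge[i1].first, edge[i1].second,
                            edge[i2].first, edge[i2].second,
                            edge[i3].first, edge[i3].second);
      if (c.collinear || c.r < min_radius || c.r > max_radius) continue;
      int hits, msize;
      double support = support_of(c, hits, msize);
      if (support <= min_support || hits < min_hits) continue;
      auto ref = refine(c, support, hits, msize);
      if (ref.support > best_sup) {
        best = ref.c;
        best_sup = ref.support;
        best_hits = ref.hits;
        best_mask = ref.msize;
      }
      if (best_sup > 0.9) break; // unambiguous circle
    }
    if (best.collinear || best_sup <= min_support) break;
    a_cr.push_back(best.cr + 1.0);
    a_cc.push_back(best.cc + 1.0);
    a_r.push_back(best.r);
    a_sup.push_back(best_sup);
    a_hits.push_back(best_hits);
    a_mask.push_back(best_mask);
    // the supporting pixel set is the annulus |dist - r| <= remove_band, so
    // rasterization round-off cannot strand isolated ring fragments
    std::vector<std::pair<int, int>> sup_pix;
    for (const auto& p : edge) {
      double dr = p.first - best.cr, dc = p.second - best.cc;
      if (std::fabs(std::sqrt(dr * dr + dc * dc) - best.r) <= remove_band)
        sup_pix.push_back(p);
    }
    if (sup_pix.empty()) break; // cannot make progress
    IntegerMatrix pix(sup_pix.size(), 2);
    for (size_t q = 0; q < sup_pix.size(); ++q) {
      pix(q, 0) = sup_pix[q].first + 1;
      pix(q, 1) = sup_pix[q].second + 1;
      F[(size_t)sup_pix[q].first * cols + sup_pix[q].second] = 0;
    }
    a_pix.push_back(pix);
    edge.clear();
    for (int ir = 0; ir < rows; ++ir)
      for (int ic = 0; ic < cols; ++ic)
        if (F[(size_t)ir * cols + ic]) edge.push_back({ir, ic});
  }

  return List::create(
      _["center_row"] = NumericVector(a_cr.begin(), a_cr.end()),
      _["center_col"] = NumericVector(a_cc.begin(), a_cc.end()),
      _["radius"] = NumericVector(a_r.begin(), a_r.end()),
      _["support"] = NumericVector(a_sup.begin(), a_sup.end()),
      _["n_hit"] = IntegerVector(a_hits.begin(), a_hits.end()),
      _["n_mask"] = IntegerVector(a_mask.begin(), a_mask.end()),
      _["pixels"] = wrap(a_pix));
}
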