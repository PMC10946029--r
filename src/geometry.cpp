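#include <Rcpp.h>
using namespace Rcpp;

static inline bool in_extent2(double x, double y, double cx, double cy,
                              double sx, double sy) {
  double u = (x - cx) / sx, v = (y - cy) / sy;
  return u * u + v * v < 4.0; // strict: the 2SD boundary itself is outside
}

// Ray casting for closure. For each of n_rays radial directions from
// (ox, oy), find the first (smallest positive t) intersection with the
// contour polyline and report whether it falls inside the 2SD extent of
// the CRF. Collinear grazing along a segment counts as a collision at the
// nearest point of overlap.
// [[Rcpp::export]]
LogicalVector closure_hits_cpp(NumericVector px, NumericVector py,
                               double ox, double oy, int n_rays,
                               double cx, double cy, double sx, double sy) {
  const int n = px.size();
  LogicalVector hit(n_rays);
  const double teps = 1e-9;
  for (int r = 0; r < n_rays; ++r) {
    double th = 2.0 * M_PI * r / n_rays;
    double dx = std::cos(th), dy = std::sin(th);
    double tbest = R_PosInf;
    for (int i = 0; i + 1 < n; ++i) {
      double ax = px[i], ay = py[i];
      double ex = px[i + 1] - ax, ey = py[i + 1] - ay;
      double rx = ax - ox, ry = ay - oy;
      double denom = dx * ey - dy * ex;
      if (std::fabs(denom) < 1e-12) {
        // Parallel. Collinear overlap counts (tangential grazing).
        if (std::fabs(dx * ry - dy * rx) < 1e-9) {
          double t1 = rx * dx + ry * dy;
          double t2 = (px[i + 1] - ox) * dx + (py[i + 1] - oy) * dy;
          double tmax = std::max(t1, t2);
          if (tmax > teps) {
            double tc = std::max(std::min(t1, t2), teps);
            if (tc < tbest) tbest = tc;
          }
        }
        continue;
      }
      double t = (rx * ey - ry * ex) / denom;
      double u = (rx * dy - ry * dx) / denom;
      if (t > teps && u >= -1e-9 && u <= 1.0 + 1e-9) {
        if (t < tbest) tbest = t;
      }
    }
    if (R_FINITE(tbest)) {
      hit[r] = in_extent2(ox + tbest * dx, oy + tbest * dy, cx, cy, sx, sy);
    } else {
      hit[r] = false;
    }
  }
  return hit;
}

// Kaasa algebraic circle fit on centred coordinates. Returns 0 on success,
// 1 if the points are (near) collinear.
static int kasa_fit(const std::vector<double>& xs, const std::vector<double>& ys,
                    double& qx, double& qy, double& radius, double& rms) {
  const int m = xs.size();
  double mx = 0, my = 0;
  for (int i = 0; i < m; ++i) { mx += xs[i]; my += ys[i]; }
  mx /= m; my /= m;
  double suu = 0, svv = 0, suv = 0, suuu = 0, svvv = 0, suvv = 0, svuu = 0;
  for (int i = 0; i < m; ++i) {
    double u = xs[i] - mx, v = ys[i] - my;
    suu += u * u; svv += v * v; suv += u * v;
    suuu += u * u * u; svvv += v * v * v;
    suvv += u * v * v; svuu += v * u * u;
  }
  double det = suu * svv - suv * suv;
  double scale = (suu + svv);
  if (scale <= 0 || det < 1e-9 * scale * scale) return 1;
  double b1 = 0.5 * (suuu + suvv);
  double b2 = 0.5 * (svvv + svuu);
  double uc = (svv * b1 - suv * b2) / det;
  double vc = (suu * b2 - suv * b1) / det;
  radius = std::sqrt(uc * uc + vc * vc + (suu + svv) / m);
  qx = mx + uc; qy = my + vc;
  double ss = 0;
  for (int i = 0; i < m; ++i) {
    double d = std::hypot(xs[i] - qx, ys[i] - qy) - radius;
    ss += d * d;
  }
  rms = std::sqrt(ss / m);
  return 0;
}

// Total-least-squares line fit; rms orthogonal residual.
static double line_rms(const std::vector<double>& xs, const std::vector<double>& ys) {
  const int m = xs.size();
  double mx = 0, my = 0;
  for (int i = 0; i < m; ++i) { mx += xs[i]; my += ys[i]; }
  mx /= m; my /= m;
  double suu = 0, svv = 0, suv = 0;
  for (int i = 0; i < m; ++i) {
    double u = xs[i] - mx, v = ys[i] - my;
    suu += u * u; svv += v * v; suv += u * v;
  }
  // smaller eigenvalue of [[suu suv][suv svv]]
  double tr = suu + svv;
  double dt = suu * svv - suv * suv;
  double lam = 0.5 * (tr - std::sqrt(std::max(0.0, tr * tr - 4.0 * dt)));
  return std::sqrt(std::max(0.0, lam / m));
}

// Windowed circle-fit scan for local curvature. Windows of width
// scale*patch are slid every `step` pixels; contour points inside the
// window AND the CRF extent are fitted when at least min_pts of them fall
// in. Collinear point sets are reported with radius = Inf (zero raw
// curvature) and a line-fit residual.
// [[Rcpp::export]]
DataFrame curvature_scan_cpp(NumericVector px, NumericVector py,
                             double cx, double cy, double sx, double sy,
                             double patch, NumericVector scales,
                             double step, int min_pts) {
  const int n = px.size();
  std::vector<double> o_scale, o_wx, o_wy, o_qx, o_qy, o_radius, o_err;
  std::vector<int> o_n, o_imid, o_line;

  // precompute extent membership
  std::vector<char> inext(n);
  for (int i = 0; i < n; ++i)
    inext[i] = in_extent2(px[i], py[i], cx, cy, sx, sy) ? 1 : 0;

  for (int s = 0; s < scales.size(); ++s) {
    double w = scales[s] * patch;
    std::vector<double> offs;
    if (w >= patch) {
      offs.push_back(0.0);
    } else {
      double last = patch - w;
      for (double o = 0.0; o < last - 1e-9; o += step) offs.push_back(o);
      offs.push_back(last);
    }
    for (size_t iy = 0; iy < offs.size(); ++iy) {
      for (size_t ix = 0; ix < offs.size(); ++ix) {
        double wx = offs[ix], wy = offs[iy];
        std::vector<double> xs, ys; std::vector<int> idx;
        for (int i = 0; i < n; ++i) {
          if (!inext[i]) continue;
          if (px[i] >= wx && px[i] <= wx + w && py[i] >= wy && py[i] <= wy + w) {
            xs.push_back(px[i]); ys.push_back(py[i]); idx.push_back(i);
          }
        }
        if ((int)xs.size() < min_pts) continue;
        double qx = NA_REAL, qy = NA_REAL, radius = R_PosInf, rms = 0;
        int bad = kasa_fit(xs, ys, qx, qy, radius, rms);
        if (bad) {
          radius = R_PosInf;
          rms = line_rms(xs, ys);
          qx = NA_REAL; qy = NA_REAL;
        }
        o_scale.push_back(scales[s]);
        o_wx.push_back(wx); o_wy.push_back(wy);
        o_n.push_back((int)xs.size());
        o_qx.push_back(qx); o_qy.push_back(qy);
        o_radius.push_back(radius);
        o_err.push_back(rms);
        o_imid.push_back(idx[idx.size() / 2] + 1); // 1-based middle point
        o_line.push_back(bad);
      }
    }
  }
  return DataFrame::create(
      _["scale"] = o_scale, _["wx"] = o_wx, _["wy"] = o_wy,
      _["n"] = o_n, _["qx"] = o_qx, _["qy"] = o_qy,
      _["radius"] = o_radius, _["fit_error"] = o_err,
      _["imid"] = o_imid, _["collinear"] = o_line);
}

// Fold-overlap symmetry scores: for each axis angle through the patch
// centre, build the density map of the reflected points and accumulate
// the overlap with the original map (sum of pixel-wise minima, or the
// dot product).
// [[Rcpp::export]]
NumericVector symmetry_overlaps_cpp(NumericVector px, NumericVector py,
                                    int size, double sd,
                                    NumericVector angles_deg,
                                    bool use_min = true,
                                    double trunc = 4.0) {
  const int npx = size * size;
  const int rad = (int)std::ceil(trunc * sd);
  const double inv2s2 = 1.0 / (2.0 * sd * sd);
  const double ctr = (size - 1) / 2.0;
  std::vector<double> D(npx, 0.0), Dr(npx);
  const int n = px.size();
  for (int i = 0; i < n; ++i) {
    int x0 = std::max(0, (int)std::floor(px[i]) - rad);
    int x1 = std::min(size - 1, (int)std::ceil(px[i]) + rad);
    int y0 = std::max(0, (int)std::floor(py[i]) - rad);
    int y1 = std::min(size - 1, (int)std::ceil(py[i]) + rad);
    for (int yy = y0; yy <= y1; ++yy) {
      double dy = yy - py[i];
      for (int xx = x0; xx <= x1; ++xx) {
        double dx = xx - px[i];
        D[yy + size * xx] += std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  NumericVector out(angles_deg.size());
  for (int a = 0; a < angles_deg.size(); ++a) {
    double th = angles_deg[a] * M_PI / 180.0;
    double ux = std::cos(th), uy = std::sin(th);
    std::fill(Dr.begin(), Dr.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double vx = px[i] - ctr, vy = py[i] - ctr;
      double dot = vx * ux + vy * uy;
      double rx = ctr + 2.0 * dot * ux - vx;
      double ry = ctr + 2.0 * dot * uy - vy;
      int x0 = std::max(0, (int)std::floor(rx) - rad);
      int x1 = std::min(size - 1, (int)std::ceil(rx) + rad);
      int y0 = std::max(0, (int)std::floor(ry) - rad);
      int y1 = std::min(size - 1, (int)std::ceil(ry) + rad);
      for (int yy = y0; yy <= y1; ++yy) {
        double dy = yy - ry;
        for (int xx = x0; xx <= x1; ++xx) {
          double dx = xx - rx;
          Dr[yy + size * xx] += std::exp(-(dx * dx + dy * dy) * inv2s2);
        }
      }
    }
    double s = 0;
    if (use_min) {
      for (int k = 0; k < npx; ++k) s += std::min(D[k], Dr[k]);
    } else {
      for (int k = 0; k < npx; ++k) s += D[k] * Dr[k];
    }
    out[a] = s;
  }
  return out;
}

// Gaussian point-density map on a size x size pixel grid (0-based pixel
// centres). Each point stamps a truncated Gaussian of the given SD.
// [[Rcpp::export]]
NumericMatrix density_map_cpp(NumericVector px, NumericVector py,
                              int size, double sd, double trunc = 4.0) {
  NumericMatrix D(size, size); // row = y, col = x
  const int rad = (int)std::ceil(trunc * sd);
  const double inv2s2 = 1.0 / (2.0 * sd * sd);
  for (int i = 0; i < px.size(); ++i) {
    int x0 = (int)std::floor(px[i]) - rad, x1 = (int)std::ceil(px[i]) + rad;
    int y0 = (int)std::floor(py[i]) - rad, y1 = (int)std::ceil(py[i]) + rad;
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0;
    if (x1 > size - 1) x1 = size - 1; if (y1 > size - 1) y1 = size - 1;
    for (int yy = y0; yy <= y1; ++yy) {
      double dy = yy - py[i];
      for (int xx = x0; xx <= x1; ++xx) {
        double dx = xx - px[i];
        D(yy, xx) += std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  return D;
}
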