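#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Siddon-style ray tracer for a 2D parallel-beam geometry.
//
// Pixel (r, c), 0-based, has centre x = (c + 0.5 - n_cols/2) * h,
// y = (r + 0.5 - n_rows/2) * h; pixels are flattened column-major
// (j = r + n_rows * c) to match R's array layout.
// A ray with angle theta and radial offset t0 is
//   p(t) = t0 * (-sin t, cos t) + t * (cos t, sin t),
// so t = 0 is the point of closest approach to the iso-centre; t is the
// signed position used for TOF binning.
//
// Returns parallel vectors (ray index, pixel index, intersection length,
// signed midpoint position), all 0-based.
// [[Rcpp::export]]
List trace_rays(int n_rows, int n_cols, double pixel_size,
                NumericVector angles, NumericVector offsets) {
  const double h = pixel_size;
  const double W = n_cols * h, H = n_rows * h;
  const double xmin = -W / 2.0, ymin = -H / 2.0;
  const double eps = 1e-12;

  std::vector<int> ray_idx, pix_idx;
  std::vector<double> lens, spos;
  std::vector<double> ts;
  ts.reserve(n_rows + n_cols + 4);

  int ray = 0;
  for (int a = 0; a < angles.size(); ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int o = 0; o < offsets.size(); ++o, ++ray) {
      const double ox = -offsets[o] * st, oy = offsets[o] * ct;
      const double dx = ct, dy = st;

      // slab intersection with the image bounding box
      double tmin = -std::numeric_limits<double>::infinity();
      double tmax = std::numeric_limits<double>::infinity();
      bool miss = false;
      if (std::fabs(dx) > eps) {
        double t1 = (xmin - ox) / dx, t2 = (xmin + W - ox) / dx;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
      } else if (ox < xmin || ox > xmin + W) miss = true;
      if (std::fabs(dy) > eps) {
        double t1 = (ymin - oy) / dy, t2 = (ymin + H - oy) / dy;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
      } else if (oy < ymin || oy > ymin + H) miss = true;
      if (miss || tmax - tmin <= eps) continue;

      ts.clear();
      ts.push_back(tmin);
      ts.push_back(tmax);
      if (std::fabs(dx) > eps)
        for (int q = 0; q <= n_cols; ++q) {
          double t = (xmin + q * h - ox) / dx;
          if (t > tmin + eps && t < tmax - eps) ts.push_back(t);
        }
      if (std::fabs(dy) > eps)
        for (int q = 0; q <= n_rows; ++q) {
          double t = (ymin + q * h - oy) / dy;
          if (t > tmin + eps && t < tmax - eps) ts.push_back(t);
        }
      std::sort(ts.begin(), ts.end());

      for (size_t s = 0; s + 1 < ts.size(); ++s) {
        const double len = ts[s + 1] - ts[s];
        if (len < 1e-12) continue;
        const double tm = 0.5 * (ts[s] + ts[s + 1]);
        const double px = ox + tm * dx, py = oy + tm * dy;
        int c = (int)std::floor((px - xmin) / h);
        int r = (int)std::floor((py - ymin) / h);
        if (c < 0) c = 0; if (c >= n_cols) c = n_cols - 1;
        if (r < 0) r = 0; if (r >= n_rows) r = n_rows - 1;
        ray_idx.push_back(ray);
        pix_idx.push_back(r + n_rows * c);
        lens.push_back(len);
        spos.push_back(tm);
      }
    }
  }

  return List::create(_["ray"] = wrap(ray_idx), _["pixel"] = wrap(pix_idx),
                      _["length"] = wrap(lens), _["s"] = wrap(spos));
}

// Expand traced segments into TOF-binned triplets: each (ray, pixel)
// entry is distributed over n_tof bins with Gaussian weights centred on
// the segment's signed position, renormalized per entry so the bins sum
// to the full intersection length (TOF adds no counts).
// Returned row index is bin * n_rays + ray (bin-major stacking).
// [[Rcpp::export]]
List tof_expand(IntegerVector ray, IntegerVector pixel, NumericVector len,
                NumericVector s, int n_rays, int n_tof,
                double tof_sigma, double bin_width) {
  const int nseg = ray.size();
  std::vector<int> gi, gj;
  std::vector<double> gv;
  gi.reserve((size_t)nseg * n_tof);
  gj.reserve((size_t)nseg * n_tof);
  gv.reserve((size_t)nseg * n_tof);
  std::vector<double> w(n_tof);
  const double c0 = (n_tof - 1) / 2.0;

  for (int q = 0; q < nseg; ++q) {
    double tot = 0.0;
    for (int m = 0; m < n_tof; ++m) {
      const double cm = (m - c0) * bin_width;
      const double z = (s[q] - cm) / tof_sigma;
      w[m] = std::exp(-0.5 * z * z);
      tot += w[m];
    }
    for (int m = 0; m < n_tof; ++m) {
      const double v = len[q] * w[m] / tot;
      if (v <= 0) continue;
      gi.push_back(m * n_rays + ray[q]);
      gj.push_back(pixel[q]);
      gv.push_back(v);
    }
  }
  return List::create(_["i"] = wrap(gi), _["j"] = wrap(gj), _["v"] = wrap(gv));
}
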