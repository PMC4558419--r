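#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Rasterize one dot -- an ellipse with sinusoidal radial boundary
// perturbation r(theta) = r_e(theta) * (1 + a * sin(h * theta + phase)) --
// and place it on the dot mask if every candidate pixel is clear of the
// halo (the set of pixels within Chebyshev distance 2 of existing dots).
// On acceptance the dot mask and halo are updated in place. Coordinates
// are 1-based matrix indices; centroids are returned 0-based to match the
// package's coordinate convention.
static bool place_one(LogicalMatrix &dot_mask, LogicalMatrix &halo,
                      double row, double col, double radius, double aspect,
                      double amplitude, int harmonics, double orientation,
                      double phase, double &out_r, double &out_c,
                      int &out_n) {
  const int nr = dot_mask.nrow(), nc = dot_mask.ncol();
  const double sa = std::sqrt(aspect);
  const double A = radius * sa, B = radius / sa;
  const double maxr = A * (1.0 + amplitude);

  const int r0 = std::max(1, (int)std::floor(row - maxr));
  const int r1 = std::min(nr, (int)std::ceil(row + maxr));
  const int c0 = std::max(1, (int)std::floor(col - maxr));
  const int c1 = std::min(nc, (int)std::ceil(col + maxr));
  if (r1 < r0 || c1 < c0) return false;

  std::vector<int> pr, pc;
  pr.reserve(64); pc.reserve(64);
  for (int c = c0; c <= c1; ++c) {
    const double dc = c - col;
    for (int r = r0; r <= r1; ++r) {
      const double dr = r - row;
      const double rho = std::sqrt(dr * dr + dc * dc);
      if (rho > maxr) continue;
      const double theta = std::atan2(dr, dc);
      const double t = theta - orientation;
      const double ct = std::cos(t), st = std::sin(t);
      const double re = A * B / std::sqrt(B * B * ct * ct + A * A * st * st);
      const double lim = re * (1.0 + amplitude *
                               std::sin(harmonics * theta + phase));
      if (rho <= lim) {
        if (halo(r - 1, c - 1)) return false;   // collision
        pr.push_back(r); pc.push_back(c);
      }
    }
  }
  const int n = pr.size();
  if (n < 1) return false;

  double sr = 0.0, sc = 0.0;
  for (int k = 0; k < n; ++k) {
    dot_mask(pr[k] - 1, pc[k] - 1) = true;
    sr += pr[k]; sc += pc[k];
    for (int dr = -2; dr <= 2; ++dr) {
      const int rr = pr[k] + dr;
      if (rr < 1 || rr > nr) continue;
      for (int dc = -2; dc <= 2; ++dc) {
        const int cc = pc[k] + dc;
        if (cc < 1 || cc > nc) continue;
        halo(rr - 1, cc - 1) = true;
      }
    }
  }
  out_r = sr / n - 1.0;
  out_c = sc / n - 1.0;
  out_n = n;
  return true;
}

// [[Rcpp::export(name = ".try_place_dot")]]
List try_place_dot(LogicalMatrix dot_mask, LogicalMatrix halo,
                   double row, double col, double radius, double aspect,
                   double amplitude, int harmonics, double orientation,
                   double phase) {
  double cr, cc; int n;
  if (place_one(dot_mask, halo, row, col, radius, aspect, amplitude,
                harmonics, orientation, phase, cr, cc, n))
    return List::create(_["accepted"] = true, _["area"] = n,
                        _["centroid_r"] = cr, _["centroid_c"] = cc);
  return List::create(_["accepted"] = false);
}

// Place all intranuclear dots of one nucleus: draw dot parameters from
// R's RNG stream, rejection-sample positions inside the nucleus, and
// accept collision-free rasters (up to 80 tries per dot). Returns the
// accepted dots' centroids (0-based), pixel areas and aspect ratios.
// [[Rcpp::export(name = ".place_nucleus_dots")]]
List place_nucleus_dots(LogicalMatrix dot_mask, LogicalMatrix halo,
                        double nuc_row, double nuc_col, double nuc_radius,
                        int k, double dot_radius, double aspect_mean,
                        double amplitude, int harmonics) {
  std::vector<double> out_r, out_c, out_asp;
  std::vector<int> out_n;
  RNGScope scope;
  for (int j = 0; j < k; ++j) {
    for (int attempt = 0; attempt < 80; ++attempt) {
      const double u1 = R::runif(0.0, 1.0), u2 = R::runif(0.0, 1.0),
                   u3 = R::runif(0.0, 1.0), u4 = R::runif(0.0, 1.0),
                   u5 = R::runif(0.0, 1.0);
      double R_ = dot_radius * (0.8 + 0.4 * u1);
      const double asp = 1.0 + (aspect_mean - 1.0) * R::rgamma(6.0, 1.0 / 6.0);
      const double ori = M_PI * u2;
      const double phase = 2.0 * M_PI * u3;
      double maxr = R_ * std::sqrt(asp) * (1.0 + amplitude);
      if (maxr > nuc_radius - 2.0) {          // shrink oversized dots
        R_ *= (nuc_radius - 2.0) / maxr;
        maxr = nuc_radius - 2.0;
      }
      if (R_ < 0.7) break;
      const double free = nuc_radius - maxr - 1.0;
      if (free <= 0.0) continue;
      const double rr = (2.0 * u4 - 1.0) * free;
      const double cc = (2.0 * u5 - 1.0) * free;
      if (rr * rr + cc * cc > free * free) continue;
      double cr_, cc_; int n_;
      if (place_one(dot_mask, halo, nuc_row + rr, nuc_col + cc, R_, asp,
                    amplitude, harmonics, ori, phase, cr_, cc_, n_)) {
        out_r.push_back(cr_); out_c.push_back(cc_);
        out_n.push_back(n_); out_asp.push_back(asp);
        break;
      }
    }
  }
  return List::create(_["centroid_r"] = wrap(out_r),
                      _["centroid_c"] = wrap(out_c),
                      _["pixel_area"] = wrap(out_n),
                      _["aspect"] = wrap(out_asp));
}

// 8-connected two-pass labeling with union-find; provisional labels are
// assigned in column-major scan order and renumbered to raster order on
// the R side.
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!m(r, c)) continue;
      int best = 0;
      // neighbours already scanned in column-major order
      const int pr[4] = {r - 1, r - 1, r, r + 1};
      const int pc[4] = {c, c - 1, c - 1, c - 1};
      for (int i = 0; i < 4; ++i) {
        if (pr[i] < 0 || pr[i] >= nr || pc[i] < 0 || pc[i] >= nc) continue;
        const int l = lab(pr[i], pc[i]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        parent.push_back((int)parent.size());
        best = (int)parent.size() - 1;
      }
      lab(r, c) = best;
    }
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = find(lab(r, c));
  return lab;
}
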