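// Inner loops of the model: subspace residual surfaces and saddle-operator
// activity maps. Both are evaluated thousands of times per flow field, so
// they live here; the R level keeps reference implementations for small
// cases that the test suite checks against these kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Solve M x = c for symmetric positive semi-definite 3x3 M, via adjugate
// when well-conditioned, else eigen pseudo-inverse. Returns c' M^+ c.
static double quad_form_pinv(const arma::mat33 &M, const arma::vec3 &c) {
  double scale = (M(0, 0) + M(1, 1) + M(2, 2)) / 3.0;
  if (scale <= 0.0) return 0.0;
  double det =
      M(0, 0) * (M(1, 1) * M(2, 2) - M(1, 2) * M(1, 2)) -
      M(0, 1) * (M(0, 1) * M(2, 2) - M(1, 2) * M(0, 2)) +
      M(0, 2) * (M(0, 1) * M(1, 2) - M(1, 1) * M(0, 2));
  if (det > 1e-12 * scale * scale * scale) {
    arma::vec3 x;
    x(0) = (M(1, 1) * M(2, 2) - M(1, 2) * M(1, 2)) * c(0) +
           (M(0, 2) * M(1, 2) - M(0, 1) * M(2, 2)) * c(1) +
           (M(0, 1) * M(1, 2) - M(0, 2) * M(1, 1)) * c(2);
    x(1) = (M(0, 2) * M(1, 2) - M(0, 1) * M(2, 2)) * c(0) +
           (M(0, 0) * M(2, 2) - M(0, 2) * M(0, 2)) * c(1) +
           (M(0, 1) * M(0, 2) - M(0, 0) * M(1, 2)) * c(2);
    x(2) = (M(0, 1) * M(1, 2) - M(0, 2) * M(1, 1)) * c(0) +
           (M(0, 1) * M(0, 2) - M(0, 0) * M(1, 2)) * c(1) +
           (M(0, 0) * M(1, 1) - M(0, 1) * M(0, 1)) * c(2);
    return arma::dot(c, x) / det;
  }
  arma::vec eigval;
  arma::mat eigvec;
  arma::eig_sym(eigval, eigvec, arma::mat(M));
  double tol = 1e-12 * eigval.max();
  double out = 0.0;
  for (int i = 0; i < 3; ++i) {
    if (eigval(i) > tol) {
      double proj = arma::dot(eigvec.col(i), arma::vec(c));
      out += proj * proj / eigval(i);
    }
  }
  return out;
}

// Raw subspace residuals R_v(T) for every heading candidate.
//
// For candidate image position (cx, cy) the translation column at sample i
// is proportional to the radial offset (x_i - cx, y_i - cy); projecting each
// flow vector onto the unit perpendicular d_i eliminates the per-sample
// depth unknown, and a final rank-3 projection removes the rotational
// subspace spanned by the d-projected rows of B(p_i).
// [[Rcpp::export]]
arma::vec residual_surface_cpp(const arma::mat &pts, const arma::mat &vel,
                               const arma::mat &cand, double f) {
  const int n = pts.n_rows, m = cand.n_rows;
  arma::vec out(m);
  // Per-sample constants: positions, velocities and the B(p) rows, held in
  // contiguous arrays so the candidate loop vectorizes. The unit projector
  // d_i = (-dy, dx)/|.| enters every accumulator quadratically, so the
  // normalization collapses to a common weight 1/(dx^2+dy^2) and no square
  // root is needed; the tiny ridge in the denominator makes a sample that
  // coincides with the candidate drop out smoothly.
  std::vector<double> X(n), Y(n), VX(n), VY(n),
      B10(n), B11(n), B12(n), B20(n), B21(n), B22(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    X[i] = x; Y[i] = y; VX[i] = vel(i, 0); VY[i] = vel(i, 1);
    B10[i] = x * y / f; B11[i] = -f - x * x / f; B12[i] = y;
    B20[i] = f + y * y / f; B21[i] = -x * y / f; B22[i] = -x;
  }
  for (int j = 0; j < m; ++j) {
    const double cx = cand(j, 0), cy = cand(j, 1);
    double M00 = 0, M01 = 0, M02 = 0, M11 = 0, M12 = 0, M22 = 0;
    double c0 = 0, c1 = 0, c2 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      double dx = X[i] - cx, dy = Y[i] - cy;
      double k = 1.0 / (dx * dx + dy * dy + 1e-18);
      double w = dx * VY[i] - dy * VX[i];
      double b0 = dx * B20[i] - dy * B10[i];
      double b1 = dx * B21[i] - dy * B11[i];
      double b2 = dx * B22[i] - dy * B12[i];
      M00 += k * b0 * b0; M01 += k * b0 * b1; M02 += k * b0 * b2;
      M11 += k * b1 * b1; M12 += k * b1 * b2; M22 += k * b2 * b2;
      double kw = k * w;
      c0 += kw * b0; c1 += kw * b1; c2 += kw * b2;
      s2 += kw * w;
    }
    arma::mat33 M;
    M(0, 0) = M00; M(0, 1) = M01; M(0, 2) = M02;
    M(1, 0) = M01; M(1, 1) = M11; M(1, 2) = M12;
    M(2, 0) = M02; M(2, 1) = M12; M(2, 2) = M22;
    arma::vec3 cv{c0, c1, c2};
    double r = s2 - quad_form_pinv(M, cv);
    out(j) = r > 0.0 ? r : 0.0;
  }
  return out;
}

// Unit vector of a direction in degrees, exact at the cardinal angles so
// axis-aligned surround discs stay symmetric to the last bit.
static inline void unit_deg(double deg, double &c, double &s) {
  double m = deg;
  while (m >= 360.0) m -= 360.0;
  while (m < 0.0) m += 360.0;
  if (m == 0.0) { c = 1.0; s = 0.0; }
  else if (m == 90.0) { c = 0.0; s = 1.0; }
  else if (m == 180.0) { c = -1.0; s = 0.0; }
  else if (m == 270.0) { c = 0.0; s = -1.0; }
  else { c = std::cos(deg * M_PI / 180.0); s = std::sin(deg * M_PI / 180.0); }
}

// Simple uniform binning of candidate points for disc queries.
struct CandBins {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;
  CandBins(const arma::mat &cand, double cell_) : cell(cell_) {
    x0 = cand.col(0).min(); y0 = cand.col(1).min();
    nx = (int)std::floor((cand.col(0).max() - x0) / cell) + 1;
    ny = (int)std::floor((cand.col(1).max() - y0) / cell) + 1;
    bins.resize((size_t)nx * ny);
    for (int i = 0; i < (int)cand.n_rows; ++i) {
      int ix = (int)std::floor((cand(i, 0) - x0) / cell);
      int iy = (int)std::floor((cand(i, 1) - y0) / cell);
      bins[(size_t)iy * nx + ix].push_back(i);
    }
  }
};

// Mean of each column of vals over candidates within radius r of (qx, qy).
// Returns the number of member candidates (0 -> means untouched).
static int disc_mean(const arma::mat &cand, const arma::mat &vals,
                     const CandBins &bins, double qx, double qy, double r,
                     arma::rowvec &mean_out) {
  int ix0 = std::max(0, (int)std::floor((qx - r - bins.x0) / bins.cell));
  int ix1 = std::min(bins.nx - 1, (int)std::floor((qx + r - bins.x0) / bins.cell));
  int iy0 = std::max(0, (int)std::floor((qy - r - bins.y0) / bins.cell));
  int iy1 = std::min(bins.ny - 1, (int)std::floor((qy + r - bins.y0) / bins.cell));
  double r2 = r * r;
  int count = 0;
  mean_out.zeros();
  for (int iy = iy0; iy <= iy1; ++iy) {
    for (int ix = ix0; ix <= ix1; ++ix) {
      for (int i : bins.bins[(size_t)iy * bins.nx + ix]) {
        double dx = cand(i, 0) - qx, dy = cand(i, 1) - qy;
        if (dx * dx + dy * dy <= r2) {
          mean_out += vals.row(i);
          ++count;
        }
      }
    }
  }
  if (count > 0) mean_out /= (double)count;
  return count;
}

// Cumulative saddle-operator activity maps for K surfaces sharing one
// candidate grid. vals is (n_candidates x K) of likelihood values; locs the
// activity-map grid; one operator per (radius, orientation) pair with
// surround discs at distance surround_factor * r. Operators whose discs
// leave the [-extent/2, extent/2] square or contain no candidate are
// inactive. Activity is |d1|+|d2|+|d3|+|d4| when the four surround-minus-
// center differences strictly alternate in sign around the cross.
// [[Rcpp::export]]
arma::mat activity_maps_cpp(const arma::mat &cand, const arma::mat &vals,
                            const arma::mat &locs, const arma::vec &radii,
                            const arma::vec &thetas, double surround_factor,
                            double extent) {
  const int L = locs.n_rows, K = vals.n_cols, nt = thetas.n_elem;
  const double half = extent / 2.0;
  arma::mat out(L, K, arma::fill::zeros);
  CandBins bins(cand, 1.0);
  arma::rowvec cmean(K);
  arma::mat smean(4 * nt, K);
  std::vector<int> scount(4 * nt);
  for (int l = 0; l < L; ++l) {
    double lx = locs(l, 0), ly = locs(l, 1);
    for (arma::uword ri = 0; ri < radii.n_elem; ++ri) {
      double r = radii(ri), dist = surround_factor * r;
      if (lx - r < -half || lx + r > half || ly - r < -half || ly + r > half)
        continue;
      int ccount = disc_mean(cand, vals, bins, lx, ly, r, cmean);
      // surround discs for all orientations
      bool any_fit = false;
      for (int ti = 0; ti < nt; ++ti) {
        for (int k = 0; k < 4; ++k) {
          double ca, sa;
          unit_deg(thetas(ti) + 90.0 * k, ca, sa);
          double qx = lx + dist * ca, qy = ly + dist * sa;
          if (qx - r < -half || qx + r > half || qy - r < -half ||
              qy + r > half) {
            scount[4 * ti + k] = -1;  // outside surface: operator inactive
            continue;
          }
          any_fit = true;
          arma::rowvec mrow = smean.row(4 * ti + k);
          scount[4 * ti + k] = disc_mean(cand, vals, bins, qx, qy, r, mrow);
          smean.row(4 * ti + k) = mrow;
        }
      }
      if (ccount == 0 || !any_fit) continue;
      for (int ti = 0; ti < nt; ++ti) {
        if (scount[4 * ti] <= 0 || scount[4 * ti + 1] <= 0 ||
            scount[4 * ti + 2] <= 0 || scount[4 * ti + 3] <= 0)
          continue;
        for (int k = 0; k < K; ++k) {
          double c = cmean(k);
          double d1 = smean(4 * ti, k) - c, d2 = smean(4 * ti + 1, k) - c,
                 d3 = smean(4 * ti + 2, k) - c, d4 = smean(4 * ti + 3, k) - c;
          bool alt = (d1 > 0 && d3 > 0 && d2 < 0 && d4 < 0) ||
                     (d1 < 0 && d3 < 0 && d2 > 0 && d4 > 0);
          if (alt)
            out(l, k) += std::abs(d1) + std::abs(d2) + std::abs(d3) +
                         std::abs(d4);
        }
      }
    }
  }
  return out;
}
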