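// Hot paths of the imaging pipeline: pixel-integrated Gaussian rendering,
// local-maximum candidate detection, and per-spot 2-D Gaussian least-squares
// fits (Levenberg-Marquardt on the pixel-integrated model, weighted-centroid
// fallback).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Integral of a normal density N(mu, s^2) over the unit pixel [c-0.5, c+0.5].
static inline double pix_int(double c, double mu, double s) {
  const double inv = 1.0 / (s * M_SQRT2);
  return 0.5 * (std::erf((c + 0.5 - mu) * inv) - std::erf((c - 0.5 - mu) * inv));
}

static inline double norm_pdf(double u) {
  return std::exp(-0.5 * u * u) * 0.3989422804014327;
}

// Expected photon image of point/extended emitters on a uniform background.
// x = column coordinate, y = row coordinate, both 0-based with pixel centers
// at integers; sigma in pixels; photons = total expected counts per emitter.
// [[Rcpp::export]]
NumericMatrix render_spots_cpp(int height, int width,
                               NumericVector x, NumericVector y,
                               NumericVector sigma, NumericVector photons,
                               double background) {
  NumericMatrix img(height, width);
  std::fill(img.begin(), img.end(), background);
  const double support = 5.0;
  for (int k = 0; k < x.size(); ++k) {
    const double s = sigma[k];
    if (!R_finite(x[k]) || !R_finite(y[k])) continue;
    int c0 = std::max(0, (int)std::floor(x[k] - support * s));
    int c1 = std::min(width - 1, (int)std::ceil(x[k] + support * s));
    int r0 = std::max(0, (int)std::floor(y[k] - support * s));
    int r1 = std::min(height - 1, (int)std::ceil(y[k] + support * s));
    if (c1 < c0 || r1 < r0) continue;
    std::vector<double> fy(r1 - r0 + 1);
    for (int r = r0; r <= r1; ++r) fy[r - r0] = pix_int((double)r, y[k], s);
    for (int c = c0; c <= c1; ++c) {
      const double fx = photons[k] * pix_int((double)c, x[k], s);
      for (int r = r0; r <= r1; ++r) img(r, c) += fx * fy[r - r0];
    }
  }
  return img;
}

// Strict local maxima above `threshold` within a Chebyshev `radius` window.
// Plateau ties are resolved in favour of the first pixel in scan order.
// Returns a k x 2 matrix of 0-based (row, col).
// [[Rcpp::export]]
IntegerMatrix find_candidates_cpp(NumericMatrix img, int radius, double threshold) {
  const int h = img.nrow(), w = img.ncol();
  std::vector<int> rows, cols;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      const double v = img(r, c);
      if (!(v > threshold)) continue;
      bool is_max = true;
      for (int dc = -radius; dc <= radius && is_max; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= w) continue;
        for (int dr = -radius; dr <= radius; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= h || (dr == 0 && dc == 0)) continue;
          const double u = img(rr, cc);
          // earlier pixel in column-major scan order wins exact ties
          const bool earlier = (cc < c) || (cc == c && rr < r);
          if (u > v || (u == v && earlier)) { is_max = false; break; }
        }
      }
      if (is_max) { rows.push_back(r); cols.push_back(c); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) { out(i, 0) = rows[i]; out(i, 1) = cols[i]; }
  return out;
}

struct FitResult {
  double x, y, sigma, amp, bg, rss;
  bool converged;
};

// Moment initialisation / fallback: background from the window border median,
// center and width from background-subtracted intensity moments.
static FitResult moment_estimate(const arma::mat& z, int r0, int c0) {
  const int nr = z.n_rows, nc = z.n_cols;
  std::vector<double> border;
  for (int c = 0; c < nc; ++c) { border.push_back(z(0, c)); border.push_back(z(nr - 1, c)); }
  for (int r = 1; r < nr - 1; ++r) { border.push_back(z(r, 0)); border.push_back(z(r, nc - 1)); }
  std::nth_element(border.begin(), border.begin() + border.size() / 2, border.end());
  const double bg = border[border.size() / 2];
  double sw = 0, sx = 0, sy = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const double wgt = std::max(z(r, c) - bg, 0.0);
      sw += wgt; sx += wgt * c; sy += wgt * r;
    }
  FitResult f;
  f.bg = bg;
  if (sw <= 0) {
    f.x = c0 + (nc - 1) / 2.0; f.y = r0 + (nr - 1) / 2.0;
    f.sigma = 1.0; f.amp = 0.0; f.rss = NA_REAL; f.converged = false;
    return f;
  }
  const double mx = sx / sw, my = sy / sw;
  double sxx = 0, syy = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const double wgt = std::max(z(r, c) - bg, 0.0);
      sxx += wgt * (c - mx) * (c - mx);
      syy += wgt * (r - my) * (r - my);
    }
  f.sigma = std::sqrt(std::max((sxx + syy) / (2.0 * sw), 0.09));
  f.x = c0 + mx; f.y = r0 + my;
  f.amp = sw;  // integrated counts above background
  f.rss = NA_REAL;
  f.converged = false;
  return f;
}

// Levenberg-Marquardt least squares of the pixel-integrated Gaussian
//   m(r, c) = bg + amp * Fx(c) * Fy(r)
// where Fx, Fy are unit-pixel integrals of N(x0, s^2), N(y0, s^2).
// amp is the total integrated photon count of the spot.
static FitResult fit_one(const NumericMatrix& img, int row, int col, int half,
                         int max_iter, double prefilter_mass) {
  const int h = img.nrow(), w = img.ncol();
  const int r0 = std::max(0, row - half), r1 = std::min(h - 1, row + half);
  const int c0 = std::max(0, col - half), c1 = std::min(w - 1, col + half);
  const int nr = r1 - r0 + 1, nc = c1 - c0 + 1;
  arma::mat z(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) z(r, c) = img(r0 + r, c0 + c);

  FitResult init = moment_estimate(z, r0, c0);
  // candidates whose crude integrated mass cannot reach the mass filter are
  // not worth a refinement pass
  if (init.amp <= 0 || init.amp < prefilter_mass) return init;

  const int npix = nr * nc;
  arma::vec zz(npix);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) zz(c * nr + r) = z(r, c);

  // parameters: amp, x0, y0, sigma, bg
  arma::vec p(5);
  p(0) = init.amp; p(1) = init.x; p(2) = init.y;
  p(3) = std::min(std::max(init.sigma, 0.5), (double)half);
  p(4) = init.bg;

  const double smin = 0.3, smax = 2.0 * half;
  double lambda = 1e-3, rss = R_PosInf;
  bool converged = false;
  arma::vec m(npix), fx(nc), fy(nr), dfx(nc), dfy(nr), gfx(nc), gfy(nr);
  arma::mat J(npix, 5);

  for (int it = 0; it < max_iter; ++it) {
    const double amp = p(0), x0 = p(1), y0 = p(2), s = p(3), bg = p(4);
    for (int c = 0; c < nc; ++c) {
      const double cc = c0 + c;
      const double u1 = (cc - 0.5 - x0) / s, u2 = (cc + 0.5 - x0) / s;
      fx(c) = 0.5 * (std::erf(u2 / M_SQRT2) - std::erf(u1 / M_SQRT2));
      dfx(c) = -(norm_pdf(u2) - norm_pdf(u1)) / s;
      gfx(c) = -(u2 * norm_pdf(u2) - u1 * norm_pdf(u1)) / s;
    }
    for (int r = 0; r < nr; ++r) {
      const double rr = r0 + r;
      const double u1 = (rr - 0.5 - y0) / s, u2 = (rr + 0.5 - y0) / s;
      fy(r) = 0.5 * (std::erf(u2 / M_SQRT2) - std::erf(u1 / M_SQRT2));
      dfy(r) = -(norm_pdf(u2) - norm_pdf(u1)) / s;
      gfy(r) = -(u2 * norm_pdf(u2) - u1 * norm_pdf(u1)) / s;
    }
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        const int i = c * nr + r;
        m(i) = bg + amp * fx(c) * fy(r);
        J(i, 0) = fx(c) * fy(r);
        J(i, 1) = amp * dfx(c) * fy(r);
        J(i, 2) = amp * fx(c) * dfy(r);
        J(i, 3) = amp * (gfx(c) * fy(r) + fx(c) * gfy(r));
        J(i, 4) = 1.0;
      }
    arma::vec e = zz - m;
    rss = arma::dot(e, e);
    arma::mat JtJ = J.t() * J;
    arma::vec Jte = J.t() * e;

    bool stepped = false;
    for (int attempt = 0; attempt < 8; ++attempt) {
      arma::mat A = JtJ;
      A.diag() += lambda * (JtJ.diag() + 1e-12);
      arma::vec delta;
      if (!arma::solve(delta, A, Jte, arma::solve_opts::no_approx)) {
        lambda *= 10; continue;
      }
      arma::vec q = p + delta;
      // keep the fit inside the window and physically sensible
      q(0) = std::max(q(0), 1e-9);
      q(1) = std::min(std::max(q(1), (double)c0 - 1.0), (double)c1 + 1.0);
      q(2) = std::min(std::max(q(2), (double)r0 - 1.0), (double)r1 + 1.0);
      q(3) = std::min(std::max(q(3), smin), smax);
      // evaluate candidate rss
      double rss_new = 0;
      for (int c = 0; c < nc; ++c) {
        const double cc = c0 + c;
        fx(c) = pix_int(cc, q(1), q(3));
      }
      for (int r = 0; r < nr; ++r) {
        const double rr = r0 + r;
        fy(r) = pix_int(rr, q(2), q(3));
      }
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          const double res = zz(c * nr + r) - (q(4) + q(0) * fx(c) * fy(r));
          rss_new += res * res;
        }
      if (rss_new <= rss) {
        const double shift = std::max(std::abs(delta(1)), std::abs(delta(2)));
        p = q;
        lambda = std::max(lambda / 3.0, 1e-12);
        stepped = true;
        if (shift < 1e-4 && std::abs(rss - rss_new) <= 1e-10 * (rss + 1e-30)) {
          rss = rss_new; converged = true;
        }
        rss = rss_new;
        break;
      }
      lambda *= 10;
    }
    if (converged || !stepped) break;
  }

  FitResult f;
  f.amp = p(0); f.x = p(1); f.y = p(2); f.sigma = p(3); f.bg = p(4);
  f.rss = rss; f.converged = converged;
  const bool sane = R_finite(f.x) && R_finite(f.y) && R_finite(f.sigma) &&
    f.sigma > smin && f.sigma < smax && f.amp > 0;
  if (!sane) {
    FitResult fb = moment_estimate(z, r0, c0);
    fb.converged = false;
    return fb;
  }
  return f;
}

// Fit all candidates; returns one row per candidate.
// mass = amp (total integrated background-subtracted counts).
// [[Rcpp::export]]
DataFrame fit_spots_cpp(NumericMatrix img, IntegerVector row, IntegerVector col,
                        int half, int max_iter, double prefilter_mass) {
  const int n = row.size();
  NumericVector x(n), y(n), sigma(n), mass(n), bg(n), rss(n);
  LogicalVector conv(n);
  for (int i = 0; i < n; ++i) {
    FitResult f = fit_one(img, row[i], col[i], half, max_iter, prefilter_mass);
    x[i] = f.x; y[i] = f.y; sigma[i] = f.sigma;
    mass[i] = f.amp; bg[i] = f.bg; rss[i] = f.rss; conv[i] = f.converged;
  }
  return DataFrame::create(_["x_px"] = x, _["y_px"] = y, _["sigma_px"] = sigma,
                           _["intensity"] = mass, _["background"] = bg,
                           _["rss"] = rss, _["converged"] = conv);
}
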