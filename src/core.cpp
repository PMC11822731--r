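// Hot numerical primitives for evacount.
//
// Everything here is deliberately simple and deterministic: separable
// convolution with replicate padding, a strict local-maximum scan, integrated
// 2-D Gaussian rendering, camera-noise application driven by R's RNG, a
// damped Gauss-Newton fitter for the symmetric-Gaussian-plus-constant spot
// model, and an exact grid-accelerated nearest-neighbour search.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable convolution, replicate boundary. Kernel length must be odd.
// [[Rcpp::export(name = ".cpp_sep_convolve")]]
NumericMatrix cpp_sep_convolve(const NumericMatrix& img,
                               const NumericVector& kernel) {
  const int nr = img.nrow(), nc = img.ncol(), nk = kernel.size();
  const int h = nk / 2;
  if (nk % 2 == 0) stop("kernel length must be odd");
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical direction, index i)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = 0; k < nk; ++k) {
        int ii = i + k - h;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += kernel[k] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  // along columns (horizontal direction, index j)
  for (int j = 0; j < nc; ++j) {
    for (int k = 0; k < nk; ++k) {
      int jj = j + k - h;
      if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
      const double w = kernel[k];
      for (int i = 0; i < nr; ++i) out(i, j) += w * tmp(i, jj);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Strict local maxima above `threshold` within a Chebyshev `radius` window.
// Plateaus yield exactly one maximum (the first pixel in scan order).
// Returns a 2-column integer matrix of 1-based (row, col).
// [[Rcpp::export(name = ".cpp_local_maxima")]]
IntegerMatrix cpp_local_maxima(const NumericMatrix& img, double threshold,
                               int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> rows, cols;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double v = img(i, j);
      if (!(v > threshold)) continue;
      bool is_max = true;
      for (int dj = -radius; dj <= radius && is_max; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -radius; di <= radius; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          const double nb = img(ii, jj);
          // earlier in column-major scan order: (jj, ii) before (j, i)
          const bool earlier = (jj < j) || (jj == j && ii < i);
          if (earlier ? (nb >= v) : (nb > v)) { is_max = false; break; }
        }
      }
      if (is_max) { rows.push_back(i + 1); cols.push_back(j + 1); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k];
    out(k, 1) = cols[k];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Add integrated symmetric Gaussians to an image in place (returns a copy).
// Positions are 0-based pixel coordinates with pixel centres at integers
// (x = column, y = row); each spot integrates to its intensity over the
// infinite plane and is rendered on a +/- `extent`-pixel window.
// [[Rcpp::export(name = ".cpp_add_spots")]]
NumericMatrix cpp_add_spots(const NumericMatrix& img,
                            const NumericVector& x, const NumericVector& y,
                            const NumericVector& intensity, double sigma,
                            int extent) {
  NumericMatrix out = clone(img);
  const int nr = out.nrow(), nc = out.ncol(), n = x.size();
  for (int s = 0; s < n; ++s) {
    const int jlo = std::max(0, (int)std::floor(x[s]) - extent);
    const int jhi = std::min(nc - 1, (int)std::ceil(x[s]) + extent);
    const int ilo = std::max(0, (int)std::floor(y[s]) - extent);
    const int ihi = std::min(nr - 1, (int)std::ceil(y[s]) + extent);
    if (jlo > jhi || ilo > ihi) continue;
    std::vector<double> fx(jhi - jlo + 1), fy(ihi - ilo + 1);
    for (int j = jlo; j <= jhi; ++j)
      fx[j - jlo] = R::pnorm(j + 0.5, x[s], sigma, 1, 0) -
                    R::pnorm(j - 0.5, x[s], sigma, 1, 0);
    for (int i = ilo; i <= ihi; ++i)
      fy[i - ilo] = R::pnorm(i + 0.5, y[s], sigma, 1, 0) -
                    R::pnorm(i - 0.5, y[s], sigma, 1, 0);
    for (int j = jlo; j <= jhi; ++j) {
      const double cx = intensity[s] * fx[j - jlo];
      for (int i = ilo; i <= ihi; ++i) out(i, j) += cx * fy[i - ilo];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Camera model: optional Poisson shot noise on (signal + offset), Gaussian
// read noise, rounding, clipping to [0, 65535]. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".cpp_camera_noise")]]
NumericMatrix cpp_camera_noise(const NumericMatrix& signal, double offset,
                               bool shot_noise, double read_noise_sd) {
  const int n = signal.size();
  NumericMatrix out(signal.nrow(), signal.ncol());
  RNGScope scope;
  for (int k = 0; k < n; ++k) {
    double v = signal[k] + offset;
    if (v < 0) v = 0;
    if (shot_noise) v = R::rpois(v);
    if (read_noise_sd > 0) v += R::rnorm(0.0, read_noise_sd);
    v = std::round(v);
    if (v < 0) v = 0; else if (v > 65535.0) v = 65535.0;
    out[k] = v;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Damped Gauss-Newton fit of the pixel-integrated Gaussian
//   v(i, j) = b + I * Fx(j) * Fy(i),
//   Fx(j) = Phi((j + 1/2 - x0)/s) - Phi((j - 1/2 - x0)/s)
// over one pixel window (the model the camera actually samples). Parameters
// p = (x0, y0, I, s, b); returns (x0, y0, I, sigma, b, converged, rss).
static inline double phi_cdf(double z) { return 0.5 * erfc(-z * M_SQRT1_2); }
static inline double phi_pdf(double z) {
  return 0.3989422804014327 * std::exp(-0.5 * z * z);
}

// 1-D integrated-Gaussian factors and derivatives along one axis.
static void axis_factors(const arma::vec& c, double c0, double s,
                         arma::vec& F, arma::vec& dF_dc0, arma::vec& dF_ds) {
  const int n = c.n_elem;
  F.set_size(n); dF_dc0.set_size(n); dF_ds.set_size(n);
  for (int k = 0; k < n; ++k) {
    const double a = (c[k] - 0.5 - c0) / s, b = (c[k] + 0.5 - c0) / s;
    const double pa = phi_pdf(a), pb = phi_pdf(b);
    F[k] = phi_cdf(b) - phi_cdf(a);
    dF_dc0[k] = (pa - pb) / s;
    dF_ds[k] = (a * pa - b * pb) / s;
  }
}

static arma::vec::fixed<5> gn_step(const arma::vec& px, const arma::vec& py,
                                   const arma::vec& val, const arma::vec& p,
                                   double lambda, double* sse_out) {
  arma::vec Fx, dFx_dx0, dFx_ds, Fy, dFy_dy0, dFy_ds;
  axis_factors(px, p[0], p[3], Fx, dFx_dx0, dFx_ds);
  axis_factors(py, p[1], p[3], Fy, dFy_dy0, dFy_ds);
  const arma::vec FxFy = Fx % Fy;
  const arma::vec model = p[4] + p[2] * FxFy;
  const arma::vec r = model - val;
  if (sse_out) *sse_out = arma::dot(r, r);
  arma::mat J(px.n_elem, 5);
  J.col(0) = p[2] * (dFx_dx0 % Fy);
  J.col(1) = p[2] * (Fx % dFy_dy0);
  J.col(2) = FxFy;
  J.col(3) = p[2] * (dFx_ds % Fy + Fx % dFy_ds);
  J.col(4).ones();
  arma::mat JtJ = J.t() * J;
  JtJ.diag() += lambda * JtJ.diag() + 1e-12;
  arma::vec delta;
  const bool ok = arma::solve(delta, JtJ, -J.t() * r,
                              arma::solve_opts::no_approx);
  arma::vec::fixed<5> out;
  if (!ok) out.fill(arma::datum::nan); else out = delta;
  return out;
}

static void fit_one(const arma::vec& px, const arma::vec& py,
                    const arma::vec& val, double x0, double y0,
                    double sigma0, double bg0, int max_iter, double* res) {
  arma::vec p(5);
  p[0] = x0; p[1] = y0; p[3] = sigma0; p[4] = bg0;
  p[2] = (val.max() - bg0) * 2.0 * M_PI * sigma0 * sigma0;
  if (p[2] <= 0) p[2] = 1.0;
  double lambda = 1e-3, sse = arma::datum::inf;
  bool converged = false;
  {
    double s0;
    gn_step(px, py, val, p, 0.0, &s0);
    sse = s0;
  }
  for (int it = 0; it < max_iter; ++it) {
    bool accepted = false;
    for (int inner = 0; inner < 8; ++inner) {
      double dummy;
      arma::vec::fixed<5> delta = gn_step(px, py, val, p, lambda, &dummy);
      if (!delta.is_finite()) { lambda *= 10.0; continue; }
      arma::vec cand = p + arma::vec(delta);
      if (cand[3] < 0.25) cand[3] = 0.25;
      if (cand[3] > px.n_elem) cand[3] = px.n_elem;
      double sse_new;
      gn_step(px, py, val, cand, 0.0, &sse_new);
      if (std::isfinite(sse_new) && sse_new <= sse * (1.0 + 1e-12)) {
        const double shift = std::max(std::abs(delta[0]), std::abs(delta[1]));
        p = cand;
        const bool small = shift < 1e-7 && std::abs(delta[3]) < 1e-7;
        sse = sse_new;
        lambda = std::max(lambda / 5.0, 1e-12);
        accepted = true;
        if (small) converged = true;
        break;
      }
      lambda *= 10.0;
    }
    if (!accepted || converged) break;
  }
  res[0] = p[0]; res[1] = p[1]; res[2] = p[2]; res[3] = p[3]; res[4] = p[4];
  res[5] = converged ? 1.0 : 0.0;
  res[6] = sse;
}

// Batch fit at candidate positions (0-based pixel coords). Windows are
// clipped at the image border. Returns one row per candidate:
// x, y, amplitude, sigma, background, converged, rss.
// [[Rcpp::export(name = ".cpp_fit_spots")]]
NumericMatrix cpp_fit_spots(const NumericMatrix& img,
                            const NumericVector& x0, const NumericVector& y0,
                            int window, double sigma0, double bg0,
                            int max_iter) {
  const int nr = img.nrow(), nc = img.ncol(), n = x0.size();
  const int h = window / 2;
  NumericMatrix out(n, 7);
  for (int s = 0; s < n; ++s) {
    const int jc = (int)std::round(x0[s]), ic = (int)std::round(y0[s]);
    const int jlo = std::max(0, jc - h), jhi = std::min(nc - 1, jc + h);
    const int ilo = std::max(0, ic - h), ihi = std::min(nr - 1, ic + h);
    const int np = (jhi - jlo + 1) * (ihi - ilo + 1);
    arma::vec px(np), py(np), val(np);
    int k = 0;
    for (int j = jlo; j <= jhi; ++j)
      for (int i = ilo; i <= ihi; ++i, ++k) {
        px[k] = j; py[k] = i; val[k] = img(i, j);
      }
    double res[7];
    fit_one(px, py, val, x0[s], y0[s], sigma0, bg0, max_iter, res);
    for (int m = 0; m < 7; ++m) out(s, m) = res[m];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pearson correlation of the overlap of a and b for each integer offset
// (dx, dy): b's pixel (x, y) aligns with a's pixel (x + dx, y + dy).
// Overlaps smaller than `min_px` pixels per side give NA.
// [[Rcpp::export(name = ".cpp_overlap_corr")]]
NumericVector cpp_overlap_corr(const NumericMatrix& a,
                               const NumericMatrix& b,
                               const IntegerVector& dx,
                               const IntegerVector& dy, int min_px) {
  const int nra = a.nrow(), nca = a.ncol(), nrb = b.nrow(), ncb = b.ncol();
  const int ns = dx.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    const int ox = dx[s], oy = dy[s];
    const int j0 = std::max(0, ox), j1 = std::min(nca - 1, ncb - 1 + ox);
    const int i0 = std::max(0, oy), i1 = std::min(nra - 1, nrb - 1 + oy);
    if (j1 - j0 + 1 < min_px || i1 - i0 + 1 < min_px) {
      out[s] = NA_REAL;
      continue;
    }
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    long n = 0;
    for (int j = j0; j <= j1; ++j) {
      const double* ca = &a(0, j);
      const double* cb = &b(0, j - ox);
      for (int i = i0; i <= i1; ++i) {
        const double va = ca[i], vb = cb[i - oy];
        sa += va; sb += vb; saa += va * va; sbb += vb * vb; sab += va * vb;
        ++n;
      }
    }
    const double va_var = saa - sa * sa / n, vb_var = sbb - sb * sb / n;
    if (va_var <= 0 || vb_var <= 0) { out[s] = NA_REAL; continue; }
    out[s] = (sab - sa * sb / n) / std::sqrt(va_var * vb_var);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact nearest-neighbour distances via a uniform cell grid with ring
// expansion; after scanning all cells within Chebyshev ring m, any unseen
// point is at least m * cell apart, so the current best is final once
// best <= m * cell.
// [[Rcpp::export(name = ".cpp_nn_distances")]]
NumericVector cpp_nn_distances(const NumericVector& x,
                               const NumericVector& y) {
  const int n = x.size();
  NumericVector out(n);
  if (n < 2) stop("need at least 2 points");
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double w = std::max(xmax - xmin, 1e-12);
  const double hgt = std::max(ymax - ymin, 1e-12);
  int ngrid = std::max(1, (int)std::floor(std::sqrt((double)n)));
  const double cell = std::max(w, hgt) / ngrid * 1.0000001;
  const int gx = std::max(1, (int)std::floor(w / cell) + 1);
  const int gy = std::max(1, (int)std::floor(hgt / cell) + 1);
  std::vector<std::vector<int> > bins((size_t)gx * gy);
  std::vector<int> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = std::min(gx - 1, (int)((x[i] - xmin) / cell));
    cy[i] = std::min(gy - 1, (int)((y[i] - ymin) / cell));
    bins[(size_t)cx[i] * gy + cy[i]].push_back(i);
  }
  const int mmax = std::max(gx, gy);
  for (int i = 0; i < n; ++i) {
    double best = arma::datum::inf;
    for (int m = 0; m <= mmax; ++m) {
      // scan ring m (all cells at Chebyshev distance m)
      for (int dj = -m; dj <= m; ++dj) {
        const int jj = cx[i] + dj;
        if (jj < 0 || jj >= gx) continue;
        const bool edge_col = (std::abs(dj) == m);
        for (int di = -m; di <= m; ++di) {
          if (!edge_col && std::abs(di) != m) continue;
          const int ii = cy[i] + di;
          if (ii < 0 || ii >= gy) continue;
          const std::vector<int>& b = bins[(size_t)jj * gy + ii];
          for (size_t t = 0; t < b.size(); ++t) {
            const int q = b[t];
            if (q == i) continue;
            const double dx = x[q] - x[i], dy_ = y[q] - y[i];
            const double d2 = dx * dx + dy_ * dy_;
            if (d2 < best) best = d2;
          }
        }
      }
      if (std::sqrt(best) <= (double)m * cell) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
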