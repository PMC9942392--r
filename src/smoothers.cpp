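#include <Rcpp.h>
using namespace Rcpp;

// Local-linear kernel smoothers used by the sparse-FPCA machinery.
// Gaussian kernel throughout; weighted least squares solved in closed form.

// [[Rcpp::export]]
NumericVector lls1d_cpp(NumericVector x, NumericVector y, NumericVector w,
                        NumericVector xout, double h) {
  int n = x.size(), m = xout.size();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double s0 = 0, s1 = 0, s2 = 0, t0 = 0, t1 = 0;
    for (int i = 0; i < n; ++i) {
      double d = x[i] - xout[j];
      double u = d / h;
      if (std::fabs(u) > 6.0) continue;  // kernel support cutoff
      double k = w[i] * std::exp(-0.5 * u * u);
      s0 += k; s1 += k * d; s2 += k * d * d;
      t0 += k * y[i]; t1 += k * d * y[i];
    }
    double det = s0 * s2 - s1 * s1;
    if (det > 1e-300 && s0 > 0) {
      out[j] = (s2 * t0 - s1 * t1) / det;
    } else if (s0 > 0) {
      out[j] = t0 / s0;  // degenerate design: Nadaraya-Watson fallback
    } else {
      out[j] = NA_REAL;
    }
  }
  return out;
}

// Fitted values at the data points themselves plus the hat-matrix diagonal,
// for generalized cross-validation. H_ii = k_i * S2 / det at eval point x_i
// (where its own distance is zero).
// [[Rcpp::export]]
List lls1d_gcv_cpp(NumericVector x, NumericVector y, NumericVector w, double h) {
  int n = x.size();
  NumericVector fit(n), hat(n);
  for (int j = 0; j < n; ++j) {
    double s0 = 0, s1 = 0, s2 = 0, t0 = 0, t1 = 0;
    for (int i = 0; i < n; ++i) {
      double d = x[i] - x[j];
      double u = d / h;
      if (std::fabs(u) > 6.0) continue;
      double k = w[i] * std::exp(-0.5 * u * u);
      s0 += k; s1 += k * d; s2 += k * d * d;
      t0 += k * y[i]; t1 += k * d * y[i];
    }
    double det = s0 * s2 - s1 * s1;
    if (det > 1e-300 && s0 > 0) {
      fit[j] = (s2 * t0 - s1 * t1) / det;
      hat[j] = w[j] * s2 / det;
    } else if (s0 > 0) {
      fit[j] = t0 / s0;
      hat[j] = w[j] / s0;
    } else {
      fit[j] = NA_REAL; hat[j] = 0;
    }
  }
  return List::create(_["fitted"] = fit, _["hat"] = hat);
}

// Local-linear plane fit on scattered (x1, x2, y) evaluated on a grid.
// Same bandwidth in both directions. Solves the 3x3 weighted normal
// equations by Cramer's rule at each grid node.
// [[Rcpp::export]]
NumericMatrix lls2d_cpp(NumericVector x1, NumericVector x2, NumericVector y,
                        NumericVector w, NumericVector g1, NumericVector g2,
                        double h) {
  int n = x1.size(), m1 = g1.size(), m2 = g2.size();
  NumericMatrix out(m1, m2);
  for (int a = 0; a < m1; ++a) {
    for (int b = 0; b < m2; ++b) {
      double S00 = 0, S10 = 0, S01 = 0, S20 = 0, S11 = 0, S02 = 0;
      double T0 = 0, T1 = 0, T2 = 0;
      for (int i = 0; i < n; ++i) {
        double d1 = x1[i] - g1[a];
        double d2 = x2[i] - g2[b];
        double u1 = d1 / h, u2 = d2 / h;
        if (std::fabs(u1) > 6.0 || std::fabs(u2) > 6.0) continue;
        double k = w[i] * std::exp(-0.5 * (u1 * u1 + u2 * u2));
        S00 += k; S10 += k * d1; S01 += k * d2;
        S20 += k * d1 * d1; S11 += k * d1 * d2; S02 += k * d2 * d2;
        T0 += k * y[i]; T1 += k * d1 * y[i]; T2 += k * d2 * y[i];
      }
      double det = S00 * (S20 * S02 - S11 * S11)
                 - S10 * (S10 * S02 - S11 * S01)
                 + S01 * (S10 * S11 - S20 * S01);
      if (std::fabs(det) > 1e-300 && S00 > 0) {
        // first component of A^{-1} t
        double c0 = (S20 * S02 - S11 * S11);
        double c1 = -(S10 * S02 - S01 * S11);
        double c2 = (S10 * S11 - S01 * S20);
        out(a, b) = (c0 * T0 + c1 * T1 + c2 * T2) / det;
      } else if (S00 > 0) {
        out(a, b) = T0 / S00;
      } else {
        out(a, b) = NA_REAL;
      }
    }
  }
  return out;
}

// GCV statistics for the 2-D smoother: evaluate at the data points and
// accumulate residual sum of squares and hat-trace.
// [[Rcpp::export]]
List lls2d_gcv_cpp(NumericVector x1, NumericVector x2, NumericVector y,
                   NumericVector w, double h) {
  int n = x1.size();
  double rss = 0, tr = 0;
  int used = 0;
  for (int j = 0; j < n; ++j) {
    double S00 = 0, S10 = 0, S01 = 0, S20 = 0, S11 = 0, S02 = 0;
    double T0 = 0, T1 = 0, T2 = 0;
    for (int i = 0; i < n; ++i) {
      double d1 = x1[i] - x1[j];
      double d2 = x2[i] - x2[j];
      double u1 = d1 / h, u2 = d2 / h;
      if (std::fabs(u1) > 6.0 || std::fabs(u2) > 6.0) continue;
      double k = w[i] * std::exp(-0.5 * (u1 * u1 + u2 * u2));
      S00 += k; S10 += k * d1; S01 += k * d2;
      S20 += k * d1 * d1; S11 += k * d1 * d2; S02 += k * d2 * d2;
      T0 += k * y[i]; T1 += k * d1 * y[i]; T2 += k * d2 * y[i];
    }
    double det = S00 * (S20 * S02 - S11 * S11)
               - S10 * (S10 * S02 - S11 * S01)
               + S01 * (S10 * S11 - S20 * S01);
    double fit, hat;
    if (std::fabs(det) > 1e-300 && S00 > 0) {
      double c0 = (S20 * S02 - S11 * S11);
      double c1 = -(S10 * S02 - S01 * S11);
      double c2 = (S10 * S11 - S01 * S20);
      fit = (c0 * T0 + c1 * T1 + c2 * T2) / det;
      hat = w[j] * c0 / det;
    } else if (S00 > 0) {
      fit = T0 / S00;
      hat = w[j] / S00;
    } else {
      continue;
    }
    rss += (y[j] - fit) * (y[j] - fit);
    tr += hat;
    ++used;
  }
  return List::create(_["rss"] = rss, _["trace"] = tr, _["n"] = used);
}
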