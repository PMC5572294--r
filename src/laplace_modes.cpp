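#include <Rcpp.h>
using namespace Rcpp;

// Per-subject damped-Newton search for the conditional modes of the joint
// log-density sum_i ll(y_i, eta_i) - |Linv b|^2 / 2, for random-effect
// dimension q = 1 or 2, where Linv is the inverse lower Cholesky factor of
// the random-effect covariance (so |Linv b|^2 = b' Omega b, evaluated
// without the catastrophic cancellation the raw quadratic form shows when
// Omega is near singular).  Canonical links only (binomial-logit,
// poisson-log), so the joint is strictly concave in b and Newton with step
// halving is globally convergent.  fam: 0 = binomial, 1 = poisson.

static inline double ll_one(double y, double eta, int fam) {
  if (fam == 0) {
    double sp = eta > 0 ? eta + log1p(exp(-eta)) : log1p(exp(eta));
    return y * eta - sp;
  }
  return y * eta - exp(eta) - lgamma(y + 1.0);
}

static inline double mu_one(double eta, int fam) {
  return fam == 0 ? 1.0 / (1.0 + exp(-eta)) : exp(eta);
}

static inline double w_one(double mu, int fam) {
  return fam == 0 ? mu * (1.0 - mu) : mu;
}

// [[Rcpp::export]]
List cpp_find_modes(NumericVector offset, NumericMatrix Z, NumericVector y,
                    IntegerVector start, IntegerVector len,
                    NumericMatrix Linv, NumericMatrix b_init,
                    int fam, double tol, double decr_tol, int max_iter) {
  const int J = start.size();
  const int q = Z.ncol();
  NumericMatrix b = clone(b_init);
  NumericVector joint(J), M11(J), M12(J), M22(J);
  bool all_conv = true;

  const double li11 = Linv(0, 0);
  const double li21 = q == 2 ? Linv(1, 0) : 0.0;
  const double li22 = q == 2 ? Linv(1, 1) : 0.0;
  // Omega entries, assembled from Linv products (sums of squares: stable)
  const double o11 = li11 * li11 + li21 * li21;
  const double o12 = q == 2 ? li21 * li22 : 0.0;
  const double o22 = q == 2 ? li22 * li22 : 0.0;

  for (int j = 0; j < J; ++j) {
    const int s = start[j], n = len[j];
    double b1 = b(j, 0), b2 = q == 2 ? b(j, 1) : 0.0;

    auto fval = [&](double u1, double u2) {
      double f = 0.0;
      for (int i = 0; i < n; ++i) {
        double eta = offset[s + i] + Z(s + i, 0) * u1 +
                     (q == 2 ? Z(s + i, 1) * u2 : 0.0);
        f += ll_one(y[s + i], eta, fam);
      }
      double w1 = li11 * u1;
      double w2 = q == 2 ? li21 * u1 + li22 * u2 : 0.0;
      f -= 0.5 * (w1 * w1 + w2 * w2);
      return f;
    };

    double f = fval(b1, b2);
    bool conv = false;
    for (int it = 0; it < max_iter; ++it) {
      double g1 = 0, g2 = 0, a11 = 0, a12 = 0, a22 = 0;
      for (int i = 0; i < n; ++i) {
        double z1 = Z(s + i, 0), z2 = q == 2 ? Z(s + i, 1) : 0.0;
        double eta = offset[s + i] + z1 * b1 + z2 * b2;
        double mu = mu_one(eta, fam), w = w_one(mu, fam), r = y[s + i] - mu;
        g1 += z1 * r;
        a11 += z1 * z1 * w;
        if (q == 2) { g2 += z2 * r; a12 += z1 * z2 * w; a22 += z2 * z2 * w; }
      }
      // prior gradient -Omega b as Linv' (Linv b): grouped to avoid
      // cancellation between huge same-order terms
      double w1 = li11 * b1;
      double w2 = q == 2 ? li21 * b1 + li22 * b2 : 0.0;
      g1 -= li11 * w1 + li21 * w2;
      a11 += o11;
      if (q == 2) { g2 -= li22 * w2; a12 += o12; a22 += o22; }

      double gn = std::max(std::fabs(g1), std::fabs(g2));

      double s1, s2 = 0.0;
      if (q == 1) {
        s1 = g1 / a11;
      } else {
        double det = a11 * a22 - a12 * a12;
        s1 = (a22 * g1 - a12 * g2) / det;
        s2 = (a11 * g2 - a12 * g1) / det;
      }
      // Newton decrement g'H^{-1}g is scale-invariant, unlike the raw
      // gradient norm, whose floating-point floor grows with Omega when a
      // variance component is near zero
      double decr = s1 * g1 + s2 * g2;
      if (gn < tol || decr < decr_tol) { conv = true; break; }

      double fac = 1.0;
      bool moved = false;
      for (int h = 0; h < 30; ++h) {
        double fn = fval(b1 + fac * s1, b2 + fac * s2);
        if (fn >= f - 1e-12) {
          b1 += fac * s1;
          b2 += fac * s2;
          f = fn;
          moved = true;
          break;
        }
        fac *= 0.5;
      }
      if (!moved) { conv = true; break; }  // no improving step: at the mode
    }
    if (!conv) all_conv = false;

    double m11 = 0, m12 = 0, m22 = 0;
    for (int i = 0; i < n; ++i) {
      double z1 = Z(s + i, 0), z2 = q == 2 ? Z(s + i, 1) : 0.0;
      double eta = offset[s + i] + z1 * b1 + z2 * b2;
      double w = w_one(mu_one(eta, fam), fam);
      m11 += z1 * z1 * w;
      if (q == 2) { m12 += z1 * z2 * w; m22 += z2 * z2 * w; }
    }
    b(j, 0) = b1;
    if (q == 2) b(j, 1) = b2;
    joint[j] = f;
    M11[j] = m11;
    M12[j] = m12;
    M22[j] = m22;
  }
  return List::create(_["b"] = b, _["joint"] = joint, _["M11"] = M11,
                      _["M12"] = M12, _["M22"] = M22,
                      _["converged"] = all_conv);
}
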