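#include <Rcpp.h>
using namespace Rcpp;

// Draw from inverse-gamma(shape, scale): density propto x^{-shape-1} exp(-scale/x)
static inline double rinvgamma(double shape, double scale) {
  return scale / R::rgamma(shape, 1.0);
}

// Draw z ~ N(mean, Sigma) for a 2x2 covariance via Cholesky.
static inline void rmvnorm2(const double mean[2], const double S[3],
                            double out[2]) {
  // S = (s11, s12, s22)
  double l11 = std::sqrt(S[0]);
  double l21 = S[1] / l11;
  double arg = S[2] - l21 * l21;
  double l22 = std::sqrt(arg > 0.0 ? arg : 0.0);
  double z1 = R::norm_rand(), z2 = R::norm_rand();
  out[0] = mean[0] + l11 * z1;
  out[1] = mean[1] + l21 * z1 + l22 * z2;
}

// ----------------------------------------------------------------------------
// Emax model: y_i = E0 + Emax * d_i/(ED50 + d_i) + eps, eps ~ N(0, sigma2)
// Metropolis-within-Gibbs: conjugate Normal for (E0, Emax), conjugate
// inverse-gamma for sigma2, random-walk Metropolis on log(ED50) with step
// adaptation during burn-in.
// ----------------------------------------------------------------------------

// [[Rcpp::export(name = ".emax_mcmc_cpp")]]
List emax_mcmc_cpp(NumericVector y, NumericVector dose, NumericVector grid,
                   NumericVector prior_mean, NumericVector prior_var,
                   double sig_shape, double sig_scale,
                   int n_burnin, int n_retained,
                   double init_e0, double init_emax, double init_ed50,
                   double init_sigma2,
                   bool fix_ed50, bool fix_sigma2, double mh_step) {
  int n = y.size(), J = grid.size();
  int n_iter = n_burnin + n_retained;

  double e0 = init_e0, emax = init_emax, ed50 = init_ed50, sig2 = init_sigma2;
  double step = mh_step;

  NumericMatrix draws(n_retained, 4);
  NumericMatrix dose_means(n_retained, J);

  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) x[i] = dose[i] / (ed50 + dose[i]);

  // precision-weighted prior pieces for (E0, Emax)
  double pm0 = prior_mean[0], pm1 = prior_mean[1];
  double pv0 = prior_var[0], pv1 = prior_var[1];
  double ed50_m = prior_mean[2], ed50_v = prior_var[2];

  int acc = 0, acc_window = 0, prop_window = 0, prop_total = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- (E0, Emax) | ED50, sigma2: conjugate bivariate normal ---
    double sxx = 0.0, sx = 0.0, sxy = 0.0, sy = 0.0;
    for (int i = 0; i < n; ++i) {
      sx += x[i]; sxx += x[i] * x[i];
      sy += y[i]; sxy += x[i] * y[i];
    }
    double p11 = 1.0 / pv0 + n / sig2;
    double p12 = sx / sig2;
    double p22 = 1.0 / pv1 + sxx / sig2;
    double b1 = pm0 / pv0 + sy / sig2;
    double b2 = pm1 / pv1 + sxy / sig2;
    double det = p11 * p22 - p12 * p12;
    double V[3] = { p22 / det, -p12 / det, p11 / det };
    double m[2] = { V[0] * b1 + V[1] * b2, V[1] * b1 + V[2] * b2 };
    double beta[2];
    rmvnorm2(m, V, beta);
    e0 = beta[0]; emax = beta[1];

    // --- sigma2 | rest: conjugate inverse-gamma ---
    double ssr = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - e0 - emax * x[i];
      ssr += r * r;
    }
    if (!fix_sigma2) sig2 = rinvgamma(sig_shape + 0.5 * n, sig_scale + 0.5 * ssr);

    // --- ED50 | rest: random-walk Metropolis on log(ED50) ---
    if (!fix_ed50) {
      double lp_cur = -0.5 * ssr / sig2
        - 0.5 * (ed50 - ed50_m) * (ed50 - ed50_m) / ed50_v
        + std::log(ed50); // Jacobian of log transform
      double ed50_new = std::exp(std::log(ed50) + step * R::norm_rand());
      double ssr_new = 0.0;
      for (int i = 0; i < n; ++i) {
        double xn = dose[i] / (ed50_new + dose[i]);
        double r = y[i] - e0 - emax * xn;
        ssr_new += r * r;
      }
      double lp_new = -0.5 * ssr_new / sig2
        - 0.5 * (ed50_new - ed50_m) * (ed50_new - ed50_m) / ed50_v
        + std::log(ed50_new);
      ++prop_window; ++prop_total;
      if (std::log(R::unif_rand()) < lp_new - lp_cur) {
        ed50 = ed50_new;
        for (int i = 0; i < n; ++i) x[i] = dose[i] / (ed50 + dose[i]);
        if (it >= n_burnin) ++acc;
        ++acc_window;
      }
      // adapt step toward 20-50% acceptance during burn-in only
      if (it < n_burnin && prop_window == 50) {
        double rate = acc_window / 50.0;
        if (rate > 0.5) step *= 1.25;
        else if (rate < 0.2) step *= 0.8;
        acc_window = 0; prop_window = 0;
      }
    }

    if (it >= n_burnin) {
      int k = it - n_burnin;
      draws(k, 0) = e0; draws(k, 1) = emax;
      draws(k, 2) = ed50; draws(k, 3) = sig2;
      for (int j = 0; j < J; ++j)
        dose_means(k, j) = e0 + emax * grid[j] / (ed50 + grid[j]);
    }
  }

  double acc_rate = NA_REAL;
  if (!fix_ed50 && n_retained > 0) acc_rate = (double)acc / n_retained;
  return List::create(_["draws"] = draws, _["dose_means"] = dose_means,
                      _["accept_rate"] = acc_rate, _["mh_step"] = step);
}

// ----------------------------------------------------------------------------
// Second-order NDLM over the dose index j = 1..J:
//   y_ij ~ N(theta_j, sigma2)
//   theta_j = theta_{j-1} + delta_{j-1} + omega_j,  omega_j ~ N(0, sig_th2)
//   delta_j = delta_{j-1} + v_j,                    v_j     ~ N(0, sig_de2)
// Gibbs: FFBS for the joint state (theta, delta), conjugate inverse-gamma for
// the three variances. Dose indices with no observations are pure evolution
// steps.
// ----------------------------------------------------------------------------

// [[Rcpp::export(name = ".ndlm_mcmc_cpp")]]
List ndlm_mcmc_cpp(NumericVector y, IntegerVector idx, int J,
                   double th1_mean, double th1_var,
                   double de1_mean, double de1_var,
                   double sig_shape, double sig_scale,
                   double th_shape, double th_scale,
                   double de_shape, double de_scale,
                   int n_burnin, int n_retained,
                   double init_sigma2, double init_sig_th2, double init_sig_de2,
                   bool fix_variances) {
  int n = y.size();
  int n_iter = n_burnin + n_retained;

  // sufficient statistics per dose index
  std::vector<double> nj(J, 0.0), sumj(J, 0.0), ssj(J, 0.0);
  for (int i = 0; i < n; ++i) {
    int j = idx[i] - 1;
    nj[j] += 1.0; sumj[j] += y[i]; ssj[j] += y[i] * y[i];
  }

  double sig2 = init_sigma2, sth2 = init_sig_th2, sde2 = init_sig_de2;

  NumericMatrix theta_draws(n_retained, J), delta_draws(n_retained, J);
  NumericMatrix var_draws(n_retained, 3);

  // filter storage: means m (2), covariances C (3: c11,c12,c22), and the
  // one-step-ahead predictions a, R
  std::vector<double> m(2 * J), C(3 * J), a(2 * J), R(3 * J);
  std::vector<double> th(J), de(J);

  for (int it = 0; it < n_iter; ++it) {
    // ---- forward filter ----
    for (int j = 0; j < J; ++j) {
      double aj[2], Rj[3];
      if (j == 0) {
        aj[0] = th1_mean; aj[1] = de1_mean;
        Rj[0] = th1_var; Rj[1] = 0.0; Rj[2] = de1_var;
      } else {
        // a = T m_{j-1}, R = T C_{j-1} T' + diag(sth2, sde2)
        double m1 = m[2 * (j - 1)], m2 = m[2 * (j - 1) + 1];
        double c11 = C[3 * (j - 1)], c12 = C[3 * (j - 1) + 1],
               c22 = C[3 * (j - 1) + 2];
        aj[0] = m1 + m2; aj[1] = m2;
        Rj[0] = c11 + 2.0 * c12 + c22 + sth2;
        Rj[1] = c12 + c22;
        Rj[2] = c22 + sde2;
      }
      a[2 * j] = aj[0]; a[2 * j + 1] = aj[1];
      R[3 * j] = Rj[0]; R[3 * j + 1] = Rj[1]; R[3 * j + 2] = Rj[2];
      if (nj[j] > 0.0) {
        double obs_var = sig2 / nj[j];
        double ybar = sumj[j] / nj[j];
        double Q = Rj[0] + obs_var;
        double K1 = Rj[0] / Q, K2 = Rj[1] / Q;
        double e = ybar - aj[0];
        m[2 * j] = aj[0] + K1 * e;
        m[2 * j + 1] = aj[1] + K2 * e;
        C[3 * j] = Rj[0] - K1 * Rj[0];
        C[3 * j + 1] = Rj[1] - K1 * Rj[1];
        C[3 * j + 2] = Rj[2] - K2 * Rj[1];
      } else {
        m[2 * j] = aj[0]; m[2 * j + 1] = aj[1];
        C[3 * j] = Rj[0]; C[3 * j + 1] = Rj[1]; C[3 * j + 2] = Rj[2];
      }
    }

    // ---- backward sampling ----
    {
      double mean[2] = { m[2 * (J - 1)], m[2 * (J - 1) + 1] };
      double S[3] = { C[3 * (J - 1)], C[3 * (J - 1) + 1], C[3 * (J - 1) + 2] };
      double al[2];
      rmvnorm2(mean, S, al);
      th[J - 1] = al[0]; de[J - 1] = al[1];
    }
    for (int j = J - 2; j >= 0; --j) {
      double c11 = C[3 * j], c12 = C[3 * j + 1], c22 = C[3 * j + 2];
      double r11 = R[3 * (j + 1)], r12 = R[3 * (j + 1) + 1],
             r22 = R[3 * (j + 1) + 2];
      // B = C_j T' R_{j+1}^{-1}; with T = [[1,1],[0,1]],
      // C_j T' = [[c11+c12, c12], [c12+c22, c22]]
      double g11 = c11 + c12, g12 = c12;
      double g21 = c12 + c22, g22 = c22;
      double det = r11 * r22 - r12 * r12;
      double i11 = r22 / det, i12 = -r12 / det, i22 = r11 / det;
      double B11 = g11 * i11 + g12 * i12, B12 = g11 * i12 + g12 * i22;
      double B21 = g21 * i11 + g22 * i12, B22 = g21 * i12 + g22 * i22;
      double e1 = th[j + 1] - a[2 * (j + 1)];
      double e2 = de[j + 1] - a[2 * (j + 1) + 1];
      double mean[2] = { m[2 * j] + B11 * e1 + B12 * e2,
                         m[2 * j + 1] + B21 * e1 + B22 * e2 };
      // V = C_j - B R_{j+1} B'
      double BR11 = B11 * r11 + B12 * r12, BR12 = B11 * r12 + B12 * r22;
      double BR21 = B21 * r11 + B22 * r12, BR22 = B21 * r12 + B22 * r22;
      double v11 = c11 - (BR11 * B11 + BR12 * B12);
      double v12 = c12 - (BR11 * B21 + BR12 * B22);
      double v21 = c12 - (BR21 * B11 + BR22 * B12);
      double v22 = c22 - (BR21 * B21 + BR22 * B22);
      double S[3] = { v11 > 0.0 ? v11 : 0.0, 0.5 * (v12 + v21),
                      v22 > 0.0 ? v22 : 0.0 };
      double al[2];
      rmvnorm2(mean, S, al);
      th[j] = al[0]; de[j] = al[1];
    }

    // ---- variance updates ----
    if (!fix_variances) {
      double ssr = 0.0;
      for (int j = 0; j < J; ++j)
        ssr += ssj[j] - 2.0 * th[j] * sumj[j] + nj[j] * th[j] * th[j];
      sig2 = rinvgamma(sig_shape + 0.5 * n, sig_scale + 0.5 * ssr);
      double ssw = 0.0, ssv = 0.0;
      for (int j = 1; j < J; ++j) {
        double w = th[j] - th[j - 1] - de[j - 1];
        double v = de[j] - de[j - 1];
        ssw += w * w; ssv += v * v;
      }
      sth2 = rinvgamma(th_shape + 0.5 * (J - 1), th_scale + 0.5 * ssw);
      sde2 = rinvgamma(de_shape + 0.5 * (J - 1), de_scale + 0.5 * ssv);
    }

    if (it >= n_burnin) {
      int k = it - n_burnin;
      for (int j = 0; j < J; ++j) {
        theta_draws(k, j) = th[j];
        delta_draws(k, j) = de[j];
      }
      var_draws(k, 0) = sig2; var_draws(k, 1) = sth2; var_draws(k, 2) = sde2;
    }
  }

  return List::create(_["theta"] = theta_draws, _["delta"] = delta_draws,
                      _["variances"] = var_draws);
}
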