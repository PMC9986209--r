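// Within-person Gibbs sweep for the two-level dynamic structural equation
// model: single-site imputation of latent states at missing grid slots,
// conjugate draws of each person's means and transition coefficients, and
// accumulation of the innovation sum of squares for the covariance update.
//
// All randomness comes from R's generator (norm_rand), so a single
// set.seed() on the R side makes runs fully reproducible.
//
// Conventions:
//   - series are stored as a T_max x 2 x N cube on the raw score scale;
//     column 0 = stress, column 1 = affect;
//   - person transition coefficients are the 4-vector
//     theta = (phi_ss, phi_as, phi_sa, phi_aa), i.e. the rows of
//       Phi = [ phi_ss  phi_as ]   (stress equation)
//             [ phi_sa  phi_aa ]   (affect equation);
//   - only slots first[i]..last[i] (0-based, fully observed endpoints) are
//     used; leading/trailing missing slots are trimmed on the R side.
//
// The 2-dimensional state algebra is written out in scalars: the sweep runs
// tens of thousands of times over hundreds of persons, and avoiding small
// matrix temporaries in the innermost loops is what keeps a full fit in the
// minutes range on one core.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Draw from N(P^{-1} b, P^{-1}) for a 2x2 precision given by scalars.
static inline void draw_gauss2(double p11, double p12, double p22,
                               double b1, double b2,
                               double& x1, double& x2) {
  // Cholesky P = L L', L lower
  const double l11 = std::sqrt(p11);
  const double l21 = p12 / l11;
  const double l22 = std::sqrt(p22 - l21 * l21);
  // mean: solve P m = b
  const double u1 = b1 / l11;
  const double u2 = (b2 - l21 * u1) / l22;
  const double m2 = u2 / l22;
  const double m1 = (u1 - l21 * m2) / l11;
  // draw: m + L'^{-1} z
  const double z1 = norm_rand(), z2 = norm_rand();
  x2 = m2 + z2 / l22;
  x1 = m1 + (z1 - l21 * (z2 / l22)) / l11;
}

// Draw from N(P^{-1} b, P^{-1}) for a 4x4 precision, with an unrolled
// Cholesky (P = L L', L lower): this runs once per person per iteration and
// dominates the sweep when done through LAPACK.
static inline void draw_gauss4(const double P[4][4], const double b[4],
                               double out[4]) {
  double L[4][4] = {{0}};
  for (int j = 0; j < 4; ++j) {
    double d = P[j][j];
    for (int k = 0; k < j; ++k) d -= L[j][k] * L[j][k];
    L[j][j] = std::sqrt(d);
    for (int i = j + 1; i < 4; ++i) {
      double s = P[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      L[i][j] = s / L[j][j];
    }
  }
  double u[4], m[4], z[4];
  for (int i = 0; i < 4; ++i) {            // L u = b
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * u[k];
    u[i] = s / L[i][i];
  }
  for (int i = 3; i >= 0; --i) {           // L' m = u
    double s = u[i];
    for (int k = i + 1; k < 4; ++k) s -= L[k][i] * m[k];
    m[i] = s / L[i][i];
  }
  for (int i = 0; i < 4; ++i) z[i] = norm_rand();
  for (int i = 3; i >= 0; --i) {           // L' w = z; out = m + w
    double s = z[i];
    for (int k = i + 1; k < 4; ++k) s -= L[k][i] * out[k];
    out[i] = s / L[i][i];
  }
  for (int i = 0; i < 4; ++i) out[i] += m[i];
}

// [[Rcpp::export]]
Rcpp::List within_sweep(Rcpp::NumericVector Ysexp,
                        const arma::imat& obs1,    // T x N, stress observed
                        const arma::imat& obs2,    // T x N, affect observed
                        const arma::ivec& first,
                        const arma::ivec& last,
                        arma::mat mu,              // N x 2
                        arma::mat theta,           // N x 4
                        const arma::mat& sigma_w,
                        const arma::mat& prior_mu_mean,   // N x 2
                        const arma::mat& prior_mu_prec,   // N x 2 (diagonal)
                        const arma::mat& prior_th_mean,   // N x 4
                        const arma::mat& prior_th_prec,   // N x 4 (diagonal)
                        const arma::vec& beta_mu,         // 2
                        const arma::vec& beta_th,         // 4
                        const arma::vec& eta_off,         // N
                        const double sigma_eta2,
                        const bool use_eta,
                        const bool update_states,
                        const bool update_mu,
                        const bool update_theta,
                        const bool compute_derived) {
  Rcpp::IntegerVector dims = Ysexp.attr("dim");
  const uword T = dims[0], N = dims[2];
  cube Y(Ysexp.begin(), T, 2, N, false);    // in-place view

  // W = sigma_w^{-1}
  const double sdet = sigma_w(0, 0) * sigma_w(1, 1) -
                      sigma_w(0, 1) * sigma_w(0, 1);
  const double w11 = sigma_w(1, 1) / sdet;
  const double w12 = -sigma_w(0, 1) / sdet;
  const double w22 = sigma_w(0, 0) / sdet;

  double sse11 = 0, sse12 = 0, sse22 = 0, n_tr = 0;
  vec wstd(4, fill::zeros);
  double n_valid = 0;
  // per-person raw sufficient statistics over the usable transitions,
  // enabling exact within-log-likelihood evaluation at any (mu, Phi):
  // L11 L12 L22 (sum y_t y_t', lagged range) | C11 C12 C21 C22
  // (C_jk = sum y_tj y_{t+1,k}) | U11 U12 U22 (sum y_{t+1} y_{t+1}') |
  // sl1 sl2 (sum y_t) | su1 su2 (sum y_{t+1}) | ntr
  mat pstats(N, 15, fill::zeros);

  for (uword i = 0; i < N; ++i) {
    const int f = first(i), l = last(i);
    if (l - f < 1) continue;
    double* ys = Y.slice_memptr(i);          // stress column
    double* ya = ys + T;                     // affect column
    double a = theta(i, 0), bb = theta(i, 1),
           c = theta(i, 2), d = theta(i, 3); // Phi = [a b; c d]
    double m1 = mu(i, 0), m2 = mu(i, 1);

    // Phi' W Phi entries (recomputed when theta changes)
    double q11, q12, q22;
    auto refresh_q = [&]() {
      const double t11 = a * w11 + c * w12, t12 = a * w12 + c * w22;
      const double t21 = bb * w11 + d * w12, t22 = bb * w12 + d * w22;
      q11 = t11 * a + t12 * c;
      q12 = t11 * bb + t12 * d;
      q22 = t21 * bb + t22 * d;
    };
    refresh_q();

    // ---- impute latent states at missing slots (single-site, exact) ----
    if (update_states) {
      for (int t = f; t <= l; ++t) {
        const bool miss1 = obs1(t, i) == 0, miss2 = obs2(t, i) == 0;
        if (!miss1 && !miss2) continue;
        double p11, p12, p22, b1, b2;
        if (t > f && t < l) {
          const double xm1 = ys[t - 1] - m1, xm2 = ya[t - 1] - m2;
          const double xp1 = ys[t + 1] - m1, xp2 = ya[t + 1] - m2;
          p11 = w11 + q11; p12 = w12 + q12; p22 = w22 + q22;
          const double f1 = a * xm1 + bb * xm2;   // (Phi x_{t-1})
          const double f2 = c * xm1 + d * xm2;
          const double g1 = w11 * xp1 + w12 * xp2; // W x_{t+1}
          const double g2 = w12 * xp1 + w22 * xp2;
          b1 = w11 * f1 + w12 * f2 + a * g1 + c * g2;
          b2 = w12 * f1 + w22 * f2 + bb * g1 + d * g2;
        } else if (t == f) {            // defensive: left end missing
          const double xp1 = ys[t + 1] - m1, xp2 = ya[t + 1] - m2;
          p11 = q11 + 1e-8; p12 = q12; p22 = q22 + 1e-8;
          const double g1 = w11 * xp1 + w12 * xp2;
          const double g2 = w12 * xp1 + w22 * xp2;
          b1 = a * g1 + c * g2;
          b2 = bb * g1 + d * g2;
        } else {                        // t == l, right end missing
          const double xm1 = ys[t - 1] - m1, xm2 = ya[t - 1] - m2;
          p11 = w11; p12 = w12; p22 = w22;
          const double f1 = a * xm1 + bb * xm2;
          const double f2 = c * xm1 + d * xm2;
          b1 = w11 * f1 + w12 * f2;
          b2 = w12 * f1 + w22 * f2;
        }
        if (miss1 && miss2) {
          double x1, x2;
          draw_gauss2(p11, p12, p22, b1, b2, x1, x2);
          ys[t] = m1 + x1;
          ya[t] = m2 + x2;
        } else {
          // V = P^{-1}
          const double pdet = p11 * p22 - p12 * p12;
          const double v11 = p22 / pdet, v12 = -p12 / pdet, v22 = p11 / pdet;
          const double mm1 = v11 * b1 + v12 * b2;
          const double mm2 = v12 * b1 + v22 * b2;
          if (miss1) {
            const double xk = ya[t] - m2;
            const double cm = mm1 + v12 / v22 * (xk - mm2);
            const double cv = v11 - v12 * v12 / v22;
            ys[t] = m1 + cm + std::sqrt(std::max(cv, 0.0)) * norm_rand();
          } else {
            const double xk = ys[t] - m1;
            const double cm = mm2 + v12 / v11 * (xk - mm1);
            const double cv = v22 - v12 * v12 / v11;
            ya[t] = m2 + cm + std::sqrt(std::max(cv, 0.0)) * norm_rand();
          }
        }
      }
    }

    const int ntr_i = l - f;

    // ---- person means: (y_t - Phi y_{t-1}) = (I - Phi) mu + eps ----
    if (update_mu) {
      const double d11 = 1 - a, d12 = -bb, d21 = -c, d22 = 1 - d;  // D = I - Phi
      double g1 = 0, g2 = 0;
      for (int t = f + 1; t <= l; ++t) {
        g1 += ys[t] - (a * ys[t - 1] + bb * ya[t - 1]);
        g2 += ya[t] - (c * ys[t - 1] + d * ya[t - 1]);
      }
      // D' W D
      const double e11 = d11 * w11 + d21 * w12, e12 = d11 * w12 + d21 * w22;
      const double e21 = d12 * w11 + d22 * w12, e22 = d12 * w12 + d22 * w22;
      double p11 = ntr_i * (e11 * d11 + e12 * d21) + prior_mu_prec(i, 0);
      double p12 = ntr_i * (e11 * d12 + e12 * d22);
      double p22 = ntr_i * (e21 * d12 + e22 * d22) + prior_mu_prec(i, 1);
      const double h1 = w11 * g1 + w12 * g2, h2 = w12 * g1 + w22 * g2;
      double b1 = d11 * h1 + d21 * h2 +
                  prior_mu_prec(i, 0) * prior_mu_mean(i, 0);
      double b2 = d12 * h1 + d22 * h2 +
                  prior_mu_prec(i, 1) * prior_mu_mean(i, 1);
      if (use_eta) {
        const double r = eta_off(i) -
          (beta_th(0) * a + beta_th(1) * bb + beta_th(2) * c + beta_th(3) * d);
        p11 += beta_mu(0) * beta_mu(0) / sigma_eta2;
        p12 += beta_mu(0) * beta_mu(1) / sigma_eta2;
        p22 += beta_mu(1) * beta_mu(1) / sigma_eta2;
        b1 += beta_mu(0) * r / sigma_eta2;
        b2 += beta_mu(1) * r / sigma_eta2;
      }
      draw_gauss2(p11, p12, p22, b1, b2, m1, m2);
      mu(i, 0) = m1; mu(i, 1) = m2;
    }

    // ---- transition coefficients theta = (rows of Phi) ----
    if (update_theta) {
      double sxx11 = 0, sxx12 = 0, sxx22 = 0;
      double sxy11 = 0, sxy12 = 0, sxy21 = 0, sxy22 = 0;
      for (int t = f; t < l; ++t) {
        const double x1 = ys[t] - m1, x2 = ya[t] - m2;
        const double y1 = ys[t + 1] - m1, y2 = ya[t + 1] - m2;
        sxx11 += x1 * x1; sxx12 += x1 * x2; sxx22 += x2 * x2;
        sxy11 += x1 * y1; sxy12 += x1 * y2;
        sxy21 += x2 * y1; sxy22 += x2 * y2;
      }
      double P[4][4], b[4];
      P[0][0] = w11 * sxx11; P[0][1] = w11 * sxx12;
      P[1][0] = w11 * sxx12; P[1][1] = w11 * sxx22;
      P[0][2] = w12 * sxx11; P[0][3] = w12 * sxx12;
      P[1][2] = w12 * sxx12; P[1][3] = w12 * sxx22;
      P[2][0] = w12 * sxx11; P[2][1] = w12 * sxx12;
      P[3][0] = w12 * sxx12; P[3][1] = w12 * sxx22;
      P[2][2] = w22 * sxx11; P[2][3] = w22 * sxx12;
      P[3][2] = w22 * sxx12; P[3][3] = w22 * sxx22;
      b[0] = sxy11 * w11 + sxy12 * w12;
      b[1] = sxy21 * w11 + sxy22 * w12;
      b[2] = sxy11 * w12 + sxy12 * w22;
      b[3] = sxy21 * w12 + sxy22 * w22;
      for (int k = 0; k < 4; ++k) {
        P[k][k] += prior_th_prec(i, k);
        b[k] += prior_th_prec(i, k) * prior_th_mean(i, k);
      }
      if (use_eta) {
        const double r = eta_off(i) - (beta_mu(0) * m1 + beta_mu(1) * m2);
        for (int j = 0; j < 4; ++j) {
          for (int k = 0; k < 4; ++k) {
            P[j][k] += beta_th(j) * beta_th(k) / sigma_eta2;
          }
          b[j] += beta_th(j) * (r / sigma_eta2);
        }
      }
      double th[4];
      draw_gauss4(P, b, th);
      theta(i, 0) = th[0]; theta(i, 1) = th[1];
      theta(i, 2) = th[2]; theta(i, 3) = th[3];
      a = th[0]; bb = th[1]; c = th[2]; d = th[3];
    }

    // ---- innovation sum of squares and per-person sufficient stats ----
    for (int t = f; t < l; ++t) {
      const double x1 = ys[t] - m1, x2 = ya[t] - m2;
      const double y1 = ys[t + 1] - m1, y2 = ya[t + 1] - m2;
      const double e1 = y1 - (a * x1 + bb * x2);
      const double e2 = y2 - (c * x1 + d * x2);
      sse11 += e1 * e1; sse12 += e1 * e2; sse22 += e2 * e2;
      const double r1 = ys[t], r2 = ya[t], s1 = ys[t + 1], s2 = ya[t + 1];
      pstats(i, 0) += r1 * r1; pstats(i, 1) += r1 * r2; pstats(i, 2) += r2 * r2;
      pstats(i, 3) += r1 * s1; pstats(i, 4) += r1 * s2;
      pstats(i, 5) += r2 * s1; pstats(i, 6) += r2 * s2;
      pstats(i, 7) += s1 * s1; pstats(i, 8) += s1 * s2; pstats(i, 9) += s2 * s2;
      pstats(i, 10) += r1; pstats(i, 11) += r2;
      pstats(i, 12) += s1; pstats(i, 13) += s2;
    }
    pstats(i, 14) = ntr_i;
    n_tr += ntr_i;

    // ---- person-standardised within coefficients (for reporting) ----
    if (compute_derived) {
      // stationary covariance: solve the 3x3 system for (s11, s12, s22)
      // S = Phi S Phi' + sigma_w
      const double tr = a + d, det_phi = a * d - bb * c;
      const double rad = std::sqrt(std::max(tr * tr - 4 * det_phi, 0.0)) / 2;
      const double sr = std::max(std::abs(tr / 2 + rad), std::abs(tr / 2 - rad));
      const bool complex_ev = tr * tr - 4 * det_phi < 0;
      const double sr2 = complex_ev ? std::sqrt(det_phi < 0 ? 0.0 : det_phi) : sr;
      if (std::max(sr, sr2) < 0.999) {
        mat33 K;
        K(0, 0) = 1 - a * a; K(0, 1) = -2 * a * bb;       K(0, 2) = -bb * bb;
        K(1, 0) = -a * c;    K(1, 1) = 1 - a * d - bb * c; K(1, 2) = -bb * d;
        K(2, 0) = -c * c;    K(2, 1) = -2 * c * d;         K(2, 2) = 1 - d * d;
        vec3 rhs = {sigma_w(0, 0), sigma_w(0, 1), sigma_w(1, 1)};
        vec3 s;
        const bool ok = solve(s, K, rhs);
        if (ok && s(0) > 0 && s(2) > 0) {
          const double sds = std::sqrt(s(0)), sda = std::sqrt(s(2));
          wstd(0) += a;                   // AR stress
          wstd(1) += d;                   // AR affect
          wstd(2) += bb * sda / sds;      // CL affect -> stress
          wstd(3) += c * sds / sda;       // CL stress -> affect
          n_valid += 1;
        }
      }
    }
  }

  if (compute_derived && n_valid > 0) wstd /= n_valid;

  mat SSE(2, 2);
  SSE(0, 0) = sse11; SSE(0, 1) = sse12;
  SSE(1, 0) = sse12; SSE(1, 1) = sse22;

  return Rcpp::List::create(
      Rcpp::Named("mu") = mu,
      Rcpp::Named("theta") = theta,
      Rcpp::Named("sse") = SSE,
      Rcpp::Named("n_trans") = n_tr,
      Rcpp::Named("wstd") = wstd,
      Rcpp::Named("n_valid") = n_valid,
      Rcpp::Named("pstats") = pstats);
}
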