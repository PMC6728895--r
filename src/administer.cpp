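// Adaptive-test administration engine: per-examinee item selection
// (D-optimality / Bayesian A-optimality), MAP trait updates and the
// stopping rules. Mirrors the pure-R reference functions exactly; all
// randomness is supplied from R as pre-drawn uniforms.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

namespace {

// MAP Newton with step halving, cold start at the prior mean; mirrors
// map_estimate() in R (gradient tolerance 1e-6, 50 iterations).
void map_newton(const arma::mat& A, const arma::vec& b, const arma::vec& y,
                const arma::vec& mu, const arma::mat& S0inv,
                arma::vec& theta, arma::mat& info, arma::mat& postcov) {
  const arma::uword m = A.n_rows;
  theta = mu;
  auto objfun = [&](const arma::vec& th) {
    double o = -0.5 * arma::as_scalar((th - mu).t() * S0inv * (th - mu));
    arma::vec eta = A * th + b;
    for (arma::uword i = 0; i < m; ++i) {
      double p = 1.0 / (1.0 + std::exp(-eta[i]));
      if (p < 1e-12) p = 1e-12;
      if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
      o += y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p);
    }
    return o;
  };
  for (int it = 0; it < 50; ++it) {
    arma::vec p = 1.0 / (1.0 + arma::exp(-(A * theta + b)));
    arma::vec g = A.t() * (y - p) - S0inv * (theta - mu);
    if (arma::norm(g) < 1e-6) break;
    arma::vec w = p % (1.0 - p);
    arma::mat H = A.t() * (A.each_col() % w) + S0inv;
    arma::vec step = arma::solve(H, g);
    double f0 = objfun(theta);
    double t = 1.0;
    for (int h = 0; h < 30 && objfun(theta + t * step) < f0; ++h) t *= 0.5;
    theta += t * step;
  }
  arma::vec p = 1.0 / (1.0 + arma::exp(-(A * theta + b)));
  arma::vec w = p % (1.0 - p);
  info = A.t() * (A.each_col() % w);
  postcov = arma::inv_sympd(info + S0inv);
}

inline double det_rank1(const arma::mat& M, double c, const double* a,
                        int K) {
  if (K == 1) {
    return M(0, 0) + c * a[0] * a[0];
  }
  if (K == 2) {
    const double m00 = M(0, 0) + c * a[0] * a[0];
    const double m01 = M(0, 1) + c * a[0] * a[1];
    const double m11 = M(1, 1) + c * a[1] * a[1];
    return m00 * m11 - m01 * m01;
  }
  if (K == 3) {
    const double m00 = M(0, 0) + c * a[0] * a[0];
    const double m01 = M(0, 1) + c * a[0] * a[1];
    const double m02 = M(0, 2) + c * a[0] * a[2];
    const double m11 = M(1, 1) + c * a[1] * a[1];
    const double m12 = M(1, 2) + c * a[1] * a[2];
    const double m22 = M(2, 2) + c * a[2] * a[2];
    return m00 * (m11 * m22 - m12 * m12) - m01 * (m01 * m22 - m12 * m02) +
           m02 * (m01 * m12 - m11 * m02);
  }
  arma::vec av(const_cast<double*>(a), K, false, true);
  return arma::det(M + c * (av * av.t()));
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_run_cohort(const arma::mat& A, const arma::vec& b,
                          const arma::mat& theta_true, const arma::mat& U,
                          int criterion, const arma::vec& prior_mean,
                          const arma::mat& prior_cov_inv, int stop_type,
                          int Z0, double se_threshold, int max_items) {
  const int J0 = A.n_rows, K = A.n_cols, N = theta_true.n_rows;
  const int maxlen = (stop_type == 0) ? Z0 : max_items;
  Rcpp::IntegerMatrix administered(N, maxlen), responses(N, maxlen);
  arma::mat theta_hat(N, K), se_out(N, K);
  Rcpp::IntegerVector test_len(N);
  std::vector<int> exposure(J0, 0);
  const double* Aptr = A.memptr();  // column-major J0 x K
  std::vector<double> av(K);
  std::vector<double> vals(J0);

  for (int i = 0; i < N; ++i) {
    std::vector<char> used(J0, 0);
    arma::vec theta = prior_mean;
    arma::mat info = arma::zeros<arma::mat>(K, K);
    arma::mat Aad(maxlen, K);
    arma::vec bad(maxlen), yv(maxlen);
    arma::mat postcov;
    arma::mat prior_cov = arma::inv_sympd(prior_cov_inv);
    arma::vec se = arma::sqrt(prior_cov.diag());
    int step = 0;
    while (true) {
      arma::mat Binv;
      arma::mat ridged;
      double trB = 0.0;
      if (criterion == 1) {
        Binv = arma::inv_sympd(info + prior_cov_inv);
        trB = arma::trace(Binv);
      } else {
        // ridge keeps the criterion well defined while info is singular
        ridged = info + 1e-6 * arma::eye(K, K);
      }
      double bestval = (criterion == 0) ? -1e300 : 1e300;
      for (int j = 0; j < J0; ++j) {
        if (used[j]) continue;
        double eta = b[j];
        for (int k = 0; k < K; ++k) {
          av[k] = Aptr[j + (arma::uword)k * J0];
          eta += av[k] * theta[k];
        }
        const double p = 1.0 / (1.0 + std::exp(-eta));
        const double c = p * (1.0 - p);
        double val;
        if (criterion == 0) {
          val = det_rank1(ridged, c, av.data(), K);
          if (val > bestval) bestval = val;
        } else {
          // Sherman-Morrison: trace((B + c a a^T)^-1)
          double q = 0.0, n2 = 0.0;
          for (int r = 0; r < K; ++r) {
            double vr = 0.0;
            for (int s = 0; s < K; ++s) vr += Binv(r, s) * av[s];
            n2 += vr * vr;
            q += vr * av[r];
          }
          val = trB - c * n2 / (1.0 + c * q);
          if (val < bestval) bestval = val;
        }
        vals[j] = val;
      }
      // values within rounding error of the optimum tie; lowest id wins
      const double slack = 1e-9 * std::fabs(bestval);
      int best = -1;
      for (int j = 0; j < J0; ++j) {
        if (used[j]) continue;
        const bool hit = (criterion == 0) ? (vals[j] >= bestval - slack)
                                          : (vals[j] <= bestval + slack);
        if (hit) {
          best = j;
          break;
        }
      }
      double etat = b[best];
      for (int k = 0; k < K; ++k)
        etat += Aptr[best + (arma::uword)k * J0] * theta_true(i, k);
      const double pt = 1.0 / (1.0 + std::exp(-etat));
      const int y = (U(i, step) < pt) ? 1 : 0;
      used[best] = 1;
      administered(i, step) = best + 1;
      responses(i, step) = y;
      exposure[best] += 1;
      for (int k = 0; k < K; ++k)
        Aad(step, k) = Aptr[best + (arma::uword)k * J0];
      bad[step] = b[best];
      yv[step] = y;
      ++step;
      arma::mat Asub = Aad.rows(0, step - 1);
      map_newton(Asub, bad.subvec(0, step - 1), yv.subvec(0, step - 1),
                 prior_mean, prior_cov_inv, theta, info, postcov);
      se = arma::sqrt(postcov.diag());
      const bool done =
          (stop_type == 0)
              ? (step >= Z0)
              : ((step >= K && se.max() <= se_threshold) ||
                 step >= max_items);
      if (done) break;
    }
    theta_hat.row(i) = theta.t();
    se_out.row(i) = se.t();
    test_len[i] = step;
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("administered") = administered,
      Rcpp::Named("responses") = responses,
      Rcpp::Named("theta_hat") = theta_hat, Rcpp::Named("se") = se_out,
      Rcpp::Named("test_length") = test_len,
      Rcpp::Named("exposure") =
          Rcpp::IntegerVector(exposure.begin(), exposure.end()));
}
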