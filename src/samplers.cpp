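#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs kernels for the two population models.
// Both use R's RNG (RNGScope), so chains are reproducible via set.seed()
// at the R level. Proposal scales adapt in batches of 50 during burn-in
// only and are frozen afterwards, preserving detailed balance in the
// retained phase.

static const int kBatch = 50;

static inline void adapt_scale(double &log_sd, double acc, int batch_no) {
  double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
  log_sd += (acc > 0.44) ? delta : -delta;
}

// Gompertz / AR(1): y_t = r + beta * y_{t-1} + e_t, e_t ~ N(0, s2).
// Priors: r ~ Gamma(1,1), beta ~ N(0,1) (untruncated), s2 ~ InvGamma(0.1, 0.1).
// r and beta updated by random-walk Metropolis; s2 by its conjugate
// inverse-gamma conditional.
// [[Rcpp::export]]
List gompertz_chain_cpp(NumericVector y, int n_iter, int n_burn, int thin,
                        NumericVector init, NumericVector prop_sd) {
  int n = y.size();
  int m = n - 1;
  double Szz = 0, Sxx = 0, Sxz = 0, Sz = 0, Sx = 0;
  for (int t = 0; t < m; ++t) {
    double x = y[t], z = y[t + 1];
    Szz += z * z; Sxx += x * x; Sxz += x * z; Sz += z; Sx += x;
  }
  auto sse = [&](double r, double b) {
    return Szz + m * r * r + b * b * Sxx - 2.0 * r * Sz - 2.0 * b * Sxz +
           2.0 * r * b * Sx;
  };

  double r = init[0], b = init[1], s2 = init[2];
  if (r <= 0) r = 0.5;
  if (s2 <= 0) s2 = 0.1;
  double cur_sse = sse(r, b);

  double log_sr = std::log(prop_sd[0]), log_sb = std::log(prop_sd[1]);
  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, 3);
  int kept = 0;
  long acc_r = 0, acc_b = 0, n_post = 0;
  int batch_acc_r = 0, batch_acc_b = 0, batch_no = 0;
  int n_nonstat = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // r: random-walk Metropolis, Gamma(1,1) prior (log prior = -r, r > 0)
    double r_prop = r + R::rnorm(0.0, std::exp(log_sr));
    if (r_prop > 0) {
      double sse_prop = sse(r_prop, b);
      double log_alpha = -(sse_prop - cur_sse) / (2.0 * s2) - (r_prop - r);
      if (std::log(R::runif(0.0, 1.0)) < log_alpha) {
        r = r_prop; cur_sse = sse_prop;
        if (it <= n_burn) ++batch_acc_r; else ++acc_r;
      }
    }
    // beta: random-walk Metropolis, N(0,1) prior
    double b_prop = b + R::rnorm(0.0, std::exp(log_sb));
    {
      double sse_prop = sse(r, b_prop);
      double log_alpha = -(sse_prop - cur_sse) / (2.0 * s2) -
                         0.5 * (b_prop * b_prop - b * b);
      if (std::log(R::runif(0.0, 1.0)) < log_alpha) {
        b = b_prop; cur_sse = sse_prop;
        if (it <= n_burn) ++batch_acc_b; else ++acc_b;
      }
    }
    // s2: conjugate InvGamma(0.1 + m/2, 0.1 + SSE/2)
    double shape = 0.1 + 0.5 * m;
    double rate = 0.1 + 0.5 * cur_sse;
    s2 = 1.0 / R::rgamma(shape, 1.0 / rate);

    if (it <= n_burn && it % kBatch == 0) {
      ++batch_no;
      adapt_scale(log_sr, batch_acc_r / (double)kBatch, batch_no);
      adapt_scale(log_sb, batch_acc_b / (double)kBatch, batch_no);
      batch_acc_r = batch_acc_b = 0;
    }
    if (it > n_burn) {
      ++n_post;
      if ((it - n_burn) % thin == 0 && kept < n_keep) {
        draws(kept, 0) = r;
        draws(kept, 1) = b;
        draws(kept, 2) = s2;
        if (std::fabs(b) >= 1.0) ++n_nonstat;
        ++kept;
      }
    }
  }

  return List::create(
      _["draws"] = draws,
      _["accept"] = NumericVector::create(acc_r / (double)n_post,
                                          acc_b / (double)n_post, 1.0),
      _["prop_sd"] = NumericVector::create(std::exp(log_sr), std::exp(log_sb)),
      _["n_nonstationary"] = n_nonstat);
}

// Ricker: log(Y_t / Y_{t-1}) = r (1 - Y_{t-1} / K) + e_t, e_t ~ N(0, s2).
// Priors: r ~ Gamma(1,1), K ~ Gamma(0.1, 0.1), s2 ~ Gamma(0.1, 0.1).
// All three parameters are positive and updated by random-walk Metropolis
// on the log scale (the Gamma prior on s2 admits no conjugate update).
// [[Rcpp::export]]
List ricker_chain_cpp(NumericVector Y, int n_iter, int n_burn, int thin,
                      NumericVector init, NumericVector prop_sd) {
  int n = Y.size();
  int m = n - 1;
  std::vector<double> g(m), x(m);
  double Sgg = 0, Sxx = 0, Sgx = 0, Sg = 0, Sx = 0;
  for (int t = 0; t < m; ++t) {
    g[t] = std::log(Y[t + 1] / Y[t]);
    x[t] = Y[t];
    Sgg += g[t] * g[t]; Sxx += x[t] * x[t]; Sgx += g[t] * x[t];
    Sg += g[t]; Sx += x[t];
  }
  auto sse = [&](double r, double K) {
    double c = r / K;
    return Sgg + m * r * r + c * c * Sxx - 2.0 * r * Sg + 2.0 * c * Sgx -
           2.0 * r * c * Sx;
  };
  // log prior + log Jacobian for a log-scale random walk on a Gamma(a, b)
  // variable: (a - 1) log v - b v + log v
  auto log_prior_jac = [](double v, double a, double b) {
    return a * std::log(v) - b * v;
  };

  double r = init[0], K = init[1], s2 = init[2];
  if (r <= 0) r = 0.5;
  if (K <= 0) K = 1.0;
  if (s2 <= 0) s2 = 0.1;
  double cur_sse = sse(r, K);

  double ls[3] = {std::log(prop_sd[0]), std::log(prop_sd[1]),
                  std::log(prop_sd[2])};
  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, 3);
  int kept = 0;
  long acc[3] = {0, 0, 0};
  int batch_acc[3] = {0, 0, 0};
  long n_post = 0;
  int batch_no = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // r (Gamma(1,1) prior)
    {
      double r_prop = r * std::exp(R::rnorm(0.0, std::exp(ls[0])));
      double sse_prop = sse(r_prop, K);
      double log_alpha = -(sse_prop - cur_sse) / (2.0 * s2) +
                         log_prior_jac(r_prop, 1.0, 1.0) -
                         log_prior_jac(r, 1.0, 1.0);
      if (std::log(R::runif(0.0, 1.0)) < log_alpha) {
        r = r_prop; cur_sse = sse_prop;
        if (it <= n_burn) ++batch_acc[0]; else ++acc[0];
      }
    }
    // K (Gamma(0.1, 0.1) prior)
    {
      double K_prop = K * std::exp(R::rnorm(0.0, std::exp(ls[1])));
      double sse_prop = sse(r, K_prop);
      double log_alpha = -(sse_prop - cur_sse) / (2.0 * s2) +
                         log_prior_jac(K_prop, 0.1, 0.1) -
                         log_prior_jac(K, 0.1, 0.1);
      if (std::log(R::runif(0.0, 1.0)) < log_alpha) {
        K = K_prop; cur_sse = sse_prop;
        if (it <= n_burn) ++batch_acc[1]; else ++acc[1];
      }
    }
    // s2 (Gamma(0.1, 0.1) prior)
    {
      double s2_prop = s2 * std::exp(R::rnorm(0.0, std::exp(ls[2])));
      double ll_diff = -0.5 * m * (std::log(s2_prop) - std::log(s2)) -
                       cur_sse / 2.0 * (1.0 / s2_prop - 1.0 / s2);
      double log_alpha = ll_diff + log_prior_jac(s2_prop, 0.1, 0.1) -
                         log_prior_jac(s2, 0.1, 0.1);
      if (std::log(R::runif(0.0, 1.0)) < log_alpha) {
        s2 = s2_prop;
        if (it <= n_burn) ++batch_acc[2]; else ++acc[2];
      }
    }

    if (it <= n_burn && it % kBatch == 0) {
      ++batch_no;
      for (int j = 0; j < 3; ++j) {
        adapt_scale(ls[j], batch_acc[j] / (double)kBatch, batch_no);
        batch_acc[j] = 0;
      }
    }
    if (it > n_burn) {
      ++n_post;
      if ((it - n_burn) % thin == 0 && kept < n_keep) {
        draws(kept, 0) = r;
        draws(kept, 1) = K;
        draws(kept, 2) = s2;
        ++kept;
      }
    }
  }

  return List::create(
      _["draws"] = draws,
      _["accept"] = NumericVector::create(acc[0] / (double)n_post,
                                          acc[1] / (double)n_post,
                                          acc[2] / (double)n_post),
      _["prop_sd"] = NumericVector::create(std::exp(ls[0]), std::exp(ls[1]),
                                           std::exp(ls[2])),
      _["n_nonstationary"] = 0);
}
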