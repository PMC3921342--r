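// Single-chain MCMC for the BYM (intrinsic CAR + unstructured heterogeneity)
// relative-risk model.
//
// Poisson likelihood:   O_i ~ Poisson(E_i * exp(eta_i))
// Lognormal likelihood: y_i = log((O_i + c)/E_i) ~ Normal(eta_i, sigma2_e)
// with eta_i = beta0 + x_i'beta + u_i + v_i,
// u ~ ICAR(tau_u) (sum-to-zero), v ~ iid Normal(0, 1/tau_v),
// beta0, beta ~ Normal(0, coef_prior_var), precisions ~ Gamma(shape, rate).
//
// Poisson updates are single-site adaptive random-walk Metropolis (scales
// adapted towards 0.44 acceptance during burn-in only); the lognormal model
// is fully conjugate and uses Gibbs draws throughout.  After every sweep u
// is recentred to sum to zero with the mean absorbed into beta0 (the
// WinBUGS car.normal convention).  Uses R's RNG: seed the chain from R.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// [[Rcpp::export]]
List bym_chain_cpp(NumericVector O, NumericVector E, NumericMatrix X,
                   IntegerVector num, IntegerVector adjvec,
                   int likelihood,          // 0 = poisson, 1 = lognormal
                   bool inc_u, bool inc_v,
                   double coef_prior_var, double prior_shape, double prior_rate,
                   int burn_in, int samples, int thin,
                   double fix_tau_u, double fix_tau_v, double fix_sigma2_e,
                   NumericVector y,         // lognormal response (empty if poisson)
                   NumericVector init)      // beta0, beta..., tau_u, tau_v, sigma2_e
{
  const int n = O.size();
  const int p = X.ncol();
  const bool pois = (likelihood == 0);

  // neighbour offsets into adjvec (0-based indices)
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + num[i];

  // state
  double beta0 = init[0];
  std::vector<double> beta(p);
  for (int j = 0; j < p; ++j) beta[j] = init[1 + j];
  double tau_u = init[1 + p], tau_v = init[2 + p], sigma2_e = init[3 + p];
  if (fix_tau_u > 0) tau_u = fix_tau_u;
  if (fix_tau_v > 0) tau_v = fix_tau_v;
  if (fix_sigma2_e > 0) sigma2_e = fix_sigma2_e;
  std::vector<double> u(n, 0.0), v(n, 0.0), eta(n), mu(n);

  std::vector<double> xb(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) xb[i] += X(i, j) * beta[j];
  for (int i = 0; i < n; ++i) {
    eta[i] = beta0 + xb[i] + u[i] + v[i];
    mu[i] = E[i] * std::exp(eta[i]);
  }

  // adaptive proposal scales (poisson only)
  double s0 = 0.1;
  std::vector<double> sb(p, 0.1);
  double su = 0.1, sv = 0.1;
  int a0 = 0, t0 = 0, au = 0, tu = 0, av = 0, tv = 0;
  std::vector<int> ab(p, 0), tb(p, 0);

  // running moments of (beta0, beta) collected during burn-in to drive a
  // joint Metropolis update (Haario-style); correlated covariates make
  // single-site updates mix slowly
  const int d = p + 1;
  std::vector<double> cmean(d, 0.0);
  std::vector<double> ccov(d * d, 0.0);   // raw sums of centred products
  long cnt = 0;
  std::vector<double> cchol(d * d, 0.0);
  bool have_chol = false;
  double sjoint = 1.0;
  int aj = 0, tj = 0;

  const int total_iter = burn_in + samples * thin;
  NumericMatrix out_beta(samples, p + 1);
  NumericMatrix out_u(samples, n), out_v(samples, n);
  NumericVector out_tau_u(samples), out_tau_v(samples), out_sig(samples),
                out_dev(samples);
  int kept = 0;

  RNGScope scope;

  for (int iter = 0; iter < total_iter; ++iter) {
    const bool adapting = pois && (iter < burn_in);

    if (pois) {
      // ---- beta0 (RW-MH) ----
      {
        double d = R::rnorm(0.0, s0);
        double sum_mu = 0.0, sum_O = 0.0;
        for (int i = 0; i < n; ++i) { sum_mu += mu[i]; sum_O += O[i]; }
        double dll = d * sum_O - (std::exp(d) - 1.0) * sum_mu;
        double dlp = (sq(beta0) - sq(beta0 + d)) / (2.0 * coef_prior_var);
        ++t0;
        if (std::log(R::runif(0.0, 1.0)) < dll + dlp) {
          beta0 += d;
          double ed = std::exp(d);
          for (int i = 0; i < n; ++i) { eta[i] += d; mu[i] *= ed; }
          ++a0;
        }
      }
      // ---- beta_j (RW-MH) ----
      for (int j = 0; j < p; ++j) {
        double d = R::rnorm(0.0, sb[j]);
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          double dx = d * X(i, j);
          dll += O[i] * dx - mu[i] * (std::exp(dx) - 1.0);
        }
        double dlp = (sq(beta[j]) - sq(beta[j] + d)) / (2.0 * coef_prior_var);
        ++tb[j];
        if (std::log(R::runif(0.0, 1.0)) < dll + dlp) {
          beta[j] += d;
          for (int i = 0; i < n; ++i) {
            double dx = d * X(i, j);
            eta[i] += dx; mu[i] *= std::exp(dx);
          }
          ++ab[j];
        }
      }
      // ---- joint (beta0, beta) updates from the adapted covariance ----
      if (have_chol) for (int rep = 0; rep < 3; ++rep) {
        std::vector<double> z(d), dlt(d, 0.0);
        for (int a = 0; a < d; ++a) z[a] = R::rnorm(0.0, 1.0);
        for (int r = 0; r < d; ++r)
          for (int c = 0; c <= r; ++c)
            dlt[r] += sjoint * cchol[r * d + c] * z[c];
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          double dx = dlt[0];
          for (int j = 0; j < p; ++j) dx += dlt[1 + j] * X(i, j);
          dll += O[i] * dx - mu[i] * (std::exp(dx) - 1.0);
        }
        double dlp = (sq(beta0) - sq(beta0 + dlt[0])) / (2.0 * coef_prior_var);
        for (int j = 0; j < p; ++j)
          dlp += (sq(beta[j]) - sq(beta[j] + dlt[1 + j])) /
                 (2.0 * coef_prior_var);
        ++tj;
        if (std::log(R::runif(0.0, 1.0)) < dll + dlp) {
          beta0 += dlt[0];
          for (int j = 0; j < p; ++j) beta[j] += dlt[1 + j];
          for (int i = 0; i < n; ++i) {
            double dx = dlt[0];
            for (int j = 0; j < p; ++j) dx += dlt[1 + j] * X(i, j);
            eta[i] += dx;
            mu[i] *= std::exp(dx);
          }
          ++aj;
        }
      }
      // accumulate coefficient moments during burn-in
      if (iter < burn_in) {
        ++cnt;
        std::vector<double> cur(d);
        cur[0] = beta0;
        for (int j = 0; j < p; ++j) cur[1 + j] = beta[j];
        for (int a = 0; a < d; ++a) {
          double delta = cur[a] - cmean[a];
          cmean[a] += delta / cnt;
          for (int b = 0; b <= a; ++b)
            ccov[a * d + b] += delta * (cur[b] - cmean[b]);
        }
        // refresh the proposal Cholesky every 200 iterations from iter 400 on
        if (cnt >= 400 && cnt % 200 == 0) {
          std::vector<double> S(d * d);
          for (int a = 0; a < d; ++a)
            for (int b = 0; b <= a; ++b) {
              double val = ccov[a * d + b] / (cnt - 1);
              S[a * d + b] = S[b * d + a] = val;
            }
          for (int a = 0; a < d; ++a) S[a * d + a] += 1e-10;
          // in-place lower Cholesky; on failure keep the previous one
          bool ok = true;
          std::vector<double> Lc(d * d, 0.0);
          for (int a = 0; a < d && ok; ++a) {
            for (int b = 0; b <= a; ++b) {
              double s = S[a * d + b];
              for (int k2 = 0; k2 < b; ++k2)
                s -= Lc[a * d + k2] * Lc[b * d + k2];
              if (a == b) {
                if (s <= 0) { ok = false; break; }
                Lc[a * d + a] = std::sqrt(s);
              } else Lc[a * d + b] = s / Lc[b * d + b];
            }
          }
          if (ok) {
            cchol = Lc;
            if (!have_chol) sjoint = 2.38 / std::sqrt((double)d);
            have_chol = true;
          }
        }
      }
      // ---- u_i (RW-MH with ICAR conditional prior) ----
      if (inc_u) {
        for (int i = 0; i < n; ++i) {
          double d = R::rnorm(0.0, su);
          double nb_sum = 0.0;
          for (int k = start[i]; k < start[i + 1]; ++k) nb_sum += u[adjvec[k]];
          double di = num[i];
          double ubar = nb_sum / di;
          double dll = O[i] * d - mu[i] * (std::exp(d) - 1.0);
          double dlp = -0.5 * tau_u * di * (sq(u[i] + d - ubar) - sq(u[i] - ubar));
          ++tu;
          if (std::log(R::runif(0.0, 1.0)) < dll + dlp) {
            u[i] += d; eta[i] += d; mu[i] *= std::exp(d);
            ++au;
          }
        }
      }
      // ---- v_i (RW-MH) ----
      if (inc_v) {
        for (int i = 0; i < n; ++i) {
          double d = R::rnorm(0.0, sv);
          double dll = O[i] * d - mu[i] * (std::exp(d) - 1.0);
          double dlp = -0.5 * tau_v * (sq(v[i] + d) - sq(v[i]));
          ++tv;
          if (std::log(R::runif(0.0, 1.0)) < dll + dlp) {
            v[i] += d; eta[i] += d; mu[i] *= std::exp(d);
            ++av;
          }
        }
      }
    } else {
      // ---- lognormal: full Gibbs ----
      // beta0
      {
        double sr = 0.0;
        for (int i = 0; i < n; ++i) sr += y[i] - xb[i] - u[i] - v[i];
        double prec = n / sigma2_e + 1.0 / coef_prior_var;
        double mean = (sr / sigma2_e) / prec;
        beta0 = R::rnorm(mean, std::sqrt(1.0 / prec));
      }
      // beta_j
      for (int j = 0; j < p; ++j) {
        double sxx = 0.0, sxr = 0.0;
        for (int i = 0; i < n; ++i) {
          double r = y[i] - beta0 - (xb[i] - X(i, j) * beta[j]) - u[i] - v[i];
          sxx += sq(X(i, j));
          sxr += X(i, j) * r;
        }
        double prec = sxx / sigma2_e + 1.0 / coef_prior_var;
        double mean = (sxr / sigma2_e) / prec;
        double nb = R::rnorm(mean, std::sqrt(1.0 / prec));
        for (int i = 0; i < n; ++i) xb[i] += X(i, j) * (nb - beta[j]);
        beta[j] = nb;
      }
      // u_i
      if (inc_u) {
        for (int i = 0; i < n; ++i) {
          double nb_sum = 0.0;
          for (int k = start[i]; k < start[i + 1]; ++k) nb_sum += u[adjvec[k]];
          double di = num[i];
          double r = y[i] - beta0 - xb[i] - v[i];
          double prec = tau_u * di + 1.0 / sigma2_e;
          double mean = (tau_u * nb_sum + r / sigma2_e) / prec;
          u[i] = R::rnorm(mean, std::sqrt(1.0 / prec));
        }
      }
      // v_i
      if (inc_v) {
        for (int i = 0; i < n; ++i) {
          double r = y[i] - beta0 - xb[i] - u[i];
          double prec = tau_v + 1.0 / sigma2_e;
          double mean = (r / sigma2_e) / prec;
          v[i] = R::rnorm(mean, std::sqrt(1.0 / prec));
        }
      }
      // sigma2_e
      if (fix_sigma2_e <= 0) {
        double ss = 0.0;
        for (int i = 0; i < n; ++i)
          ss += sq(y[i] - beta0 - xb[i] - u[i] - v[i]);
        double tau_e = R::rgamma(prior_shape + 0.5 * n,
                                 1.0 / (prior_rate + 0.5 * ss));
        sigma2_e = 1.0 / tau_e;
      }
    }

    // ---- recentre u (sum-to-zero), absorb mean into the intercept ----
    if (inc_u) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += u[i];
      m /= n;
      if (m != 0.0) {
        for (int i = 0; i < n; ++i) u[i] -= m;
        beta0 += m;
      }
    }

    // ---- precisions (conjugate Gamma) ----
    if (inc_u && fix_tau_u <= 0) {
      double ss = 0.0;                       // u'(D - W)u = sum over edges
      for (int i = 0; i < n; ++i)
        for (int k = start[i]; k < start[i + 1]; ++k) {
          int j = adjvec[k];
          if (j > i) ss += sq(u[i] - u[j]);
        }
      tau_u = R::rgamma(prior_shape + 0.5 * (n - 1),
                        1.0 / (prior_rate + 0.5 * ss));
    }
    if (inc_v && fix_tau_v <= 0) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += sq(v[i]);
      tau_v = R::rgamma(prior_shape + 0.5 * n,
                        1.0 / (prior_rate + 0.5 * ss));
    }

    // ---- rebuild caches (xb is not maintained incrementally under the
    //      poisson path; eta shifts when u is recentred) ----
    if (pois && p > 0) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
        xb[i] = s;
      }
    }
    for (int i = 0; i < n; ++i) {
      eta[i] = beta0 + xb[i] + u[i] + v[i];
      if (pois) mu[i] = E[i] * std::exp(eta[i]);
    }

    // ---- adaptation (burn-in only) ----
    if (adapting && ((iter + 1) % 100 == 0)) {
      auto tune = [](double s, int acc, int tot) {
        if (tot == 0) return s;
        double r = (double)acc / tot;
        double ns = s * std::exp(2.0 * (r - 0.44));
        return std::min(std::max(ns, 1e-4), 10.0);
      };
      s0 = tune(s0, a0, t0); a0 = t0 = 0;
      for (int j = 0; j < p; ++j) { sb[j] = tune(sb[j], ab[j], tb[j]); ab[j] = tb[j] = 0; }
      su = tune(su, au, tu); au = tu = 0;
      sv = tune(sv, av, tv); av = tv = 0;
      if (tj > 0) {
        double r = (double)aj / tj;
        sjoint = std::min(std::max(sjoint * std::exp(2.0 * (r - 0.234)),
                                   1e-3), 10.0);
        aj = tj = 0;
      }
    }

    // ---- store ----
    if (iter >= burn_in && ((iter - burn_in + 1) % thin == 0)) {
      double dev = 0.0;
      if (pois) {
        for (int i = 0; i < n; ++i)
          dev += -2.0 * R::dpois(O[i], mu[i], 1);
      } else {
        for (int i = 0; i < n; ++i)
          dev += -2.0 * R::dnorm(y[i], eta[i], std::sqrt(sigma2_e), 1);
      }
      if (!R_finite(dev)) stop("non-finite deviance at iteration %d", iter);
      out_beta(kept, 0) = beta0;
      for (int j = 0; j < p; ++j) out_beta(kept, j + 1) = beta[j];
      for (int i = 0; i < n; ++i) { out_u(kept, i) = u[i]; out_v(kept, i) = v[i]; }
      out_tau_u[kept] = tau_u;
      out_tau_v[kept] = tau_v;
      out_sig[kept] = sigma2_e;
      out_dev[kept] = dev;
      ++kept;
    }
  }

  // final acceptance rates over the sampling phase (poisson only)
  List accept;
  if (pois) {
    NumericVector rb(p);
    for (int j = 0; j < p; ++j)
      rb[j] = tb[j] > 0 ? (double)ab[j] / tb[j] : NA_REAL;
    accept = List::create(
      _["beta0"] = t0 > 0 ? (double)a0 / t0 : NA_REAL,
      _["beta"]  = rb,
      _["u"] = tu > 0 ? (double)au / tu : NA_REAL,
      _["v"] = tv > 0 ? (double)av / tv : NA_REAL);
  } else {
    accept = List::create(_["gibbs"] = 1.0);
  }

  return List::create(
    _["beta"] = out_beta, _["u"] = out_u, _["v"] = out_v,
    _["tau_u"] = out_tau_u, _["tau_v"] = out_tau_v, _["sigma2_e"] = out_sig,
    _["deviance"] = out_dev, _["accept"] = accept);
}
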