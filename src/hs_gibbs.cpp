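// Blocked Gibbs sampler for the hierarchical Student-t regression with
// regularized horseshoe priors on the condition-wise coefficient matrix.
//
// The Student-t likelihood is represented as a normal scale mixture
// (per-trial latent precision weights w_k ~ Gamma(nu/2, nu/2)), which makes
// the coefficient blocks B_i, the subject intercepts I_j and the subject RT
// slopes b_j conditionally Gaussian.  All scale-type parameters
// (sigma_g, sigma_I, nu, lambda, tau, c^2) are updated by univariate
// stepping-out slice sampling on their full conditionals; the horseshoe
// scales are sampled on the log scale.
//
// All randomness goes through R's RNG so set.seed() governs the draw stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// univariate stepping-out slice sampler (Neal 2003), bounded support
template <typename F>
double slice1(double x0, F logf, double w, double lower, double upper,
              int max_steps = 50) {
  double logy = logf(x0) - R::rexp(1.0);
  double u = R::runif(0.0, w);
  double L = std::max(lower, x0 - u);
  double Rr = std::min(upper, x0 - u + w);
  int k = max_steps;
  while (k-- > 0 && L > lower && logf(L) > logy) L = std::max(lower, L - w);
  k = max_steps;
  while (k-- > 0 && Rr < upper && logf(Rr) > logy) Rr = std::min(upper, Rr + w);
  for (int it = 0; it < 1000; ++it) {
    double x1 = R::runif(L, Rr);
    if (logf(x1) >= logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;  // degenerate slice; keep current value
}

// regularized local scale: lambda-tilde^2 = c^2 l^2 / (c^2 + tau^2 l^2)
inline double lt2(double l, double tau, double c2) {
  return c2 * l * l / (c2 + tau * tau * l * l);
}

inline double log_half_cauchy(double x, double scale) {
  // kernel + scale terms; the additive constant log(2/pi) is irrelevant
  return -std::log(scale) - std::log1p((x / scale) * (x / scale));
}

}  // namespace

// [[Rcpp::export]]
List hs_gibbs_chain(const arma::vec& y, const arma::mat& X,
                    const arma::ivec& cond, const arma::ivec& subj,
                    const arma::vec& rtvec, bool extended,
                    int C, int P, int J,
                    int n_warm, int n_save, int thin,
                    double p0, double nu0, double s_slab,
                    List init) {
  const int N = y.n_elem;
  const double tau0_mult = p0 / (P * (double)C - p0) / std::sqrt((double)N);

  // index sets
  std::vector<arma::uvec> idxc(C), idxj(J);
  for (int i = 0; i < C; ++i) idxc[i] = arma::find(cond == (i + 1));
  for (int j = 0; j < J; ++j) idxj[j] = arma::find(subj == (j + 1));

  // state
  arma::mat B = as<arma::mat>(init["B"]);          // C x P
  arma::vec I = as<arma::vec>(init["I"]);          // J
  arma::vec b = as<arma::vec>(init["b"]);          // J (ignored unless extended)
  double I0 = as<double>(init["I0"]);
  double sigma_g = as<double>(init["sigma_g"]);
  double sigma_I = as<double>(init["sigma_I"]);
  double nu = as<double>(init["nu"]);
  double tau = as<double>(init["tau"]);
  double c2 = as<double>(init["c2"]);
  arma::mat lam = as<arma::mat>(init["lam"]);      // C x P
  double lam_b = as<double>(init["lam_b"]);
  arma::vec w(N, arma::fill::ones);

  arma::vec XB(N, arma::fill::zeros);
  for (int i = 0; i < C; ++i) XB(idxc[i]) = X.rows(idxc[i]) * B.row(i).t();
  arma::vec Ivec(N), bterm(N, arma::fill::zeros);
  auto refresh_Ivec = [&]() { for (int k = 0; k < N; ++k) Ivec(k) = I(subj(k) - 1); };
  auto refresh_bterm = [&]() {
    if (extended) for (int k = 0; k < N; ++k) bterm(k) = b(subj(k) - 1) * rtvec(k);
  };
  refresh_Ivec(); refresh_bterm();

  // storage
  arma::cube Bdr(n_save, C, P), lamdr(n_save, C, P);
  arma::mat Idr(n_save, J), bdr(extended ? n_save : 0, extended ? J : 0);
  arma::vec I0dr(n_save), sgdr(n_save), sIdr(n_save), nudr(n_save),
      taudr(n_save), c2dr(n_save), lamb_dr(extended ? n_save : 0);

  const int n_iter = n_warm + n_save * thin;
  for (int it = 1; it <= n_iter; ++it) {
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
    const double sg2 = sigma_g * sigma_g;

    // --- latent t weights ------------------------------------------------
    {
      arma::vec r = y - XB - Ivec - bterm;
      for (int k = 0; k < N; ++k) {
        double rate = 0.5 * (nu + r(k) * r(k) / sg2);
        w(k) = R::rgamma(0.5 * (nu + 1.0), 1.0 / rate);
      }
    }

    // --- coefficient blocks B_i (conjugate MVN) --------------------------
    for (int i = 0; i < C; ++i) {
      const arma::uvec& ii = idxc[i];
      arma::mat Xi = X.rows(ii);
      arma::vec wi = w(ii);
      arma::vec resp = y(ii) - Ivec(ii) - bterm(ii);
      arma::mat Xw = Xi.each_col() % wi;
      arma::mat A = Xi.t() * Xw / sg2;
      for (int p = 0; p < P; ++p) {
        double pv = tau * tau * lt2(lam(i, p), tau, c2);
        A(p, p) += 1.0 / std::max(pv, 1e-300);
      }
      arma::vec rhs = Xi.t() * (wi % resp) / sg2;
      arma::mat U = arma::chol(A);                 // upper: A = U'U
      arma::vec mn = arma::solve(arma::trimatu(U),
                                 arma::solve(arma::trimatl(U.t()), rhs));
      arma::vec z(P);
      for (int p = 0; p < P; ++p) z(p) = R::norm_rand();
      arma::vec draw = mn + arma::solve(arma::trimatu(U), z);
      B.row(i) = draw.t();
      XB(ii) = Xi * draw;
    }

    // --- subject intercepts ----------------------------------------------
    {
      arma::vec rI = y - XB - bterm;
      const double sI2 = sigma_I * sigma_I;
      for (int j = 0; j < J; ++j) {
        const arma::uvec& jj = idxj[j];
        double sw = arma::accu(w(jj));
        double prec = sw / sg2 + 1.0 / sI2;
        double mn = (arma::dot(w(jj), rI(jj)) / sg2 + I0 / sI2) / prec;
        I(j) = R::rnorm(mn, 1.0 / std::sqrt(prec));
      }
      refresh_Ivec();
      double prec0 = J / sI2 + 1.0;  // N(0,1) prior on I0
      I0 = R::rnorm(arma::accu(I) / sI2 / prec0, 1.0 / std::sqrt(prec0));
    }

    // --- sigma_I (half-normal(0,1) prior) --------------------------------
    {
      double ss = arma::accu(arma::square(I - I0));
      sigma_I = slice1(sigma_I, [&](double s) {
        if (s <= 0.0) return R_NegInf;
        return -J * std::log(s) - ss / (2.0 * s * s) - s * s / 2.0;
      }, 0.25 * sigma_I + 0.01, 1e-8, 50.0);
    }

    // --- subject RT slopes (extended model) ------------------------------
    if (extended) {
      arma::vec rb = y - XB - Ivec;
      double pvb = std::max(tau * tau * lt2(lam_b, tau, c2), 1e-300);
      for (int j = 0; j < J; ++j) {
        const arma::uvec& jj = idxj[j];
        arma::vec rj = rtvec(jj);
        double prec = arma::dot(w(jj), rj % rj) / sg2 + 1.0 / pvb;
        double mn = arma::dot(w(jj), rj % rb(jj)) / sg2 / prec;
        b(j) = R::rnorm(mn, 1.0 / std::sqrt(prec));
      }
      refresh_bterm();
      double ssb = arma::accu(arma::square(b));
      lam_b = std::exp(slice1(std::log(lam_b), [&](double ll) {
        double l = std::exp(ll);
        double v = tau * tau * lt2(l, tau, c2);
        return -0.5 * J * std::log(v) - ssb / (2.0 * v)
               - std::log1p(l * l) + ll;           // C+(0,1) prior, log-Jacobian
      }, 1.0, -30.0, 30.0));
    }

    // --- collapsed (lambda, B) sweep --------------------------------------
    // For each coefficient, slice-sample its local scale with the
    // coefficient integrated out of the likelihood (the conditional
    // sufficient statistic m has marginal N(0, v + 1/q)), then redraw the
    // coefficient from its Gaussian full conditional.  This crosses the
    // shrinkage funnel that coordinate-wise updates mix through slowly.
    for (int i = 0; i < C; ++i) {
      const arma::uvec& ii = idxc[i];
      arma::mat Xi = X.rows(ii);
      arma::vec wi = w(ii);
      arma::vec res = y(ii) - Ivec(ii) - bterm(ii) - Xi * B.row(i).t();
      for (int p = 0; p < P; ++p) {
        arma::vec xp = Xi.col(p);
        arma::vec rp = res + xp * B(i, p);
        double q = arma::dot(wi, xp % xp) / sg2;
        if (q <= 0) continue;
        double m = arma::dot(wi, xp % rp) / sg2 / q;
        lam(i, p) = std::exp(slice1(std::log(lam(i, p)), [&](double ll) {
          double l = std::exp(ll);
          double v = tau * tau * lt2(l, tau, c2) + 1.0 / q;
          return -0.5 * std::log(v) - m * m / (2.0 * v)
                 - std::log1p(l * l) + ll;
        }, 2.0, -30.0, 30.0));
        double v = tau * tau * lt2(lam(i, p), tau, c2);
        double post_prec = q + 1.0 / std::max(v, 1e-300);
        B(i, p) = R::rnorm(q * m / post_prec, 1.0 / std::sqrt(post_prec));
        res = rp - xp * B(i, p);
      }
      XB(ii) = Xi * B.row(i).t();
    }

    // --- global scale tau --------------------------------------------------
    {
      double t0 = tau0_mult * sigma_g;
      double ssb = extended ? arma::accu(arma::square(b)) : 0.0;
      tau = std::exp(slice1(std::log(tau), [&](double lt) {
        double t = std::exp(lt);
        double lp = 0.0;
        for (int i = 0; i < C; ++i)
          for (int p = 0; p < P; ++p) {
            double v = t * t * lt2(lam(i, p), t, c2);
            lp += -0.5 * std::log(v) - B(i, p) * B(i, p) / (2.0 * v);
          }
        if (extended) {
          double v = t * t * lt2(lam_b, t, c2);
          lp += -0.5 * J * std::log(v) - ssb / (2.0 * v);
        }
        return lp + log_half_cauchy(t, t0) + lt;
      }, 1.0, -40.0, 20.0));
    }

    // --- slab width c^2 ~ Inv-Gamma(nu0/2, nu0 s^2/2) ----------------------
    {
      double ssb = extended ? arma::accu(arma::square(b)) : 0.0;
      c2 = std::exp(slice1(std::log(c2), [&](double lc) {
        double cc = std::exp(lc);
        double lp = 0.0;
        for (int i = 0; i < C; ++i)
          for (int p = 0; p < P; ++p) {
            double v = tau * tau * lt2(lam(i, p), tau, cc);
            lp += -0.5 * std::log(v) - B(i, p) * B(i, p) / (2.0 * v);
          }
        if (extended) {
          double v = tau * tau * lt2(lam_b, tau, cc);
          lp += -0.5 * J * std::log(v) - ssb / (2.0 * v);
        }
        return lp - (nu0 / 2.0 + 1.0) * std::log(cc)
               - nu0 * s_slab * s_slab / (2.0 * cc) + lc;
      }, 1.0, -20.0, 20.0));
    }

    // --- sigma_g and nu, with the latent t weights integrated out ---------
    // These use the marginal Student-t likelihood; the weights w are redrawn
    // from their conditional at the top of the next iteration, so each pair
    // (sigma_g, w) / (nu, w) forms a valid joint block and mixing does not
    // suffer from the data-augmentation coupling.
    {
      arma::vec r = y - XB - Ivec - bterm;
      arma::vec r2 = r % r;
      sigma_g = slice1(sigma_g, [&](double sg) {
        if (sg <= 0.0) return R_NegInf;
        double t0 = tau0_mult * sg;
        double q = 0.0;
        for (int k = 0; k < N; ++k) q += std::log1p(r2(k) / (nu * sg * sg));
        return -0.5 * (nu + 1.0) * q - N * std::log(sg) - sg * sg / 2.0
               + log_half_cauchy(tau, t0);
      }, 0.05 * sigma_g + 0.005, 1e-8, 50.0);

      const double sg2m = sigma_g * sigma_g;
      nu = slice1(nu, [&](double v) {
        if (v <= 0.5 || v > 400.0) return R_NegInf;
        double q = 0.0;
        for (int k = 0; k < N; ++k) q += std::log1p(r2(k) / (v * sg2m));
        return N * (std::lgamma(0.5 * (v + 1.0)) - std::lgamma(0.5 * v)
                    - 0.5 * std::log(v))
               - 0.5 * (v + 1.0) * q + std::log(v) - 0.1 * v;
      }, std::max(1.0, 0.25 * nu), 0.5, 400.0);
    }

    // --- store -------------------------------------------------------------
    if (it > n_warm && (it - n_warm) % thin == 0) {
      int s = (it - n_warm) / thin - 1;
      for (int i = 0; i < C; ++i)
        for (int p = 0; p < P; ++p) {
          Bdr(s, i, p) = B(i, p);
          lamdr(s, i, p) = lam(i, p);
        }
      Idr.row(s) = I.t();
      if (extended) { bdr.row(s) = b.t(); lamb_dr(s) = lam_b; }
      I0dr(s) = I0; sgdr(s) = sigma_g; sIdr(s) = sigma_I;
      nudr(s) = nu; taudr(s) = tau; c2dr(s) = c2;
    }
  }

  List out = List::create(
      _["B"] = Bdr, _["I"] = Idr, _["I0"] = I0dr,
      _["sigma_g"] = sgdr, _["sigma_I"] = sIdr, _["nu"] = nudr,
      _["tau"] = taudr, _["c2"] = c2dr, _["lambda"] = lamdr);
  if (extended) { out["b"] = bdr; out["lambda_b"] = lamb_dr; }
  return out;
}
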