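// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Polya-Gamma PG(1, z) sampler (Devroye alternating-series method, as in
// Polson, Scott & Windle).  Used for the augmented Gibbs sampler of the
// Bernoulli-logit phylogenetic trade model.
// ---------------------------------------------------------------------------

static const double TRUNC = 0.64;

static double a_coef(int n, double x) {
  if (x > TRUNC)
    return M_PI * (n + 0.5) * exp(-(n + 0.5) * (n + 0.5) * M_PI * M_PI * 0.5 * x);
  return pow(2.0 / (M_PI * x), 1.5) * M_PI * (n + 0.5) *
         exp(-2.0 * (n + 0.5) * (n + 0.5) / x);
}

static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = sqrt(1.0 / t) * (t * z - 1.0);
  double a = -sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (exp(xb) + exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse Gaussian IG(1/z, 1) truncated to (0, TRUNC]
static double rtigauss(double z) {
  double t = TRUNC, X = t + 1.0;
  if (1.0 / z > t) {
    // mu > t: rejection from scaled inverse-chi-square tail
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double E1, E2;
      do {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = exp(-0.5 * z * z * X);
    }
  } else {
    double mu = 1.0 / z;
    while (X > t) {
      double Y = R::norm_rand();
      Y *= Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * muY - 0.5 * mu * sqrt(4.0 * muY + muY * muY);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

static double rpg1(double zin) {
  double z = fabs(zin) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  for (;;) {
    double X;
    if (R::unif_rand() < mass_texpon(z))
      X = TRUNC + R::exp_rand() / fz;
    else
      X = rtigauss(z);
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X; // accept
      } else {
        S += a_coef(n, X);
        if (Y > S) break; // reject, redraw X
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg")]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

// standard normal truncated to (0, Inf), shifted/scaled: mean m, sd s
static double rtnorm_pos(double m, double s) {
  double a = -m / s; // lower bound in standard units
  if (a < 5.0) {
    // plain rejection is fine unless the mass above 0 is tiny
    for (;;) {
      double x = m + s * R::norm_rand();
      if (x > 0.0) return x;
    }
  }
  // Robert's exponential rejection for the far tail
  for (;;) {
    double lambda = 0.5 * (a + sqrt(a * a + 4.0));
    double x = a + R::exp_rand() / lambda;
    double rho = exp(-0.5 * (x - lambda) * (x - lambda));
    if (R::unif_rand() <= rho) return m + s * x;
  }
}

// ---------------------------------------------------------------------------
// Gibbs kernel for: y_i ~ Bern(logit^-1(x_i'beta + u_i)),
//   u ~ N(0, sigma^2 C),  beta_j ~ N(0, tau^2),  sigma ~ HalfNormal(s_sigma).
// PG augmentation; single-site u updates with running s = Cinv u; exact
// likelihood-invariant shift moves between beta_j and u along each column of
// X; sigma updated both centred (slice on log sigma) and non-centred
// (conjugate truncated normal given z = u/sigma) for mixing.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".gibbs_pg")]]
List gibbs_pg(IntegerVector y, arma::mat X, arma::mat Cinv,
              int n_iter, int n_warmup,
              double tau, double s_sigma,
              arma::vec beta0, arma::vec u0, double sigma0) {
  int n = X.n_rows, p = X.n_cols;
  int kept = n_iter - n_warmup;
  arma::vec kappa(n);
  for (int i = 0; i < n; ++i) kappa[i] = y[i] - 0.5;

  arma::vec beta = beta0, u = u0;
  double sigma = sigma0;
  arma::vec s = Cinv * u;              // running Cinv u
  arma::mat CinvX = Cinv * X;          // n x p, fixed
  arma::vec xCx(p);                    // x_j' Cinv x_j
  for (int j = 0; j < p; ++j) xCx[j] = arma::dot(X.col(j), CinvX.col(j));
  arma::vec Cdiag = Cinv.diag();

  arma::mat beta_draws(kept, p), u_draws(kept, n);
  arma::vec sigma_draws(kept);

  arma::vec m = X * beta, omega(n);

  for (int it = 0; it < n_iter; ++it) {
    arma::vec eta = m + u;

    // 1. Polya-Gamma auxiliaries
    for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

    // 2. beta block (p-dimensional Gaussian)
    arma::mat A = X.t() * (X.each_col() % omega);
    A.diag() += 1.0 / (tau * tau);
    arma::vec b = X.t() * (kappa - omega % u);
    arma::mat R = arma::chol(A);
    arma::vec zp(p);
    for (int j = 0; j < p; ++j) zp[j] = R::norm_rand();
    beta = arma::solve(arma::trimatu(R),
                       arma::solve(arma::trimatl(R.t()), b) + zp);
    m = X * beta;

    // 3. u update: exact blocked Gibbs (O(n^3)) on moderate problems, a
    //    single-site sweep with running prior cross terms on large ones
    double inv_s2 = 1.0 / (sigma * sigma);
    if (n <= 600) {
      arma::mat Pu = arma::symmatu(Cinv) * inv_s2;
      Pu.diag() += omega;
      Pu = 0.5 * (Pu + Pu.t());
      arma::vec bu = kappa - omega % m;
      arma::mat Ru = arma::chol(Pu);
      arma::vec zn(n);
      for (int i = 0; i < n; ++i) zn[i] = R::norm_rand();
      u = arma::solve(arma::trimatu(Ru),
                      arma::solve(arma::trimatl(Ru.t()), bu) + zn);
      s = Cinv * u;
    } else {
      for (int i = 0; i < n; ++i) {
        double prec = omega[i] + Cdiag[i] * inv_s2;
        double rest = (s[i] - Cdiag[i] * u[i]) * inv_s2; // prior cross terms
        double mean = (kappa[i] - omega[i] * m[i] - rest) / prec;
        double unew = mean + R::norm_rand() / sqrt(prec);
        double du = unew - u[i];
        if (du != 0.0) {
          s += du * Cinv.col(i);
          u[i] = unew;
        }
      }
    }

    // 4. shift moves: beta_j += c, u -= c x_j leaves the likelihood intact;
    //    c has an exact Gaussian conditional from the two priors
    for (int j = 0; j < p; ++j) {
      double prec = 1.0 / (tau * tau) + xCx[j] * inv_s2;
      double mean = (-beta[j] / (tau * tau) + arma::dot(X.col(j), s) * inv_s2) / prec;
      double c = mean + R::norm_rand() / sqrt(prec);
      beta[j] += c;
      u -= c * X.col(j);
      s -= c * CinvX.col(j);
    }
    m = X * beta;

    // 5. sigma, centred: slice sampler on theta = log sigma
    double q = arma::dot(u, s);
    {
      double theta = log(sigma);
      double ss2 = s_sigma * s_sigma;
      #define LOGTARGET(th) (-(double)n * (th) - 0.5 * q * exp(-2.0 * (th)) \
                             - 0.5 * exp(2.0 * (th)) / ss2 + (th))
      double ly = LOGTARGET(theta) - R::exp_rand();
      double w = 1.0, L = theta - w * R::unif_rand(), Rr = L + w;
      int cnt = 0;
      while (LOGTARGET(L) > ly && cnt++ < 50) L -= w;
      cnt = 0;
      while (LOGTARGET(Rr) > ly && cnt++ < 50) Rr += w;
      for (;;) {
        double th = L + (Rr - L) * R::unif_rand();
        if (LOGTARGET(th) >= ly) { theta = th; break; }
        if (th < theta) L = th; else Rr = th;
      }
      #undef LOGTARGET
      sigma = exp(theta);
      inv_s2 = 1.0 / (sigma * sigma);
    }

    // 6. sigma, non-centred: z = u/sigma fixed, conjugate truncated normal
    {
      arma::vec zvec = u / sigma;
      double prec = arma::dot(omega, zvec % zvec) + 1.0 / (s_sigma * s_sigma);
      double mean = arma::dot(zvec, kappa - omega % m) / prec;
      double snew = rtnorm_pos(mean, 1.0 / sqrt(prec));
      double ratio = snew / sigma;
      u *= ratio;
      s *= ratio;
      sigma = snew;
    }

    if (it >= n_warmup) {
      int k = it - n_warmup;
      beta_draws.row(k) = beta.t();
      u_draws.row(k) = u.t();
      sigma_draws[k] = sigma;
    }
  }

  return List::create(_["beta"] = beta_draws,
                      _["sigma"] = sigma_draws,
                      _["u"] = u_draws);
}
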