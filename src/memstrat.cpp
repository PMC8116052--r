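// Hot loops of the memory-strategy pipeline:
//  - KL dissipation tables (shared profile matrices across parameter sweeps)
//  - lifetime ensemble simulation over an (alpha, beta) strategy grid
//  - stochastic mixture-strategy lifetime objective
// All profile KL computations use the same geometry as the R reference
// implementation: a uniform grid extending 8 cross-reactive ranges beyond
// each profile center (in scaled units u = alpha * x: [-span, s + span]),
// with n_profile points; profiles are normalized to sum to 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double shape_pow(double s, double theta) {
  if (theta == 2.0) return s * s;
  if (theta == 1.0) return s;
  if (theta == 0.0) return 0.0; // flat profile at peak height (no tradeoff)
  return std::pow(s, theta);
}

// Normalized memory (center 0) and antigen (center s) profiles and the log
// of the antigen profile, for each scaled separation s; flattened row-major
// [i_s * n_profile + j].
struct ProfileMats {
  std::vector<double> m, a, la;
  int n_profile;
};

static ProfileMats build_profiles(const NumericVector& s_grid, double theta,
                                  int n_profile, double span) {
  int n_s = s_grid.size();
  ProfileMats P;
  P.n_profile = n_profile;
  P.m.resize((size_t)n_s * n_profile);
  P.a.resize((size_t)n_s * n_profile);
  P.la.resize((size_t)n_s * n_profile);
  for (int i = 0; i < n_s; ++i) {
    double s = s_grid[i];
    double lo = -span, hi = s + span;
    double du = (hi - lo) / (n_profile - 1);
    double zm = 0.0, za = 0.0;
    size_t off = (size_t)i * n_profile;
    for (int j = 0; j < n_profile; ++j) {
      double u = lo + du * j;
      double mv = std::exp(-shape_pow(std::fabs(u), theta));
      double av = std::exp(-shape_pow(std::fabs(u - s), theta));
      P.m[off + j] = mv;
      P.a[off + j] = av;
      zm += mv;
      za += av;
    }
    double lza = std::log(za);
    for (int j = 0; j < n_profile; ++j) {
      P.m[off + j] /= zm;
      double av = P.a[off + j] / za;
      P.a[off + j] = av;
      // log of the normalized antigen profile; arguments never underflow for
      // the spans used here (|u - s| <= 2*span + s stays far below 745^(1/theta))
      P.la[off + j] = std::log(P.a[off + j] > 0 ? P.a[off + j] : 1e-320);
    }
    (void)lza;
  }
  return P;
}

// KL( w*m + (1-w)*a || a ) in nats for one row of the profile matrices
static inline double kl_row(const ProfileMats& P, int i, double w) {
  if (w <= 0.0) return 0.0;
  size_t off = (size_t)i * P.n_profile;
  double kl = 0.0;
  double wc = 1.0 - w;
  for (int j = 0; j < P.n_profile; ++j) {
    double p = w * P.m[off + j] + wc * P.a[off + j];
    if (p > 0) kl += p * (std::log(p) - P.la[off + j]);
  }
  return kl > 0 ? kl : 0.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_kl_cache(NumericVector s_grid, NumericVector lambdas,
                           double theta, int n_profile, double span) {
  // KL(s; lambda) with the single-memory recognition weight
  // w(s) = 1 - exp(-lambda * exp(-s^theta)), lambda = beta * e_max * alpha_hat
  ProfileMats P = build_profiles(s_grid, theta, n_profile, span);
  int n_s = s_grid.size(), n_l = lambdas.size();
  NumericMatrix out(n_s, n_l);
  for (int l = 0; l < n_l; ++l) {
    double lambda = lambdas[l];
    for (int i = 0; i < n_s; ++i) {
      double w = -std::expm1(-lambda * std::exp(-shape_pow(s_grid[i], theta)));
      out(i, l) = (w < 1e-14) ? 0.0 : kl_row(P, i, w);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_kl_table_w(NumericVector s_grid, NumericVector w_values,
                             double theta, int n_profile, double span) {
  // KL(s; w) on an explicit grid of mixture weights w (used by the
  // mixture-strategy accounting, where w = 1 - exp(-beta_tilde * Ebar))
  ProfileMats P = build_profiles(s_grid, theta, n_profile, span);
  int n_s = s_grid.size(), n_w = w_values.size();
  NumericMatrix out(n_s, n_w);
  for (int l = 0; l < n_w; ++l) {
    double w = w_values[l];
    for (int i = 0; i < n_s; ++i) {
      out(i, l) = (w < 1e-14) ? 0.0 : kl_row(P, i, w);
    }
  }
  return out;
}

static inline double cost_omega(int cost_form, double omega0_hat,
                                double beta_hat, double e_max) {
  if (cost_form == 1) return e_max * omega0_hat * beta_hat;
  if (cost_form == 2) return e_max * omega0_hat * beta_hat * beta_hat;
  return 0.0;
}

// [[Rcpp::export]]
List cpp_sim_strategy_grid(NumericVector alphas, NumericVector betas,
                           double alpha_max, double e_max, double theta,
                           double delta, double rel_sd, bool sqrt_drift,
                           int L, int cost_form, double omega0_hat,
                           double beta_max, NumericMatrix Z, NumericMatrix U,
                           NumericMatrix klcache, double s_max) {
  // Ensemble lifetime simulation for every (alpha_i, beta_j) grid point with
  // common random numbers: Z (standard normal) and U (uniform) are n_ens x
  // (L-1) and shared across grid points. klcache column p = j*na + i holds
  // KL(s) on a uniform s-grid [0, s_max] for lambda = beta_j*e_max*alpha_i/alpha_max.
  int na = alphas.size(), nb = betas.size();
  int n_ens = Z.nrow(), n_enc = L - 1;
  int n_s = klcache.nrow();
  double ds = s_max / (n_s - 1);
  NumericMatrix u_mean(na, nb), u_se(na, nb), kd_mean(na, nb), use_mean(na, nb);
  for (int jb = 0; jb < nb; ++jb) {
    double beta = betas[jb];
    double bhat = beta / beta_max;
    double omega = cost_omega(cost_form, omega0_hat, bhat, e_max);
    for (int ia = 0; ia < na; ++ia) {
      double alpha = alphas[ia];
      double ahat = alpha / alpha_max;
      const double* klcol = &klcache(0, (size_t)jb * na + ia);
      double mean = 0.0, M2 = 0.0, kdsum = 0.0, usesum = 0.0;
      for (int e = 0; e < n_ens; ++e) {
        int k = 1;
        double acc = 0.0;
        int used = 0;
        for (int i = 0; i < n_enc; ++i) {
          double mu = sqrt_drift ? delta * std::sqrt((double)k)
                                 : delta * (double)k;
          double d = 0.0;
          if (mu > 0.0) {
            d = mu * (1.0 + rel_sd * Z(e, i));
            while (d < 0.0) d = mu * (1.0 + rel_sd * norm_rand());
          }
          double s = alpha * d;
          double st = shape_pow(s, theta);
          double E = (st > 700.0) ? 0.0 : e_max * ahat * std::exp(-st);
          double pmem = -std::expm1(-beta * E);
          double kd = 0.0;
          if (beta > 0.0 && s < s_max && pmem > 1e-15) {
            double x = s / ds;
            int j = (int)x;
            double f = x - j;
            double kl = klcol[j] + (klcol[j + 1] - klcol[j]) * f;
            if (kl > 0) kd = kl / beta;
          }
          acc += -omega + pmem * E - kd;
          kdsum += kd;
          if (U(e, i) < pmem) {
            k += 1;
            used += 1;
          } else {
            k = 1;
          }
        }
        double m_e = acc / n_enc;
        double delta1 = m_e - mean;
        mean += delta1 / (e + 1);
        M2 += delta1 * (m_e - mean);
        usesum += (double)used / n_enc;
      }
      u_mean(ia, jb) = mean;
      u_se(ia, jb) = n_ens > 1 ? std::sqrt(M2 / (n_ens - 1.0) / n_ens) : NA_REAL;
      kd_mean(ia, jb) = kdsum / ((double)n_ens * n_enc);
      use_mean(ia, jb) = usesum / n_ens;
    }
  }
  return List::create(_["u_net"] = u_mean, _["u_net_se"] = u_se,
                      _["k_diss"] = kd_mean, _["usage"] = use_mean);
}

// [[Rcpp::export]]
List cpp_sim_mixture(NumericVector alphas, double beta_tilde,
                     NumericVector deltas, double rel_sd, int L,
                     double theta, double alpha_max, double e_max,
                     int cost_form, double omega0_hat, double beta_eff_max,
                     NumericMatrix kltab, double s_max, double eta_max) {
  // Lifetime objective for a mixture strategy: each antigen lineage has its
  // own divergence; a naive response stores one memory per specificity slot,
  // all centered on the triggering antigen. The responder among the slots is
  // drawn with probability proportional to its affinity; accounting uses the
  // responder's profile as the memory profile. kltab is KL(s, eta) on
  // uniform grids [0, s_max] x [0, eta_max], eta = beta_tilde * Ebar.
  int nm = alphas.size(), nA = deltas.size();
  int n_enc = L - 1;
  int n_s = kltab.nrow(), n_eta = kltab.ncol();
  double ds = s_max / (n_s - 1);
  double de = eta_max / (n_eta - 1);
  double bhat = beta_eff_max > 0 ? beta_tilde / beta_eff_max : 0.0;
  double omega = cost_omega(cost_form, omega0_hat, bhat, e_max);
  std::vector<double> E(nm), svec(nm);
  IntegerVector usage(nm);
  double grand = 0.0;
  long mem_rounds = 0;
  for (int a = 0; a < nA; ++a) {
    double delta = deltas[a];
    int k = 1;
    for (int i = 0; i < n_enc; ++i) {
      double mu = delta * (double)k;
      double d = 0.0;
      if (mu > 0.0) {
        d = mu * (1.0 + rel_sd * norm_rand());
        while (d < 0.0) d = mu * (1.0 + rel_sd * norm_rand());
      }
      double sumE = 0.0;
      for (int j = 0; j < nm; ++j) {
        double s = alphas[j] * d;
        svec[j] = s;
        double st = shape_pow(s, theta);
        double Ej = (st > 700.0 || alphas[j] <= 0.0)
                        ? 0.0
                        : e_max * (alphas[j] / alpha_max) * std::exp(-st);
        E[j] = Ej;
        sumE += Ej;
      }
      double ebar = sumE / nm;
      double eta = beta_tilde * ebar;
      double pmem = -std::expm1(-eta);
      int resp = -1;
      if (sumE > 0.0) {
        double r = unif_rand() * sumE;
        double cum = 0.0;
        for (int j = 0; j < nm; ++j) {
          cum += E[j];
          if (r <= cum) {
            resp = j;
            break;
          }
        }
        if (resp < 0) resp = nm - 1;
      }
      double kd = 0.0, Eresp = 0.0;
      if (resp >= 0 && pmem > 1e-15) {
        Eresp = E[resp];
        double s = svec[resp];
        if (s < s_max) {
          double x = s / ds;
          int jx = (int)x;
          double fx = x - jx;
          double y = eta / de;
          int jy = (int)y;
          if (jy >= n_eta - 1) { jy = n_eta - 2; }
          double fy = y - jy;
          if (fy > 1.0) fy = 1.0;
          double k00 = kltab(jx, jy), k10 = kltab(jx + 1, jy);
          double k01 = kltab(jx, jy + 1), k11 = kltab(jx + 1, jy + 1);
          double kl = (1 - fy) * (k00 + (k10 - k00) * fx) +
                      fy * (k01 + (k11 - k01) * fx);
          if (kl > 0 && beta_tilde > 0) kd = kl / beta_tilde;
        }
      }
      grand += -omega + pmem * Eresp - kd;
      if (unif_rand() < pmem) {
        k += 1;
        usage[resp] += 1;
        mem_rounds += 1;
      } else {
        k = 1;
      }
    }
  }
  return List::create(_["u_net"] = grand / ((double)nA * n_enc),
                      _["usage_counts"] = usage,
                      _["mem_rounds"] = (double)mem_rounds,
                      _["n_scored"] = (double)nA * n_enc);
}
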