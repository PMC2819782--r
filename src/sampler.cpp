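// Metropolis-within-Gibbs sampler for the shared spatial factor
// prevalence model. One call runs one chain; all randomness comes from
// R's RNG so set.seed() on the R side makes runs reproducible.
//
// Update sweep: f_j single-site random walks with the Leroux full
// conditional as prior; u_jp random walks; indicator loadings on the log
// scale; free prevalence loadings on the log scale; beta by conjugate
// Gibbs (the factor is Gaussian given beta); higher-area intercepts gamma
// by an independence proposal from their flat-prior Gamma conditional,
// corrected for the N(0,100) prior; kappa by logit random walk using the
// eigenvalues of D - W for the log-determinant; both precisions by Gibbs
// from Gamma full conditionals. Step sizes adapt toward 44% acceptance
// during burn-in only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Adapt {
  double s;
  int acc = 0, att = 0;
  explicit Adapt(double s0 = 0.5) : s(s0) {}
  void tally(bool a) { att++; if (a) acc++; }
  void adapt(double target) {
    if (att >= 25) {
      double rate = double(acc) / att;
      s *= std::exp(0.8 * (rate - target));
      s = std::min(std::max(s, 1e-4), 20.0);
      acc = 0; att = 0;
    }
  }
};

// (M v)_j with M = kappa (D - W) + (1 - kappa) I
arma::vec leroux_mult(const arma::vec& v, double kappa,
                      const std::vector<std::vector<int>>& nbr,
                      const arma::vec& m) {
  int n = v.n_elem;
  arma::vec out(n);
  for (int j = 0; j < n; j++) {
    double s = 0.0;
    for (int h : nbr[j]) s += v[h];
    out[j] = (1.0 - kappa + kappa * m[j]) * v[j] - kappa * s;
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(const arma::mat& y, const arma::mat& O,
                   const arma::mat& E, const arma::mat& Z,
                   const arma::mat& X,
                   const IntegerVector& Hj,       // 0-based membership
                   const List& nbr_list,          // 0-based neighbour lists
                   const List& member_list,       // 0-based members per higher area
                   const arma::vec& eigDW,        // eigenvalues of D - W
                   const bool constrained,
                   const int n_iter, const int burnin, const int thin,
                   const List& init,
                   const bool use_likelihood) {
  const int NL = y.n_rows, P = y.n_cols, Q = E.n_cols, NH = Z.n_rows;
  const int L = X.n_cols;

  std::vector<std::vector<int>> nbr(NL);
  for (int j = 0; j < NL; j++) {
    IntegerVector v = nbr_list[j];
    nbr[j].assign(v.begin(), v.end());
  }
  std::vector<std::vector<int>> members(NH);
  for (int i = 0; i < NH; i++) {
    IntegerVector v = member_list[i];
    members[i].assign(v.begin(), v.end());
  }
  arma::vec mdeg(NL);
  for (int j = 0; j < NL; j++) mdeg[j] = nbr[j].size();

  // state
  arma::vec f = as<arma::vec>(init["f"]);
  arma::mat u = as<arma::mat>(init["u"]);
  arma::vec lam_y = as<arma::vec>(init["lambda_y"]);
  arma::vec lam_z = as<arma::vec>(init["lambda_z"]);
  arma::vec beta = as<arma::vec>(init["beta"]);
  arma::mat gam = as<arma::mat>(init["gamma"]);   // NH x Q or 1 x Q
  double kap = as<double>(init["kappa"]);
  double s2f = as<double>(init["sigma2_f"]);
  double s2u = as<double>(init["sigma2_u"]);

  arma::vec eta = (L > 0) ? arma::vec(X * beta) : arma::zeros(NL);

  auto gam_at = [&](int j, int q) -> double {
    return constrained ? gam(Hj[j], q) : gam(0, q);
  };

  arma::mat delta(NL, Q), Dmat(NH, Q, arma::fill::zeros);
  auto refresh_delta = [&]() {
    Dmat.zeros();
    for (int q = 0; q < Q; q++)
      for (int j = 0; j < NL; j++) {
        delta(j, q) = E(j, q) * std::exp(gam_at(j, q) + lam_z[q] * f[j]);
        Dmat(Hj[j], q) += delta(j, q);
      }
  };
  refresh_delta();

  // adaptation state
  std::vector<Adapt> af(NL, Adapt(0.5)), au(P, Adapt(0.5)),
      aly(P, Adapt(0.1)), alz(Q, Adapt(0.1));
  Adapt akap(0.7), aloc(0.2), ascl(0.1);
  std::vector<Adapt> agam_rw(NH * Q, Adapt(0.3));

  const int T = (n_iter - burnin + thin - 1) / thin;
  arma::mat f_s(T, NL), delta_s(T, NL * Q), lamy_s(T, P), lamz_s(T, Q),
      beta_s(T, std::max(L, 1)), gam_s(T, (constrained ? NH : 1) * Q);
  arma::vec kap_s(T), s2f_s(T), s2u_s(T), devy_s(T), devz_s(T);
  arma::mat mlp_y(NL, P, arma::fill::zeros), mld_z(NL, Q, arma::fill::zeros);

  long f_acc = 0, f_att = 0, u_acc = 0, u_att = 0, k_acc = 0, k_att = 0;
  int rec = 0;

  std::vector<double> dbuf(Q);

  for (int t = 0; t < n_iter; t++) {
    const bool adapting = t < burnin;

    // ---- latent factor, single site ----
    for (int j = 0; j < NL; j++) {
      double fj = f[j];
      double prop = fj + af[j].s * norm_rand();
      double la = 0.0;
      bool ok = true;
      if (use_likelihood) {
        for (int p = 0; p < P; p++) {
          double e0 = std::exp(lam_y[p] * fj), e1 = std::exp(lam_y[p] * prop);
          la += y(j, p) * lam_y[p] * (prop - fj) -
                O(j, p) * std::exp(u(j, p)) * (e1 - e0);
        }
      }
      int i = Hj[j];
      for (int q = 0; q < Q; q++) {
        dbuf[q] = E(j, q) * std::exp(gam_at(j, q) + lam_z[q] * prop);
        if (!std::isfinite(dbuf[q])) { ok = false; break; }
        if (use_likelihood) {
          double Dold = Dmat(i, q), Dnew = Dold - delta(j, q) + dbuf[q];
          la += Z(i, q) * (std::log(Dnew) - std::log(Dold)) - (Dnew - Dold);
        }
      }
      // Leroux full conditional as prior
      double denom = 1.0 - kap + kap * mdeg[j];
      double rsum = 0.0;
      for (int h : nbr[j]) rsum += f[h] - eta[h];
      double cmean = eta[j] + kap * rsum / denom;
      la += -0.5 * (denom / s2f) *
            ((prop - cmean) * (prop - cmean) - (fj - cmean) * (fj - cmean));
      bool acc = ok && std::isfinite(la) && std::log(unif_rand()) < la;
      if (acc) {
        f[j] = prop;
        for (int q = 0; q < Q; q++) {
          Dmat(i, q) += dbuf[q] - delta(j, q);
          delta(j, q) = dbuf[q];
        }
      }
      af[j].tally(acc);
      if (adapting) af[j].adapt(0.44); else { f_att++; if (acc) f_acc++; }
    }

    // ---- unique errors ----
    if (s2u > 0) {
      for (int p = 0; p < P; p++) {
        for (int j = 0; j < NL; j++) {
          double u0 = u(j, p);
          double prop = u0 + au[p].s * norm_rand();
          double la = -0.5 * (prop * prop - u0 * u0) / s2u;
          if (use_likelihood) {
            la += y(j, p) * (prop - u0) -
                  O(j, p) * std::exp(lam_y[p] * f[j]) *
                      (std::exp(prop) - std::exp(u0));
          }
          bool acc = std::isfinite(la) && std::log(unif_rand()) < la;
          if (acc) u(j, p) = prop;
          au[p].tally(acc);
          if (!adapting) { u_att++; if (acc) u_acc++; }
        }
        if (adapting) au[p].adapt(0.44);
      }
    }

    // ---- indicator loadings (log-scale RW, Gamma(1,1) prior) ----
    for (int p = 0; p < P; p++) {
      double l0 = lam_y[p];
      double prop = l0 * std::exp(aly[p].s * norm_rand());
      double la = -(prop - l0) + (std::log(prop) - std::log(l0));
      if (use_likelihood) {
        bool ok = true;
        double s = 0.0;
        for (int j = 0; j < NL; j++) {
          double e1 = std::exp(prop * f[j]), e0 = std::exp(l0 * f[j]);
          if (!std::isfinite(e1)) { ok = false; break; }
          s += y(j, p) * (prop - l0) * f[j] -
               O(j, p) * std::exp(u(j, p)) * (e1 - e0);
        }
        if (!ok) la = -INFINITY; else la += s;
      }
      bool acc = std::isfinite(la) && std::log(unif_rand()) < la;
      if (acc) lam_y[p] = prop;
      aly[p].tally(acc);
      if (adapting) aly[p].adapt(0.44);
    }

    // ---- free prevalence loadings (first fixed at 1) ----
    for (int q = 1; q < Q; q++) {
      double l0 = lam_z[q];
      double prop = l0 * std::exp(alz[q].s * norm_rand());
      double la = -(prop - l0) + (std::log(prop) - std::log(l0));
      arma::vec dnew(NL), Dnew(NH, arma::fill::zeros);
      bool ok = true;
      for (int j = 0; j < NL; j++) {
        dnew[j] = delta(j, q) * std::exp((prop - l0) * f[j]);
        if (!std::isfinite(dnew[j])) { ok = false; break; }
        Dnew[Hj[j]] += dnew[j];
      }
      if (ok && use_likelihood)
        for (int i = 0; i < NH; i++)
          la += Z(i, q) * (std::log(Dnew[i]) - std::log(Dmat(i, q))) -
                (Dnew[i] - Dmat(i, q));
      bool acc = ok && std::isfinite(la) && std::log(unif_rand()) < la;
      if (acc) {
        lam_z[q] = prop;
        delta.col(q) = dnew;
        Dmat.col(q) = Dnew;
      }
      alz[q].tally(acc);
      if (adapting) alz[q].adapt(0.44);
    }

    // ---- cause coefficients: conjugate Gibbs ----
    if (L > 0) {
      arma::mat MX(NL, L);
      for (int l = 0; l < L; l++) MX.col(l) = leroux_mult(X.col(l), kap, nbr, mdeg);
      arma::vec Mf = leroux_mult(f, kap, nbr, mdeg);
      arma::mat A = X.t() * MX / s2f + arma::eye(L, L) / 100.0;
      arma::vec b = X.t() * Mf / s2f;
      arma::mat R = arma::chol(A);  // upper
      arma::vec mean = arma::solve(A, b);
      arma::vec zv(L);
      for (int l = 0; l < L; l++) zv[l] = norm_rand();
      beta = mean + arma::solve(arma::trimatu(R), zv);
      eta = X * beta;
    }

    // ---- higher-area intercepts ----
    {
      int ng = constrained ? NH : 1;
      for (int q = 0; q < Q; q++) {
        for (int i = 0; i < ng; i++) {
          double g0 = gam(i, q);
          double Ssum, Ztot;
          if (constrained) {
            Ssum = Dmat(i, q) * std::exp(-g0);
            Ztot = Z(i, q);
          } else {
            Ssum = arma::accu(Dmat.col(q)) * std::exp(-g0);
            Ztot = arma::accu(Z.col(q));
          }
          bool acc = false;
          double gp = g0;
          if (use_likelihood && Ztot > 0) {
            // independence proposal from the flat-prior conditional
            double tdraw = R::rgamma(Ztot, 1.0 / Ssum);
            gp = std::log(tdraw);
            double la = R::dnorm(gp, 0.0, 10.0, 1) - R::dnorm(g0, 0.0, 10.0, 1);
            acc = std::isfinite(gp) && std::log(unif_rand()) < la;
          } else {
            Adapt& ad = agam_rw[i * Q + q];
            gp = g0 + ad.s * norm_rand();
            double la = R::dnorm(gp, 0.0, 10.0, 1) - R::dnorm(g0, 0.0, 10.0, 1);
            if (use_likelihood)
              la += Ztot * (gp - g0) - Ssum * (std::exp(gp) - std::exp(g0));
            acc = std::isfinite(la) && std::log(unif_rand()) < la;
            ad.tally(acc);
            if (adapting) ad.adapt(0.44);
          }
          if (acc) {
            double mult = std::exp(gp - g0);
            gam(i, q) = gp;
            if (constrained) {
              for (int j : members[i]) delta(j, q) *= mult;
              Dmat(i, q) *= mult;
            } else {
              delta.col(q) *= mult;
              Dmat.col(q) *= mult;
            }
          }
        }
      }
    }

    // ---- joint location move: f -> f + a ----
    // the global level of f is a slow mode under single-site updates;
    // this move shifts the whole field at once. M 1 = (1-kappa) 1, so the
    // Leroux quadratic change has closed form.
    {
      double a = aloc.s * norm_rand();
      double la = 0.0;
      bool ok = true;
      if (use_likelihood) {
        for (int p = 0; p < P; p++) {
          double elap = std::exp(lam_y[p] * a);
          if (!std::isfinite(elap)) { ok = false; break; }
          for (int j = 0; j < NL; j++)
            la += y(j, p) * lam_y[p] * a -
                  O(j, p) * std::exp(lam_y[p] * f[j] + u(j, p)) * (elap - 1.0);
        }
        for (int q = 0; q < Q && ok; q++) {
          double elaq = std::exp(lam_z[q] * a);
          for (int i = 0; i < NH; i++)
            la += Z(i, q) * lam_z[q] * a - Dmat(i, q) * (elaq - 1.0);
        }
      }
      double rsum = 0.0;
      for (int j = 0; j < NL; j++) rsum += f[j] - eta[j];
      la += -0.5 * (1.0 - kap) / s2f * (2.0 * a * rsum + a * a * NL);
      bool acc = ok && std::isfinite(la) && std::log(unif_rand()) < la;
      if (acc) {
        f += a;
        for (int q = 0; q < Q; q++) {
          double elaq = std::exp(lam_z[q] * a);
          delta.col(q) *= elaq;
          Dmat.col(q) *= elaq;
        }
      }
      aloc.tally(acc);
      if (adapting) aloc.adapt(0.30);
    }

    // ---- joint scale move along the factor-loading ridge ----
    // f -> c f, lam_y -> lam_y / c, beta -> c beta, sigma2_f -> c^2
    // sigma2_f, free lam_z -> lam_z / c, and the first-outcome intercepts
    // shifted so every fitted total Delta is unchanged. Both likelihoods
    // and the Leroux density are then invariant; only the priors (and the
    // intercept shift) discriminate, so the move travels the scale ridge
    // that single-site updates cross slowly.
    {
      double epsc = ascl.s * norm_rand();
      double c = std::exp(epsc);
      double tau = 1.0 / s2f;
      double la = (double(L) - P - (Q - 1) - 2.0) * epsc;  // Jacobian net of the det term
      la += tau * (1.0 - 1.0 / (c * c));                   // Gamma(1,1) prior on precision
      for (int p = 0; p < P; p++) la += lam_y[p] * (1.0 - 1.0 / c);
      for (int q = 1; q < Q; q++) la += lam_z[q] * (1.0 - 1.0 / c);
      for (int l = 0; l < L; l++)
        la += -(c * c - 1.0) * beta[l] * beta[l] / 200.0;
      arma::vec dnew(NL), Dnew(NH, arma::fill::zeros);
      bool ok = true;
      for (int j = 0; j < NL; j++) {
        dnew[j] = delta(j, 0) * std::exp((c - 1.0) * lam_z[0] * f[j]);
        if (!std::isfinite(dnew[j])) { ok = false; break; }
        Dnew[Hj[j]] += dnew[j];
      }
      int ng0 = constrained ? NH : 1;
      arma::vec gshift(ng0, arma::fill::zeros);
      if (ok) {
        if (constrained) {
          for (int i = 0; i < NH; i++)
            gshift[i] = std::log(Dmat(i, 0)) - std::log(Dnew[i]);
        } else {
          gshift[0] = std::log(arma::accu(Dmat.col(0))) -
                      std::log(arma::accu(Dnew));
        }
        for (int i = 0; i < ng0; i++) {
          double g0 = gam(i, 0), g1 = g0 + gshift[i];
          la += R::dnorm(g1, 0.0, 10.0, 1) - R::dnorm(g0, 0.0, 10.0, 1);
        }
        if (!constrained && use_likelihood) {
          // a single intercept preserves only the global total; account
          // for the per-higher-area likelihood change
          double es = std::exp(gshift[0]);
          for (int i = 0; i < NH; i++) {
            double Dfin = Dnew[i] * es;
            la += Z(i, 0) * (std::log(Dfin) - std::log(Dmat(i, 0))) -
                  (Dfin - Dmat(i, 0));
          }
        }
      }
      bool acc = ok && std::isfinite(la) && std::log(unif_rand()) < la;
      if (acc) {
        f *= c;
        eta *= c;
        beta *= c;
        lam_y /= c;
        for (int q = 1; q < Q; q++) lam_z[q] /= c;
        s2f *= c * c;
        for (int i = 0; i < ng0; i++) gam(i, 0) += gshift[i];
        if (constrained) {
          // Dmat column 0 is unchanged by construction
          for (int j = 0; j < NL; j++)
            delta(j, 0) = dnew[j] * std::exp(gshift[Hj[j]]);
        } else {
          double es = std::exp(gshift[0]);
          delta.col(0) = dnew * es;
          Dmat.col(0) = Dnew * es;
        }
      }
      ascl.tally(acc);
      if (adapting) ascl.adapt(0.30);
    }

    // ---- spatial correlation kappa (logit RW) ----
    {
      arma::vec r = f - eta;
      double SI = arma::dot(r, r), SW = 0.0;
      for (int j = 0; j < NL; j++)
        for (int h : nbr[j])
          if (h > j) SW += (r[j] - r[h]) * (r[j] - r[h]);
      auto lp_k = [&](double k) {
        double ld = 0.0;
        for (unsigned int e = 0; e < eigDW.n_elem; e++)
          ld += std::log(k * eigDW[e] + 1.0 - k);
        return 0.5 * ld - 0.5 * (k * SW + (1.0 - k) * SI) / s2f +
               std::log(k) + std::log(1.0 - k);  // logit Jacobian
      };
      double lo = std::log(kap) - std::log1p(-kap);
      double lprop = lo + akap.s * norm_rand();
      double kp = 1.0 / (1.0 + std::exp(-lprop));
      kp = std::min(std::max(kp, 1e-6), 1.0 - 1e-6);
      double la = lp_k(kp) - lp_k(kap);
      bool acc = std::isfinite(la) && std::log(unif_rand()) < la;
      if (acc) kap = kp;
      akap.tally(acc);
      if (adapting) akap.adapt(0.44); else { k_att++; if (acc) k_acc++; }

      // ---- variance parameters: Gibbs ----
      double quad = kap * SW + (1.0 - kap) * SI;
      s2f = 1.0 / R::rgamma(1.0 + NL / 2.0, 1.0 / (1.0 + 0.5 * quad));
      double ssu = arma::accu(u % u);
      s2u = 1.0 / R::rgamma(1.0 + NL * P / 2.0, 1.0 / (1.0 + 0.5 * ssu));
    }

    // ---- record ----
    if (t >= burnin && (t - burnin) % thin == 0) {
      f_s.row(rec) = f.t();
      delta_s.row(rec) = arma::vectorise(delta).t();
      lamy_s.row(rec) = lam_y.t();
      lamz_s.row(rec) = lam_z.t();
      if (L > 0) beta_s.row(rec) = beta.t(); else beta_s(rec, 0) = 0.0;
      gam_s.row(rec) = arma::vectorise(gam).t();
      kap_s[rec] = kap; s2f_s[rec] = s2f; s2u_s[rec] = s2u;

      double dy = 0.0, dz = 0.0;
      for (int p = 0; p < P; p++)
        for (int j = 0; j < NL; j++) {
          double lm = lam_y[p] * f[j] + u(j, p);
          mlp_y(j, p) += lm;
          dy += -2.0 * R::dpois(y(j, p), O(j, p) * std::exp(lm), 1);
        }
      for (int q = 0; q < Q; q++) {
        for (int j = 0; j < NL; j++) mld_z(j, q) += std::log(delta(j, q));
        for (int i = 0; i < NH; i++)
          dz += -2.0 * R::dpois(Z(i, q), Dmat(i, q), 1);
      }
      devy_s[rec] = dy; devz_s[rec] = dz;
      rec++;
    }

    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }

  mlp_y /= std::max(rec, 1);
  mld_z /= std::max(rec, 1);

  return List::create(
      _["f"] = f_s, _["delta"] = delta_s, _["lambda_y"] = lamy_s,
      _["lambda_z"] = lamz_s, _["beta"] = beta_s, _["gamma"] = gam_s,
      _["kappa"] = kap_s, _["sigma2_f"] = s2f_s, _["sigma2_u"] = s2u_s,
      _["dev_y"] = devy_s, _["dev_z"] = devz_s,
      _["mean_linpred_y"] = mlp_y, _["mean_logdelta"] = mld_z,
      _["accept"] = NumericVector::create(
          _["f"] = f_att ? double(f_acc) / f_att : NA_REAL,
          _["u"] = u_att ? double(u_acc) / u_att : NA_REAL,
          _["kappa"] = k_att ? double(k_acc) / k_att : NA_REAL),
      _["n_retained"] = rec);
}
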