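// Reversible-jump MCMC core for the variable-rates regression.
//
// Model: y ~ N(X beta, sigma2 * V_lambda(r)), where V(r) is the phylogenetic
// covariance built from branch lengths multiplied by their effective rate
// scalars (products of active branch- and clade-level scalars), and
// V_lambda applies Pagel's lambda to the off-diagonal. The rj dimension is
// the set of active scalars; inactive positions have r = 1 exactly.
//
// The `power` argument tempers the likelihood (power posterior), which is
// what the stepping-stone marginal-likelihood estimator samples from.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double mvn_loglik(const arma::mat& X, const arma::vec& y,
                         const arma::mat& A, const arma::vec& blen,
                         const arma::vec& reff, double lambda, double sigma2,
                         const arma::vec& beta) {
  arma::vec w = blen % reff;
  arma::mat V = A * arma::diagmat(w) * A.t();
  arma::vec d = V.diag();
  V *= lambda;
  V.diag() = d;
  V *= sigma2;
  arma::mat L;
  bool ok = arma::chol(L, V, "lower");
  if (!ok) return -std::numeric_limits<double>::infinity();
  arma::vec resid = y - X * beta;
  arma::vec z = arma::solve(arma::trimatl(L), resid);
  double n = (double)y.n_elem;
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  return -0.5 * n * std::log(2.0 * M_PI) - 0.5 * logdet - 0.5 * arma::dot(z, z);
}

// [[Rcpp::export]]
double vr_loglik_cpp(const arma::mat& X, const arma::vec& y,
                     const arma::mat& A, const arma::vec& blen,
                     const arma::vec& reff, double lambda, double sigma2,
                     const arma::vec& beta) {
  return mvn_loglik(X, y, A, blen, reff, lambda, sigma2, beta);
}

// [[Rcpp::export]]
List varrates_chain_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::mat& A, const arma::vec& blen,
                        const List& clades,
                        int n_iter, int burnin, int thin,
                        double power, bool allow_scalars,
                        double scalar_shape, double scalar_scale,
                        double sigma2_rate, double beta_bound,
                        double k_prior_mean,
                        const arma::vec& beta_sd, double lsig_sd,
                        double lambda_sd, double lnr_sd,
                        arma::vec beta, double sigma2, double lambda) {
  const int p = X.n_cols, m = blen.n_elem, ncl = clades.size();

  std::vector<arma::uvec> clbr(ncl);
  for (int i = 0; i < ncl; i++) {
    IntegerVector v = clades[i];
    arma::uvec u(v.size());
    for (int j = 0; j < v.size(); j++) u[j] = (unsigned)(v[j] - 1);
    clbr[i] = u;
  }

  // active scalar bookkeeping: type 0 = single branch, type 1 = clade
  std::vector<int> act_type, act_idx;
  std::vector<double> act_val;
  std::vector<bool> br_act(m, false), cl_act(ncl, false);
  int n_br_act = 0, n_cl_act = 0;

  auto reff_of = [&]() {
    arma::vec r(m, arma::fill::ones);
    for (size_t k = 0; k < act_type.size(); k++) {
      if (act_type[k] == 0) r[act_idx[k]] *= act_val[k];
      else r.elem(clbr[act_idx[k]]) *= act_val[k];
    }
    return r;
  };

  arma::vec reff = reff_of();
  double ll = mvn_loglik(X, y, A, blen, reff, lambda, sigma2, beta);

  const int nsamp = (n_iter - burnin) / thin;
  arma::mat samples(nsamp, p + 4 + m);
  int isamp = 0;

  long cont_acc = 0, cont_tot = 0, birth_acc = 0, birth_tot = 0,
       death_acc = 0, death_tot = 0, pert_acc = 0, pert_tot = 0;

  for (int it = 1; it <= n_iter; it++) {
    double u = R::runif(0.0, 1.0);
    if (!allow_scalars || u < 0.5) {
      // continuous parameter update
      int j = (int)std::floor(R::runif(0.0, 1.0) * (p + 2));
      if (j >= p + 2) j = p + 1;
      cont_tot++;
      if (j < p) {
        double b_old = beta[j];
        double b_new = b_old + R::rnorm(0.0, beta_sd[j]);
        if (std::fabs(b_new) <= beta_bound) {
          beta[j] = b_new;
          double ll_new = mvn_loglik(X, y, A, blen, reff, lambda, sigma2, beta);
          if (std::log(R::runif(0.0, 1.0)) < power * (ll_new - ll)) {
            ll = ll_new; cont_acc++;
          } else beta[j] = b_old;
        }
      } else if (j == p) {
        // log sigma2 random walk; Exp(sigma2_rate) prior, Jacobian included
        double ls_old = std::log(sigma2);
        double ls_new = ls_old + R::rnorm(0.0, lsig_sd);
        double s2_new = std::exp(ls_new);
        double ll_new = mvn_loglik(X, y, A, blen, reff, lambda, s2_new, beta);
        double la = power * (ll_new - ll)
                  - sigma2_rate * (s2_new - sigma2) + (ls_new - ls_old);
        if (std::log(R::runif(0.0, 1.0)) < la) {
          sigma2 = s2_new; ll = ll_new; cont_acc++;
        }
      } else {
        // lambda random walk with reflection at [0, 1]
        double l_new = lambda + R::rnorm(0.0, lambda_sd);
        while (l_new < 0.0 || l_new > 1.0) {
          if (l_new < 0.0) l_new = -l_new;
          if (l_new > 1.0) l_new = 2.0 - l_new;
        }
        double ll_new = mvn_loglik(X, y, A, blen, reff, l_new, sigma2, beta);
        if (std::log(R::runif(0.0, 1.0)) < power * (ll_new - ll)) {
          lambda = l_new; ll = ll_new; cont_acc++;
        }
      }
    } else {
      double v = R::runif(0.0, 1.0);
      int k = (int)act_type.size();
      if (v < 0.25) {
        // birth: pick type, then a uniform inactive position; propose from prior
        birth_tot++;
        int type = (R::runif(0.0, 1.0) < 0.5) ? 0 : 1;
        int n_inact = (type == 0) ? (m - n_br_act) : (ncl - n_cl_act);
        if (ncl == 0) { type = 0; n_inact = m - n_br_act; }
        if (n_inact > 0) {
          int pick = (int)std::floor(R::runif(0.0, 1.0) * n_inact);
          if (pick >= n_inact) pick = n_inact - 1;
          int idx = -1, seen = 0;
          if (type == 0) {
            for (int b = 0; b < m; b++) if (!br_act[b]) { if (seen++ == pick) { idx = b; break; } }
          } else {
            for (int c = 0; c < ncl; c++) if (!cl_act[c]) { if (seen++ == pick) { idx = c; break; } }
          }
          double r_new = R::rgamma(scalar_shape, scalar_scale);
          act_type.push_back(type); act_idx.push_back(idx);
          act_val.push_back(r_new);
          arma::vec reff_new = reff_of();
          double ll_new = mvn_loglik(X, y, A, blen, reff_new, lambda, sigma2, beta);
          // placement prior matches the proposal (those terms cancel); a
          // Poisson(k_prior_mean) prior on the scalar count supplies the
          // complexity penalty
          double la = power * (ll_new - ll)
                    + std::log(k_prior_mean) - std::log((double)(k + 1));
          if (std::log(R::runif(0.0, 1.0)) < la) {
            reff = reff_new; ll = ll_new; birth_acc++;
            if (type == 0) { br_act[idx] = true; n_br_act++; }
            else { cl_act[idx] = true; n_cl_act++; }
          } else {
            act_type.pop_back(); act_idx.pop_back(); act_val.pop_back();
          }
        }
      } else if (v < 0.5) {
        // death: remove a uniformly chosen active scalar
        if (k > 0) {
          death_tot++;
          int pick = (int)std::floor(R::runif(0.0, 1.0) * k);
          if (pick >= k) pick = k - 1;
          int type = act_type[pick], idx = act_idx[pick];
          double val = act_val[pick];
          act_type.erase(act_type.begin() + pick);
          act_idx.erase(act_idx.begin() + pick);
          act_val.erase(act_val.begin() + pick);
          arma::vec reff_new = reff_of();
          double ll_new = mvn_loglik(X, y, A, blen, reff_new, lambda, sigma2, beta);
          double la = power * (ll_new - ll)
                    + std::log((double)k) - std::log(k_prior_mean);
          if (std::log(R::runif(0.0, 1.0)) < la) {
            reff = reff_new; ll = ll_new; death_acc++;
            if (type == 0) { br_act[idx] = false; n_br_act--; }
            else { cl_act[idx] = false; n_cl_act--; }
          } else {
            act_type.insert(act_type.begin() + pick, type);
            act_idx.insert(act_idx.begin() + pick, idx);
            act_val.insert(act_val.begin() + pick, val);
          }
        }
      } else {
        // perturb an existing scalar with a log-normal random walk
        if (k > 0) {
          pert_tot++;
          int pick = (int)std::floor(R::runif(0.0, 1.0) * k);
          if (pick >= k) pick = k - 1;
          double r_old = act_val[pick];
          double r_new = r_old * std::exp(R::rnorm(0.0, lnr_sd));
          act_val[pick] = r_new;
          arma::vec reff_new = reff_of();
          double ll_new = mvn_loglik(X, y, A, blen, reff_new, lambda, sigma2, beta);
          double la = power * (ll_new - ll)
                    + R::dgamma(r_new, scalar_shape, scalar_scale, 1)
                    - R::dgamma(r_old, scalar_shape, scalar_scale, 1)
                    + std::log(r_new) - std::log(r_old);
          if (std::log(R::runif(0.0, 1.0)) < la) {
            reff = reff_new; ll = ll_new; pert_acc++;
          } else act_val[pick] = r_old;
        }
      }
    }

    if (it > burnin && (it - burnin) % thin == 0 && isamp < nsamp) {
      for (int j = 0; j < p; j++) samples(isamp, j) = beta[j];
      samples(isamp, p) = sigma2;
      samples(isamp, p + 1) = lambda;
      samples(isamp, p + 2) = (double)act_type.size();
      samples(isamp, p + 3) = ll;
      for (int b = 0; b < m; b++) samples(isamp, p + 4 + b) = reff[b];
      isamp++;
    }
  }

  return List::create(
    _["samples"] = samples,
    _["acceptance"] = NumericVector::create(
      _["continuous"] = cont_tot ? (double)cont_acc / cont_tot : NA_REAL,
      _["birth"] = birth_tot ? (double)birth_acc / birth_tot : NA_REAL,
      _["death"] = death_tot ? (double)death_acc / death_tot : NA_REAL,
      _["perturb"] = pert_tot ? (double)pert_acc / pert_tot : NA_REAL),
    _["n_proposed"] = NumericVector::create(
      _["continuous"] = (double)cont_tot, _["birth"] = (double)birth_tot,
      _["death"] = (double)death_tot, _["perturb"] = (double)pert_tot)
  );
}
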