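#include <Rcpp.h>
using namespace Rcpp;

// Sequential filter over one subject-condition choice sequence.
//
// Learner 0 = Kalman (Bayesian mean tracking), 1 = Delta rule. Both carry the
// choice-dependent Kalman variance recursion, which does not depend on the
// observed rewards; the Delta learner uses it only to supply the uncertainty
// term of choice rules 2-4 while its values are updated with a constant
// learning rate.
//
// Choice rules: 1 softmax (SM), 2 + uncertainty bonus (SME),
// 3 + perseveration bonus (SMEP), 4 + total-uncertainty random
// exploration (SMERP). The inverse temperature multiplies the full
// augmented value in every rule.

static inline double log_sum_exp(const std::vector<double>& x) {
  double m = x[0];
  for (size_t i = 1; i < x.size(); ++i) if (x[i] > m) m = x[i];
  double s = 0.0;
  for (size_t i = 0; i < x.size(); ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export(name = ".filter_cpp")]]
List filter_cpp(IntegerVector choice, NumericVector reward,
                LogicalVector responded,
                int learner, int rule,
                double alpha, double beta, double phi, double rho,
                double gamma,
                double lambda, double center, double obs_var,
                double diff_var, double init_mean, double init_var,
                double v1, bool trajectory) {
  const int T = choice.size();
  const int K = 4;
  std::vector<double> mu(K), varv(K), val(K);
  for (int i = 0; i < K; ++i) {
    mu[i] = init_mean;
    varv[i] = init_var;
    val[i] = v1;
  }
  int prev = -1; // previous responded choice, 0-based; -1 = none
  double ll = 0.0;
  const double eps = std::numeric_limits<double>::epsilon();

  NumericMatrix mu_pre, sd_pre, prob;
  NumericVector kgain, pe;
  IntegerVector prev_out;
  if (trajectory) {
    mu_pre = NumericMatrix(T, K);
    sd_pre = NumericMatrix(T, K);
    prob = NumericMatrix(T, K);
    kgain = NumericVector(T, NA_REAL);
    pe = NumericVector(T, NA_REAL);
    prev_out = IntegerVector(T);
  }

  std::vector<double> logits(K), lp(K);
  for (int t = 0; t < T; ++t) {
    double sum_sd = 0.0;
    std::vector<double> sd(K);
    for (int i = 0; i < K; ++i) {
      sd[i] = std::sqrt(varv[i]);
      sum_sd += sd[i];
    }
    // augmented value per bandit
    for (int i = 0; i < K; ++i) {
      double m = (learner == 0) ? mu[i] : val[i];
      double v = m;
      if (rule >= 2) v += phi * sd[i];
      if (rule >= 3 && prev == i) v += rho;
      if (rule >= 4) v += gamma * m / sum_sd;
      logits[i] = beta * v;
    }
    double lse = log_sum_exp(logits);
    for (int i = 0; i < K; ++i) lp[i] = logits[i] - lse;

    if (trajectory) {
      for (int i = 0; i < K; ++i) {
        mu_pre(t, i) = (learner == 0) ? mu[i] : val[i];
        sd_pre(t, i) = sd[i];
        prob(t, i) = std::exp(lp[i]);
      }
      prev_out[t] = prev + 1; // 0 when no previous choice
    }

    bool resp = responded[t];
    if (resp) {
      int c = choice[t] - 1;
      if (c < 0 || c >= K) stop("choice out of range at trial %d", t + 1);
      double p = std::exp(lp[c]);
      if (p < eps) p = eps; // floor inside the likelihood only
      ll += std::log(p);
      // within-trial update of the chosen bandit
      double kap = varv[c] / (varv[c] + obs_var);
      double delta_k = reward[t] - mu[c];
      double delta_d = reward[t] - val[c];
      if (trajectory) {
        kgain[t] = kap;
        pe[t] = (learner == 0) ? delta_k : delta_d;
      }
      mu[c] += kap * delta_k;
      val[c] += alpha * delta_d;
      varv[c] = (1.0 - kap) * varv[c];
      prev = c;
    } else {
      prev = -1; // a missed trial clears the perseveration indicator
    }
    // between-trial drift of all bandits
    for (int i = 0; i < K; ++i) {
      mu[i] = lambda * mu[i] + (1.0 - lambda) * center;
      varv[i] = lambda * lambda * varv[i] + diff_var;
    }
  }

  if (!trajectory) return List::create(_["loglik"] = ll);
  return List::create(_["loglik"] = ll, _["mu_pre"] = mu_pre,
                      _["sd_pre"] = sd_pre, _["prob"] = prob,
                      _["kalman_gain"] = kgain, _["pe"] = pe,
                      _["prev_choice"] = prev_out);
}

// Log-likelihood for a matrix of parameter draws (rows) on one sequence.
// pars columns: alpha, beta, phi, rho, gamma.
// [[Rcpp::export(name = ".loglik_draws_cpp")]]
NumericVector loglik_draws_cpp(IntegerVector choice, NumericVector reward,
                               LogicalVector responded,
                               int learner, int rule, NumericMatrix pars,
                               double lambda, double center, double obs_var,
                               double diff_var, double init_mean,
                               double init_var, double v1) {
  const int n = pars.nrow();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    List r = filter_cpp(choice, reward, responded, learner, rule,
                        pars(j, 0), pars(j, 1), pars(j, 2), pars(j, 3),
                        pars(j, 4), lambda, center, obs_var, diff_var,
                        init_mean, init_var, v1, false);
    out[j] = as<double>(r["loglik"]);
  }
  return out;
}
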