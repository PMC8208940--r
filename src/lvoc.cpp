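#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Euler-Maruyama walk between absorbing boundaries {0, a}, start z.
// boundary: 1 = upper, 0 = lower, -1 = deadline reached without absorption.
// rt includes the non-decision time t0; timeouts report rt = deadline.
static inline void ddm_walk(double v, double a, double z, double s,
                            double t0, double dt, double deadline,
                            int &boundary, double &rt) {
  double x = z, t = 0.0;
  const double sq = s * std::sqrt(dt);
  const double tmax = deadline - t0;
  while (t < tmax) {
    x += v * dt + sq * norm_rand();
    t += dt;
    if (x >= a) { boundary = 1; rt = t + t0; return; }
    if (x <= 0.0) { boundary = 0; rt = t + t0; return; }
  }
  boundary = -1;
  rt = deadline;
}

// [[Rcpp::export]]
DataFrame cpp_ddm_simulate(int n, double v, double a, double z, double s,
                           double t0, double dt, double deadline) {
  IntegerVector boundary(n);
  NumericVector rt(n);
  LogicalVector timed(n);
  for (int i = 0; i < n; ++i) {
    if (i % 4096 == 0) checkUserInterrupt();
    int b; double r;
    ddm_walk(v, a, z, s, t0, dt, deadline, b, r);
    boundary[i] = b;
    rt[i] = r;
    timed[i] = (b < 0);
  }
  return DataFrame::create(_["boundary"] = boundary, _["rt"] = rt,
                           _["timed_out"] = timed);
}

static inline double ctrl_cost(double c, double c_prev, double alpha,
                               double beta, bool baseline_subtracted) {
  double cost = std::exp(alpha + beta * std::fabs(c)) +
                std::exp(alpha + beta * std::fabs(c - c_prev));
  if (baseline_subtracted) cost -= 2.0 * std::exp(alpha);
  return cost;
}

// Full LVOC agent run over one participant's trial schedule.
// Feature layout (0-based): colors 0..7, words 8..15,
// conjunctions 16 + 8*(color-1) + (word-1), global 80. 81 features total.
// Boundary convention: upper = color-naming (CN) response, so the drift is
// d = c * d_controlled - (1 - c) * d_automatic on incongruent stimuli.
// [[Rcpp::export]]
List cpp_run_lvoc(IntegerVector color_idx, IntegerVector word_idx,
                  IntegerVector rewarded_cn, IntegerVector points,
                  arma::vec mu, arma::mat Sigma, double sigma_n2,
                  double alpha, double beta, double omega,
                  bool baseline_subtracted, bool cost_in_target,
                  NumericVector grid,
                  double d_controlled, double d_automatic,
                  double a, double z, double s, double t0,
                  double dt, double deadline,
                  bool include_conjunctions, double c_init) {
  const int n = color_idx.size();
  const int ng = grid.size();
  NumericVector c_chosen(n), drift(n), rt(n), reward(n);
  IntegerVector response(n);  // 1 = CN, 0 = WR, -1 = timeout
  LogicalVector timed(n);

  double c_prev = c_init;
  const int nact = include_conjunctions ? 4 : 3;
  arma::uvec idx(nact);
  arma::vec zdraw(nact);

  for (int i = 0; i < n; ++i) {
    if (i % 64 == 0) checkUserInterrupt();
    const int ci = color_idx[i] - 1, wi = word_idx[i] - 1;
    idx(0) = (arma::uword)ci;
    idx(1) = (arma::uword)(8 + wi);
    if (include_conjunctions) {
      idx(2) = (arma::uword)(16 + 8 * ci + wi);
      idx(3) = 80;
    } else {
      idx(2) = 80;
    }

    // Thompson sample of the active weights (marginal of the joint draw).
    arma::mat S = Sigma.submat(idx, idx);
    arma::mat L;
    if (!arma::chol(L, S, "lower")) {
      S.diag() += 1e-10;
      if (!arma::chol(L, S, "lower"))
        stop("posterior covariance not positive definite");
    }
    for (int j = 0; j < nact; ++j) zdraw(j) = norm_rand();
    arma::vec wtil = mu.elem(idx) + L * zdraw;
    const double W = arma::accu(wtil);

    // Grid argmax of c * sum(w) - cost(c, c_prev); ties -> smallest c.
    double best_c = grid[0];
    double best_v = grid[0] * W -
      ctrl_cost(grid[0], c_prev, alpha, beta, baseline_subtracted);
    for (int g = 1; g < ng; ++g) {
      const double val = grid[g] * W -
        ctrl_cost(grid[g], c_prev, alpha, beta, baseline_subtracted);
      if (val > best_v) { best_v = val; best_c = grid[g]; }
    }

    const double d = best_c * d_controlled - (1.0 - best_c) * d_automatic;
    int b; double r;
    ddm_walk(d, a, z, s, t0, dt, deadline, b, r);

    double R = 0.0;
    if (b >= 0 && ((b == 1) == (rewarded_cn[i] == 1))) R = points[i];

    double value = R - omega * r;
    if (cost_in_target)
      value -= ctrl_cost(best_c, c_prev, alpha, beta, baseline_subtracted);

    if (best_c > 0.0) {
      // Rank-1 conjugate update with sparse features f = best_c at idx.
      arma::vec k = best_c * arma::sum(Sigma.cols(idx), 1);
      const double fTk = best_c * arma::accu(k.elem(idx));
      const double denom = sigma_n2 + fTk;
      const double resid = value - best_c * arma::accu(mu.elem(idx));
      mu += k * (resid / denom);
      Sigma -= (k * k.t()) / denom;
    }

    c_chosen[i] = best_c;
    drift[i] = d;
    response[i] = b;
    rt[i] = r;
    timed[i] = (b < 0);
    reward[i] = R;
    c_prev = best_c;
  }

  return List::create(_["c_chosen"] = c_chosen, _["drift"] = drift,
                      _["response"] = response, _["rt"] = rt,
                      _["timed_out"] = timed, _["reward"] = reward,
                      _["posterior_mean"] = mu);
}
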