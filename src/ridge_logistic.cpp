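// Ridge-penalized logistic regression (no intercept) and forward-stepwise
// likelihood screening. Objective, with yt in {-1,+1}:
//   f(w) = 0.5 * lambda * ||w||^2 + C * sum_i log(1 + exp(-yt_i * x_i.w))
// Newton iterations with backtracking; the unpenalized log-likelihood is
// returned for likelihood-ratio comparisons.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softplus(double u) {
  // log(1 + exp(u)), overflow-safe
  if (u > 30.0) return u;
  if (u < -30.0) return std::exp(u);
  return std::log1p(std::exp(u));
}

static double objective(const vec& w, const vec& m, double lambda, double C) {
  double s = 0.0;
  for (uword i = 0; i < m.n_elem; ++i) s += softplus(-m[i]);
  return 0.5 * lambda * dot(w, w) + C * s;
}

static vec newton_fit(const mat& X, const vec& yt, double lambda, double C,
                      double tol, int maxit, double* grad_norm_out,
                      const vec* warm = nullptr) {
  const uword p = X.n_cols;
  vec w(p, fill::zeros);
  if (warm && warm->n_elem == p) w = *warm;
  vec m = yt % (X * w);          // margins
  double gn = datum::inf;
  for (int it = 0; it < maxit; ++it) {
    vec sig(m.n_elem);
    for (uword i = 0; i < m.n_elem; ++i) sig[i] = 1.0 / (1.0 + std::exp(-m[i]));
    vec grad = lambda * w - C * (X.t() * (yt % (1.0 - sig)));
    gn = norm(grad, 2);
    if (gn <= tol) break;
    vec wd = C * (sig % (1.0 - sig));
    // guard: keep Hessian well-posed under (quasi-)separation
    wd.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    mat H = X.t() * (X.each_col() % wd);
    H.diag() += lambda;
    vec step;
    if (!solve(step, H, grad, solve_opts::likely_sympd + solve_opts::no_approx)) {
      H.diag() += 1e-8;
      step = solve(H, grad);
    }
    double obj0 = objective(w, m, lambda, C);
    double t = 1.0;
    bool moved = false;
    for (int h = 0; h < 40; ++h) {
      vec wn = w - t * step;
      vec mn = yt % (X * wn);
      if (objective(wn, mn, lambda, C) <= obj0 - 1e-14 * std::fabs(obj0)) {
        w = wn; m = mn; moved = true; break;
      }
      t *= 0.5;
    }
    if (!moved) {
      // near the optimum the objective decrease is below float resolution;
      // the undamped Newton step is locally contractive, so take it
      if (gn < 1e-4) { w -= step; m = yt % (X * w); continue; }
      break;
    }
  }
  if (grad_norm_out) *grad_norm_out = gn;
  return w;
}

static double loglik_of(const vec& m) {
  double s = 0.0;
  for (uword i = 0; i < m.n_elem; ++i) s -= softplus(-m[i]);
  return s;
}

// [[Rcpp::export(name = ".ridge_logistic_cpp")]]
Rcpp::List ridge_logistic_cpp(const arma::mat& X, const arma::vec& y01,
                              double lambda, double C,
                              double tol = 1e-10, int maxit = 200) {
  vec yt = 2.0 * y01 - 1.0;
  double gn = 0.0;
  vec w = newton_fit(X, yt, lambda, C, tol, maxit, &gn);
  vec m = yt % (X * w);
  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("loglik") = loglik_of(m),
                            Rcpp::Named("grad_norm") = gn);
}

// Greedy forward selection of k features by maximal log-likelihood gain
// (equivalently minimal 1-df LRT p-value); micro-ridge lambda stabilizes
// fits under separation. Ties broken by feature order (first wins).
// [[Rcpp::export(name = ".stepwise_cpp")]]
Rcpp::List stepwise_cpp(const arma::mat& X, const arma::vec& y01, int k,
                        double lambda = 1e-6, double C = 1.0) {
  const int p = (int)X.n_cols;
  const int n = (int)X.n_rows;
  vec yt = 2.0 * y01 - 1.0;
  std::vector<int> path;
  std::vector<double> llpath;
  std::vector<bool> used(p, false);
  double ll_cur = -n * std::log(2.0);   // empty model, score 0
  llpath.push_back(ll_cur);
  vec w_cur;                            // weights of the current model
  for (int step = 0; step < k; ++step) {
    int best = -1;
    double best_ll = -datum::inf;
    vec w_best;
    mat Xs(n, path.size() + 1);
    for (size_t q = 0; q < path.size(); ++q) Xs.col(q) = X.col(path[q]);
    // warm start: current optimum with a zero coefficient for the candidate
    vec warm(path.size() + 1, fill::zeros);
    if (w_cur.n_elem == path.size()) warm.head(path.size()) = w_cur;
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      Xs.col(path.size()) = X.col(j);
      vec w = newton_fit(Xs, yt, lambda, C, 1e-7, 50, nullptr, &warm);
      double ll = loglik_of(yt % (Xs * w));
      if (ll > best_ll + 1e-12) { best_ll = ll; best = j; w_best = w; }
    }
    if (best < 0) break;
    used[best] = true;
    path.push_back(best);
    llpath.push_back(best_ll);
    w_cur = w_best;
  }
  return Rcpp::List::create(Rcpp::Named("path") = path,
                            Rcpp::Named("loglik") = llpath);
}
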