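// First-order solvers for l2-regularized multinomial logistic regression and
// Cox proportional hazards with the Efron tie correction. Both minimize
//   f(theta) = mean data loss + lambda * ||weights||^2   (intercepts free)
// by accelerated gradient descent with backtracking line search, so fits are
// deterministic and usable at p >> n where second-order solvers are not.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// ---------- softmax objective -------------------------------------------------

// y is 0-based class index; theta packs [W (p x K), b (K)]
static double softmax_loss_grad(const mat& X, const uvec& y, int K,
                                double lambda, const vec& theta,
                                vec& grad) {
  const int n = X.n_rows, p = X.n_cols;
  mat W(const_cast<double*>(theta.memptr()), p, K, false, true);
  rowvec b(const_cast<double*>(theta.memptr()) + p * K, K, false, true);

  mat eta = X * W;
  eta.each_row() += b;
  vec m = max(eta, 1);
  eta.each_col() -= m;
  mat P = exp(eta);
  vec Z = sum(P, 1);
  P.each_col() /= Z;

  double loss = 0.0;
  for (int i = 0; i < n; ++i) loss -= eta(i, y(i)) - std::log(Z(i));
  loss /= n;
  loss += lambda * accu(W % W);

  mat R = P;                                  // P - Y
  for (int i = 0; i < n; ++i) R(i, y(i)) -= 1.0;
  mat gW = X.t() * R / n + 2.0 * lambda * W;
  rowvec gb = sum(R, 0) / n;

  grad.set_size(p * K + K);
  std::copy(gW.begin(), gW.end(), grad.begin());
  std::copy(gb.begin(), gb.end(), grad.begin() + p * K);
  return loss;
}

// ---------- Efron pseudolikelihood -------------------------------------------

// Negative mean Efron log partial likelihood and its gradient at beta.
// Xt is the transposed design (p x n) with columns pre-sorted by DESCENDING
// time; ties in event times are Efron-weighted.
static double efron_neglik_grad_sorted(const mat& Xt, const vec& time,
                                       const vec& event, const vec& beta,
                                       vec& grad, bool want_grad) {
  const int n = Xt.n_cols, p = Xt.n_rows;
  vec eta = Xt.t() * beta;
  double emax = eta.max();          // guard exp overflow; cancels in ratios
  vec w = exp(eta - emax);

  double ll = 0.0;
  double S_R = 0.0;                 // running risk-set sum of w
  vec G_R(p, fill::zeros);          // running risk-set sum of w * x
  if (want_grad) grad.zeros(p);

  int i = 0;
  while (i < n) {
    double t = time(i);
    int j = i;
    double S_D = 0.0, eta_D = 0.0;
    vec G_D, x_D;
    if (want_grad) { G_D.zeros(p); x_D.zeros(p); }
    int d = 0;
    while (j < n && time(j) == t) {
      S_R += w(j);
      if (want_grad) G_R += w(j) * Xt.col(j);
      if (event(j) > 0.5) {
        ++d;
        S_D += w(j);
        eta_D += eta(j);
        if (want_grad) {
          G_D += w(j) * Xt.col(j);
          x_D += Xt.col(j);
        }
      }
      ++j;
    }
    if (d > 0) {
      ll += eta_D;
      for (int l = 0; l < d; ++l) {
        double frac = double(l) / d;
        double denom = S_R - frac * S_D;
        ll -= std::log(denom) + emax;
        if (want_grad) grad += (G_R - frac * G_D) / denom;
      }
      if (want_grad) grad -= x_D;
    }
    i = j;
  }
  if (want_grad) grad /= n;
  return -ll / n;
}

// ---------- accelerated descent with backtracking ----------------------------

template <typename F>
static Rcpp::List fista(F obj, vec theta, int maxit, double tol,
                        double step0) {
  vec grad, grad_y;
  double step = step0;
  vec x_prev = theta, y = theta;
  double tk = 1.0;
  std::vector<double> trace;
  double f_x = obj(theta, grad, true);
  trace.push_back(f_x);
  int it = 0;
  for (; it < maxit; ++it) {
    double f_y = obj(y, grad_y, true);
    if (norm(grad_y, "inf") < tol) { theta = y; f_x = f_y; break; }
    // backtracking on the majorizer at y
    vec x_new;
    for (int ls = 0; ls < 60; ++ls) {
      x_new = y - step * grad_y;
      vec dummy;
      double f_new = obj(x_new, dummy, false);
      if (std::isfinite(f_new) &&
          f_new <= f_y - 0.5 * step * dot(grad_y, grad_y)) {
        f_x = f_new;
        break;
      }
      step *= 0.5;
    }
    double t_next = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    vec y_next = x_new + ((tk - 1.0) / t_next) * (x_new - x_prev);
    // adaptive restart: drop momentum when objective rises
    if (f_x > trace.back()) { y_next = x_new; t_next = 1.0; }
    x_prev = x_new;
    theta = x_new;
    y = y_next;
    tk = t_next;
    step *= 1.25;                   // allow step to grow back
    trace.push_back(f_x);
  }
  if (!theta.is_finite())
    Rcpp::stop("optimizer diverged (non-finite parameters)");
  return Rcpp::List::create(
      Rcpp::Named("theta") = theta,
      Rcpp::Named("loss") = f_x,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = it);
}

// [[Rcpp::export]]
Rcpp::List cpp_logistic_fit(const arma::mat& X, const arma::uvec& y, int K,
                            double lambda, int maxit, double tol) {
  const int p = X.n_cols;
  vec theta(p * K + K, fill::zeros);
  auto obj = [&](const vec& th, vec& g, bool wg) {
    if (!wg) { vec gg; return softmax_loss_grad(X, y, K, lambda, th, gg); }
    return softmax_loss_grad(X, y, K, lambda, th, g);
  };
  return fista(obj, theta, maxit, tol, 1.0);
}

// [[Rcpp::export]]
Rcpp::List cpp_efron_neglik(const arma::mat& X, const arma::vec& time,
                            const arma::vec& event, const arma::vec& beta) {
  uvec ord = stable_sort_index(time, "descend");
  mat Xt = X.rows(ord).t();
  vec ts = time(ord), ev = event(ord);
  vec grad;
  double v = efron_neglik_grad_sorted(Xt, ts, ev, beta, grad, true);
  return Rcpp::List::create(Rcpp::Named("value") = v,
                            Rcpp::Named("gradient") = grad);
}

// [[Rcpp::export]]
Rcpp::List cpp_cox_fit(const arma::mat& X, const arma::vec& time,
                       const arma::vec& event, double lambda, int maxit,
                       double tol) {
  uvec ord = stable_sort_index(time, "descend");
  mat Xt = X.rows(ord).t();
  vec ts = time(ord), ev = event(ord);
  vec beta(X.n_cols, fill::zeros);
  auto obj = [&](const vec& th, vec& g, bool wg) {
    double v = efron_neglik_grad_sorted(Xt, ts, ev, th, g, wg);
    if (wg) g += 2.0 * lambda * th;
    return v + lambda * dot(th, th);
  };
  return fista(obj, beta, maxit, tol, 1.0);
}
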