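// Fast evaluation of the trial-2 prediction errors that drive prior
// fitting. For each transformed batch the observer updates its Gaussian
// belief with the first trial's evidence and predicts the second-trial
// hand via the inverse MAP transformation; the robust cost saturates each
// Euclidean error at c. Model codes: 1 standard, 2 shift, 3 rotscale,
// 4 affine, 5 none.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double BIG_ERR = 1e6;  // sentinel for undefined predictions

static double wrap_angle(double x) {
  // reduce to (-pi, pi] without fmod
  double y = x - 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI));
  return (y > M_PI) ? y - 2.0 * M_PI : y;
}

// data columns: h1x h1y v1x v1y t2x t2y h2x h2y
static vec trial2_errors(const mat& Lambda, int model, const mat& data,
                         double sigma2, double angular_var,
                         double radial_var) {
  const uword n = data.n_rows;
  vec err(n);
  for (uword i = 0; i < n; ++i) {
    const double h1x = data(i, 0), h1y = data(i, 1);
    const double v1x = data(i, 2), v1y = data(i, 3);
    const double t2x = data(i, 4), t2y = data(i, 5);
    double px, py;
    bool ok = true;
    if (model == 5) {            // no adaptation: aim at the target
      px = t2x; py = t2y;
    } else if (model == 1) {     // standard linear
      mat L1 = Lambda;
      const double hh11 = h1x * h1x / sigma2, hh12 = h1x * h1y / sigma2,
                   hh22 = h1y * h1y / sigma2;
      L1(0, 0) += hh11; L1(0, 1) += hh12; L1(1, 0) += hh12; L1(1, 1) += hh22;
      L1(2, 2) += hh11; L1(2, 3) += hh12; L1(3, 2) += hh12; L1(3, 3) += hh22;
      vec mu0 = {1, 0, 0, 1};
      vec rhs = Lambda * mu0;
      rhs(0) += v1x * h1x / sigma2; rhs(1) += v1x * h1y / sigma2;
      rhs(2) += v1y * h1x / sigma2; rhs(3) += v1y * h1y / sigma2;
      vec mu;
      ok = solve(mu, L1, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
      if (ok) {
        const double det = mu(0) * mu(3) - mu(1) * mu(2);
        if (std::abs(det) <= 1e-10) ok = false;
        else {
          px = ( mu(3) * t2x - mu(1) * t2y) / det;
          py = (-mu(2) * t2x + mu(0) * t2y) / det;
        }
      }
    } else if (model == 2) {     // shift
      mat L1 = Lambda;
      L1(0, 0) += 1.0 / sigma2; L1(1, 1) += 1.0 / sigma2;
      vec rhs = {(v1x - h1x) / sigma2, (v1y - h1y) / sigma2};
      vec mu;
      ok = solve(mu, L1, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
      if (ok) { px = t2x - mu(0); py = t2y - mu(1); }
    } else if (model == 3) {     // rotation and uniform scaling
      const double r_h = std::sqrt(h1x * h1x + h1y * h1y);
      if (r_h <= 0.5) ok = false;
      else {
        const double th_h = std::atan2(h1y, h1x);
        const double th_v = std::atan2(v1y, v1x);
        const double r_v = std::sqrt(v1x * v1x + v1y * v1y);
        mat L1 = Lambda;
        L1(0, 0) += 1.0 / angular_var;
        L1(1, 1) += r_h * r_h / radial_var;
        vec mu0 = {0, 1};
        vec rhs = Lambda * mu0;
        rhs(0) += wrap_angle(th_v - th_h) / angular_var;
        rhs(1) += r_h * r_v / radial_var;
        vec mu;
        ok = solve(mu, L1, rhs,
                   solve_opts::likely_sympd + solve_opts::no_approx);
        if (ok) {
          const double g = mu(1);
          if (g <= 0.05) ok = false;
          else {
            const double r_t = std::sqrt(t2x * t2x + t2y * t2y) / g;
            const double th_t = std::atan2(t2y, t2x) - mu(0);
            px = r_t * std::cos(th_t); py = r_t * std::sin(th_t);
          }
        }
      }
    } else {                     // affine
      mat L1 = Lambda;
      const double hh11 = h1x * h1x / sigma2, hh12 = h1x * h1y / sigma2,
                   hh22 = h1y * h1y / sigma2;
      L1(0, 0) += hh11; L1(0, 1) += hh12; L1(1, 0) += hh12; L1(1, 1) += hh22;
      L1(2, 2) += hh11; L1(2, 3) += hh12; L1(3, 2) += hh12; L1(3, 3) += hh22;
      L1(0, 4) += h1x / sigma2; L1(4, 0) += h1x / sigma2;
      L1(1, 4) += h1y / sigma2; L1(4, 1) += h1y / sigma2;
      L1(2, 5) += h1x / sigma2; L1(5, 2) += h1x / sigma2;
      L1(3, 5) += h1y / sigma2; L1(5, 3) += h1y / sigma2;
      L1(4, 4) += 1.0 / sigma2; L1(5, 5) += 1.0 / sigma2;
      vec mu0 = {1, 0, 0, 1, 0, 0};
      vec rhs = Lambda * mu0;
      rhs(0) += v1x * h1x / sigma2; rhs(1) += v1x * h1y / sigma2;
      rhs(2) += v1y * h1x / sigma2; rhs(3) += v1y * h1y / sigma2;
      rhs(4) += v1x / sigma2; rhs(5) += v1y / sigma2;
      vec mu;
      ok = solve(mu, L1, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
      if (ok) {
        const double det = mu(0) * mu(3) - mu(1) * mu(2);
        if (std::abs(det) <= 1e-10) ok = false;
        else {
          const double ux = t2x - mu(4), uy = t2y - mu(5);
          px = ( mu(3) * ux - mu(1) * uy) / det;
          py = (-mu(2) * ux + mu(0) * uy) / det;
        }
      }
    }
    if (!ok) { err(i) = BIG_ERR; continue; }
    const double dx = px - data(i, 6), dy = py - data(i, 7);
    err(i) = std::sqrt(dx * dx + dy * dy);
  }
  return err;
}

// par holds the free elements of the upper-triangular factor(s) U in
// column-major upper-triangle order; Lambda = U'U + eps I. The affine
// model has a block-diagonal precision (4x4 linear block, 2x2 shift block).
static mat par_to_precision(const vec& par, int model, double eps) {
  int k = (model == 1) ? 4 : (model == 4) ? 6 : 2;
  mat Lambda(k, k, fill::zeros);
  if (model == 4) {
    mat U4(4, 4, fill::zeros), U2(2, 2, fill::zeros);
    uword p = 0;
    for (int j = 0; j < 4; ++j)
      for (int i = 0; i <= j; ++i) U4(i, j) = par(p++);
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i <= j; ++i) U2(i, j) = par(p++);
    Lambda.submat(0, 0, 3, 3) = U4.t() * U4;
    Lambda.submat(4, 4, 5, 5) = U2.t() * U2;
  } else {
    mat U(k, k, fill::zeros);
    uword p = 0;
    for (int j = 0; j < k; ++j)
      for (int i = 0; i <= j; ++i) U(i, j) = par(p++);
    Lambda = U.t() * U;
  }
  Lambda.diag() += eps;
  return Lambda;
}

// [[Rcpp::export(name = ".vm_trial2_errors_prec")]]
arma::vec vm_trial2_errors_prec(const arma::mat& Lambda, int model,
                                const arma::mat& data, double sigma2,
                                double angular_var, double radial_var) {
  return trial2_errors(Lambda, model, data, sigma2, angular_var, radial_var);
}

// [[Rcpp::export(name = ".vm_trial2_cost_par")]]
double vm_trial2_cost_par(const arma::vec& par, int model,
                          const arma::mat& data, double sigma2,
                          double angular_var, double radial_var,
                          double cost_c, double eps) {
  if (model == 5) {
    vec e = trial2_errors(mat(0, 0), 5, data, sigma2, angular_var,
                          radial_var);
    return accu(min(e, vec(e.n_elem, fill::value(cost_c))));
  }
  mat Lambda = par_to_precision(par, model, eps);
  vec e = trial2_errors(Lambda, model, data, sigma2, angular_var,
                        radial_var);
  return accu(min(e, vec(e.n_elem, fill::value(cost_c))));
}

// forward-difference gradient of the cost, evaluated entirely in
// compiled code (npar + 1 cost evaluations per call)
// [[Rcpp::export(name = ".vm_trial2_cost_grad_par")]]
arma::vec vm_trial2_cost_grad_par(const arma::vec& par, int model,
                                  const arma::mat& data, double sigma2,
                                  double angular_var, double radial_var,
                                  double cost_c, double eps) {
  const double f0 = vm_trial2_cost_par(par, model, data, sigma2,
                                       angular_var, radial_var, cost_c,
                                       eps);
  vec g(par.n_elem);
  for (uword j = 0; j < par.n_elem; ++j) {
    vec p = par;
    const double h = 1e-7 * std::max(1.0, std::abs(p(j)));
    p(j) += h;
    const double fj = vm_trial2_cost_par(p, model, data, sigma2,
                                         angular_var, radial_var, cost_c,
                                         eps);
    g(j) = (fj - f0) / h;
  }
  return g;
}
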