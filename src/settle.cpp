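#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forward-Euler relaxation of the continuous attractor dynamics
//   tau du_i/dt = -u_i + 0.5 * (1 + tanh(sum_j w_ij u_j + I_i))
// Convergence is declared when the largest component of du/dt (in units of
// 1/tau) falls below `tol`. Returns the trajectory endpoint together with
// the number of Euler steps taken and a convergence flag; the caller decides
// how to signal non-convergence.
// [[Rcpp::export]]
List settle_euler(const arma::vec& u0, const arma::mat& W, const arma::vec& I,
                  double tau, double dt, double tol, int max_steps) {
  arma::vec u = u0;
  const double step = dt / tau;
  bool converged = false;
  int steps = 0;

  for (steps = 0; steps < max_steps; ++steps) {
    arma::vec drive = W * u + I;
    arma::vec dudt = -u + 0.5 * (1.0 + arma::tanh(drive));
    if (!dudt.is_finite()) {
      stop("non-finite activity encountered while settling");
    }
    double resid = arma::abs(dudt).max();
    if (resid < tol) {
      converged = true;
      break;
    }
    u += step * dudt;
  }

  return List::create(_["u"] = u,
                      _["converged"] = converged,
                      _["steps"] = steps);
}
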