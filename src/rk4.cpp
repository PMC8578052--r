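// Fixed-step RK4 integration of the linear kinetic system dI/dt = A I and the
// adjoint (reverse-mode) gradient of the penalized least-squares data misfit
// with respect to the entries of A.
//
// For a constant A the classic four-stage RK4 update is exactly the linear map
//   y_{n+1} = Phi y_n,  Phi = I + hA + (hA)^2/2 + (hA)^3/6 + (hA)^4/24,
// so the cost/gradient kernel propagates Phi once per step and the adjoint
// chains through Phi and then through Phi's polynomial dependence on A.
// This differentiates the discretization itself, not the continuous ODE.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat phi_matrix(const arma::mat& A, double h) {
  const arma::uword n = A.n_rows;
  arma::mat hA = h * A;
  arma::mat phi = arma::eye(n, n) + hA;
  arma::mat term = hA;
  for (int p = 2; p <= 4; ++p) {
    term = (term * hA) / static_cast<double>(p);
    phi += term;
  }
  return phi;
}

// Classic stage-wise RK4; returns the full trajectory, one column per node
// (column 0 is the initial state).
// [[Rcpp::export(name = ".rk4ForwardCpp")]]
arma::mat rk4_forward_cpp(const arma::mat& A, const arma::vec& y0,
                          double h, int nsteps) {
  const arma::uword n = y0.n_elem;
  arma::mat Y(n, nsteps + 1);
  Y.col(0) = y0;
  arma::vec y = y0, k1(n), k2(n), k3(n), k4(n);
  for (int s = 0; s < nsteps; ++s) {
    k1 = A * y;
    k2 = A * (y + (h / 2.0) * k1);
    k3 = A * (y + (h / 2.0) * k2);
    k4 = A * (y + h * k3);
    y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    Y.col(s + 1) = y;
  }
  return Y;
}

// One-step transition-matrix form of the same recursion (used by the fitting
// kernel; pinned against rk4_forward_cpp in the test suite).
// [[Rcpp::export(name = ".phiForwardCpp")]]
arma::mat phi_forward_cpp(const arma::mat& A, const arma::vec& y0,
                          double h, int nsteps) {
  arma::mat phi = phi_matrix(A, h);
  arma::mat Y(y0.n_elem, nsteps + 1);
  Y.col(0) = y0;
  for (int s = 0; s < nsteps; ++s) Y.col(s + 1) = phi * Y.col(s);
  return Y;
}

// Sum-squared error between the mixed prediction and the measurements, and
// (optionally) its gradient with respect to every entry of A.
//
// lo_idx: 0-based node index at or below each sampling time; wfrac: linear
// interpolation weight toward node lo_idx + 1 (0 when the time is on-grid).
// M is the measured-channel mixing operator (channels x states); meas is
// channels x n_samples.
// [[Rcpp::export(name = ".costGradCpp")]]
List cost_grad_cpp(const arma::mat& A, const arma::vec& y0, double h,
                   int nsteps, const arma::mat& M, const arma::mat& meas,
                   const arma::ivec& lo_idx, const arma::vec& wfrac,
                   bool want_grad) {
  const arma::uword n = y0.n_elem;
  const arma::uword nt = lo_idx.n_elem;
  arma::mat phi = phi_matrix(A, h);
  arma::mat Y(n, nsteps + 1);
  Y.col(0) = y0;
  for (int s = 0; s < nsteps; ++s) Y.col(s + 1) = phi * Y.col(s);
  if (!Y.is_finite())
    stop("non-finite state encountered during integration");

  double sse = 0.0;
  // per-node adjoint seeds dJ/dy_n from the sampled residuals
  arma::mat C;
  if (want_grad) C.zeros(n, nsteps + 1);
  for (arma::uword j = 0; j < nt; ++j) {
    const int i = lo_idx[j];
    const double w = wfrac[j];
    arma::vec ys = (w > 0.0) ? arma::vec((1.0 - w) * Y.col(i) + w * Y.col(i + 1))
                             : arma::vec(Y.col(i));
    arma::vec r = M * ys - meas.col(j);
    sse += arma::dot(r, r);
    if (want_grad) {
      arma::vec g = 2.0 * (M.t() * r);
      C.col(i) += (1.0 - w) * g;
      if (w > 0.0) C.col(i + 1) += w * g;
    }
  }

  if (!want_grad)
    return List::create(_["sse"] = sse);

  // reverse sweep: lambda_n = dJ/dy_n; Phi_bar accumulates dJ/dPhi
  arma::mat phiT = phi.t();
  arma::vec lambda = C.col(nsteps);
  arma::mat phi_bar(n, n, arma::fill::zeros);
  for (int s = nsteps; s >= 1; --s) {
    phi_bar += lambda * Y.col(s - 1).t();
    lambda = phiT * lambda;
    if (s >= 2) lambda += C.col(s - 1);
  }

  // chain through Phi = sum_p c_p A^p:  A_bar = sum_p c_p sum_q B^q Phi_bar B^{p-1-q}
  // with B = A^T and c_p = h^p / p!
  arma::mat B = A.t();
  arma::mat B2 = B * B;
  arma::mat B3 = B2 * B;
  const double c1 = h, c2 = h * h / 2.0, c3 = h * h * h / 6.0,
               c4 = h * h * h * h / 24.0;
  arma::mat A_bar = c1 * phi_bar;
  A_bar += c2 * (phi_bar * B + B * phi_bar);
  A_bar += c3 * (phi_bar * B2 + B * phi_bar * B + B2 * phi_bar);
  A_bar += c4 * (phi_bar * B3 + B * phi_bar * B2 + B2 * phi_bar * B +
                 B3 * phi_bar);

  return List::create(_["sse"] = sse, _["gradA"] = A_bar);
}
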