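// Pseudospectral core for 2D active nematodynamics on a periodic grid.
//
// State is the traceless-symmetric alignment tensor Q = [[q1, q2], [q2, -q1]]
// advanced by an exponential-time-differencing (ETD2, Cox--Matthews) scheme;
// the overdamped Stokes flow with substrate friction is solved spectrally at
// every step.  First derivatives use Nyquist-zeroed wavenumbers (dkx, dky) so
// that spectral divergences vanish identically; the Laplacian uses the full
// |k|^2.  All heavy lifting is element-wise on arma matrices with FFTW-backed
// fft2/ifft2.

#define ARMA_USE_FFTW3
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat irfft2(const cx_mat& ah) { return real(ifft2(ah)); }

struct FlowWork {
  mat u1, u2, om, press;
  cx_mat u1h, u2h;
};

// Assemble the total stress divergence from (q1h, q2h) and the activity
// field (already in internal stress units), project onto divergence-free
// modes, and return velocity, vorticity and zero-mean pressure.
static FlowWork flow_solve_internal(const cx_mat& q1h, const cx_mat& q2h,
                                    const mat& alpha,
                                    const mat& dkx, const mat& dky,
                                    const mat& k2,
                                    double a2, double a4, double K,
                                    double lambda, double Gamma, double eta) {
  const cx_double I(0.0, 1.0);
  mat q1 = irfft2(q1h), q2 = irfft2(q2h);
  mat dq1x = irfft2(I * dkx % q1h), dq1y = irfft2(I * dky % q1h);
  mat dq2x = irfft2(I * dkx % q2h), dq2y = irfft2(I * dky % q2h);
  mat lap1 = irfft2(-k2 % q1h), lap2 = irfft2(-k2 % q2h);

  mat trq2 = 2.0 * (q1 % q1 + q2 % q2);
  mat h1 = (a2 - a4 * trq2) % q1 + K * lap1;
  mat h2 = (a2 - a4 * trq2) % q2 + K * lap2;

  mat qh = 2.0 * (q1 % h1 + q2 % h2);           // Q:H
  mat anti = 2.0 * (q1 % h2 - q2 % h1);         // (QH - HQ)_xy
  mat sxx = -2.0 * K * (dq1x % dq1x + dq2x % dq2x) + 2.0 * lambda * qh % q1 -
            lambda * h1 + alpha % q1;
  mat syy = -2.0 * K * (dq1y % dq1y + dq2y % dq2y) - 2.0 * lambda * qh % q1 +
            lambda * h1 - alpha % q1;
  mat sym_xy = 2.0 * lambda * qh % q2 - lambda * h2 + alpha % q2 -
               2.0 * K * (dq1x % dq1y + dq2x % dq2y);
  mat sxy = sym_xy + anti;
  mat syx = sym_xy - anti;

  // F_j = d_i sigma_ij
  cx_mat fxh = I * (dkx % fft2(sxx) + dky % fft2(syx));
  cx_mat fyh = I * (dkx % fft2(sxy) + dky % fft2(syy));

  mat dk2 = dkx % dkx + dky % dky;
  // dk2 vanishes at the zero mode and on Nyquist lines, where F vanishes in
  // this derivative convention; guard the division (0/0 -> 0)
  mat dk2s = dk2;
  dk2s.elem(find(dk2s == 0.0)).ones();
  cx_mat kf = (dkx % fxh + dky % fyh) / dk2s;
  kf.elem(find(dk2 == 0.0)).zeros();
  mat den = Gamma + eta * k2;
  FlowWork w;
  w.u1h = (fxh - dkx % kf) / den;
  w.u2h = (fyh - dky % kf) / den;
  w.u1 = irfft2(w.u1h);
  w.u2 = irfft2(w.u2h);
  w.om = irfft2(I * (dkx % w.u2h - dky % w.u1h));
  cx_mat ph = -I * kf;  // laplacian(P) = div F  =>  P_hat = -i (k.F)/k^2
  ph(0, 0) = cx_double(0.0, 0.0);
  w.press = irfft2(ph);
  return w;
}

// [[Rcpp::export]]
Rcpp::List nd_solve_flow_cpp(const arma::cx_mat& q1h, const arma::cx_mat& q2h,
                             const arma::mat& alpha, const arma::mat& dkx,
                             const arma::mat& dky, const arma::mat& k2,
                             double a2, double a4, double K, double lambda,
                             double Gamma, double eta) {
  FlowWork w = flow_solve_internal(q1h, q2h, alpha, dkx, dky, k2, a2, a4, K,
                                   lambda, Gamma, eta);
  return Rcpp::List::create(
      Rcpp::Named("ux") = w.u1, Rcpp::Named("uy") = w.u2,
      Rcpp::Named("omega") = w.om, Rcpp::Named("pressure") = w.press);
}

// One ETD2 step.  e1 = exp(L dt); (f1, f2) the Cox--Matthews weights for the
// current and previous nonlinear terms (precomputed in R, with series
// expansions near L = 0).  When `first` is true an ETD1 step is taken with
// weight f0 = (exp(L dt) - 1)/L.
// [[Rcpp::export]]
Rcpp::List nd_step_cpp(const arma::cx_mat& q1h, const arma::cx_mat& q2h,
                       const arma::cx_mat& n1h_prev, const arma::cx_mat& n2h_prev,
                       const arma::mat& alpha, const arma::mat& dkx,
                       const arma::mat& dky, const arma::mat& k2,
                       const arma::mat& e1, const arma::mat& f0,
                       const arma::mat& f1, const arma::mat& f2,
                       const arma::mat& dealias, bool first, double a2,
                       double a4, double K, double lambda, double Gamma,
                       double eta, double gamma_rot) {
  const cx_double I(0.0, 1.0);
  FlowWork w = flow_solve_internal(q1h, q2h, alpha, dkx, dky, k2, a2, a4, K,
                                   lambda, Gamma, eta);
  mat q1 = irfft2(q1h), q2 = irfft2(q2h);
  mat dq1x = irfft2(I * dkx % q1h), dq1y = irfft2(I * dky % q1h);
  mat dq2x = irfft2(I * dkx % q2h), dq2y = irfft2(I * dky % q2h);

  mat du1x = irfft2(I * dkx % w.u1h);
  mat du1y = irfft2(I * dky % w.u1h);
  mat du2x = irfft2(I * dkx % w.u2h);
  // incompressibility: du2y = -du1x exactly in this derivative convention
  mat ee1 = du1x;
  mat ee2 = 0.5 * (du1y + du2x);
  mat om = du2x - du1y;

  mat trq2 = 2.0 * (q1 % q1 + q2 % q2);
  mat qe = 2.0 * (q1 % ee1 + q2 % ee2);
  // the full local Landau term is explicit; the exponentiated linear part
  // is the (contractive) spectral diffusion only
  mat n1 = -(w.u1 % dq1x + w.u2 % dq1y) - om % q2 -
           2.0 * lambda * qe % q1 + lambda * ee1 +
           ((a2 - a4 * trq2) % q1) / gamma_rot;
  mat n2 = -(w.u1 % dq2x + w.u2 % dq2y) + om % q1 -
           2.0 * lambda * qe % q2 + lambda * ee2 +
           ((a2 - a4 * trq2) % q2) / gamma_rot;

  cx_mat n1h = fft2(n1) % dealias;
  cx_mat n2h = fft2(n2) % dealias;

  cx_mat q1h_new, q2h_new;
  if (first) {
    q1h_new = e1 % q1h + f0 % n1h;
    q2h_new = e1 % q2h + f0 % n2h;
  } else {
    q1h_new = e1 % q1h + f1 % n1h + f2 % n1h_prev;
    q2h_new = e1 % q2h + f1 % n2h + f2 % n2h_prev;
  }

  mat q1n = irfft2(q1h_new), q2n = irfft2(q2h_new);
  double maxq = std::sqrt((q1n % q1n + q2n % q2n).max());
  double maxu = std::sqrt((w.u1 % w.u1 + w.u2 % w.u2).max());

  return Rcpp::List::create(
      Rcpp::Named("q1h") = q1h_new, Rcpp::Named("q2h") = q2h_new,
      Rcpp::Named("n1h") = n1h, Rcpp::Named("n2h") = n2h,
      Rcpp::Named("q1") = q1n, Rcpp::Named("q2") = q2n,
      Rcpp::Named("max_q") = maxq, Rcpp::Named("max_u") = maxu);
}
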