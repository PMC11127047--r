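#' Calibrate the 1D defect-hydrodynamics coefficients
#'
#' Fits the coarse-grained model to measured defect profiles from a
#' full 2D strip simulation (the shallow-interface case), mirroring the
#' workflow in which constants are pre-fit on one profile family and then
#' used without further fitting to predict others:
#' \itemize{
#'   \item `c_n` by regressing the measured density n(x) on |alpha(x)|
#'     through the origin;
#'   \item `zeta1` from the single-defect response calibration
#'     ([calibrate_response()]), `zeta2 = zeta2_2d / 4` (the 1/4 converts
#'     the complex-derivative normalization to the plain second
#'     x-derivative used in 1D) and `zeta3` directly;
#'   \item the mobilities `mu_R`, `mu` (and `tau_R` unless supplied, e.g.
#'     from the defect-diffusion estimate) by box-bounded least squares of
#'     the model-predicted p(x), T3(x) and rho(x) against the measured
#'     profiles.
#' }
#'
#' @param profiles Tibble from [strip_profiles()] (columns x, n, rho, p,
#'   T3).
#' @param alpha_fn Function x -> alpha for the strip the profiles came from.
#' @param response A [calibrate_response()] result (or a list with zeta1,
#'   zeta2, zeta3).
#' @param tau_R Reorientation time; `NULL` (default) fits it, otherwise it
#'   is held at the supplied (independently measured) value.
#' @param bounds Named list of box bounds for the fitted parameters.
#' @return A [hydro_params()] object with attribute `fit` (the optim result
#'   and the fitted profile table).
#' @export
calibrate_hydro <- function(profiles, alpha_fn, response, tau_R = NULL,
                            bounds = list(tau_R = c(0.5, 30),
                                          mu_R = c(0.05, 5),
                                          mu = c(0.05, 20))) {
  x <- profiles$x
  a <- alpha_fn(x)
  cn_fit <- stats::lm(profiles$n ~ 0 + abs(a))
  c_n <- max(stats::coef(cn_fit)[[1]], 1e-8)
  z1 <- response$zeta1
  z2 <- response$zeta2 / 4
  z3 <- response$zeta3
  scale_p <- max(abs(profiles$p), 1e-12)
  scale_t <- max(abs(profiles$T3), 1e-12)
  scale_r <- max(abs(profiles$rho), 1e-12)
  fit_tau <- is.null(tau_R)
  mk <- function(par) {
    hydro_params(tau_R = if (fit_tau) par[["tau_R"]] else tau_R,
                 mu_R = par[["mu_R"]], mu = par[["mu"]], c_n = c_n,
                 zeta1 = z1, zeta2 = z2, zeta3 = z3)
  }
  obj <- function(parv) {
    par <- as.list(parv)
    hp <- mk(par)
    prof <- suppressWarnings(steady_state_solve(a, x, hp))
    sum(((prof$p - profiles$p) / scale_p)^2) +
      sum(((prof$T3 - profiles$T3) / scale_t)^2) +
      sum(((prof$rho - profiles$rho) / scale_r)^2)
  }
  par0 <- c(mu_R = 1, mu = 1)
  lo <- c(bounds$mu_R[1], bounds$mu[1])
  hi <- c(bounds$mu_R[2], bounds$mu[2])
  if (fit_tau) {
    par0 <- c(tau_R = 5, par0)
    lo <- c(bounds$tau_R[1], lo); hi <- c(bounds$tau_R[2], hi)
  }
  fit <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lo,
                      upper = hi, control = list(maxit = 300))
  hp <- mk(as.list(fit$par))
  attr(hp, "fit") <- list(optim = fit,
                          fitted = suppressWarnings(
                            steady_state_solve(a, x, hp)))
  hp
}
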