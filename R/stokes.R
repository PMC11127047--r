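#' Solve the screened Stokes problem for the instantaneous flow
#'
#' Force balance \eqn{-\Gamma u + \eta \nabla^2 u - \nabla \Pi +
#' \nabla\cdot(\sigma^a + \sigma^{el}) = 0} with \eqn{\nabla \cdot u = 0} on
#' the periodic grid.  In Fourier space
#' \eqn{(\Gamma + \eta k^2)\hat u = P_\perp(k)\hat F} with
#' \eqn{F = \nabla\cdot(\sigma^a + \sigma^{el})} and \eqn{P_\perp} the
#' transverse projector; this is equivalent to eliminating the pressure via
#' the Poisson equation \eqn{\nabla^2 \Pi = \partial_i\partial_j \sigma_{ij}}.
#' The zero mode of the force vanishes identically by periodicity, so the
#' mean flow is zero; the pressure is returned in the zero-mean gauge.
#'
#' @param q A [nematic_field()].
#' @param alpha Activity (dimensionless, units of \eqn{K\Gamma/\gamma}):
#'   matrix or scalar.
#' @param params A [model_params()].
#' @param engine `"cpp"` (default, FFTW-backed) or `"r"` (reference
#'   implementation composed from the exported field operations).
#' @return A [flow_field()] with velocity, vorticity and zero-mean pressure.
#' @export
solve_flow <- function(q, alpha, params, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  g <- q$grid
  if (params$Gamma <= 0 && params$eta <= 0)
    stop("Gamma = 0 with eta = 0: singular Stokes operator")
  if (length(alpha) == 1) alpha <- matrix(alpha, g$nx, g$ny)
  stopifnot(all(dim(alpha) == c(g$nx, g$ny)))
  check_finite(alpha, "alpha")
  if (engine == "cpp") {
    res <- nd_solve_flow_cpp(spec_fft(q$qxx), spec_fft(q$qxy),
                             alpha * params$stress_unit,
                             g$DKX, g$DKY, g$K2,
                             params$a2, params$a4, params$elastic_K,
                             params$lambda, params$Gamma, params$eta)
    return(flow_field(res$ux, res$uy, g, omega = res$omega,
                      pressure = res$pressure))
  }
  H <- molecular_field(q, params)
  sel <- elastic_stress(q, H, params)
  sa <- active_stress(q, alpha, params)
  stot <- stress_field(sel$sxx + sa$sxx, sel$sxy + sa$sxy,
                       sel$syx + sa$syx, sel$syy + sa$syy, g)
  f <- stress_divergence(stot)
  fxh <- spec_fft(f$fx); fyh <- spec_fft(f$fy)
  dk2 <- g$DKX^2 + g$DKY^2
  dk2s <- dk2; dk2s[dk2 == 0] <- 1   # zero mode and Nyquist lines: F = 0 there
  kf <- (g$DKX * fxh + g$DKY * fyh) / dk2s
  kf[dk2 == 0] <- 0
  den <- params$Gamma + params$eta * g$K2
  uxh <- (fxh - g$DKX * kf) / den
  uyh <- (fyh - g$DKY * kf) / den
  ph <- -1i * kf
  flow_field(spec_ifft(uxh), spec_ifft(uyh), g,
             omega = spec_ifft(1i * (g$DKX * uyh - g$DKY * uxh)),
             pressure = spec_ifft(ph))
}
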