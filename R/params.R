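#' Model parameters for active nematodynamics
#'
#' Collects the material constants of the Q-tensor model in the standard
#' nondimensionalization: lengths in units of the nematic coherence length
#' \eqn{\xi = \sqrt{K/a_2}}, times in units of the nematic relaxation time
#' \eqn{\tau_n = \gamma/a_2}, and stresses (hence activity values) in units of
#' the passive elastic stress scale \eqn{K\Gamma/\gamma}.  With the defaults
#' `a2 = a4 = K = gamma_rot = 1` the first two units are exactly 1 and the
#' remaining knobs are the screening length `l_eta` \eqn{= \sqrt{\eta/\Gamma}},
#' the viscosity ratio `gamma_tilde` \eqn{= \gamma/\eta}, and the
#' flow-alignment parameter `lambda`.  Viscosity and friction are derived:
#' \eqn{\eta = \gamma/\tilde\gamma}, \eqn{\Gamma = \eta/\ell_\eta^2}.
#'
#' Activity fields handed to the solver are dimensionless multiples of the
#' stress unit \eqn{K\Gamma/\gamma}; the conversion happens internally.
#'
#' @param lambda Flow-alignment parameter (default 1.8, flow-aligning).
#' @param l_eta Hydrodynamic screening length \eqn{\ell_\eta} in units of
#'   \eqn{\xi} (default 5).
#' @param gamma_tilde Rotational-to-shear viscosity ratio
#'   \eqn{\tilde\gamma = \gamma/\eta} (default 0.1).
#' @param a2,a4 Landau coefficients of the bulk free energy (both positive;
#'   defaults `a2 = 1`, `a4 = a2` so the ordered state has
#'   \eqn{\mathrm{tr}[Q^2] = a_2/a_4}).
#' @param elastic_K Frank elastic constant \eqn{K} (default 1).
#' @param gamma_rot Rotational viscosity \eqn{\gamma} (default 1, so the time
#'   unit is \eqn{\tau_n = 1}).
#' @return An object of class `model_params`: a list with the supplied fields
#'   plus the derived `eta`, `Gamma`, `xi`, `tau_n`, `stress_unit`
#'   (\eqn{K\Gamma/\gamma}) and ground-state amplitude
#'   `q_amp0` \eqn{= \sqrt{a_2/(2a_4)}} (so \eqn{S_0 = 2\,q_{amp0}}).
#' @examples
#' p <- model_params()
#' p$stress_unit   # K Gamma / gamma
#' @export
model_params <- function(lambda = 1.8, l_eta = 5, gamma_tilde = 0.1,
                         a2 = 1, a4 = a2, elastic_K = 1, gamma_rot = 1) {
  stopifnot(a2 > 0, a4 > 0, elastic_K > 0, gamma_rot > 0,
            l_eta >= 0, gamma_tilde > 0)
  eta <- gamma_rot / gamma_tilde
  Gamma <- if (l_eta > 0) eta / l_eta^2 else stop(
    "l_eta = 0 gives infinite friction; use a small positive value")
  p <- list(
    lambda = lambda, l_eta = l_eta, gamma_tilde = gamma_tilde,
    a2 = a2, a4 = a4, elastic_K = elastic_K, gamma_rot = gamma_rot,
    eta = eta, Gamma = Gamma,
    xi = sqrt(elastic_K / a2), tau_n = gamma_rot / a2,
    stress_unit = elastic_K * Gamma / gamma_rot,
    q_amp0 = sqrt(a2 / (2 * a4))
  )
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  lambda = %g, l_eta = %g, gamma_tilde = %g\n",
              x$lambda, x$l_eta, x$gamma_tilde))
  cat(sprintf("  a2 = %g, a4 = %g, K = %g, gamma = %g\n",
              x$a2, x$a4, x$elastic_K, x$gamma_rot))
  cat(sprintf("  derived: eta = %g, Gamma = %g, xi = %g, tau_n = %g, stress unit = %g\n",
              x$eta, x$Gamma, x$xi, x$tau_n, x$stress_unit))
  invisible(x)
}

#' Solver configuration
#'
#' @param nx,ny Grid points in x and y (powers of two recommended).
#' @param dx Grid spacing in units of \eqn{\xi} (default 0.5).
#' @param dt Timestep in units of \eqn{\tau_n} (default 0.1).
#' @param n_steps Number of steps for [run_protocol()].
#' @param dealias Apply the 2/3-rule mask to the nonlinear term (default TRUE).
#' @param seed Integer seed controlling every random initial condition.
#' @param noise_amplitude Amplitude of the Gaussian Q perturbation used by
#'   random initial states, as a fraction of \eqn{\sqrt{a_2/a_4}}
#'   (default 0.01).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(nx = 256, ny = 256, dx = 0.5, dt = 0.1,
                          n_steps = 1000L, dealias = TRUE, seed = 1L,
                          noise_amplitude = 0.01) {
  stopifnot(nx >= 4, ny >= 4, dx > 0, dt > 0, n_steps >= 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dt = dt,
                 n_steps = as.integer(n_steps), dealias = isTRUE(dealias),
                 seed = as.integer(seed), noise_amplitude = noise_amplitude),
            class = "solver_config")
}

#' @export
print.solver_config <- function(x, ...) {
  cat(sprintf("<solver_config> %d x %d grid, dx = %g, dt = %g, %d steps, dealias = %s, seed = %d\n",
              x$nx, x$ny, x$dx, x$dt, x$n_steps, x$dealias, x$seed))
  invisible(x)
}
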