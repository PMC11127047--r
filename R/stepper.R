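#' @useDynLib actnem, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
NULL

# ETD weight matrices for the diagonal linear operator L = -K k^2 / gamma
# (the exact spectral diffusion; the local Landau term is integrated
# explicitly so that every exponentiated mode is contractive -- splitting
# the growing a2 part into L destabilizes slowly-evolving defect textures).
# e1 = exp(z), f0 = dt (e^z - 1)/z (first step, ETD1),
# f1 = dt ((1+z)e^z - 1 - 2z)/z^2, f2 = dt (-e^z + 1 + z)/z^2
# (Cox--Matthews second-order weights), with series near z = 0.
etd_coefs <- function(grid, params, dt) {
  L <- -params$elastic_K * grid$K2 / params$gamma_rot
  z <- L * dt
  small <- abs(z) < 1e-3
  ez <- exp(z)
  em1 <- expm1(z)
  f0 <- ifelse(small, 1 + z / 2 + z^2 / 6 + z^3 / 24, em1 / z) * dt
  f1 <- ifelse(small, 3 / 2 + 2 * z / 3 + 5 * z^2 / 24 + z^3 / 20,
               ((1 + z) * em1 - z) / z^2) * dt
  f2 <- ifelse(small, -1 / 2 - z / 6 - z^2 / 24 - z^3 / 120,
               (z - em1) / z^2) * dt
  list(e1 = ez, f0 = f0, f1 = f1, f2 = f2, dt = dt)
}

#' Simulation state
#'
#' Bundles the current time, the Q field, the last sampled activity field and
#' internal ETD history.  The flow field is a diagnostic re-solved from
#' `(q, alpha)` on demand by [state_flow()].
#'
#' @param q A [nematic_field()].
#' @param params A [model_params()].
#' @param pattern An [activity_pattern()] or `NULL` (no activity).
#' @param time Initial time (default 0).
#' @return An object of class `simulation_state`.
#' @export
init_state <- function(q, params, pattern = NULL, time = 0) {
  alpha <- sample_pattern(pattern, q$grid, time)
  structure(list(time = time, q = q, alpha = alpha, params = params,
                 nprev = NULL, etd = NULL, flow = NULL),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state> t = %g, grid %d x %d, max S = %.4g\n",
              x$time, x$q$grid$nx, x$q$grid$ny, max(order_S(x$q))))
  invisible(x)
}

#' Stokes flow of a simulation state
#'
#' @param state A [init_state()] result.
#' @return A [flow_field()], the Stokes solution for the state's current
#'   `(q, alpha)`.
#' @export
state_flow <- function(state) {
  if (is.null(state$flow))
    state$flow <- solve_flow(state$q, state$alpha, state$params)
  state$flow
}

#' Random near-isotropic or perturbed-nematic initial state
#'
#' A uniform nematic along x plus a seeded Gaussian perturbation of both Q
#' components with amplitude `cfg$noise_amplitude * sqrt(a2/a4)`; with
#' `base = "isotropic"` the uniform part is dropped.
#'
#' @param grid A [grid_spec()].
#' @param params A [model_params()].
#' @param cfg A [solver_config()] (supplies `seed` and `noise_amplitude`).
#' @param base `"nematic"` (default) or `"isotropic"`.
#' @return A [nematic_field()].
#' @export
perturbed_state <- function(grid, params, cfg, base = c("nematic", "isotropic")) {
  base <- match.arg(base)
  set.seed(cfg$seed)
  amp <- cfg$noise_amplitude * sqrt(params$a2 / params$a4)
  n <- grid$nx * grid$ny
  q0 <- if (base == "nematic") uniform_nematic(grid, params) else
    nematic_field(matrix(0, grid$nx, grid$ny), matrix(0, grid$nx, grid$ny), grid)
  # band-limit the noise to structures no finer than the coherence length
  smooth_noise <- function() {
    w <- matrix(stats::rnorm(n), grid$nx, grid$ny)
    flt <- exp(-(grid$K2 * params$xi^2))
    s <- spec_ifft(spec_fft(w) * flt)
    amp * s / stats::sd(s)
  }
  nematic_field(q0$qxx + smooth_noise(), q0$qxy + smooth_noise(), grid)
}

#' Advance the nematodynamic state by one timestep
#'
#' Second-order exponential-time-differencing (ETD2) pseudospectral update of
#' the Q field: the diagonal linear operator \eqn{(a_2 - K k^2)/\gamma} is
#' integrated exactly, while advection, flow coupling and the cubic Landau
#' term are treated explicitly (with 2/3-rule dealiasing by default).  The
#' Stokes flow is re-solved from the current `(q, alpha)` within the step,
#' and the activity is re-sampled from `pattern` at the new time.
#'
#' @param state A [init_state()] result.
#' @param pattern An [activity_pattern()] or `NULL`.
#' @param cfg A [solver_config()] (supplies `dt` and `dealias`).
#' @return The advanced `simulation_state`.
#' @export
step <- function(state, pattern, cfg) {
  p <- state$params
  g <- state$q$grid
  if (is.null(state$etd) || state$etd$dt != cfg$dt) {
    state$etd <- etd_coefs(g, p, cfg$dt)
    state$etd$mask <- if (cfg$dealias) dealias_mask(g) else
      matrix(1, g$nx, g$ny)
  }
  first <- is.null(state$nprev)
  # spectral state is carried between steps; (re)derive it only when the
  # field was replaced from outside the stepper
  if (is.null(state$qh)) {
    state$qh <- list(spec_fft(state$q$qxx), spec_fft(state$q$qxy))
  }
  np <- if (first) list(state$qh[[1]] * 0, state$qh[[2]] * 0) else state$nprev
  res <- nd_step_cpp(state$qh[[1]], state$qh[[2]], np[[1]], np[[2]],
                     state$alpha * p$stress_unit,
                     g$DKX, g$DKY, g$K2,
                     state$etd$e1, state$etd$f0, state$etd$f1, state$etd$f2,
                     state$etd$mask, first,
                     p$a2, p$a4, p$elastic_K, p$lambda, p$Gamma, p$eta,
                     p$gamma_rot)
  guard <- 10 * p$q_amp0
  if (!is.finite(res$max_q) || res$max_q > guard)
    stop(sprintf(paste0("numerical instability: max|Q| = %.3g exceeds %.3g ",
                        "(dt = %g, max |alpha| = %.3g); reduce dt or activity"),
                 res$max_q, guard, cfg$dt, max(abs(state$alpha))),
         call. = FALSE)
  state$q <- structure(list(qxx = res$q1, qxy = res$q2, grid = g),
                       class = "nematic_field")
  state$qh <- list(res$q1h, res$q2h)
  state$nprev <- list(res$n1h, res$n2h)
  state$time <- state$time + cfg$dt
  state$alpha <- sample_pattern(pattern, g, state$time)
  state$flow <- NULL
  state$max_u <- res$max_u
  state$max_q <- res$max_q
  state
}

#' Run a simulation protocol
#'
#' Deterministic time integration given `(state, pattern, cfg)`, with
#' optional snapshotting and a per-snapshot callback (e.g. defect tracking).
#'
#' @param state Initial [init_state()].
#' @param pattern An [activity_pattern()] or `NULL`.
#' @param cfg A [solver_config()]; `cfg$n_steps` steps are taken.
#' @param snapshot_stride Every how many steps to record a snapshot (`NULL` =
#'   only the final state is kept).
#' @param callback Optional `function(state)` evaluated at each snapshot
#'   (including the initial state); its results are collected in the output.
#' @param store_fields Keep full field snapshots (default FALSE; diagnostics
#'   and callback results are always kept).
#' @param verbose Print a progress line every 500 steps.
#' @return An `nd_run` object: list with `final` (state), `diag` (tibble of
#'   step, time, max_u, max_q), `snapshots` (list of states or `NULL`),
#'   `callback_results` (list), `times` (snapshot times).
#' @export
run_protocol <- function(state, pattern, cfg, snapshot_stride = NULL,
                         callback = NULL, store_fields = FALSE,
                         verbose = FALSE) {
  n <- cfg$n_steps
  diag_step <- integer(0); diag_t <- diag_mu <- diag_mq <- numeric(0)
  snaps <- list(); cb <- list(); times <- numeric(0)
  take_snap <- function(s, i) {
    if (store_fields) snaps[[length(snaps) + 1]] <<- s
    if (!is.null(callback)) cb[[length(cb) + 1]] <<- callback(s)
    times[length(times) + 1] <<- s$time
  }
  if (!is.null(snapshot_stride)) take_snap(state, 0L)
  if (n > 0) for (i in seq_len(n)) {
    state <- tryCatch(step(state, pattern, cfg), error = function(e)
      stop(sprintf("step %d: %s", i, conditionMessage(e)), call. = FALSE))
    diag_step <- c(diag_step, i); diag_t <- c(diag_t, state$time)
    diag_mu <- c(diag_mu, state$max_u)
    diag_mq <- c(diag_mq, state$max_q)
    if (!is.null(snapshot_stride) && i %% snapshot_stride == 0)
      take_snap(state, i)
    if (verbose && i %% 500 == 0)
      message(sprintf("step %d/%d t = %.1f max|u| = %.3g", i, n, state$time,
                      state$max_u))
  }
  structure(list(final = state,
                 diag = tibble::tibble(step = diag_step, time = diag_t,
                                       max_u = diag_mu, max_q = diag_mq),
                 snapshots = if (store_fields) snaps else NULL,
                 callback_results = cb, times = times),
            class = "nd_run")
}

#' @export
print.nd_run <- function(x, ...) {
  cat(sprintf("<nd_run> %d steps to t = %g; %d snapshots\n",
              nrow(x$diag), x$final$time, length(x$times)))
  invisible(x)
}

#' Linear growth rate of bend perturbations about the uniform nematic
#'
#' Dispersion relation of the nematodynamic equations linearized about the
#' ordered state \eqn{\hat n = \hat x} for a bend perturbation
#' \eqn{\delta q_{xy} \propto e^{ikx}} (wavevector along the director),
#' including the activity-driven flow feedback:
#' \deqn{\sigma(k) = -\frac{(q_0 + \lambda/2)\,k^2\,(\alpha_c - (2q_0 -
#'   \lambda)K k^2)}{\Gamma + \eta k^2} - \frac{K k^2}{\gamma},}
#' with \eqn{q_0 = \sqrt{a_2/(2a_4)}} and \eqn{\alpha_c} the activity in
#' internal stress units.  The decoupled amplitude mode relaxes at
#' \eqn{-(2a_2 + Kk^2)/\gamma}; the larger of the two rates is returned.
#' Extensile activity (\eqn{\alpha < 0}) destabilizes bend above
#' \eqn{|\alpha| \sim (K\Gamma/\gamma)(1 + \ell_\eta^2 k^2)}.
#'
#' @param k Wavenumber magnitude (> 0), in units of \eqn{1/\xi}.
#' @param alpha Activity (dimensionless, units of \eqn{K\Gamma/\gamma}).
#' @param params A [model_params()].
#' @return The largest real growth rate (vectorized over `k`).
#' @export
bend_growth_rate <- function(k, alpha, params) {
  stopifnot(all(k > 0))
  p <- params
  ac <- alpha * p$stress_unit
  q0 <- p$q_amp0
  bend <- -(q0 + p$lambda / 2) * k^2 *
    (ac - (2 * q0 - p$lambda) * p$elastic_K * k^2) /
    (p$Gamma + p$eta * k^2) - p$elastic_K * k^2 / p$gamma_rot
  ampl <- -(2 * p$a2 + p$elastic_K * k^2) / p$gamma_rot
  pmax(bend, ampl)
}

#' Maximum activity for a stable (bend-free) tweezer disc
#'
#' Design bound \eqn{|\alpha| \lesssim (K\Gamma/\gamma)\,\min(1,
#' (\pi\ell_\eta/R)^2)} for a disc of radius R, returned in activity units of
#' \eqn{K\Gamma/\gamma}.
#'
#' @param R Tweezer radius (units of \eqn{\xi}).
#' @param params A [model_params()].
#' @return The dimensionless activity bound.
#' @export
max_stable_activity <- function(R, params) {
  stopifnot(all(R > 0))
  pmin(1, (pi * params$l_eta / R)^2)
}
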