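#' Prepare an isolated-pair measurement texture
#'
#' Seeds a well-separated neutral \eqn{(+1/2, -1/2)} pair on the periodic
#' grid (the minimal charge-neutral arrangement a torus admits) and relaxes
#' it passively.  Used by the response-measurement and calibration routines.
#'
#' @param grid A [grid_spec()].
#' @param params A [model_params()].
#' @param beta Polarity angle imposed on the +1/2 defect (default 0).
#' @param relax_steps Passive relaxation steps (default 50).
#' @return List with the relaxed field `q`, the defect table `defects`
#'   (+1/2 first) and the passive reference flow `flow0`.
#' @export
measurement_pair <- function(grid, params, beta = 0, relax_steps = 50) {
  ch <- data.frame(charge = c(0.5, -0.5),
                   x = c(grid$Lx / 4, 3 * grid$Lx / 4),
                   y = c(grid$Ly / 2, grid$Ly / 2),
                   angle = c(beta, NA))
  q <- seed_defect_texture(ch, grid, params, relax_steps = relax_steps)
  d <- detect_defects(q)
  d <- d[order(-d$charge), ]
  if (nrow(d) != 2) stop("measurement texture lost its defect pair")
  list(q = q, defects = d, flow0 = solve_flow(q, 0, params))
}

#' Linear flow response of a defect to an activity pattern
#'
#' Measures the activity-induced core velocity and vorticity for a frozen
#' defect texture: the Stokes flow is solved with and without the pattern
#' and differenced, which by linearity of the force balance in \eqn{\alpha}
#' isolates the active response (and removes the passive elastic
#' pair-attraction flow).
#'
#' @param q A [nematic_field()] (typically from [measurement_pair()]).
#' @param pattern Activity pattern, matrix or scalar.
#' @param pos Core position (length 2).
#' @param params A [model_params()].
#' @param flow0 Optional precomputed passive flow (`alpha = 0`).
#' @return List `u0` (length-2 vector), `speed`, `omega0`.
#' @export
defect_response <- function(q, pattern, pos, params, flow0 = NULL) {
  if (is.null(flow0)) flow0 <- solve_flow(q, 0, params)
  fl <- solve_flow(q, sample_pattern(pattern, q$grid, 0), params)
  ca <- core_flow(fl, pos); c0 <- core_flow(flow0, pos)
  u0 <- as.numeric(ca$u0 - c0$u0)
  list(u0 = u0, speed = sqrt(sum(u0^2)), omega0 = ca$omega0 - c0$omega0)
}

#' Numerical verification of the defect-mobility selection rule
#'
#' For each combination of defect symmetry index \eqn{s \in \{1, 3\}} and
#' activity harmonic \eqn{n \in \{0, ..., n_max\}}, centres a pure-harmonic
#' activity disc on the defect core and measures the activity-induced core
#' speed and vorticity.  Pure harmonics (no sign-constancy offset) are used:
#' by linearity they equal the difference between the offset-carrying disc
#' and its n = 0 control run.  Each measurement takes the maximum over two
#' pattern phases (0 and \eqn{\pi/2}) so that accidental alignment of a
#' pattern gradient with the defect orientation cannot mask a response.
#'
#' @param params A [model_params()].
#' @param grid A [grid_spec()] (default 128 x 128, dx = 0.5).
#' @param n_max Largest harmonic (default 3).
#' @param alpha0 Disc amplitude (default -0.5).
#' @param R Disc radius (default 8).
#' @param relax_steps Texture relaxation (default 50).
#' @return A tibble with columns `s`, `n`, `speed`, `omega`,
#'   `can_translate`, `can_rotate` (the selection-rule prediction).
#' @export
selection_rule_suite <- function(params, grid = grid_spec(128, 128, 0.5),
                                 n_max = 3, alpha0 = -0.5, R = 8,
                                 relax_steps = 50) {
  mp <- measurement_pair(grid, params, relax_steps = relax_steps)
  purrr::map_dfr(seq_len(2), function(si) {
    pos <- c(mp$defects$x[si], mp$defects$y[si])
    s <- mp$defects$s[si]
    purrr::map_dfr(0:n_max, function(n) {
      r <- lapply(c(0, pi / 2), function(ph) {
        pat <- harmonic_disc(n, phase = ph, R = R, alpha0 = alpha0,
                             center = pos, include_offset = FALSE)
        defect_response(mp$q, pat, pos, params, mp$flow0)
      })
      pred <- predicted_mobility(s, n)
      tibble::tibble(s = s, n = n,
                     speed = max(r[[1]]$speed, r[[2]]$speed),
                     omega = max(abs(r[[1]]$omega0), abs(r[[2]]$omega0)),
                     can_translate = pred$can_translate,
                     can_rotate = pred$can_rotate)
    })
  })
}

#' Classify selection-rule measurements against the prediction
#'
#' A channel responds if it exceeds `frac` of the per-defect, per-channel
#' maximum over harmonics (relative-contrast criterion).
#'
#' @param suite Output of [selection_rule_suite()].
#' @param frac Contrast threshold (default 0.25).
#' @return The suite tibble with logical columns `translates`, `rotates`,
#'   `agrees`.
#' @export
classify_selection_rule <- function(suite, frac = 0.25) {
  out <- dplyr::mutate(dplyr::group_by(suite, .data$s),
                       translates = .data$speed > frac * max(.data$speed),
                       rotates = .data$omega > frac * max(.data$omega))
  out <- dplyr::ungroup(out)
  dplyr::mutate(out, agrees = .data$translates == .data$can_translate &
                  .data$rotates == .data$can_rotate)
}

# complex activity derivatives at a point: alpha_I, d_alpha (dx, dy),
# dbar2 = (d/dx - i d/dy)^2 alpha / 4, dbar3 analogous third derivative
activity_derivs <- function(alpha, grid, pos) {
  ah <- spec_fft(alpha)
  at <- function(field) interp_bicubic(field, pos[1], pos[2], grid)
  dxm <- spec_ifft(1i * grid$DKX * ah); dym <- spec_ifft(1i * grid$DKY * ah)
  dxx <- spec_ifft(-grid$DKX^2 * ah); dyy <- spec_ifft(-grid$DKY^2 * ah)
  dxy <- spec_ifft(-grid$DKX * grid$DKY * ah)
  dxxx <- spec_ifft(-1i * grid$DKX^3 * ah)
  dxxy <- spec_ifft(-1i * grid$DKX^2 * grid$DKY * ah)
  dxyy <- spec_ifft(-1i * grid$DKX * grid$DKY^2 * ah)
  dyyy <- spec_ifft(-1i * grid$DKY^3 * ah)
  d2 <- complex(real = at(dxx) - at(dyy), imaginary = -2 * at(dxy)) / 4
  d3 <- complex(real = at(dxxx) - 3 * at(dxyy),
                imaginary = -(3 * at(dxxy) - at(dyyy))) / 8
  list(alpha = at(alpha), grad = c(at(dxm), at(dym)), dbar2 = d2, dbar3 = d3)
}

#' Calibrate the defect response coefficients
#'
#' Measures the four linear response coefficients of \eqn{\pm 1/2} defects
#' to smooth activity landscapes by single-defect flow solves in polynomial
#' activity patterns and linear fits of the measured core velocity /
#' vorticity against the corresponding activity derivative at the core:
#' \deqn{V_+ = \zeta_1 \alpha, \quad \Omega_+ = \zeta_3 \nabla\alpha, \quad
#'       V_- = \zeta_2 \partial^2\alpha, \quad \Omega_- = \zeta_4
#'       \partial^3\alpha,}
#' with \eqn{\partial = (\partial_x - i\partial_y)/2}.  The composition with
#' defect orientation is \eqn{u_0^+ = V_+ \hat e}, \eqn{\omega_0^+ = \hat z
#' \cdot \Omega_+ \times \hat e}, \eqn{u_0^- = (\mathrm{Re}[\Theta_3 V_-],
#' \mathrm{Im}[\Theta_3 V_-])}, \eqn{\omega_0^- =
#' -\mathrm{Re}[i\Theta_3\Omega_-]}.
#'
#' @param params A [model_params()].
#' @param grid A [grid_spec()] (default 128 x 128, dx = 0.5).
#' @param amplitudes Activity amplitudes for the linear fits (default
#'   `c(0.2, 0.4, 0.6)`; kept below the instability bound).
#' @param R Envelope radius of the polynomial landscapes (default 10).
#' @return Object of class `response_calibration`: `zeta1` ... `zeta4`
#'   (zeta3, zeta4 complex-normalized to real constants), fit details, and
#'   the measurement geometry.
#' @export
calibrate_response <- function(params, grid = grid_spec(128, 128, 0.5),
                               amplitudes = c(0.2, 0.4, 0.6), R = 10) {
  mp <- measurement_pair(grid, params)
  dplus <- mp$defects[mp$defects$charge > 0, ]
  dminus <- mp$defects[mp$defects$charge < 0, ]
  ppos <- c(dplus$x[1], dplus$y[1]); mpos <- c(dminus$x[1], dminus$y[1])
  ehat <- c(dplus$ex[1], dplus$ey[1])
  th3 <- complex(real = dminus$re_theta3[1], imaginary = dminus$im_theta3[1])
  env <- function(r) exp(-(r / R)^4)   # smooth compact-ish envelope
  land <- function(pos, kind, a0) {
    p <- polar_about(grid, pos)
    base <- switch(kind,
                   const = 1,
                   linear = p$dx / R,
                   quad = (p$dx^2 - p$dy^2) / R^2,
                   cubic = (p$dx^3 - 3 * p$dx * p$dy^2) / R^3)
    -abs(a0) * base * env(p$r)
  }
  fit_slope <- function(xs, ys) {
    stats::coef(stats::lm(ys ~ 0 + xs))[[1]]
  }
  # zeta1: u0+ . ehat vs alpha(core), constant landscape
  m1 <- vapply(amplitudes, function(a0) {
    al <- land(ppos, "const", a0)
    dv <- activity_derivs(al, grid, ppos)
    r <- defect_response(mp$q, al, ppos, params, mp$flow0)
    c(dv$alpha, sum(r$u0 * ehat))
  }, numeric(2))
  zeta1 <- fit_slope(m1[1, ], m1[2, ])
  # zeta3: omega0+ vs (grad alpha x ehat)_z, linear landscape
  m3 <- vapply(amplitudes, function(a0) {
    al <- land(ppos, "linear", a0)
    dv <- activity_derivs(al, grid, ppos)
    cross <- dv$grad[1] * ehat[2] - dv$grad[2] * ehat[1]
    r <- defect_response(mp$q, al, ppos, params, mp$flow0)
    c(cross, r$omega0)
  }, numeric(2))
  zeta3 <- fit_slope(m3[1, ], m3[2, ])
  # zeta2: u0- vs Theta3 * dbar2 alpha, quadratic landscape
  m2 <- vapply(amplitudes, function(a0) {
    al <- land(mpos, "quad", a0)
    dv <- activity_derivs(al, grid, mpos)
    pred <- th3 * dv$dbar2
    r <- defect_response(mp$q, al, mpos, params, mp$flow0)
    meas <- complex(real = r$u0[1], imaginary = r$u0[2])
    # project measurement on the predicted direction
    c(Mod(pred), sum(r$u0 * c(Re(pred), Im(pred))) / max(Mod(pred), 1e-30))
  }, numeric(2))
  zeta2 <- fit_slope(m2[1, ], m2[2, ])
  # zeta4: omega0- vs -Re[i Theta3 dbar3 alpha], cubic landscape
  m4 <- vapply(amplitudes, function(a0) {
    al <- land(mpos, "cubic", a0)
    dv <- activity_derivs(al, grid, mpos)
    pred <- -Re(1i * th3 * dv$dbar3)
    r <- defect_response(mp$q, al, mpos, params, mp$flow0)
    c(pred, r$omega0)
  }, numeric(2))
  zeta4 <- fit_slope(m4[1, ], m4[2, ])
  structure(list(zeta1 = zeta1, zeta2 = zeta2, zeta3 = zeta3, zeta4 = zeta4,
                 grid = grid, R = R, amplitudes = amplitudes,
                 ehat = ehat, theta3 = th3),
            class = "response_calibration")
}

#' @export
print.response_calibration <- function(x, ...) {
  cat(sprintf("<response_calibration> zeta1 = %.4g, zeta2 = %.4g, zeta3 = %.4g, zeta4 = %.4g\n",
              x$zeta1, x$zeta2, x$zeta3, x$zeta4))
  invisible(x)
}

#' Predicted defect response from calibrated coefficients
#'
#' Composes the calibrated response coefficients with the local activity
#' derivatives and the defect orientation.
#'
#' @param calib A [calibrate_response()] result.
#' @param charge Defect charge (+1/2 or -1/2).
#' @param orientation For +1/2 the polarity vector (length 2); for -1/2 the
#'   complex \eqn{\Theta_3}.
#' @param derivs Activity derivatives at the core (from the internal
#'   evaluator; a list with `alpha`, `grad`, `dbar2`, `dbar3`).
#' @return List `u0` (length 2), `omega0`.
#' @export
response_coefficients <- function(calib, charge, orientation, derivs) {
  if (!inherits(calib, "response_calibration"))
    stop("not calibrated: run calibrate_response() first")
  if (charge > 0) {
    ehat <- orientation
    u0 <- calib$zeta1 * derivs$alpha * ehat
    om <- calib$zeta3 * (derivs$grad[1] * ehat[2] - derivs$grad[2] * ehat[1])
  } else {
    vm <- calib$zeta2 * derivs$dbar2
    z <- orientation * vm
    u0 <- c(Re(z), Im(z))
    om <- -Re(1i * orientation * calib$zeta4 * derivs$dbar3)
  }
  list(u0 = u0, omega0 = om)
}

#' Activity derivatives at a point
#'
#' Spectral evaluation of the local activity value, gradient and the complex
#' derivatives \eqn{\partial^2\alpha, \partial^3\alpha}
#' (\eqn{\partial = (\partial_x - i\partial_y)/2}) at a core position.
#'
#' @param pattern Activity pattern, matrix or scalar.
#' @param grid A [grid_spec()].
#' @param pos Position (length 2).
#' @param t Time (default 0).
#' @return List `alpha`, `grad`, `dbar2`, `dbar3`.
#' @export
activity_derivatives <- function(pattern, grid, pos, t = 0) {
  activity_derivs(sample_pattern(pattern, grid, t), grid, pos)
}
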