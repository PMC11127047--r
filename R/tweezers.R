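# Tweezer transport protocols: a prescribed disc path plus an orientation
# controller that keeps the steered defect attached to the moving disc.
#
# Steering maps (linear response, re-read from the texture every `refresh`
# steps so slow reorientation of the defect cannot detune the drive):
#  -1/2: quadrupolar disc alpha0 (1 + cos(2 phi - chi)); drift direction
#        psi = Arg(Theta3) + pi - chi  =>  chi = Arg(Theta3) + pi - psi.
#  +1/2: plain disc (self-propulsion along the polarity e) plus an n = 1
#        dipole component that torques e toward the desired direction.

waypoint_path <- function(waypoints) {
  wp <- as.matrix(waypoints)
  seg <- sqrt(rowSums((wp[-1, , drop = FALSE] -
                       wp[-nrow(wp), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  list(wp = wp, cum = cum, total = sum(seg))
}

path_point <- function(pp, sdist) {
  sdist <- min(max(sdist, 0), pp$total)
  i <- max(which(pp$cum <= sdist + 1e-12))
  if (i >= nrow(pp$wp)) return(pp$wp[nrow(pp$wp), ])
  f <- (sdist - pp$cum[i]) / (pp$cum[i + 1] - pp$cum[i])
  pp$wp[i, ] + f * (pp$wp[i + 1, ] - pp$wp[i, ])
}

path_tangent <- function(pp, sdist) {
  sdist <- min(max(sdist, 0), pp$total)
  i <- max(which(pp$cum <= sdist + 1e-12))
  i <- min(i, nrow(pp$wp) - 1)
  d <- pp$wp[i + 1, ] - pp$wp[i, ]
  n <- sqrt(sum(d^2))
  if (n < 1e-12) c(1, 0) else d / n
}

#' Transport a defect with an active topological tweezer
#'
#' Moves an activity disc along a prescribed waypoint path at speed `V`; the
#' disc's internal pattern (quadrupole phase for a -1/2, dipole steering for
#' a +1/2) is refreshed every `refresh` steps from the measured position and
#' orientation of the steered defect, so the defect is dragged along with
#' the disc.  Transport succeeds while `V` stays below the activity-induced
#' defect speed; a much faster disc leaves the defect behind.
#'
#' @param state A [init_state()] whose texture contains the defect to steer
#'   (e.g. from [measurement_pair()] or after nucleation).
#' @param charge Which defect to steer (+0.5 or -0.5).
#' @param waypoints Matrix (k x 2) of path waypoints; the path starts at the
#'   defect's current position (prepended automatically).
#' @param cfg A [solver_config()] (`n_steps` bounds the protocol length).
#' @param V Disc speed along the path.
#' @param R Disc radius (default 8).
#' @param alpha0 Disc activity (default -4; the quadrupole lobes are small
#'   enough that the local bend threshold stays above this).
#' @param refresh Steps between controller updates (default 10).
#' @param lead Aim distance ahead of the disc centre (default 3).
#' @param core_radius Quadrupole smooth-core radius (default 4).
#' @param k_steer +1/2 steering gain (default 2).
#' @return List of class `tweezer_run`: final `state`, `track` (tibble of
#'   time, defect and disc positions, separation), `success` (path completed
#'   with the defect within `R` of the disc), `max_sep`.
#' @export
run_tweezer_protocol <- function(state, charge, waypoints, cfg, V,
                                 R = 8, alpha0 = -4, refresh = 10,
                                 lead = 3, core_radius = 4, k_steer = 2) {
  ctrl <- tweezer_controller(charge, waypoints, V, R = R, alpha0 = alpha0,
                             core_radius = core_radius, lead = lead,
                             k_steer = k_steer)
  run <- run_multi_tweezer(state, list(ctrl), cfg, refresh = refresh)
  tr <- run$track
  done <- nrow(tr) > 0 &&
    abs(tr$s_along[nrow(tr)] - tr$s_total[nrow(tr)]) < 1e-9
  structure(list(state = run$state, track = tr,
                 success = done && tr$sep[nrow(tr)] < R,
                 max_sep = if (nrow(tr)) max(tr$sep) else Inf,
                 detections = run$detections, V = V, R = R,
                 path_total = if (nrow(tr)) tr$s_total[nrow(tr)] else NA),
            class = "tweezer_run")
}

#' @export
print.tweezer_run <- function(x, ...) {
  cat(sprintf("<tweezer_run> path %.3g long, V = %g: %s (max defect-disc separation %.3g, R = %g)\n",
              x$path_total, x$V,
              if (x$success) "completed" else "incomplete", x$max_sep, x$R))
  invisible(x)
}

#' Instantaneous tweezer drift response of a -1/2 defect
#'
#' Linear-response drift velocity of a -1/2 defect centred in a quadrupolar
#' tweezer with phase `chi`, used to verify the steering map and the
#' drift-reversal property (rotating the quadrupole phase by \eqn{\pi},
#' i.e. the profile by 90 degrees, reverses the drift).
#'
#' @param q Frozen [nematic_field()] containing the defect.
#' @param pos Defect position.
#' @param chi Quadrupole phase: `A = sin(chi)`, `B = cos(chi)`.
#' @param params A [model_params()].
#' @param alpha0,R Tweezer parameters.
#' @param flow0 Optional passive reference flow.
#' @return List `u0`, `speed`, `direction`.
#' @export
tweezer_drift <- function(q, pos, chi, params, alpha0 = -1, R = 6,
                          flow0 = NULL) {
  pat <- tweezer(alpha0, R, center = pos, A = sin(chi), B = cos(chi))
  r <- defect_response(q, pat, pos, params, flow0)
  list(u0 = r$u0, speed = r$speed, direction = atan2(r$u0[2], r$u0[1]))
}
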