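# Multi-tweezer orchestration: several activity discs, each servo-steering
# its own defect along a waypoint path, superposed into one activity field.
# Controllers are refreshed together from a single detection pass.

new_controller <- function(charge, waypoints, V, R = 8, alpha0 = -4,
                           core_radius = 4, lead = 3, k_steer = 2,
                           t_on = 0, t_off = Inf, label = NULL) {
  list(charge = charge, waypoints = as.matrix(waypoints), V = V, R = R,
       alpha0 = alpha0, core_radius = core_radius, lead = lead,
       k_steer = k_steer, t_on = t_on, t_off = t_off,
       label = label %||% sprintf("%+.1f", charge))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a tweezer controller for one defect
#'
#' Describes a servo-controlled activity disc that steers one defect along
#' a waypoint path at speed `V` between `t_on` and `t_off`.  For a -1/2
#' defect the disc carries a smooth-cored quadrupole whose phase is set from
#' the measured triatic orientation (drift direction
#' \eqn{\psi = \mathrm{Arg}\,\Theta_3 + \pi - \chi}); for a +1/2 defect a
#' plain disc propels the defect along its polarity and an n = 1 dipole
#' component torques the polarity toward the path direction.
#'
#' @param charge Steered defect charge (+0.5 or -0.5).
#' @param waypoints Matrix (k x 2) of path points (the defect's position at
#'   `t_on` is prepended automatically).
#' @param V Disc speed along the path.
#' @param R Disc radius.
#' @param alpha0 Disc activity amplitude (extensile, negative).
#' @param core_radius Quadrupole smooth-core radius (-1/2 controllers).
#' @param lead Aim distance ahead of the disc centre.
#' @param k_steer Polarity-steering gain (+1/2 controllers).
#' @param t_on,t_off Activation window (simulation time).
#' @param label Optional label used in the returned track table.
#' @return A controller specification for [run_multi_tweezer()].
#' @export
tweezer_controller <- function(charge, waypoints, V, R = 8, alpha0 = -4,
                               core_radius = 4, lead = 3, k_steer = 2,
                               t_on = 0, t_off = Inf, label = NULL) {
  new_controller(charge, waypoints, V, R, alpha0, core_radius, lead,
                 k_steer, t_on, t_off, label)
}

controller_pattern <- function(ctrl, st8, grid) {
  # st8: controller runtime state (dpos, orient, sdist, path)
  cpos <- path_point(st8$path, st8$sdist)
  aim <- path_point(st8$path, st8$sdist + ctrl$lead)
  psi <- atan2(wrap_delta(aim[2] - st8$dpos[2], grid$Ly),
               wrap_delta(aim[1] - st8$dpos[1], grid$Lx))
  if (ctrl$charge < 0) {
    chi <- st8$orient + pi - psi
    tweezer(ctrl$alpha0, ctrl$R, center = cpos, A = sin(chi), B = cos(chi),
            core_radius = ctrl$core_radius)
  } else {
    # +1/2: the n = 0 disc propels the defect along its polarity; the n = 2
    # quadrupole phase (spin-2, frame 2*beta) serves two duties relative to
    # the polarity: chi_rel = 0 is the fast configuration, chi_rel = pi the
    # slow one (speed throttle keeping the defect near the disc centre),
    # and chi_rel = +/- pi/2 bends the translation direction.  A weak n = 1
    # dipole (peak at beta + pi/2 for counterclockwise rotation) slowly
    # aligns the polarity with the path.  The disc edge is smoothed so the
    # core never meets an activity discontinuity.
    beta <- st8$orient
    err <- wrap_angle(psi - beta)
    tang <- path_tangent(st8$path, st8$sdist)
    along <- (st8$dpos[1] - cpos[1]) * tang[1] +
             (st8$dpos[2] - cpos[2]) * tang[2]
    chi_rel <- if (abs(err) > 0.15) sign(err) * pi / 2 else
      pi * max(0, min(1, 0.5 + along / ctrl$R))
    chi <- 2 * beta + chi_rel
    a1 <- max(-0.2, min(0.2, ctrl$k_steer * err))
    alpha0 <- ctrl$alpha0; R <- ctrl$R
    ph1 <- beta + pi / 2
    activity_pattern(function(grid, t) {
      pol <- polar_about(grid, cpos)
      prof <- alpha0 * (1 + a1 * cos(pol$phi - ph1) +
                          0.8 * cos(2 * pol$phi - chi))
      prof * logistic((R - pol$r) / 0.75)
    }, kind = "steer_plus", alpha0 = alpha0)
  }
}

#' Run several tweezer controllers simultaneously
#'
#' Advances the nematodynamic state while a set of [tweezer_controller()]s
#' steer their defects; the controllers' discs are superposed into a single
#' activity field, refreshed every `refresh` steps from one defect-detection
#' pass.  Additional static or scheduled patterns (e.g. nucleation patches)
#' can be supplied via `extra_pattern`.
#'
#' @param state Initial [init_state()].
#' @param controllers List of [tweezer_controller()] specs.
#' @param cfg A [solver_config()] (`n_steps` bounds the run).
#' @param refresh Steps between controller updates (default 10).
#' @param extra_pattern An [activity_pattern()] (or `NULL`) added to the
#'   controller discs.
#' @param snapshot_stride Record defect tables every so many steps for
#'   trajectory analysis (default = `refresh`).
#' @return List of class `multi_tweezer_run`: `state` (final), `track`
#'   (controller telemetry tibble), `detections` (per-frame defect tables
#'   bound into one tibble with `frame`, `time`), `controllers`.
#' @export
run_multi_tweezer <- function(state, controllers, cfg, refresh = 10,
                              extra_pattern = NULL, snapshot_stride = NULL) {
  g <- state$q$grid
  snapshot_stride <- snapshot_stride %||% refresh
  # runtime state per controller
  rt <- lapply(controllers, function(ctrl) list(active = FALSE, done = FALSE,
                                               dpos = NULL, orient = NULL,
                                               sdist = 0, path = NULL))
  track <- list(); detections <- list(); frame <- 0L
  pat_mat <- NULL
  for (i in seq_len(cfg$n_steps)) {
    if ((i - 1) %% refresh == 0) {
      dd <- detect_defects(state$q)
      mats <- list()
      for (k in seq_along(controllers)) {
        ctrl <- controllers[[k]]
        if (state$time < ctrl$t_on || state$time >= ctrl$t_off ||
            rt[[k]]$done) next
        cand <- dd[abs(dd$charge - ctrl$charge) < 0.01, ]
        if (nrow(cand) == 0) {
          # a controller that already held a defect and lost it is done
          # (annihilation); one that has not attached yet keeps waiting
          if (!is.null(rt[[k]]$dpos)) rt[[k]]$done <- TRUE
          next
        }
        ref <- if (is.null(rt[[k]]$dpos)) ctrl$waypoints[1, ] else
          rt[[k]]$dpos
        sep <- sqrt(wrap_delta(cand$x - ref[1], g$Lx)^2 +
                    wrap_delta(cand$y - ref[2], g$Ly)^2)
        j <- which.min(sep)
        if (is.null(rt[[k]]$dpos) && sep[j] > 2 * ctrl$R) next  # not born yet
        if (!is.null(rt[[k]]$dpos) && sep[j] > 3 * ctrl$R) {
          rt[[k]]$done <- TRUE; next   # lost the defect
        }
        rt[[k]]$dpos <- c(cand$x[j], cand$y[j])
        rt[[k]]$orient <- if (ctrl$charge < 0)
          Arg(complex(real = cand$re_theta3[j],
                      imaginary = cand$im_theta3[j])) else
          atan2(cand$ey[j], cand$ex[j])
        if (is.null(rt[[k]]$path))
          rt[[k]]$path <- waypoint_path(rbind(rt[[k]]$dpos, ctrl$waypoints))
        pat <- controller_pattern(ctrl, rt[[k]], g)
        mats[[length(mats) + 1]] <- sample_pattern(pat, g, state$time)
        cpos <- path_point(rt[[k]]$path, rt[[k]]$sdist)
        track[[length(track) + 1]] <- tibble::tibble(
          label = ctrl$label, step = i - 1L, time = state$time,
          x = rt[[k]]$dpos[1], y = rt[[k]]$dpos[2],
          cx = cpos[1], cy = cpos[2],
          sep = sqrt(wrap_delta(rt[[k]]$dpos[1] - cpos[1], g$Lx)^2 +
                     wrap_delta(rt[[k]]$dpos[2] - cpos[2], g$Ly)^2),
          s_along = rt[[k]]$sdist, s_total = rt[[k]]$path$total)
      }
      base <- if (is.null(extra_pattern)) matrix(0, g$nx, g$ny) else
        sample_pattern(extra_pattern, g, state$time)
      pat_mat <- Reduce(`+`, mats, base)
    }
    if ((i - 1) %% snapshot_stride == 0) {
      frame <- frame + 1L
      dd2 <- detect_defects(state$q)
      if (nrow(dd2)) { dd2$frame <- frame; dd2$time <- state$time }
      detections[[frame]] <- dd2
    }
    state <- step(state, pat_mat, cfg)
    for (k in seq_along(controllers)) {
      ctrl <- controllers[[k]]
      if (!is.null(rt[[k]]$path) && !rt[[k]]$done &&
          state$time >= ctrl$t_on && state$time < ctrl$t_off)
        rt[[k]]$sdist <- min(rt[[k]]$sdist + ctrl$V * cfg$dt,
                             rt[[k]]$path$total)
    }
  }
  structure(list(state = state, track = dplyr::bind_rows(track),
                 detections = dplyr::bind_rows(detections),
                 controllers = controllers),
            class = "multi_tweezer_run")
}

#' @export
print.multi_tweezer_run <- function(x, ...) {
  cat(sprintf("<multi_tweezer_run> %d controllers, %d telemetry rows, t = %g\n",
              length(x$controllers), nrow(x$track), x$state$time))
  invisible(x)
}
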