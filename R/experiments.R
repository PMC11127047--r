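#' Run a strip experiment in the turbulent regime
#'
#' Core engine for the collective-patterning experiments: integrates the
#' nematodynamic equations with a (static, oscillating, or traveling) strip
#' of extensile activity on a periodic domain, detecting and recording
#' defects at a fixed stride.
#'
#' @param pattern A strip-like [activity_pattern()].
#' @param params A [model_params()].
#' @param nx,ny,dx Grid (defaults 256 x 64 at dx = 0.5: a 128 x 32 box with
#'   the strip along y).
#' @param n_steps Steps (default 20000).
#' @param seed RNG seed for the initial perturbation.
#' @param stride Defect-detection stride in steps (default 25).
#' @param with_orientations Extract orientations at each frame (default
#'   TRUE; needed for polarization and diffusion estimates).
#' @return List of class `strip_run`: `detections` (tibble with frame,
#'   time), `final` state, `diag`, `grid`, `pattern`.
#' @export
run_strip_experiment <- function(pattern, params, nx = 256, ny = 64,
                                 dx = 0.5, n_steps = 20000, seed = 1L,
                                 stride = 25, with_orientations = TRUE) {
  g <- grid_spec(nx, ny, dx)
  cfg <- solver_config(nx, ny, dx, n_steps = as.integer(n_steps),
                       seed = as.integer(seed), noise_amplitude = 0.15)
  q0 <- perturbed_state(g, params, cfg, base = "isotropic")
  st <- init_state(q0, params, pattern)
  frame <- 0L
  detections <- list()
  cb <- function(s) {
    frame <<- frame + 1L
    d <- detect_defects(s$q, orientations = with_orientations)
    if (nrow(d)) { d$frame <- frame; d$time <- s$time }
    detections[[frame]] <<- d
    NULL
  }
  run <- run_protocol(st, pattern, cfg, snapshot_stride = stride,
                      callback = cb)
  structure(list(detections = dplyr::bind_rows(detections),
                 final = run$final, diag = run$diag, grid = g,
                 pattern = pattern, seed = seed, stride = stride),
            class = "strip_run")
}

#' @export
print.strip_run <- function(x, ...) {
  cat(sprintf("<strip_run> t = %g, %d detection frames, %d detections\n",
              x$final$time, length(unique(x$detections$frame)),
              nrow(x$detections)))
  invisible(x)
}

#' Coarse-grained defect profiles from a strip run
#'
#' Bins time-averaged defect statistics about the strip centre: mean defect
#' density n(x), charge density rho(x), +1/2 polarization p(x) and triatic
#' order T3(x) (real part), all per unit area.
#'
#' @param run A [run_strip_experiment()] result.
#' @param strip_center Strip centre (default half the box).
#' @param bin_dx Bin width (default 4).
#' @param steady_frac Burn-in fraction discarded (default 0.25).
#' @return Tibble with x (offset from centre), n, rho, p, T3.
#' @export
strip_profiles <- function(run, strip_center = run$grid$Lx / 2, bin_dx = 4,
                           steady_frac = 0.25) {
  g <- run$grid
  det <- run$detections
  fmax <- max(det$frame)
  det <- det[det$frame > steady_frac * fmax, ]
  nframes <- length(unique(det$frame))
  edges <- seq(-g$Lx / 2, g$Lx / 2, by = bin_dx)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  xr <- wrap_delta(det$x - strip_center, g$Lx)
  bin <- findInterval(xr, edges, rightmost.closed = TRUE)
  area <- bin_dx * g$Ly * nframes
  per_bin <- function(w) {
    v <- rep(0, length(mids))
    t <- tapply(w, bin, sum)
    v[as.integer(names(t))] <- t
    v / area
  }
  plus <- det$charge > 0
  tibble::tibble(
    x = mids,
    n = per_bin(rep(1, nrow(det))) / 2,       # n = (rho+ + rho-)/2
    rho = per_bin(det$charge),                # rho = (rho+ - rho-)/2
    p = per_bin(ifelse(plus & !is.na(det$ex), det$ex, 0)),
    T3 = per_bin(ifelse(!plus & !is.na(det$re_theta3), det$re_theta3, 0)))
}

#' Static dipole experiment (activity strip, fixed interface width)
#'
#' The charge-dipole patterning experiment: turbulent active strip with
#' sigmoidal interfaces; measures the steady-state topological dipole
#' moment and the coarse-grained defect profiles.  Shallow interfaces give
#' D > 0 (+1/2 defects escape to the passive sides); sharp interfaces trap
#' -1/2 defects at the edge and invert the dipole (D < 0).
#'
#' @param w Interface width.
#' @param alpha0 Strip activity (default -5).
#' @param Ws Strip width (default 50).
#' @param params A [model_params()].
#' @param seeds Replicate seeds (default 1).
#' @param n_steps Steps per replicate (default 20000).
#' @param ... Passed to [run_strip_experiment()].
#' @return List of class `dipole_experiment`: `D` (pooled steady mean),
#'   `sd`, `replicates` (tibble seed, D, sd), `profiles` (pooled), `runs`.
#' @export
fig_static_dipole <- function(w, alpha0 = -5, Ws = 50,
                              params = model_params(l_eta = 2),
                              seeds = 1L, n_steps = 20000, ...) {
  runs <- lapply(seeds, function(s) {
    pat <- strip(Ws, w, alpha0, X0 = 64)
    run_strip_experiment(pat, params, n_steps = n_steps, seed = s, ...)
  })
  reps <- purrr::map_dfr(seq_along(runs), function(i) {
    ds <- dipole_from_trajectories(runs[[i]]$detections, runs[[i]]$grid,
                                   strip_center = 64)
    tibble::tibble(seed = seeds[i], D = ds$mean, sd = ds$sd)
  })
  profs <- lapply(runs, strip_profiles)
  prof <- profs[[1]]
  if (length(profs) > 1) {
    for (col in c("n", "rho", "p", "T3"))
      prof[[col]] <- rowMeans(sapply(profs, `[[`, col))
  }
  structure(list(D = mean(reps$D), sd = stats::sd(reps$D) %||% reps$sd[1],
                 replicates = reps, profiles = prof, runs = runs,
                 w = w, alpha0 = alpha0, Ws = Ws),
            class = "dipole_experiment")
}

#' @export
print.dipole_experiment <- function(x, ...) {
  cat(sprintf("<dipole_experiment> w = %g, alpha0 = %g: D = %.4g (replicate sd %.3g, n = %d)\n",
              x$w, x$alpha0, x$D, x$sd, nrow(x$replicates)))
  invisible(x)
}

#' Oscillating-gradient experiment
#'
#' Sinusoidally driven interface width; fits the steady dipole time series
#' with a sinusoid at the drive frequency.
#'
#' @param f Drive frequency.
#' @param wmin,wmax Interface width extremes (defaults 15, 35).
#' @param alpha0 Strip activity (default -5).
#' @param Ws Strip width (default 50).
#' @param params A [model_params()].
#' @param n_steps Steps (default: 2.5 drive periods after a quarter-period
#'   burn-in, at dt = 0.1).
#' @param seed RNG seed.
#' @param ... Passed to [run_strip_experiment()].
#' @return List of class `oscillation_experiment`: the [sinusoid_fit()],
#'   dipole series, and the run.
#' @export
fig_oscillation <- function(f, wmin = 15, wmax = 35, alpha0 = -5, Ws = 50,
                            params = model_params(l_eta = 2), n_steps = NULL,
                            seed = 1L, ...) {
  if (is.null(n_steps)) n_steps <- ceiling(2.75 / f / 0.1)
  pat <- oscillating_strip(Ws, wmin, wmax, f, alpha0, X0 = 64)
  run <- run_strip_experiment(pat, params, n_steps = n_steps, seed = seed,
                              ...)
  ds <- dipole_from_trajectories(run$detections, run$grid, strip_center = 64,
                                 steady_frac = 1 / 11)
  ser <- ds$series[ds$series$frame > max(ds$series$frame) / 11, ]
  fit <- sinusoid_fit(ser$time, ser$D, f)
  structure(list(fit = fit, series = ds$series, run = run, f = f),
            class = "oscillation_experiment")
}

#' @export
print.oscillation_experiment <- function(x, ...) {
  cat(sprintf("<oscillation_experiment> f = %g:\n", x$f)); print(x$fit)
  invisible(x)
}

#' Traveling-strip transport experiment
#'
#' A sharp-interfaced strip moving at speed V; measures the leakage count
#' and the +1/2 polarization in the strip frame over the steady window.
#'
#' @param V Strip speed.
#' @param alpha0 Strip activity (default -4).
#' @param Ws Strip width (default 20).
#' @param w Interface width (default 10).
#' @param params A [model_params()].
#' @param n_steps Steps (default 10000).
#' @param seed RNG seed.
#' @param steady_frac Burn-in fraction (default 0.25).
#' @param ... Passed to [run_strip_experiment()].
#' @return List of class `transport_experiment`: `N_leak` (steady mean),
#'   `P` (steady mean +1/2 polarization, x component), per-frame table,
#'   and the run.
#' @export
fig_transport <- function(V, alpha0 = -4, Ws = 20, w = 10,
                          params = model_params(l_eta = 2), n_steps = 10000,
                          seed = 1L, steady_frac = 0.25, ...) {
  X00 <- 32
  pat <- traveling_strip(Ws, w, alpha0, V, X0 = X00)
  run <- run_strip_experiment(pat, params, nx = 128, ny = 64,
                              n_steps = n_steps, seed = seed, ...)
  det <- run$detections
  frames <- sort(unique(det$frame))
  tab <- purrr::map_dfr(frames, function(f) {
    rows <- det[det$frame == f, ]
    t <- rows$time[1]
    x0t <- X00 + V * t
    tibble::tibble(frame = f, time = t,
                   N = nrow(rows),
                   N_leak = leak_count(rows, run$grid, x0t, Ws, w),
                   Px = polarization_total(rows)[["Px"]])
  })
  keep <- tab$frame > steady_frac * max(tab$frame)
  structure(list(N_leak = mean(tab$N_leak[keep]),
                 sd_leak = stats::sd(tab$N_leak[keep]),
                 P = mean(tab$Px[keep]), sd_P = stats::sd(tab$Px[keep]),
                 table = tab, run = run, V = V),
            class = "transport_experiment")
}

#' @export
print.transport_experiment <- function(x, ...) {
  cat(sprintf("<transport_experiment> V = %g: N_leak = %.3g +/- %.3g, P = %.3g +/- %.3g\n",
              x$V, x$N_leak, x$sd_leak, x$P, x$sd_P))
  invisible(x)
}

#' Scripted figure-level experiments
#'
#' End-to-end scripted pipelines reproducing the headline defect-control
#' experiments at either reduced ("desk") or publication ("paper") problem
#' sizes: tweezer transport of single defects, defect braiding, static and
#' oscillated dipole patterning, and traveling-strip transport.
#'
#' Desk scale uses 128-256 point grids, 10-20 k steps and few replicates;
#' paper scale uses 256 x 256 grids and the original durations.
#'
#' @param which One of `"fig2_minus"`, `"fig2_plus"`, `"fig2_braid"`,
#'   `"fig3_static"`, `"fig4_oscillation"`, `"fig5_transport"`.
#' @param scale `"desk"` (default) or `"paper"`.
#' @param seeds Integer seeds (replicates where applicable).
#' @param params A [model_params()].
#' @param ... Overrides passed to the underlying experiment function.
#' @return An `experiment_report`: list with `id`, `scale`, `seeds`,
#'   `stats` (tibble of summary statistics with uncertainties and replicate
#'   counts), and `result` (the underlying experiment object(s)).
#' @export
run_figure_experiment <- function(which = c("fig2_minus", "fig2_plus",
                                            "fig2_braid", "fig3_static",
                                            "fig4_oscillation",
                                            "fig5_transport"),
                                  scale = c("desk", "paper"), seeds = 1L,
                                  params = NULL, ...) {
  which <- match.arg(which)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  # tweezer demos use the tweezer-family screening length (5); the
  # collective strip experiments the defect-gas value (2)
  if (is.null(params))
    params <- if (grepl("fig2", which)) model_params() else
      model_params(l_eta = 2)
  res <- switch(which,
    fig2_minus = fig_tweezer_demo(-0.5, params,
                                  n_steps = if (desk) 4000 else 6000, ...),
    fig2_plus = fig_tweezer_demo(0.5, params,
                                 n_steps = if (desk) 1800 else 1800, ...),
    fig2_braid = fig_braid(params, ...),
    fig3_static = {
      ns <- if (desk) 16000 else 100000
      list(shallow = fig_static_dipole(40, params = params, seeds = seeds,
                                       n_steps = ns, ...),
           sharp = fig_static_dipole(15, params = params, seeds = seeds,
                                     n_steps = ns, ...))
    },
    fig4_oscillation = {
      tau <- 25^2 / 7   # wbar^2 / Da at the desk diffusion constant
      list(slow = fig_oscillation(0.7 / tau, params = params,
                                  seed = seeds[1], ...),
           fast = fig_oscillation(1.3 / tau, params = params,
                                  seed = seeds[1], ...))
    },
    fig5_transport = lapply(c(0.025, 1, 2), function(V)
      fig_transport(V, params = params,
                    n_steps = if (desk) 10000 else 50000,
                    seed = seeds[1], ...)))
  stats <- experiment_stats(which, res, seeds)
  structure(list(id = which, scale = scale, seeds = seeds, stats = stats,
                 result = res),
            class = "experiment_report")
}

experiment_stats <- function(which, res, seeds) {
  switch(which,
    fig2_minus = ,
    fig2_plus = tibble::tibble(
      stat = c("path_total", "max_sep", "success"),
      value = c(res$path_total, res$max_sep, as.numeric(res$success)),
      sd = NA_real_, n = 1L),
    fig2_braid = tibble::tibble(
      stat = c("crossings", "n_final_defects"),
      value = c(res$crossings$count, res$n_final),
      sd = NA_real_, n = 1L),
    fig3_static = tibble::tibble(
      stat = c("D_shallow", "D_sharp"),
      value = c(res$shallow$D, res$sharp$D),
      sd = c(res$shallow$sd, res$sharp$sd),
      n = length(seeds)),
    fig4_oscillation = tibble::tibble(
      stat = c("D_bar_slow", "D_bar_fast", "tau_D_slow", "tau_D_fast"),
      value = c(res$slow$fit$D_bar, res$fast$fit$D_bar,
                res$slow$fit$tau_D, res$fast$fit$tau_D),
      sd = c(res$slow$fit$se_D_bar, res$fast$fit$se_D_bar, NA, NA),
      n = 1L),
    fig5_transport = purrr::map_dfr(res, function(r) tibble::tibble(
      stat = c(sprintf("N_leak_V%g", r$V), sprintf("P_V%g", r$V)),
      value = c(r$N_leak, r$P), sd = c(r$sd_leak, r$sd_P), n = 1L)))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s (%s scale), seeds = %s\n",
              x$id, x$scale, paste(x$seeds, collapse = ",")))
  print(as.data.frame(x$stats), digits = 4)
  invisible(x)
}

#' Single-defect tweezer transport demo
#'
#' Seeds an isolated defect pair on a 256 x 256 grid and transports the
#' chosen defect along a bent (L-shaped) path with a servo-controlled
#' tweezer.
#'
#' @param charge Which defect to transport.
#' @param params A [model_params()].
#' @param n_steps Protocol length in steps.
#' @param leg Leg length of the bent path (default 2 for -1/2, 6 for +1/2,
#'   matched to the achievable drift speeds).
#' @param V Disc speed (defaults matched to the species).
#' @return A `tweezer_run` (with `path_total`, `max_sep`, `success`).
#' @export
fig_tweezer_demo <- function(charge, params = model_params(),
                             n_steps = 4000, leg = NULL, V = NULL) {
  g <- grid_spec(256, 256, 0.5)
  mp <- measurement_pair(g, params)
  d <- mp$defects[sign(mp$defects$charge) == sign(charge), ]
  start <- c(d$x[1], d$y[1])
  if (charge < 0) {
    leg <- leg %||% 2; V <- V %||% 0.012
    wp <- rbind(start + c(0, leg), start + c(leg, leg))
  } else {
    # S-bend within the quadrupole steering cone about the initial polarity
    leg <- leg %||% 5; V <- V %||% 0.055
    beta <- atan2(d$ey[1], d$ex[1])
    dir1 <- beta + 0.3; dir2 <- beta - 0.3
    p1 <- start + leg * c(cos(dir1), sin(dir1))
    wp <- rbind(p1, p1 + leg * c(cos(dir2), sin(dir2)))
  }
  cfg <- solver_config(256, 256, 0.5, n_steps = as.integer(n_steps))
  run_tweezer_protocol(init_state(mp$q, params), charge, wp, cfg, V = V,
                       alpha0 = if (charge < 0) -4 else -0.5)
}

#' Defect pair nucleation, braiding and exchange
#'
#' Scripted multi-defect control demo, run as a single closed control loop:
#' two elliptic high-activity patches nucleate a defect pair each in a
#' uniform nematic; the moment a patch's pair is well separated the patch
#' is cut and a strong throttled tweezer catches that pair's +1/2 and pulls
#' it out of its partner's capture range while a weak disc holds the -1/2.
#' Once both pairs are staged, the pluses are steered along waypoint paths
#' chosen from the measured geometry (optional detours and approach sides)
#' so that carrying each +1/2 across the box to annihilate the *opposite*
#' pair's -1/2 (pair exchange) closes the four world lines into a braid
#' with exactly four transversal crossings in the (x, t) projection.
#'
#' @param params A [model_params()]; default is the defect-gas screening
#'   length (l_eta = 2), at which localized patches can nucleate against
#'   flow screening.
#' @param nx Grid size (default 128, a 64 x 64 box).
#' @param max_steps Overall step budget (default 26000).
#' @param alpha_peak Patch activity (default -11, deliberately far above
#'   the bend threshold for the patch size).
#' @param seed RNG seed for the initial texture noise.
#' @return List of class `braid_experiment`: `crossings`, `trajectories`,
#'   `n_final`, `planned` (crossing-plan toggles), final state.
#' @export
fig_braid <- function(params = model_params(l_eta = 2), nx = 128,
                      max_steps = 26000, alpha_peak = -11, seed = 2L,
                      cut_sep = 6) {
  g <- grid_spec(nx, nx, 0.5)
  L <- g$Lx
  set.seed(seed)
  q0 <- uniform_nematic(g, params, theta0 = pi / 2)
  noise <- 0.005 * sqrt(params$a2 / params$a4)
  q0 <- nematic_field(q0$qxx + matrix(stats::rnorm(nx^2, sd = noise), nx),
                      q0$qxy + matrix(stats::rnorm(nx^2, sd = noise), nx), g)
  cen <- list(A = c(L * 0.36, L * 0.5), B = c(L * 0.64, L * 0.5))
  patches <- lapply(cen, function(cc)
    sample_pattern(nucleation_patch(cc, c(6, 3), pi / 2, alpha_peak, 0),
                   g, 1))
  cfg <- solver_config(nx, nx, 0.5, n_steps = 1L, seed = seed)
  st <- init_state(q0, params, 0)

  # per-side controller state: phase patch -> escape -> staged -> final
  side <- list(A = list(phase = "patch", plus = NULL, minus = NULL),
               B = list(phase = "patch", plus = NULL, minus = NULL))
  stage_y <- L * 0.28
  detections <- list(); frame <- 0L
  plan <- NULL; sdistL <- 0; sdistR <- 0; pathL <- NULL; pathR <- NULL
  ramp <- function(t) min(1, t / 10)

  plus_disc <- function(dpos, beta, psi, cpos, R = 6, alpha0 = -1.2) {
    err <- wrap_angle(psi - beta)
    chi_rel <- if (abs(err) > 0.15) sign(err) * pi / 2 else 0
    chi <- 2 * beta + chi_rel
    a1 <- max(-0.2, min(0.2, 2 * err))
    pol <- polar_about(g, cpos)
    alpha0 * (1 + a1 * cos(pol$phi - (beta + pi / 2)) +
                0.8 * cos(2 * pol$phi - chi)) *
      logistic((R - pol$r) / 0.75)
  }
  minus_disc <- function(dpos, th3, target, alpha0 = -3) {
    psi <- atan2(wrap_delta(target[2] - dpos[2], L),
                 wrap_delta(target[1] - dpos[1], L))
    chi <- th3 + pi - psi
    pol <- polar_about(g, dpos)
    ramp2 <- pmin(1, (pol$r / 4)^2)
    alpha0 * (1 + ramp2 * (sin(chi) * sin(2 * pol$phi) +
                           cos(chi) * cos(2 * pol$phi))) * (pol$r <= 8)
  }
  nearest <- function(d, ref, chg, radius = 9) {
    cand <- d[sign(d$charge) == sign(chg), ]
    if (nrow(cand) == 0) return(NULL)
    sep <- sqrt(wrap_delta(cand$x - ref[1], L)^2 +
                wrap_delta(cand$y - ref[2], L)^2)
    if (min(sep) > radius) return(NULL)
    c(cand$x[which.min(sep)], cand$y[which.min(sep)],
      if (chg > 0) atan2(cand$ey[which.min(sep)], cand$ex[which.min(sep)])
      else Arg(complex(real = cand$re_theta3[which.min(sep)],
                       imaginary = cand$im_theta3[which.min(sep)])))
  }
  pat_mat <- matrix(0, nx, nx)
  for (i in seq_len(max_steps)) {
    if ((i - 1) %% 10 == 0) {
      d <- detect_defects(st$q)
      frame <- frame + 1L
      dd <- d
      if (nrow(dd)) { dd$frame <- frame; dd$time <- st$time }
      detections[[frame]] <- dd
      mats <- list()
      for (s_ in c("A", "B")) {
        ss <- side[[s_]]
        cc <- cen[[s_]]
        if (ss$phase == "patch") {
          mine <- d[abs(wrap_delta(d$x - cc[1], L)) < L / 4, ]
          pl <- mine[mine$charge > 0, ]; mi <- mine[mine$charge < 0, ]
          sepmax <- if (nrow(pl) && nrow(mi))
            max(sqrt(outer(pl$x, mi$x, "-")^2 +
                     outer(pl$y, mi$y, "-")^2)) else 0
          if (sepmax >= cut_sep) {
            side[[s_]]$phase <- "escape"
          } else mats[[length(mats) + 1]] <- ramp(st$time) * patches[[s_]]
        }
        if (side[[s_]]$phase %in% c("escape", "staged", "final")) {
          pl <- nearest(d, ss$plus %||% cc, 1)
          mi <- nearest(d, ss$minus %||% cc, -1)
          if (is.null(pl) || is.null(mi)) {
            # pair lost: before the plan this means re-annihilation --
            # re-ignite the patch and try again; after the plan it is the
            # intended annihilation at the exchange target
            if (is.null(plan)) {
              side[[s_]]$phase <- "patch"
              side[[s_]]$plus <- NULL; side[[s_]]$minus <- NULL
            } else side[[s_]]$phase <- "gone"
          } else {
            side[[s_]]$plus <- pl[1:2]; side[[s_]]$minus <- mi[1:2]
            side[[s_]]$beta <- pl[3]; side[[s_]]$th3 <- mi[3]
          }
        }
        ss <- side[[s_]]
        if (ss$phase == "escape") {
          away <- atan2(wrap_delta(ss$plus[2] - ss$minus[2], L),
                        wrap_delta(ss$plus[1] - ss$minus[1], L))
          stage <- c(ss$minus[1] + (if (s_ == "A") -1 else 1) * 2,
                     stage_y + (if (s_ == "A") 0 else 8))
          tostage <- atan2(wrap_delta(stage[2] - ss$plus[2], L),
                           wrap_delta(stage[1] - ss$plus[1], L))
          dmin <- sqrt(wrap_delta(ss$plus[1] - ss$minus[1], L)^2 +
                       wrap_delta(ss$plus[2] - ss$minus[2], L)^2)
          psi <- if (dmin < 10) away else tostage
          mats[[length(mats) + 1]] <- plus_disc(ss$plus, ss$beta, psi,
                                                ss$plus)
          mats[[length(mats) + 1]] <- minus_disc(ss$minus, ss$th3,
                                                 ss$minus)
          if (dmin >= 14) side[[s_]]$phase <- "staged"
        } else if (ss$phase %in% c("staged", "final")) {
          mats[[length(mats) + 1]] <- minus_disc(ss$minus, ss$th3, ss$minus)
        }
      }
      # once both sides staged, freeze the crossing plan
      if (is.null(plan) && side$A$phase == "staged" &&
          side$B$phase == "staged") {
        mLs <- if (side$A$minus[1] < side$B$minus[1]) side$A$minus else
          side$B$minus
        mRs <- if (side$A$minus[1] < side$B$minus[1]) side$B$minus else
          side$A$minus
        pLs <- if (side$A$minus[1] < side$B$minus[1]) side$A$plus else
          side$B$plus
        pRs <- if (side$A$minus[1] < side$B$minus[1]) side$B$plus else
          side$A$plus
        if (sqrt(sum((mLs - mRs)^2)) < 4 || sqrt(sum((pLs - pRs)^2)) < 4)
          stop("staging collapsed onto a single pair")
        plan <- braid_plan(pLs, pRs, mLs, mRs, stage_y, L)
        if (is.null(plan))
          stop(sprintf("no waypoint template achieves 4 crossings (pL %.1f,%.1f pR %.1f,%.1f mL %.1f,%.1f mR %.1f,%.1f)",
                       pLs[1], pLs[2], pRs[1], pRs[2], mLs[1], mLs[2],
                       mRs[1], mRs[2]))
        pathL <- waypoint_path(rbind(pLs, plan$paths$pL))
        pathR <- waypoint_path(rbind(pRs, plan$paths$pR))
        side$A$phase <- "final"; side$B$phase <- "final"
        whoL <- if (side$A$minus[1] < side$B$minus[1]) "A" else "B"
        side$A$role <- if (whoL == "A") "L" else "R"
        side$B$role <- if (whoL == "A") "R" else "L"
      }
      if (!is.null(plan)) {
        for (s_ in c("A", "B")) {
          ss <- side[[s_]]
          if (ss$phase != "final") next
          pp <- if (ss$role == "L") pathL else pathR
          sd_ <- if (ss$role == "L") sdistL else sdistR
          cpos <- path_point(pp, sd_)
          aim <- path_point(pp, sd_ + 3)
          psi <- atan2(wrap_delta(aim[2] - ss$plus[2], L),
                       wrap_delta(aim[1] - ss$plus[1], L))
          mats[[length(mats) + 1]] <- plus_disc(ss$plus, ss$beta, psi,
                                                cpos)
        }
      }
      pat_mat <- Reduce(`+`, mats, matrix(0, nx, nx))
      if (side$A$phase == "gone" && side$B$phase == "gone") break
    }
    st <- step(st, pat_mat, cfg)
    if (!is.null(plan)) {
      sdistL <- min(sdistL + 0.06 * cfg$dt, pathL$total)
      sdistR <- min(sdistR + 0.06 * cfg$dt, pathR$total)
    }
  }
  det <- dplyr::bind_rows(detections)
  traj <- link_trajectories(det, g, max_disp = 6)
  cr <- braid_crossings(traj)
  nf <- nrow(detect_defects(st$q))
  structure(list(crossings = cr, trajectories = traj, n_final = nf,
                 planned = if (is.null(plan)) NULL else plan$toggles,
                 phase_times = c(end = st$time),
                 state = st, track = NULL),
            class = "braid_experiment")
}

# choose plus waypoint paths whose ideal crossing count is exactly four
braid_plan <- function(pL, pR, mL, mR, yl, L) {
  build <- function(detL, farL, farR) {
    apprL <- if (farL) rbind(c(mR[1] + 6, yl), c(mR[1] + 3, mR[2])) else
      rbind(c(mR[1] - 3, yl), c(mR[1] - 3, mR[2]))
    apprR <- if (farR) rbind(c(mL[1] - 6, yl + 8), c(mL[1] - 3, mL[2])) else
      rbind(c(mL[1] + 3, yl + 8), c(mL[1] + 3, mL[2]))
    list(pL = rbind(if (detL) rbind(c(mL[1] - 6, yl)) else NULL,
                    c(pL[1], yl), apprL, c(mR[1], mR[2])),
         pR = rbind(c(pR[1], yl + 8), apprR, c(mL[1], mL[2])))
  }
  sample_path <- function(start, wp, n = 1200) {
    pts <- rbind(start, wp)
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    stats::approx(cum, pts[, 1], xout = seq(0, max(cum), length.out = n),
                  rule = 2)$y
  }
  count <- function(paths) {
    sL <- sample_path(pL[1:2], paths$pL)
    sR <- sample_path(pR[1:2], paths$pR)
    cross <- function(s, mx, drop_end = 0) {
      ddv <- s - mx
      if (drop_end > 0) ddv <- ddv[seq_len(length(ddv) - drop_end)]
      ddv <- ddv[abs(ddv) > 1e-9]
      sum(diff(sign(ddv)) != 0)
    }
    tot <- cross(sL, mL[1]) + cross(sR, mR[1]) +
      cross(sL, mR[1], drop_end = 24) + cross(sR, mL[1], drop_end = 24)
    ddv <- sL - sR
    ddv <- ddv[abs(ddv) > 1e-9]
    tot + sum(diff(sign(ddv)) != 0)
  }
  for (detL in c(FALSE, TRUE)) for (farL in c(FALSE, TRUE))
    for (farR in c(FALSE, TRUE)) {
      paths <- build(detL, farL, farR)
      if (count(paths) == 4)
        return(list(paths = paths, toggles = c(detL = detL, farL = farL,
                                               farR = farR)))
    }
  NULL
}

transform_frames <- function(det, frame_offset, time_offset) {
  if (nrow(det) == 0) return(det)
  det$frame <- det$frame + frame_offset
  det$time <- det$time + time_offset
  det
}

#' @export
print.braid_experiment <- function(x, ...) {
  cat(sprintf("<braid_experiment> %d crossings, %d defects at end\n",
              x$crossings$count, x$n_final))
  invisible(x)
}
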