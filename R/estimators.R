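#' Dipole-moment time series from tracked defects
#'
#' Bins per-frame defect charges into a y-averaged 1D charge density
#' \eqn{\rho(x)} about the strip centre and applies [dipole_moment()],
#' returning the time series and a steady-window summary.
#'
#' @param detections Tibble with `frame`, `time`, `x`, `charge`.
#' @param grid A [grid_spec()] (bin geometry and y-normalization).
#' @param strip_center Strip centre: scalar or function of time.
#' @param bin_dx Bin width (default 2).
#' @param steady_frac Fraction of the run treated as burn-in and discarded
#'   from the summary (default 0.25).
#' @return A list of class `dipole_series`: `series` (tibble frame, time, D),
#'   `mean`, `sd`, `n_frames` (summary over the steady window).
#' @export
dipole_from_trajectories <- function(detections, grid, strip_center = 0,
                                     bin_dx = 2, steady_frac = 0.25) {
  frames <- sort(unique(detections$frame))
  edges <- seq(-grid$Lx / 2, grid$Lx / 2, by = bin_dx)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  D <- vapply(frames, function(f) {
    rows <- detections[detections$frame == f, ]
    if (nrow(rows) == 0) return(0)
    xc <- resolve_path(strip_center, rows$time[1])
    xr <- wrap_delta(rows$x - xc, grid$Lx)
    rho <- vapply(seq_along(mids), function(b) {
      sel <- xr >= edges[b] & xr < edges[b + 1]
      sum(rows$charge[sel])
    }, 0) / (bin_dx * grid$Ly)
    dipole_moment(rho, mids)
  }, 0)
  series <- tibble::tibble(frame = frames,
                           time = vapply(frames, function(f)
                             detections$time[detections$frame == f][1], 0),
                           D = D)
  keep <- series$frame > stats::quantile(frames, steady_frac, names = FALSE)
  structure(list(series = series, mean = mean(series$D[keep]),
                 sd = stats::sd(series$D[keep]), n_frames = sum(keep)),
            class = "dipole_series")
}

#' @export
print.dipole_series <- function(x, ...) {
  cat(sprintf("<dipole_series> %d frames; steady D = %.4g +/- %.4g (n = %d)\n",
              nrow(x$series), x$mean, x$sd, x$n_frames))
  invisible(x)
}

#' Total +1/2 polarization
#'
#' \eqn{P = \sum_i \hat e_i} over +1/2 defects.
#'
#' @param defects Defect table with `charge`, `ex`, `ey`.
#' @return Named vector `c(Px, Py)`.
#' @export
polarization_total <- function(defects) {
  plus <- defects[!is.na(defects$charge) & defects$charge > 0 &
                    !is.na(defects$ex), ]
  c(Px = sum(plus$ex), Py = sum(plus$ey))
}

#' Count defects outside a strip
#'
#' Support is \eqn{|x - X_0| \le W_s/2 + w}; defects beyond it have leaked.
#'
#' @param defects Defect table with `x` (and `time` if `X0` moves).
#' @param grid A [grid_spec()].
#' @param X0 Strip centre (scalar or function of time).
#' @param Ws,w Strip geometry.
#' @return Integer count.
#' @export
leak_count <- function(defects, grid, X0, Ws, w) {
  if (nrow(defects) == 0) return(0L)
  t0 <- if ("time" %in% names(defects)) defects$time else 0
  xc <- if (is.function(X0)) vapply(t0, X0, 0) else X0
  sum(abs(wrap_delta(defects$x - xc, grid$Lx)) > Ws / 2 + w)
}

#' Count world-line crossings of defect trajectories
#'
#' Projects world lines onto (axis, time), resamples each pair onto the
#' shared frame grid by linear interpolation, and counts transversal sign
#' changes of the pairwise coordinate difference; each crossing is signed by
#' the ordering of the orthogonal coordinate at the crossing time.
#' Coincident positions at a sample time are resolved by evaluating half a
#' frame later (documented tie-break).
#'
#' @param traj A `defect_trajectories` object or its `trajectories` tibble.
#' @param axis Projection axis, `"x"` (default) or `"y"`.
#' @return List with `count` (total crossings) and `crossings` (tibble id1,
#'   id2, time, sign).
#' @export
braid_crossings <- function(traj, axis = c("x", "y")) {
  axis <- match.arg(axis)
  df <- if (inherits(traj, "defect_trajectories")) traj$trajectories else traj
  coord <- if (axis == "x") "x" else "y"
  ortho <- if (axis == "x") "y" else "x"
  ids <- sort(unique(df$id))
  crossings <- list()
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (b <= a) next
    da <- df[df$id == ids[a], ]; db <- df[df$id == ids[b], ]
    shared <- intersect(da$frame, db$frame)
    if (length(shared) < 2) next
    shared <- sort(shared)
    pa <- da[match(shared, da$frame), ]
    pb <- db[match(shared, db$frame), ]
    d <- pa[[coord]] - pb[[coord]]
    if (any(d == 0)) {     # tie-break: nudge to the midpoint of neighbours
      z <- which(d == 0)
      for (m in z) {
        lo <- max(1, m - 1); hi <- min(length(d), m + 1)
        d[m] <- (d[lo] + d[hi]) / 2
        if (d[m] == 0) d[m] <- .Machine$double.eps
      }
    }
    sgn <- sign(d)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (m in flips) {
      frac <- abs(d[m]) / (abs(d[m]) + abs(d[m + 1]))
      tcross <- pa$time[m] + frac * (pa$time[m + 1] - pa$time[m])
      o <- (pa[[ortho]][m] + frac * (pa[[ortho]][m + 1] - pa[[ortho]][m])) -
           (pb[[ortho]][m] + frac * (pb[[ortho]][m + 1] - pb[[ortho]][m]))
      crossings[[length(crossings) + 1]] <- tibble::tibble(
        id1 = ids[a], id2 = ids[b], time = tcross,
        sign = ifelse(o >= 0, 1L, -1L))
    }
  }
  cr <- if (length(crossings)) dplyr::bind_rows(crossings) else
    tibble::tibble(id1 = integer(0), id2 = integer(0), time = numeric(0),
                   sign = integer(0))
  list(count = nrow(cr), crossings = cr)
}

#' Synthetic active-Brownian defect tracks
#'
#' Constant-speed tracks whose heading performs rotational diffusion with
#' correlation time `tau_R` (so \eqn{\langle \hat e(t)\cdot\hat e(0)\rangle
#' = e^{-t/\tau_R}} in 2D); the reference dynamics for the diffusion
#' estimator, with \eqn{D_a = v^2 \tau_R / 2}.
#'
#' @param n_tracks Number of tracks.
#' @param n_frames Frames per track.
#' @param dt_frame Frame interval.
#' @param v Propulsion speed.
#' @param tau_R Reorientation time.
#' @param seed RNG seed.
#' @return Tibble with frame, time, id, x, y, ex, ey, charge (+1/2).
#' @export
simulate_abp_tracks <- function(n_tracks, n_frames, dt_frame, v, tau_R,
                                seed = 1L) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_tracks), function(id) {
    # rotational diffusion Dr = 1/tau_R: heading variance 2 Dr dt per step,
    # so <e(t).e(0)> = exp(-t/tau_R)
    ang <- cumsum(c(stats::runif(1, 0, 2 * pi),
                    stats::rnorm(n_frames - 1,
                                 sd = sqrt(2 * dt_frame / tau_R))))
    x <- cumsum(c(0, v * dt_frame * cos(ang[-n_frames])))
    y <- cumsum(c(0, v * dt_frame * sin(ang[-n_frames])))
    tibble::tibble(frame = seq_len(n_frames),
                   time = (seq_len(n_frames) - 1) * dt_frame, id = id,
                   x = x, y = y, ex = cos(ang), ey = sin(ang), charge = 0.5)
  })
}

#' Estimate the active diffusion constant of +1/2 defects
#'
#' \eqn{D_a = \langle|u_0|^2\rangle \tau_R / 2}: the reorientation time
#' \eqn{\tau_R} from an exponential fit of the polarity autocorrelation
#' \eqn{\langle \hat e(t)\cdot\hat e(0)\rangle}, and the squared core speed
#' from frame-to-frame displacements.  Uncertainty by bootstrap over tracks.
#'
#' @param tracks Tibble with `frame`, `time`, `id`, `x`, `y`, `ex`, `ey`
#'   (+1/2 rows only are used if a `charge` column is present).
#' @param grid Optional [grid_spec()] for periodic minimal-image
#'   displacements.
#' @param max_lag Maximum autocorrelation lag in frames (default 20).
#' @param min_segments Minimum displacement segments required (default 100).
#' @param n_boot Bootstrap replicates (default 200).
#' @return Object of class `diffusion_fit` with elements `Da`, `tau_R`,
#'   `mean_u2`, `sd_Da`, `n_segments`, `nondecay`, `acf` (lag table).
#' @export
estimate_diffusion <- function(tracks, grid = NULL, max_lag = 20,
                               min_segments = 100, n_boot = 200) {
  if ("charge" %in% names(tracks)) tracks <- tracks[tracks$charge > 0, ]
  tracks <- tracks[!is.na(tracks$ex), ]
  tracks <- dplyr::arrange(tracks, .data$id, .data$frame)
  by_id <- split(tracks, tracks$id)
  by_id <- by_id[vapply(by_id, nrow, 0L) >= 2]
  nseg <- sum(vapply(by_id, nrow, 0L) - 1)
  if (nseg < min_segments)
    stop(sprintf("insufficient statistics: %d displacement segments (< %d)",
                 nseg, min_segments))
  dtf <- stats::median(diff(sort(unique(tracks$time))))
  est_one <- function(ids) {
    sub <- by_id[ids]
    u2 <- unlist(lapply(sub, function(d) {
      ddx_ <- diff(d$x); ddy_ <- diff(d$y); ddt <- diff(d$time)
      if (!is.null(grid)) {
        ddx_ <- wrap_delta(ddx_, grid$Lx); ddy_ <- wrap_delta(ddy_, grid$Ly)
      }
      (ddx_^2 + ddy_^2) / ddt^2
    }))
    cf <- vapply(seq_len(max_lag), function(l) {
      v <- unlist(lapply(sub, function(d) {
        n <- nrow(d)
        if (n <= l) return(NULL)
        d$ex[1:(n - l)] * d$ex[(l + 1):n] + d$ey[1:(n - l)] * d$ey[(l + 1):n]
      }))
      if (length(v)) mean(v) else NA_real_
    }, 0)
    lag_t <- seq_len(max_lag) * dtf
    pos <- which(!is.na(cf) & cf > 0.05)
    if (length(pos) < 3) return(c(NA, NA, mean(u2)))
    fit <- stats::lm(log(cf[pos]) ~ 0 + lag_t[pos])
    tau <- -1 / stats::coef(fit)[1]
    c(tau * mean(u2) / 2, tau, mean(u2))
  }
  full <- est_one(seq_along(by_id))
  window <- max_lag * dtf
  nondecay <- is.na(full[2]) || full[2] > 10 * window
  boot <- replicate(n_boot, est_one(sample(seq_along(by_id),
                                           length(by_id), replace = TRUE))[1])
  acf_tab <- tibble::tibble(lag = seq_len(max_lag) * dtf)
  structure(list(Da = full[1], tau_R = full[2], mean_u2 = full[3],
                 sd_Da = stats::sd(boot, na.rm = TRUE), n_segments = nseg,
                 nondecay = nondecay, acf = acf_tab),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> Da = %.4g +/- %.4g (tau_R = %.4g, <|u0|^2> = %.4g, n = %d)\n",
              x$Da, x$sd_Da, x$tau_R, x$mean_u2, x$n_segments))
  if (x$nondecay) cat("  warning: polarity autocorrelation did not decay\n")
  invisible(x)
}

#' Sinusoidal fit of a driven dipole time series
#'
#' Least-squares fit \eqn{D(t) = \bar D + \Delta D \sin(2\pi f (t -
#' \tau_D))} at known drive frequency f (linear in the quadrature
#' amplitudes), with \eqn{\Delta D \ge 0} and \eqn{\tau_D \in [0, 1/f)}.
#'
#' @param time,D Time series vectors.
#' @param f Drive frequency.
#' @return Object of class `sinusoid_fit`: `D_bar`, `Delta_D`, `tau_D`,
#'   standard errors, and `degenerate` flag (amplitude consistent with 0).
#' @export
sinusoid_fit <- function(time, D, f) {
  stopifnot(length(time) == length(D), f > 0)
  s <- sin(2 * pi * f * time); c_ <- cos(2 * pi * f * time)
  fit <- stats::lm(D ~ s + c_)
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  a <- cf[["s"]]; b <- cf[["c_"]]
  amp <- sqrt(a^2 + b^2)
  tau_D <- (atan2(-b, a) / (2 * pi * f)) %% (1 / f)
  amp_se <- if (amp > 0) sqrt((a * se[["s"]])^2 + (b * se[["c_"]])^2) / amp
            else mean(se[c("s", "c_")])
  degenerate <- amp < 2 * amp_se
  structure(list(D_bar = cf[[1]], Delta_D = amp,
                 tau_D = if (degenerate) NA_real_ else tau_D,
                 se_D_bar = se[[1]], se_Delta_D = amp_se,
                 degenerate = degenerate, f = f, fit = fit),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("<sinusoid_fit> D_bar = %.4g +/- %.4g, Delta_D = %.4g +/- %.4g, tau_D = %.4g (f = %g)\n",
              x$D_bar, x$se_D_bar, x$Delta_D, x$se_Delta_D, x$tau_D, x$f))
  invisible(x)
}
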