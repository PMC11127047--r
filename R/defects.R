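#' Detect half-integer disclinations in a nematic field
#'
#' Plaquette winding-number detection: for every grid plaquette the
#' branch-corrected increment of the director angle around the loop is
#' accumulated (increments wrapped into \eqn{(-\pi/2, \pi/2]}, the nematic
#' identification \eqn{\theta \sim \theta + \pi}); plaquettes with total
#' winding \eqn{\pm\pi} carry a \eqn{\nu = \pm 1/2} defect.  The position is
#' refined to subgrid precision from the joint zero crossing of
#' \eqn{(q_{xx}, q_{xy})} by a local plane fit, and a low-order-parameter
#' core (\eqn{S < 0.5\,S_{bulk}}) is required.
#'
#' @param q A [nematic_field()].
#' @param orientations Also extract \eqn{\hat e} (+1/2) and \eqn{\Theta_3}
#'   (-1/2) for each defect (default TRUE).
#' @param flow Optional [flow_field()]: adds interpolated core flow columns
#'   `u0x`, `u0y`, `omega0`.
#' @param s_bulk Bulk order parameter used for the core criterion; default is
#'   the 90th percentile of S over the grid.
#' @return A tibble with one row per defect: `x`, `y` (physical units),
#'   `charge`, `s` (symmetry index \eqn{2|1-\nu|}), `ex`, `ey`,
#'   `re_theta3`, `im_theta3`, `theta3_ok`, and core-flow columns when
#'   `flow` is given.  Empty tibble when no defects are present.
#' @export
detect_defects <- function(q, orientations = TRUE, flow = NULL,
                           s_bulk = NULL) {
  g <- q$grid
  th <- 0.5 * atan2(q$qxy, q$qxx)
  ix2 <- c(2:g$nx, 1L); iy2 <- c(2:g$ny, 1L)
  wrap_half <- function(d) d - pi * round(d / pi)
  # corners: 1 = (i,j), 2 = (i+1,j), 3 = (i+1,j+1), 4 = (i,j+1)
  t1 <- th; t2 <- th[ix2, , drop = FALSE]
  t3 <- th[ix2, iy2, drop = FALSE]; t4 <- th[, iy2, drop = FALSE]
  wind <- wrap_half(t2 - t1) + wrap_half(t3 - t2) +
    wrap_half(t4 - t3) + wrap_half(t1 - t4)
  charge <- round(wind / pi) / 2
  S <- order_S(q)
  if (is.null(s_bulk)) s_bulk <- stats::quantile(S, 0.9, names = FALSE)
  smin <- pmin(S, S[ix2, ], S[ix2, iy2], S[, iy2])
  hit <- which(abs(charge) > 0.25 & smin < 0.5 * s_bulk, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_defect_table())
  i <- hit[, 1]; j <- hit[, 2]
  i2 <- ix2[i]; j2 <- iy2[j]
  # plane fit of each q component over the 4 corners; zero crossing
  pos <- vapply(seq_along(i), function(k) {
    c1 <- c(q$qxx[i[k], j[k]], q$qxx[i2[k], j[k]],
            q$qxx[i2[k], j2[k]], q$qxx[i[k], j2[k]])
    c2 <- c(q$qxy[i[k], j[k]], q$qxy[i2[k], j[k]],
            q$qxy[i2[k], j2[k]], q$qxy[i[k], j2[k]])
    a1 <- mean(c1); b1x <- (c1[2] + c1[3] - c1[1] - c1[4]) / (2 * g$dx)
    b1y <- (c1[3] + c1[4] - c1[1] - c1[2]) / (2 * g$dx)
    a2 <- mean(c2); b2x <- (c2[2] + c2[3] - c2[1] - c2[4]) / (2 * g$dx)
    b2y <- (c2[3] + c2[4] - c2[1] - c2[2]) / (2 * g$dx)
    det <- b1x * b2y - b1y * b2x
    if (abs(det) < 1e-14) return(c(0, 0))
    d <- c(-(a1 * b2y - a2 * b1y) / det, -(b1x * a2 - b2x * a1) / det)
    pmin(pmax(d, -g$dx / 2), g$dx / 2)  # stay inside the plaquette
  }, numeric(2))
  x <- wrap_coord((i - 1) * g$dx + g$dx / 2 + pos[1, ], g$Lx)
  y <- wrap_coord((j - 1) * g$dx + g$dx / 2 + pos[2, ], g$Ly)
  # Newton refinement of the joint zero of (qxx, qxy) on the bicubic
  # interpolant (spectral first derivatives)
  dq1x <- ddx(q$qxx, g); dq1y <- ddy(q$qxx, g)
  dq2x <- ddx(q$qxy, g); dq2y <- ddy(q$qxy, g)
  for (it in 1:4) {
    f1 <- interp_bicubic(q$qxx, x, y, g)
    f2 <- interp_bicubic(q$qxy, x, y, g)
    j11 <- interp_bicubic(dq1x, x, y, g); j12 <- interp_bicubic(dq1y, x, y, g)
    j21 <- interp_bicubic(dq2x, x, y, g); j22 <- interp_bicubic(dq2y, x, y, g)
    det <- j11 * j22 - j12 * j21
    ok_det <- abs(det) > 1e-12
    sx <- ifelse(ok_det, (f1 * j22 - f2 * j12) / det, 0)
    sy <- ifelse(ok_det, (j11 * f2 - j21 * f1) / det, 0)
    # cap the update at one grid cell to stay attached to the plaquette
    sx <- pmin(pmax(sx, -g$dx), g$dx); sy <- pmin(pmax(sy, -g$dx), g$dx)
    x <- wrap_coord(x - sx, g$Lx); y <- wrap_coord(y - sy, g$Ly)
  }
  nu <- charge[hit]
  out <- tibble::tibble(x = x, y = y, charge = nu,
                        s = as.integer(2 * abs(1 - nu)),
                        ex = NA_real_, ey = NA_real_,
                        re_theta3 = NA_real_, im_theta3 = NA_real_,
                        theta3_ok = NA)
  if (orientations && nrow(out) > 0) {
    plus <- which(out$charge > 0.25 & out$charge < 0.75)
    if (length(plus)) {
      e <- plus_orientation(q, cbind(out$x[plus], out$y[plus]))
      out$ex[plus] <- e[, 1]; out$ey[plus] <- e[, 2]
    }
    minus <- which(out$charge < -0.25 & out$charge > -0.75)
    if (length(minus)) {
      th3 <- minus_triatic(q, cbind(out$x[minus], out$y[minus]),
                           others = cbind(out$x, out$y))
      out$re_theta3[minus] <- Re(th3$theta3)
      out$im_theta3[minus] <- Im(th3$theta3)
      out$theta3_ok[minus] <- th3$ok
    }
  }
  if (!is.null(flow)) {
    cf <- core_flow(flow, cbind(out$x, out$y))
    out$u0x <- cf$u0[, 1]; out$u0y <- cf$u0[, 2]; out$omega0 <- cf$omega0
  }
  out
}

empty_defect_table <- function() {
  tibble::tibble(x = numeric(0), y = numeric(0), charge = numeric(0),
                 s = integer(0), ex = numeric(0), ey = numeric(0),
                 re_theta3 = numeric(0), im_theta3 = numeric(0),
                 theta3_ok = logical(0))
}

#' Total topological charge
#'
#' @param defects Defect table from [detect_defects()].
#' @return Sum of winding numbers (0 on a torus).
#' @export
total_charge <- function(defects) {
  if (nrow(defects) == 0) return(0)
  sum(defects$charge)
}

#' Polarity of +1/2 defects
#'
#' The comet axis \eqn{\hat e}, computed from the divergence of the
#' alignment tensor at the core (spectral differentiation, bicubic
#' interpolation): \eqn{\hat e = -\mathrm{normalize}(\partial_j Q_{xj},
#' \partial_j Q_{yj})}.  The sign is fixed so that \eqn{\hat e} is the
#' self-propulsion direction of the defect under uniform extensile
#' activity.  The polarity is equivariant: rotating the texture by
#' \eqn{\beta} rotates \eqn{\hat e} by \eqn{\beta}.
#'
#' @param q A [nematic_field()].
#' @param pos Matrix (n x 2) or length-2 vector of core positions.
#' @return n x 2 matrix of unit vectors.
#' @export
plus_orientation <- function(q, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, 1)
  g <- q$grid
  dx1 <- ddx(q$qxx, g); dy2 <- ddy(q$qxy, g)
  dx2 <- ddx(q$qxy, g); dy1 <- ddy(q$qxx, g)
  Dx <- -(dx1 + dy2); Dy <- -(dx2 - dy1)
  ex <- interp_bicubic(Dx, pos[, 1], pos[, 2], g)
  ey <- interp_bicubic(Dy, pos[, 1], pos[, 2], g)
  nrm <- sqrt(ex^2 + ey^2)
  if (any(nrm < 1e-12))
    stop("vanishing |div Q| at requested core: orientation undefined")
  cbind(ex / nrm, ey / nrm)
}

#' Triatic orientation of -1/2 defects
#'
#' The three-fold orientation \eqn{\Theta_3 = e^{3i\psi}} (\eqn{\psi} the
#' angle of one symmetry axis) extracted from the phase of the third angular
#' harmonic of the director angle sampled on a ring about the core:
#' \eqn{\Theta_3 \propto \langle e^{i(2\theta(\phi) + \phi)}
#' \rangle_{ring}}, normalized to unit modulus.  Equivariant with weight 3:
#' rotating the texture by \eqn{\beta} multiplies \eqn{\Theta_3} by
#' \eqn{e^{3i\beta}}.
#'
#' @param q A [nematic_field()].
#' @param pos Matrix (n x 2) or length-2 vector of -1/2 core positions.
#' @param radius Ring radius (default 2.5, in units of \eqn{\xi}).
#' @param n_ring Number of ring sample points (default 48).
#' @param others Optional positions of all defects; a ring passing within
#'   2 length units of another core is flagged low-confidence.
#' @return List with complex vector `theta3` (unit modulus) and logical `ok`.
#' @export
minus_triatic <- function(q, pos, radius = 2.5, n_ring = 48, others = NULL) {
  if (is.null(dim(pos))) pos <- matrix(pos, 1)
  g <- q$grid
  phis <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  th3 <- complex(length(pos[, 1]))
  ok <- rep(TRUE, nrow(pos))
  for (k in seq_len(nrow(pos))) {
    rx <- pos[k, 1] + radius * cos(phis)
    ry <- pos[k, 2] + radius * sin(phis)
    q1 <- interp_bicubic(q$qxx, rx, ry, g)
    q2 <- interp_bicubic(q$qxy, rx, ry, g)
    th <- 0.5 * atan2(q2, q1)
    z <- mean(exp(1i * (2 * th + phis)))
    th3[k] <- if (Mod(z) < 1e-12) NA else z / Mod(z)
    if (!is.null(others)) {
      d2 <- sqrt(wrap_delta(others[, 1] - pos[k, 1], g$Lx)^2 +
                 wrap_delta(others[, 2] - pos[k, 2], g$Ly)^2)
      d2 <- d2[d2 > 1e-9]
      if (any(d2 < radius + 2)) ok[k] <- FALSE
    }
  }
  list(theta3 = th3, ok = ok)
}

#' Flow at a defect core
#'
#' Bicubic (periodic Catmull-Rom) interpolation of velocity and vorticity at
#' the given positions; positions outside the box are wrapped.
#'
#' @param flow A [flow_field()].
#' @param pos Matrix (n x 2) or length-2 vector.
#' @return List with `u0` (n x 2 matrix) and `omega0` (vector).
#' @export
core_flow <- function(flow, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, 1)
  g <- flow$grid
  list(u0 = cbind(interp_bicubic(flow$ux, pos[, 1], pos[, 2], g),
                  interp_bicubic(flow$uy, pos[, 1], pos[, 2], g)),
       omega0 = interp_bicubic(flow$omega, pos[, 1], pos[, 2], g))
}

# periodic Catmull-Rom bicubic interpolation of matrix A at physical (x, y)
interp_bicubic <- function(A, x, y, grid) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx
  fx <- (x / dx) %% nx; fy <- (y / dx) %% ny
  ix <- floor(fx); iy <- floor(fy)
  tx <- fx - ix; ty <- fy - iy
  wts <- function(t) cbind(((-t + 2) * t - 1) * t / 2,
                           ((3 * t - 5) * t^2 + 2) / 2,
                           (((-3 * t + 4) * t + 1) * t) / 2,
                           ((t - 1) * t^2) / 2)
  wx <- wts(tx); wy <- wts(ty)
  out <- numeric(length(x))
  for (a in 0:3) {
    ii <- (ix + a - 1) %% nx + 1
    row <- numeric(length(x))
    for (b in 0:3) {
      jj <- (iy + b - 1) %% ny + 1
      row <- row + wy[, b + 1] * A[cbind(ii, jj)]
    }
    out <- out + wx[, a + 1] * row
  }
  out
}

#' Seed an exact multi-defect texture
#'
#' Constructs a periodic Q field with prescribed \eqn{\pm 1/2} windings at
#' the given positions, using the spectral Coulomb-gas construction: the
#' doubled director phase \eqn{\Phi = 2\theta} is obtained by line
#' integration of the divergence-free vector field \eqn{\hat z \times \nabla
#' G}, where \eqn{G} solves the periodic Poisson problem with unit-winding
#' sources at the cores.  Individual defect orientations are imposed by
#' adding smooth local phase "bubbles" around each core, the order-parameter
#' magnitude is suppressed over \eqn{\sim \xi} at each core, and a short
#' passive relaxation (\eqn{\alpha = 0}) regularizes the texture.
#'
#' @param charges Data frame with columns `charge` (\eqn{\pm 1/2}), `x`, `y`
#'   and optionally `angle` (target orientation: polarity angle \eqn{\beta}
#'   for +1/2, symmetry-axis angle \eqn{\psi} for -1/2; `NA` = free).
#' @param grid A [grid_spec()].
#' @param params A [model_params()].
#' @param relax_steps Passive relaxation steps (default 25, dt = 0.1).
#' @param relax_dt Relaxation timestep.
#' @return A [nematic_field()].
#' @export
seed_defect_texture <- function(charges, grid, params, relax_steps = 25,
                                relax_dt = 0.1) {
  charges <- as.data.frame(charges)
  stopifnot(all(c("charge", "x", "y") %in% names(charges)))
  if (!"angle" %in% names(charges)) charges$angle <- NA_real_
  if (abs(sum(charges$charge)) > 1e-9)
    stop("total charge must vanish on the periodic torus; ",
         "add a neutralizing defect")
  phi <- seeded_phase(charges, grid)
  build <- function(phi) {
    S <- s_profile(charges, grid, params)
    nematic_field(S / 2 * cos(phi), S / 2 * sin(phi), grid)
  }
  q <- build(phi)
  # Impose requested orientations.  The first one is set by a global phase
  # offset (an elastic zero mode, so it survives relaxation exactly); any
  # further ones by smooth local phase bubbles, which relaxation partially
  # undoes as the texture returns to its elastically preferred state.
  want <- which(!is.na(charges$angle))
  if (length(want)) {
    measure_delta <- function(q, k) {
      pos <- c(charges$x[k], charges$y[k])
      if (charges$charge[k] > 0) {
        e <- plus_orientation(q, pos)
        wrap_angle(charges$angle[k] - atan2(e[2], e[1]))
      } else {
        t3 <- minus_triatic(q, pos)$theta3
        wrap_angle(3 * charges$angle[k] - Arg(t3))
      }
    }
    phi <- phi + measure_delta(q, want[1])
    q <- build(phi)
    if (length(want) > 1) {
      r0 <- bubble_radius(charges, grid)
      for (k in want[-1]) {
        delta <- measure_delta(q, k)
        p <- polar_about(grid, c(charges$x[k], charges$y[k]))
        chi <- smoothstep01(1 - pmin(pmax(p$r / r0, 0), 1))
        phi <- phi + delta * chi
        q <- build(phi)
      }
    }
  }
  if (relax_steps > 0) {
    cfg <- solver_config(grid$nx, grid$ny, grid$dx, dt = relax_dt,
                         n_steps = as.integer(relax_steps))
    st <- init_state(q, params)
    q <- run_protocol(st, NULL, cfg)$final$q
  }
  q
}

# doubled phase field with prescribed windings (line-integrated vortex field)
seeded_phase <- function(charges, grid) {
  rhs <- matrix(0, grid$nx, grid$ny)
  cell <- grid$dx^2
  for (k in seq_len(nrow(charges))) {
    i <- round(charges$x[k] / grid$dx) %% grid$nx + 1
    j <- round(charges$y[k] / grid$dx) %% grid$ny + 1
    rhs[i, j] <- rhs[i, j] + 2 * pi * (2 * charges$charge[k]) / cell
  }
  rh <- spec_fft(rhs)
  k2 <- grid$K2; k2[1, 1] <- 1
  gh <- -rh / k2; gh[1, 1] <- 0
  vx <- -spec_ifft(1i * grid$DKY * gh)   # z x grad G
  vy <- spec_ifft(1i * grid$DKX * gh)
  # quantize the two cycle circulations to multiples of 2*pi by adding the
  # minimal uniform harmonic piece; otherwise the reconstructed phase has a
  # pi-mismatch domain wall at the wrap seam
  j0 <- far_index(charges$y, grid$y, grid$Ly)
  i0 <- far_index(charges$x, grid$x, grid$Lx)
  cx <- sum(vx[, j0]) * grid$dx
  cy <- sum(vy[i0, ]) * grid$dx
  vx <- vx + (2 * pi * round(cx / (2 * pi)) - cx) / grid$Lx
  vy <- vy + (2 * pi * round(cy / (2 * pi)) - cy) / grid$Ly
  phi <- matrix(0, grid$nx, grid$ny)
  dxs <- grid$dx
  # integrate along the first column, then along each row
  for (i in 2:grid$nx)
    phi[i, 1] <- phi[i - 1, 1] + dxs * (vx[i - 1, 1] + vx[i, 1]) / 2
  cumy <- t(apply(cbind(0, (vy[, -grid$ny, drop = FALSE] +
                            vy[, -1, drop = FALSE]) / 2 * dxs), 1, cumsum))
  phi + cumy
}

s_profile <- function(charges, grid, params) {
  S <- matrix(2 * params$q_amp0, grid$nx, grid$ny)
  for (k in seq_len(nrow(charges))) {
    p <- polar_about(grid, c(charges$x[k], charges$y[k]))
    S <- S * tanh(p$r / params$xi)
  }
  S
}

bubble_radius <- function(charges, grid) {
  n <- nrow(charges)
  if (n < 2) return(min(grid$Lx, grid$Ly) / 4)
  dmin <- Inf
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    d <- sqrt(wrap_delta(charges$x[a] - charges$x[b], grid$Lx)^2 +
              wrap_delta(charges$y[a] - charges$y[b], grid$Ly)^2)
    dmin <- min(dmin, d)
  }
  min(0.45 * dmin, min(grid$Lx, grid$Ly) / 4)
}

smoothstep01 <- function(t) t * t * (3 - 2 * t)

# grid index along one axis maximally distant from all listed coordinates
far_index <- function(coords, axis, L) {
  dmin <- vapply(axis, function(a)
    min(abs(wrap_delta(a - coords, L))), 0)
  which.max(dmin)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))
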