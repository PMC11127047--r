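#' Coefficients of the coarse-grained defect hydrodynamics
#'
#' Parameters of the 1D steady-state defect-gas model: reorientation time
#' `tau_R`, dimensionless rotational mobility `mu_R`, translational mobility
#' `mu` (\eqn{\propto 1/\gamma}), elasticity `K`, the density-closure
#' constant `c_n` in \eqn{n(x) = c_n |\alpha(x)|}, and the linear response
#' coefficients entering \eqn{V_+(x) = \zeta_1 \alpha}, \eqn{V_-(x) = \zeta_2
#' \alpha''}, \eqn{\Omega_+(x) = \zeta_3 \alpha'}.
#'
#' @param tau_R Defect reorientation time (> 0).
#' @param mu_R Rotational mobility (dimensionless).
#' @param mu Translational mobility (> 0).
#' @param K Elastic constant (default 1).
#' @param c_n Density-closure constant (> 0).
#' @param zeta1,zeta2,zeta3 Response coefficients.
#' @return An object of class `hydro_params`.
#' @export
hydro_params <- function(tau_R, mu_R, mu, K = 1, c_n, zeta1, zeta2, zeta3) {
  stopifnot(tau_R > 0, mu > 0, c_n > 0)
  structure(list(tau_R = tau_R, mu_R = mu_R, mu = mu, K = K, c_n = c_n,
                 zeta1 = zeta1, zeta2 = zeta2, zeta3 = zeta3),
            class = "hydro_params")
}

#' @export
print.hydro_params <- function(x, ...) {
  cat(sprintf(
    "<hydro_params> tau_R = %.3g, mu_R = %.3g, mu = %.3g, K = %.3g, c_n = %.3g\n",
    x$tau_R, x$mu_R, x$mu, x$K, x$c_n))
  cat(sprintf("  zeta1 = %.3g, zeta2 = %.3g, zeta3 = %.3g\n",
              x$zeta1, x$zeta2, x$zeta3))
  invisible(x)
}

#' Mean defect density closure
#'
#' In sustained active turbulence, defect creation/annihilation balance
#' pins the mean density to the local activity: \eqn{n(x) = c_n |\alpha(x)|}.
#'
#' @param alpha Activity values on the 1D grid.
#' @param c_n Closure constant.
#' @return Density vector \eqn{n \ge 0}.
#' @export
density_closure <- function(alpha, c_n) c_n * abs(alpha)

# central first/second derivatives on a uniform 1D grid, one-sided ends
d1 <- function(f, dx) {
  n <- length(f)
  c(f[2] - f[1], (f[3:n] - f[1:(n - 2)]) / 2, f[n] - f[n - 1]) / dx
}

d2 <- function(f, dx) {
  n <- length(f)
  c(0, f[3:n] - 2 * f[2:(n - 1)] + f[1:(n - 2)], 0) / dx^2
}

#' Steady-state solution of the 1D defect hydrodynamics
#'
#' Solves the linearized steady flux-balance equations for the +1/2
#' polarization \eqn{p(x)}, the triatic order \eqn{T_3(x)} and the smoothed
#' phase gradient \eqn{v_n(x)} in a static 1D activity landscape:
#' \deqn{-p/\tau_R - \tfrac12\partial_x(n V_+) - \tfrac12 n \Omega_+
#'   + \mu_R V_+ n v_n = 0,}
#' \deqn{-T_3/\tau_R - \tfrac12\partial_x(n V_-) + \mu_R V_- n v_n = 0,}
#' \deqn{p V_+ - T_3 V_- + 2\mu K n v_n = 0,}
#' with \eqn{\rho_\pm} replaced by \eqn{n(x) = c_n|\alpha(x)|} in all
#' coefficient positions (no nonlinear buildup of defect order).  Eliminating
#' \eqn{v_n} via the third equation yields a sparse linear system in
#' \eqn{(p, T_3)}, solved with homogeneous Dirichlet conditions at the domain
#' ends; \eqn{v_n} follows from the force balance and the charge density from
#' the Gauss law \eqn{2\pi\rho = \partial_x v_n}.
#'
#' @param alpha Activity values on the 1D grid (must decay to ~0 at both
#'   ends).
#' @param x Grid coordinates (uniform spacing).
#' @param params A [hydro_params()].
#' @return A tibble (class `hydro_profiles`) with columns `x`, `alpha`, `n`,
#'   `p`, `T3`, `vn`, `rho`, `rho_plus`, `rho_minus` and attribute
#'   `negative_density` flagging \eqn{\rho_\pm < 0} anywhere.
#' @export
steady_state_solve <- function(alpha, x, params) {
  stopifnot(length(alpha) == length(x), length(x) > 4)
  dx <- x[2] - x[1]
  m <- length(x)
  n <- density_closure(alpha, params$c_n)
  if (max(n) <= 0) stop("degenerate input: n(x) = 0 everywhere")
  Vp <- params$zeta1 * alpha
  Vm <- params$zeta2 * d2(alpha, dx)
  Op <- params$zeta3 * d1(alpha, dx)
  Gp <- -0.5 * d1(n * Vp, dx) - 0.5 * n * Op
  Gt <- -0.5 * d1(n * Vm, dx)
  C <- 1 / (2 * params$mu * params$K)
  tR <- params$tau_R; mR <- params$mu_R
  # pointwise 2x2 blocks: [1 + tR mR C Vp^2, -tR mR C Vp Vm; tR mR C Vm Vp,
  #                        1 - tR mR C Vm^2] (p, T3) = tR (Gp, Gt)
  a11 <- 1 + tR * mR * C * Vp^2
  a12 <- -tR * mR * C * Vp * Vm
  a21 <- tR * mR * C * Vm * Vp
  a22 <- 1 - tR * mR * C * Vm^2
  ii <- c(seq_len(m), seq_len(m), m + seq_len(m), m + seq_len(m))
  jj <- c(seq_len(m), m + seq_len(m), seq_len(m), m + seq_len(m))
  vv <- c(a11, a12, a21, a22)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(2 * m, 2 * m))
  b <- c(tR * Gp, tR * Gt)
  # decay (Dirichlet) conditions at the domain ends
  for (row in c(1, m, m + 1, 2 * m)) {
    A[row, ] <- 0; A[row, row] <- 1; b[row] <- 0
  }
  sol <- as.numeric(Matrix::solve(A, b))
  p <- sol[seq_len(m)]; T3 <- sol[m + seq_len(m)]
  nfloor <- 1e-8 * max(n)
  vn <- ifelse(n > nfloor, C * (T3 * Vm - p * Vp) / pmax(n, nfloor), 0)
  rho <- charge_from_gauss(vn, x)
  out <- tibble::tibble(x = x, alpha = alpha, n = n, p = p, T3 = T3,
                        vn = vn, rho = rho,
                        rho_plus = n + rho, rho_minus = n - rho)
  neg <- any(out$rho_plus < -1e-12) || any(out$rho_minus < -1e-12)
  if (neg) warning("linearized solution has rho_plus or rho_minus < 0 ",
                   "(outside the validity of the linearization)")
  attr(out, "negative_density") <- neg
  class(out) <- c("hydro_profiles", class(out))
  out
}

#' Charge density from the nematic Gauss law
#'
#' \eqn{\rho(x) = \partial_x v_n / 2\pi} by central differences.
#'
#' @param vn Smoothed phase-gradient component on the grid.
#' @param x Grid coordinates (uniform).
#' @return Charge density vector.
#' @export
charge_from_gauss <- function(vn, x) d1(vn, x[2] - x[1]) / (2 * pi)

#' Topological dipole moment
#'
#' \eqn{D = \tfrac12 \int dx\, |x - x_c|\, \rho(x)} by trapezoidal
#' quadrature; positive D means excess +1/2 charge at large \eqn{|x|}
#' (the low-activity side of a centred strip).
#'
#' @param rho Charge density on the grid.
#' @param x Grid coordinates.
#' @param center Strip centre \eqn{x_c} (default 0).
#' @return Scalar dipole moment.
#' @export
dipole_moment <- function(rho, x, center = 0) {
  f <- 0.5 * abs(x - center) * rho
  sum((f[-1] + f[-length(f)]) / 2 * diff(x))
}

#' Dipole-flip threshold scan
#'
#' Scans a family of strip profiles at fixed maximal activity over interface
#' widths `w`, solving the 1D defect hydrodynamics for each and locating the
#' sign change of the dipole moment by bisection.  Returns the critical
#' interfacial gradient \eqn{\alpha_x^* = |\alpha_0|/w^*}.
#'
#' @param params A [hydro_params()].
#' @param alpha0 Strip activity (default -5).
#' @param Ws Strip width (default 50).
#' @param w_range Interface-width scan range (default c(8, 60)).
#' @param dx 1D grid spacing (default 0.25).
#' @param padding Padded length on each side of the strip, as a multiple of
#'   `Ws` (default 4).
#' @param tol Bisection tolerance on w (default 0.05).
#' @return List with `flipped`, `w_star`, `alpha_x_star`, and the scan table
#'   `scan` (tibble of w, alpha_x, D).
#' @export
flip_threshold <- function(params, alpha0 = -5, Ws = 50, w_range = c(8, 60),
                           dx = 0.25, padding = 4, tol = 0.05) {
  L <- Ws * (1 + 2 * padding)
  x <- seq(-L / 2, L / 2, by = dx)
  D_of_w <- function(w) {
    a <- alpha0 * logistic((Ws / 2 - abs(x)) / (w / 4))
    prof <- steady_state_solve(a, x, params)
    dipole_moment(prof$rho, x)
  }
  ws <- seq(w_range[1], w_range[2], length.out = 12)
  Ds <- vapply(ws, D_of_w, 0)
  scan <- tibble::tibble(w = ws, alpha_x = abs(alpha0) / ws, D = Ds)
  sgn <- sign(Ds)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0)
    return(list(flipped = FALSE, w_star = NA_real_,
                alpha_x_star = NA_real_, scan = scan))
  lo <- ws[flips[1]]; hi <- ws[flips[1] + 1]
  Dlo <- Ds[flips[1]]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    Dm <- D_of_w(mid)
    if (sign(Dm) == sign(Dlo)) { lo <- mid; Dlo <- Dm } else hi <- mid
  }
  w_star <- (lo + hi) / 2
  list(flipped = TRUE, w_star = w_star,
       alpha_x_star = abs(alpha0) / w_star, scan = scan)
}
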