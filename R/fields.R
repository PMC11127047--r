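#' Nematic order-parameter field
#'
#' The traceless-symmetric alignment tensor
#' \eqn{Q = [[q_{xx}, q_{xy}], [q_{xy}, -q_{xx}]]} on a periodic grid, stored
#' as its two independent components.  The scalar order parameter is
#' \eqn{S = 2\sqrt{q_{xx}^2 + q_{xy}^2}} (so \eqn{\mathrm{tr}[Q^2] = S^2/2})
#' and the director angle is
#' \eqn{\theta = \tfrac12 \mathrm{atan2}(q_{xy}, q_{xx})}.
#'
#' @param qxx,qxy Real `nx x ny` matrices.
#' @param grid A [grid_spec()] with matching dimensions.
#' @return An object of class `nematic_field`.
#' @export
nematic_field <- function(qxx, qxy, grid) {
  stopifnot(inherits(grid, "grid_spec"),
            is.matrix(qxx), is.matrix(qxy),
            all(dim(qxx) == c(grid$nx, grid$ny)),
            all(dim(qxy) == c(grid$nx, grid$ny)))
  check_finite(qxx, "qxx"); check_finite(qxy, "qxy")
  structure(list(qxx = qxx, qxy = qxy, grid = grid), class = "nematic_field")
}

#' @export
print.nematic_field <- function(x, ...) {
  cat(sprintf("<nematic_field> %d x %d, dx = %g, max S = %.4g\n",
              x$grid$nx, x$grid$ny, x$grid$dx, max(order_S(x))))
  invisible(x)
}

#' Scalar order parameter S of a nematic field
#' @param q A [nematic_field()].
#' @return Matrix of \eqn{S = 2\sqrt{q_{xx}^2+q_{xy}^2} \ge 0}.
#' @export
order_S <- function(q) 2 * sqrt(q$qxx^2 + q$qxy^2)

#' Director angle of a nematic field
#' @param q A [nematic_field()].
#' @return Matrix of angles \eqn{\theta \in (-\pi/2, \pi/2]}.
#' @export
director_angle <- function(q) {
  th <- 0.5 * atan2(q$qxy, q$qxx)
  # map -pi/2 to +pi/2 so the range is half-open as documented
  th[th <= -pi / 2 + 1e-15] <- pi / 2
  th
}

#' Uniformly ordered nematic state
#'
#' Ground state \eqn{Q = S_0(\hat n \hat n - I/2)} with
#' \eqn{S_0 = \sqrt{2 a_2/a_4}} and director at angle `theta0`.
#'
#' @param grid A [grid_spec()].
#' @param params A [model_params()].
#' @param theta0 Director angle (radians, default 0 = along x).
#' @return A [nematic_field()].
#' @export
uniform_nematic <- function(grid, params, theta0 = 0) {
  amp <- params$q_amp0
  nematic_field(matrix(amp * cos(2 * theta0), grid$nx, grid$ny),
                matrix(amp * sin(2 * theta0), grid$nx, grid$ny), grid)
}

#' Flow field on the grid
#'
#' @param ux,uy Velocity component matrices.
#' @param grid A [grid_spec()].
#' @param omega Optional vorticity \eqn{\omega = \partial_x u_y - \partial_y
#'   u_x}; computed spectrally when missing.
#' @param pressure Optional zero-mean pressure matrix.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(ux, uy, grid, omega = NULL, pressure = NULL) {
  stopifnot(inherits(grid, "grid_spec"),
            all(dim(ux) == c(grid$nx, grid$ny)),
            all(dim(uy) == c(grid$nx, grid$ny)))
  if (is.null(omega)) omega <- ddx(uy, grid) - ddy(ux, grid)
  if (is.null(pressure)) pressure <- matrix(0, grid$nx, grid$ny)
  structure(list(ux = ux, uy = uy, omega = omega, pressure = pressure,
                 grid = grid), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d, max |u| = %.4g\n",
              x$grid$nx, x$grid$ny, max(sqrt(x$ux^2 + x$uy^2))))
  invisible(x)
}

#' Stress tensor field
#'
#' A generally non-symmetric 2D stress tensor per grid node.  Active stress
#' (`tag = "active"`) is symmetric and traceless; the elastic stress carries
#' an antisymmetric part from the co-rotational coupling.
#'
#' @param sxx,sxy,syx,syy Component matrices.
#' @param grid A [grid_spec()].
#' @param tag Either `"active"` or `"elastic"`.
#' @return An object of class `stress_field`.
#' @export
stress_field <- function(sxx, sxy, syx, syy, grid, tag = c("elastic", "active")) {
  tag <- match.arg(tag)
  structure(list(sxx = sxx, sxy = sxy, syx = syx, syy = syy,
                 grid = grid, tag = tag), class = "stress_field")
}

# ---- local terms of the nematodynamic equations ----------------------------

#' Molecular field H
#'
#' \eqn{H = (a_2 - a_4 \mathrm{tr}[Q^2])\,Q + K \nabla^2 Q}, with the
#' Laplacian evaluated spectrally on the periodic grid.  H is
#' traceless-symmetric; only its `hxx`, `hxy` components are returned.
#'
#' @param q A [nematic_field()].
#' @param params A [model_params()].
#' @return A list with matrices `hxx`, `hxy`.
#' @export
molecular_field <- function(q, params) {
  check_finite(q$qxx); check_finite(q$qxy)
  trq2 <- 2 * (q$qxx^2 + q$qxy^2)
  pref <- params$a2 - params$a4 * trq2
  list(hxx = pref * q$qxx + params$elastic_K * laplacian(q$qxx, q$grid),
       hxy = pref * q$qxy + params$elastic_K * laplacian(q$qxy, q$grid))
}

#' Strain rate, vorticity tensor and scalar vorticity of a flow
#'
#' \eqn{E_{ij} = (\partial_i u_j + \partial_j u_i)/2} (traceless for
#' incompressible flow), \eqn{W_{ij} = (\partial_i u_j - \partial_j u_i)/2},
#' and \eqn{\omega = \hat z \cdot (\nabla \times u) = \partial_x u_y -
#' \partial_y u_x = 2 W_{xy}}.
#'
#' @param flow A [flow_field()].
#' @return List with strain components `exx`, `eyy`, `exy` (for incompressible
#'   flow `eyy = -exx`), `wxy` (\eqn{W_{xy} = \omega/2}) and `omega`.
#' @export
strain_vorticity <- function(flow) {
  g <- flow$grid
  duxx <- ddx(flow$ux, g); duxy <- ddy(flow$ux, g)
  duyx <- ddx(flow$uy, g); duyy <- ddy(flow$uy, g)
  list(exx = duxx, eyy = duyy,
       exy = 0.5 * (duxy + duyx),
       wxy = 0.5 * (duyx - duxy),
       omega = duyx - duxy)
}

#' Flow-coupling tensor S(u, Q)
#'
#' The generalized co-rotational advection of the alignment tensor,
#' \deqn{S_{ij} = Q_{ik}W_{kj} - W_{ik}Q_{kj} - 2\lambda Q_{kl}E_{kl} Q_{ij}
#'   + \lambda E_{ij} + \lambda(E_{ik}Q_{kj} + Q_{ik}E_{kj}
#'   - \delta_{ij} Q_{kl}E_{kl}),}
#' with E and W computed spectrally from the flow.  In 2D the final
#' bracket vanishes identically for traceless-symmetric Q and E.
#'
#' @param q A [nematic_field()].
#' @param flow A [flow_field()] on the same grid.
#' @param lambda Flow-alignment parameter.
#' @return List with matrices `sxx`, `sxy` (traceless-symmetric tensor).
#' @export
flow_coupling <- function(q, flow, lambda) {
  stopifnot(identical(dim(q$qxx), dim(flow$ux)))
  sv <- strain_vorticity(flow)
  exx <- 0.5 * (sv$exx - sv$eyy)  # deviatoric part (equals exx if div u = 0)
  qe <- 2 * (q$qxx * exx + q$qxy * sv$exy)
  om <- sv$omega
  list(sxx = -om * q$qxy - 2 * lambda * qe * q$qxx + lambda * exx,
       sxy = om * q$qxx - 2 * lambda * qe * q$qxy + lambda * sv$exy)
}

#' Elastic (passive liquid-crystal) stress
#'
#' \deqn{\sigma^{el}_{ij} = Q_{ik}H_{kj} - H_{ik}Q_{kj}
#'  - K\,\partial_i Q_{kl}\partial_j Q_{kl}
#'  + \lambda(2Q_{ij} + \delta_{ij}) Q_{kl}H_{kl}
#'  - \lambda H_{ik}(Q_{kj} + \tfrac12\delta_{kj})
#'  - \lambda (Q_{ik} + \tfrac12\delta_{ik}) H_{kj}.}
#' The Ericksen gradient term uses spectral gradients.
#'
#' @param q A [nematic_field()].
#' @param H Molecular field as returned by [molecular_field()].
#' @param params A [model_params()].
#' @return A [stress_field()] with `tag = "elastic"`.
#' @export
elastic_stress <- function(q, H, params) {
  g <- q$grid; K <- params$elastic_K; lam <- params$lambda
  dq1x <- ddx(q$qxx, g); dq1y <- ddy(q$qxx, g)
  dq2x <- ddx(q$qxy, g); dq2y <- ddy(q$qxy, g)
  qh <- 2 * (q$qxx * H$hxx + q$qxy * H$hxy)           # Q:H
  anti <- 2 * (q$qxx * H$hxy - q$qxy * H$hxx)         # (QH - HQ)_xy
  sxx <- -2 * K * (dq1x^2 + dq2x^2) + 2 * lam * qh * q$qxx - lam * H$hxx
  syy <- -2 * K * (dq1y^2 + dq2y^2) - 2 * lam * qh * q$qxx + lam * H$hxx
  sym_xy <- -2 * K * (dq1x * dq1y + dq2x * dq2y) +
    2 * lam * qh * q$qxy - lam * H$hxy
  stress_field(sxx, sym_xy + anti, sym_xy - anti, syy, g, tag = "elastic")
}

#' Active stress
#'
#' \eqn{\sigma^a = \alpha Q} pointwise; `alpha` is the dimensionless activity
#' (in units of \eqn{K\Gamma/\gamma}) sampled on the grid, and the stress is
#' returned in internal units (the conversion factor `params$stress_unit` is
#' applied).
#'
#' @param q A [nematic_field()].
#' @param alpha Activity matrix (dimensionless), or a scalar.
#' @param params A [model_params()]; if omitted the stress unit is taken as 1.
#' @return A [stress_field()] with `tag = "active"` (symmetric, traceless).
#' @export
active_stress <- function(q, alpha, params = NULL) {
  su <- if (is.null(params)) 1 else params$stress_unit
  if (length(alpha) == 1) alpha <- matrix(alpha, q$grid$nx, q$grid$ny)
  a <- alpha * su
  stress_field(a * q$qxx, a * q$qxy, a * q$qxy, -a * q$qxx, q$grid,
               tag = "active")
}

#' Divergence of a stress field
#'
#' Force density \eqn{F_j = \partial_i \sigma_{ij}} via spectral derivatives.
#'
#' @param s A [stress_field()].
#' @return List with matrices `fx`, `fy`.
#' @export
stress_divergence <- function(s) {
  g <- s$grid
  list(fx = ddx(s$sxx, g) + ddy(s$syx, g),
       fy = ddx(s$sxy, g) + ddy(s$syy, g))
}
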