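# Selection rule and response-coefficient machinery.  The frozen-texture
# measurements here are fast (a handful of Stokes solves on a relaxed pair
# texture); the full suite across harmonics runs in the acceptance tests.

test_that("measurement pair provides an isolated +/- pair with orientations", {
  p <- model_params()
  g <- grid_spec(128, 128, 0.5)
  mp <- measurement_pair(g, p, beta = 0.5)
  expect_equal(nrow(mp$defects), 2)
  expect_equal(sort(mp$defects$charge), c(-0.5, 0.5))
  b <- atan2(mp$defects$ey[1], mp$defects$ex[1])
  expect_lt(abs(atan2(sin(b - 0.5), cos(b - 0.5))), 0.05)
})

test_that("+1/2 self-propulsion is along the polarity; -1/2 response to
           uniform activity is far below the +1/2 control", {
  p <- model_params()
  g <- grid_spec(128, 128, 0.5)
  mp <- measurement_pair(g, p)
  dp <- mp$defects[mp$defects$charge > 0, ]
  dm <- mp$defects[mp$defects$charge < 0, ]
  rp <- defect_response(mp$q, harmonic_disc(0, R = 8, alpha0 = -0.5,
                                            center = c(dp$x, dp$y)),
                        c(dp$x, dp$y), p, mp$flow0)
  rm <- defect_response(mp$q, harmonic_disc(0, R = 8, alpha0 = -0.5,
                                            center = c(dm$x, dm$y)),
                        c(dm$x, dm$y), p, mp$flow0)
  ehat <- c(dp$ex, dp$ey)
  expect_gt(sum(rp$u0 * ehat) / rp$speed, 0.95)
  expect_lt(rm$speed, 0.05 * rp$speed)
})

test_that("response calibration returns finite coefficients and its
           composition rules are equivariant", {
  p <- model_params()
  cal <- calibrate_response(p, grid = grid_spec(128, 128, 0.5),
                            amplitudes = c(0.3, 0.6))
  expect_true(all(is.finite(c(cal$zeta1, cal$zeta2, cal$zeta3, cal$zeta4))))
  # +1/2 under uniform alpha: only V+ contributes; u0 along ehat
  drv <- list(alpha = -1, grad = c(0, 0), dbar2 = 0 + 0i, dbar3 = 0 + 0i)
  for (b in c(0, 1.2)) {
    e <- c(cos(b), sin(b))
    r <- response_coefficients(cal, 0.5, e, drv)
    expect_equal(r$u0, cal$zeta1 * (-1) * e)
    expect_equal(r$omega0, 0)
  }
  # alpha linear in x: Omega+ along x => omega0+ = zeta3 (grad x ehat)_z,
  # V- = 0
  drv2 <- list(alpha = 0, grad = c(0.2, 0), dbar2 = 0 + 0i, dbar3 = 0 + 0i)
  r2 <- response_coefficients(cal, 0.5, c(0, 1), drv2)
  expect_equal(r2$omega0, cal$zeta3 * 0.2 * 1)   # grad_x * e_y
  expect_equal(r2$u0, c(0, 0))
  r2m <- response_coefficients(cal, -0.5, exp(0i), drv2)
  expect_equal(r2m$u0, c(0, 0))   # V- needs curvature
  # quadrupolar curvature: -1/2 drift direction rotates with the Theta3
  # phase as Arg(Theta3) + Arg(V-)
  drv3 <- list(alpha = 0, grad = c(0, 0), dbar2 = 0.1 + 0i, dbar3 = 0 + 0i)
  for (ph in c(0, 2 * pi / 3, pi / 3)) {
    th3 <- exp(1i * ph)
    r3 <- response_coefficients(cal, -0.5, th3, drv3)
    expect_equal(atan2(r3$u0[2], r3$u0[1]),
                 Arg(th3 * cal$zeta2 * 0.1), tolerance = 1e-9)
  }
})

test_that("activity derivatives are exact for polynomial-in-box patterns", {
  g <- grid_spec(64, 64, 0.5)
  pos <- c(16, 16)
  # smooth single-mode field with known derivatives at pos
  kx <- 2 * pi / g$Lx
  a <- sin(kx * (g$X - pos[1]))
  drv <- activity_derivatives(a, g, pos)
  expect_equal(drv$alpha, 0, tolerance = 1e-9)
  expect_equal(drv$grad, c(kx, 0), tolerance = 1e-6)
  # dbar2 of sin(kx x) at the node: -(kx^2/4) * sin = 0; dbar3:
  # (d/dx)^3 sin = -kx^3 cos = -kx^3 at pos, complex /8
  expect_equal(drv$dbar2, 0 + 0i, tolerance = 1e-9)
  expect_equal(drv$dbar3, complex(real = -kx^3 / 8, imaginary = 0),
               tolerance = 1e-6)
})

test_that("tweezer drift reversal: quadrupole phase + pi reverses the
           -1/2 linear drift direction", {
  p <- model_params()
  g <- grid_spec(128, 128, 0.5)
  mp <- measurement_pair(g, p)
  dm <- mp$defects[mp$defects$charge < 0, ]
  pos <- c(dm$x, dm$y)
  d1 <- tweezer_drift(mp$q, pos, chi = 0.8, p, flow0 = mp$flow0)
  d2 <- tweezer_drift(mp$q, pos, chi = 0.8 + pi, p, flow0 = mp$flow0)
  ang <- abs(atan2(sin(d1$direction - d2$direction),
                   cos(d1$direction - d2$direction)))
  expect_gt(ang, pi - 0.2)   # antiparallel
  expect_equal(d1$speed, d2$speed, tolerance = 0.1)
})
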