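params16 <- model_params()
grid16 <- grid_spec(16, 16, 0.5)

random_q <- function(grid, sd = 0.2, seed = 1) {
  set.seed(seed)
  nematic_field(matrix(rnorm(grid$nx * grid$ny, sd = sd), grid$nx),
                matrix(rnorm(grid$nx * grid$ny, sd = sd), grid$nx), grid)
}

test_that("molecular field vanishes for the ground state and for Q = 0", {
  p <- params16
  q0 <- uniform_nematic(grid16, p)
  # ground state: tr[Q^2] = a2/a4
  expect_equal(2 * (q0$qxx[1, 1]^2 + q0$qxy[1, 1]^2), p$a2 / p$a4)
  H <- molecular_field(q0, p)
  expect_lt(max(abs(H$hxx)), 1e-13)
  expect_lt(max(abs(H$hxy)), 1e-13)
  qz <- nematic_field(matrix(0, 16, 16), matrix(0, 16, 16), grid16)
  Hz <- molecular_field(qz, p)
  expect_equal(max(abs(Hz$hxx)), 0)
})

test_that("molecular field matches (a2 - K k^2) q for a single mode and a
           finite-difference oracle", {
  p <- params16
  k <- 2 * pi / grid16$Lx * 2          # mode index 2
  eps <- 1e-4
  qxx <- eps * cos(k * grid16$X)
  q <- nematic_field(qxx, matrix(0, 16, 16), grid16)
  H <- molecular_field(q, p)
  expect_equal(H$hxx, (p$a2 - p$elastic_K * k^2) * qxx,
               tolerance = 1e-6)
  # independent finite-difference Laplacian oracle on a rough field
  qr <- random_q(grid16, sd = 0.05, seed = 7)
  qs <- nematic_field(bandlimited_field(grid16, 2, 0.1, 3),
                      bandlimited_field(grid16, 2, 0.1, 4), grid16)
  Hs <- molecular_field(qs, p)
  trq2 <- 2 * (qs$qxx^2 + qs$qxy^2)
  fd <- (p$a2 - p$a4 * trq2) * qs$qxx +
    p$elastic_K * fd_laplacian(qs$qxx, grid16$dx)
  # 5-point Laplacian truncation at the band limit: (k dx)^2/12 ~ 5%
  expect_equal(Hs$hxx, fd, tolerance = 0.08)
})

test_that("molecular field rejects non-finite input", {
  q <- random_q(grid16)
  q$qxx[3, 3] <- NaN
  expect_error(molecular_field(q, params16), "non-finite")
})

test_that("flow coupling: trivial limits and loop oracle", {
  p <- params16
  q <- random_q(grid16, sd = 0.1, seed = 2)
  zero_flow <- flow_field(matrix(0, 16, 16), matrix(0, 16, 16), grid16)
  S0 <- flow_coupling(q, zero_flow, p$lambda)
  expect_equal(max(abs(S0$sxx)), 0)
  # Q = 0 in shear: only the lambda E term survives
  qz <- nematic_field(matrix(0, 16, 16), matrix(0, 16, 16), grid16)
  ux <- 0.3 * sin(2 * pi * grid16$Y / grid16$Ly)
  fl <- flow_field(ux, matrix(0, 16, 16), grid16)
  sv <- strain_vorticity(fl)
  Ssh <- flow_coupling(qz, fl, p$lambda)
  expect_equal(Ssh$sxy, p$lambda * sv$exy, tolerance = 1e-12)
  # random small Q and band-limited u on 8x8: plain-loop contraction oracle
  g8 <- grid_spec(8, 8, 0.5)
  set.seed(5)
  q8 <- nematic_field(matrix(rnorm(64, sd = 0.1), 8),
                      matrix(rnorm(64, sd = 0.1), 8), g8)
  u8 <- flow_field(bandlimited_field(g8, 2, 0.2, 11),
                   bandlimited_field(g8, 2, 0.2, 12), g8)
  sv8 <- strain_vorticity(u8)
  exx_dev <- 0.5 * (sv8$exx - sv8$eyy)
  S8 <- flow_coupling(q8, u8, p$lambda)
  L8 <- loop_flow_coupling(q8$qxx, q8$qxy, exx_dev, sv8$exy, sv8$wxy,
                           p$lambda)
  expect_equal(S8$sxx, L8$sxx, tolerance = 1e-12)
  expect_equal(S8$sxy, L8$sxy, tolerance = 1e-12)
})

test_that("elastic stress: ground state is stress-free; loop oracle agrees;
           total elastic force vanishes on the torus", {
  p <- params16
  q0 <- uniform_nematic(grid16, p)
  s0 <- elastic_stress(q0, molecular_field(q0, p), p)
  expect_lt(max(abs(s0$sxx)), 1e-12)
  g8 <- grid_spec(8, 8, 0.5)
  set.seed(9)
  q8 <- nematic_field(bandlimited_field(g8, 2, 0.15, 21),
                      bandlimited_field(g8, 2, 0.15, 22), g8)
  H8 <- molecular_field(q8, p)
  s8 <- elastic_stress(q8, H8, p)
  dq1x <- actnem:::ddx(q8$qxx, g8); dq1y <- actnem:::ddy(q8$qxx, g8)
  dq2x <- actnem:::ddx(q8$qxy, g8); dq2y <- actnem:::ddy(q8$qxy, g8)
  L8 <- loop_elastic_stress(q8$qxx, q8$qxy, H8$hxx, H8$hxy,
                            dq1x, dq1y, dq2x, dq2y, p$elastic_K, p$lambda)
  expect_equal(s8$sxx, L8$sxx, tolerance = 1e-12)
  expect_equal(s8$sxy, L8$sxy, tolerance = 1e-12)
  expect_equal(s8$syx, L8$syx, tolerance = 1e-12)
  expect_equal(s8$syy, L8$syy, tolerance = 1e-12)
  # seeded defect texture: net elastic force integrates to zero by
  # periodicity
  pbig <- model_params()
  gb <- grid_spec(64, 64, 0.5)
  ch <- data.frame(charge = c(0.5, -0.5), x = c(8, 24), y = c(16, 16))
  qd <- seed_defect_texture(ch, gb, pbig, relax_steps = 5)
  sd_ <- elastic_stress(qd, molecular_field(qd, pbig), pbig)
  f <- stress_divergence(sd_)
  expect_lt(abs(mean(f$fx)), 1e-10 * max(abs(f$fx)))
  expect_gt(max(abs(f$fx)), 0)   # nonzero near the cores
})

test_that("active stress is alpha Q with the stress-unit conversion", {
  p <- params16
  q <- random_q(grid16, seed = 3)
  sa <- active_stress(q, -2, p)
  expect_equal(sa$sxx, -2 * p$stress_unit * q$qxx)
  expect_equal(sa$sxy, sa$syx)                     # symmetric
  expect_equal(sa$sxx + sa$syy, matrix(0, 16, 16)) # traceless
  # alpha = 0
  expect_equal(max(abs(active_stress(q, 0, p)$sxx)), 0)
  # linear ramp alpha with uniform Q: div sigma = (grad alpha) . Q
  q0 <- uniform_nematic(grid16, p)
  al <- 0.5 * sin(2 * pi * grid16$X / grid16$Lx)
  f <- stress_divergence(active_stress(q0, al, p))
  dax <- actnem:::ddx(al * p$stress_unit, grid16)
  expect_equal(f$fx, dax * q0$qxx[1, 1], tolerance = 1e-12)
  expect_equal(f$fy, dax * q0$qxy[1, 1], tolerance = 1e-12)
})

test_that("strain and vorticity: rigid rotation, pure shear, and the
           E + W = grad u reconstruction identity", {
  g <- grid16
  # pure shear u = (gdot y, 0): Exy = gdot/2, omega = -gdot (evaluated with
  # a periodic single-mode proxy at the band centre)
  gd <- 0.2
  ux <- gd * (g$Ly / (2 * pi)) * sin(2 * pi * g$Y / g$Ly)
  fl <- flow_field(ux, matrix(0, 16, 16), g)
  sv <- strain_vorticity(fl)
  ctr <- which.min(abs(g$y - 0))   # cos factor = 1 at y = 0
  expect_equal(sv$exy[1, ctr], gd / 2, tolerance = 1e-10)
  expect_equal(sv$omega[1, ctr], -gd, tolerance = 1e-10)
  # reconstruction: E + W = grad u exactly for band-limited u
  u1 <- bandlimited_field(g, 3, 0.2, 31)
  u2 <- bandlimited_field(g, 3, 0.2, 32)
  fl2 <- flow_field(u1, u2, g)
  s2 <- strain_vorticity(fl2)
  duxy <- actnem:::ddy(u1, g)   # d_y u_x = E_xy - W_xy
  expect_equal(s2$exy - s2$wxy, duxy, tolerance = 1e-12)
  duyx <- actnem:::ddx(u2, g)
  expect_equal(s2$exy + s2$wxy, duyx, tolerance = 1e-12)
  expect_equal(s2$omega, duyx - duxy, tolerance = 1e-12)
})

test_that("derived S and theta satisfy their range conventions", {
  q <- random_q(grid16, seed = 8)
  S <- order_S(q)
  th <- director_angle(q)
  expect_true(all(S >= 0))
  expect_true(all(th > -pi / 2 & th <= pi / 2))
  expect_equal(S^2 / 2, 2 * (q$qxx^2 + q$qxy^2))  # tr[Q^2] = S^2/2
})
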