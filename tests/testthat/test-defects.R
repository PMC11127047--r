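p_d <- model_params()
g128 <- grid_spec(128, 128, 0.5)

test_that("uniform nematic contains no defects", {
  q <- uniform_nematic(g128, p_d, theta0 = 0.7)
  expect_equal(nrow(detect_defects(q)), 0)
  expect_equal(total_charge(detect_defects(q)), 0)
})

test_that("seeded pair is detected with correct charges, positions and
           symmetry indices", {
  ch <- data.frame(charge = c(0.5, -0.5), x = c(16, 48), y = c(32, 32))
  q <- seed_defect_texture(ch, g128, p_d, relax_steps = 10)
  d <- detect_defects(q)
  expect_equal(nrow(d), 2)
  expect_equal(sort(d$charge), c(-0.5, 0.5))
  expect_equal(total_charge(d), 0)
  expect_equal(d$s[d$charge > 0], 1L)
  expect_equal(d$s[d$charge < 0], 3L)
  for (k in 1:2) {
    i <- which.min(abs(d$x - ch$x[k]))
    expect_lt(abs(d$x[i] - ch$x[k]), 1)
    expect_lt(abs(d$y[i] - ch$y[k]), 1)
  }
  expect_error(seed_defect_texture(data.frame(charge = 0.5, x = 10, y = 10),
                                   g128, p_d), "total charge")
})

test_that("detection-position accuracy over random placements", {
  set.seed(21)
  for (rep in 1:5) {
    # seed on grid nodes so the construction itself is exact and the
    # measured offset is detector precision plus brief relaxation drift
    x1 <- round(runif(1, 12, 20) * 2) / 2
    y1 <- round(runif(1, 24, 40) * 2) / 2
    ch <- data.frame(charge = c(0.5, -0.5),
                     x = c(x1, x1 + 32), y = c(y1, y1))
    q <- seed_defect_texture(ch, g128, p_d, relax_steps = 5)
    d <- detect_defects(q)
    expect_equal(nrow(d), 2)
    for (k in 1:2) {
      dd <- sqrt(min((d$x - ch$x[k])^2 + (d$y - ch$y[k])^2))
      expect_lt(dd, 0.45)   # within a grid cell of the seeded core
    }
  }
})

test_that("quadrupole seeding yields four defects of zero total charge", {
  ch <- data.frame(charge = c(0.5, 0.5, -0.5, -0.5),
                   x = c(16, 48, 16, 48), y = c(16, 48, 48, 16))
  q <- seed_defect_texture(ch, g128, p_d, relax_steps = 10)
  d <- detect_defects(q)
  expect_equal(nrow(d), 4)
  expect_equal(total_charge(d), 0)
})

test_that("polarity equivariance: seeded orientation is measured back and
           rotating the texture rotates e-hat", {
  angles <- seq(-pi, pi, length.out = 13)[-13]
  ch0 <- data.frame(charge = c(0.5, -0.5), x = c(16, 48), y = c(32, 32),
                    angle = c(0, NA))
  for (b in angles[seq(1, 12, by = 3)]) {
    ch0$angle[1] <- b
    q <- seed_defect_texture(ch0, g128, p_d)
    d <- detect_defects(q)
    i <- which(d$charge > 0)
    err <- abs(atan2(sin(atan2(d$ey[i], d$ex[i]) - b),
                     cos(atan2(d$ey[i], d$ex[i]) - b)))
    expect_lt(err, 2 * pi / 180)   # within 2 degrees
  }
})

test_that("triatic orientation: unit modulus, 2pi/3 symmetry and weight-3
           equivariance", {
  ch <- data.frame(charge = c(0.5, -0.5), x = c(16, 48), y = c(32, 32),
                   angle = c(NA, 0))
  q <- seed_defect_texture(ch, g128, p_d)
  d <- detect_defects(q)
  m <- d[d$charge < 0, ]
  z <- complex(real = m$re_theta3, imaginary = m$im_theta3)
  expect_equal(Mod(z), 1, tolerance = 1e-9)
  expect_lt(abs(Arg(z)), 3 * pi / 180)   # one axis along +x => Theta3 = 1
  # rotating the seeded axis by 2pi/3 leaves Theta3 unchanged; by beta
  # multiplies it by exp(3 i beta) (check at beta = pi/6 => phase pi/2)
  for (case in list(c(2 * pi / 3, 0), c(pi / 6, pi / 2))) {
    ch$angle[2] <- case[1]
    q2 <- seed_defect_texture(ch, g128, p_d)
    m2 <- detect_defects(q2)
    m2 <- m2[m2$charge < 0, ]
    z2 <- complex(real = m2$re_theta3, imaginary = m2$im_theta3)
    dphase <- Arg(z2 * Conj(z)) - case[2]
    expect_lt(abs(atan2(sin(dphase), cos(dphase))), 4 * pi / 180)
  }
})

test_that("core flow interpolation is exact for an analytic field and
           wraps periodically", {
  g <- grid_spec(64, 64, 0.5)
  ux <- sin(2 * pi * g$X / g$Lx) * cos(2 * pi * g$Y / g$Ly)
  fl <- flow_field(ux, 0.5 * ux, g)
  pos <- cbind(c(7.3, 31.9, -1.0), c(12.1, 0.2, 63.5))
  cf <- core_flow(fl, pos)
  exact <- sin(2 * pi * pos[, 1] / g$Lx) * cos(2 * pi * pos[, 2] / g$Ly)
  expect_equal(cf$u0[, 1], exact, tolerance = 5e-3)
  expect_equal(cf$u0[, 2], 0.5 * exact, tolerance = 5e-3)
  # wrap: x = -1 equals x = 31 (Lx = 32)
  cf2 <- core_flow(fl, c(-1 + g$Lx, 63.5))
  expect_equal(cf$u0[3, ], as.numeric(cf2$u0), tolerance = 1e-12)
})

test_that("passive pair attraction: separation is non-increasing", {
  ch <- data.frame(charge = c(0.5, -0.5), x = c(24, 40), y = c(32, 32))
  q <- seed_defect_texture(ch, g128, p_d, relax_steps = 10)
  st <- init_state(q, p_d)
  cfg <- solver_config(128, 128, 0.5, n_steps = 150)
  seps <- c()
  for (b in 1:3) {
    r <- run_protocol(st, NULL, cfg)
    st <- r$final
    d <- detect_defects(st$q)
    expect_equal(nrow(d), 2)
    seps <- c(seps, sqrt(diff(d$x)^2 + diff(d$y)^2))
  }
  expect_true(all(diff(seps) < 0.2))   # non-increasing up to jitter
})

test_that("trajectory linking: drift, annihilation event, and the
           adversarial swap is not mislinked", {
  g <- grid_spec(64, 64, 0.5)
  # single drifting defect
  det1 <- dplyr::bind_rows(lapply(1:10, function(f)
    tibble::tibble(frame = f, time = f * 1.0, x = 5 + 0.5 * f, y = 10,
                   charge = 0.5)))
  tr1 <- link_trajectories(det1, g, max_disp = 1)
  expect_equal(length(unique(tr1$trajectories$id)), 1)
  # pair that annihilates: both vanish at frame 6 within the pair radius
  det2 <- dplyr::bind_rows(lapply(1:5, function(f) tibble::tibble(
    frame = f, time = f, x = c(10 + 0.4 * f, 14 - 0.4 * f), y = c(20, 20),
    charge = c(0.5, -0.5))))
  det2 <- dplyr::bind_rows(det2, tibble::tibble(frame = 6, time = 6,
                                                x = 30, y = 30,
                                                charge = 0.5))
  det2 <- dplyr::bind_rows(det2, tibble::tibble(frame = 5.5 * 0 + 6,
                                                time = 6, x = 30.5, y = 31,
                                                charge = -0.5))
  tr2 <- link_trajectories(det2, g, max_disp = 1)
  ev <- tr2$events
  expect_true(any(ev$kind == "annihilation"))
  # two defects swapping positions in one frame with max_disp smaller than
  # the swap distance: tracks break, no erroneous exchange
  det3 <- tibble::tibble(frame = c(1, 1, 2, 2), time = c(1, 1, 2, 2),
                         x = c(10, 20, 15.2, 24.8), y = c(5, 5, 5, 5),
                         charge = c(-0.5, -0.5, -0.5, -0.5))
  tr3 <- link_trajectories(det3, g, max_disp = 4)
  expect_equal(length(unique(tr3$trajectories$id)), 4)
})

test_that("turbulent snapshots conserve total charge frame by frame", {
  p2 <- model_params(l_eta = 2)
  g <- grid_spec(96, 96, 0.5)
  cfg <- solver_config(96, 96, 0.5, n_steps = 1500, seed = 5,
                       noise_amplitude = 0.15)
  qi <- perturbed_state(g, p2, cfg, base = "isotropic")
  frame_charges <- c()
  counts <- c()
  cb <- function(s) {
    d <- detect_defects(s$q, orientations = FALSE)
    frame_charges <<- c(frame_charges, total_charge(d))
    counts <<- c(counts, nrow(d))
    NULL
  }
  run_protocol(init_state(qi, p2, -5), -5, cfg, snapshot_stride = 250,
               callback = cb)
  expect_true(all(abs(frame_charges) < 1e-9))
  expect_gt(utils::tail(counts, 1), 0)   # sustained defect gas
})
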