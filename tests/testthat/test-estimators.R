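test_that("dipole estimator reproduces the hand integral for point
           charges and vanishes for mirror-symmetric configurations", {
  g <- grid_spec(128, 64, 0.5)   # Lx = 64, Ly = 32
  a <- 10
  det <- tibble::tibble(frame = 1, time = 0,
                        x = 32 + c(a, 0), charge = c(0.5, -0.5))
  ds <- dipole_from_trajectories(det, g, strip_center = 32, bin_dx = 2,
                                 steady_frac = 0)
  # rho bins: +1/2 at |x| = a, -1/2 at 0: D = 0.5 * (0.5 * a)/Ly (up to the
  # bin-centre offset)
  expect_equal(ds$series$D[1], 0.5 * 0.5 * a / g$Ly, tolerance = 0.15)
  # mirror pairs cancel (offsets chosen inside bins, away from bin edges)
  det2 <- tibble::tibble(frame = 1, time = 0,
                         x = 32 + c(10.5, -10.5, 5.5, -5.5),
                         charge = c(0.5, 0.5, -0.5, -0.5))
  ds2 <- dipole_from_trajectories(det2, g, strip_center = 32, bin_dx = 2,
                                  steady_frac = 0)
  expect_gt(ds2$series$D[1], 0)   # + outside - => positive
  det3 <- det2; det3$charge <- c(0.5, -0.5, -0.5, 0.5)
  ds3 <- dipole_from_trajectories(det3, g, strip_center = 32, bin_dx = 2,
                                  steady_frac = 0)
  expect_equal(ds3$series$D[1], 0, tolerance = 1e-12)
})

test_that("dipole estimator is Monte-Carlo consistent with the continuum
           dipole of a known charge density", {
  set.seed(31)
  g <- grid_spec(256, 64, 0.5)   # Lx = 128, Ly = 32
  bin_dx <- 2
  edges <- seq(-g$Lx / 2, g$Lx / 2, by = bin_dx)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  rho_fun <- function(x) 0.02 * (abs(x) > 20 & abs(x) < 30) -
    0.04 * (abs(x) < 10)
  D_true <- dipole_moment(rho_fun(mids), mids)
  # per frame, draw Poisson counts with mean |rho| * bin * Ly per bin and
  # sign(rho) charges: the estimator's binned density is unbiased for rho
  det <- purrr::map_dfr(1:300, function(f) {
    n_b <- stats::rpois(length(mids), abs(rho_fun(mids)) * bin_dx * g$Ly)
    keep <- n_b > 0
    tibble::tibble(frame = f, time = f,
                   x = 64 + rep(mids[keep], n_b[keep]),
                   charge = 0.5 * sign(rho_fun(rep(mids[keep], n_b[keep]))))
  })
  # charges are +/-1 in the continuum density; estimator bins nu = +/-1/2
  ds <- dipole_from_trajectories(det, g, strip_center = 64, bin_dx = bin_dx,
                                 steady_frac = 0)
  expect_equal(mean(ds$series$D), D_true / 2, tolerance = 0.05)
})

test_that("polarization and leak counting", {
  d0 <- tibble::tibble(x = numeric(0), charge = numeric(0),
                       ex = numeric(0), ey = numeric(0))
  expect_equal(unname(polarization_total(d0)), c(0, 0))
  d <- tibble::tibble(x = c(1, 2, 3), charge = c(0.5, 0.5, -0.5),
                      ex = c(-1, -1, NA), ey = c(0, 0, NA))
  expect_equal(polarization_total(d)[["Px"]], -2)
  g <- grid_spec(128, 64, 0.5)
  dd <- tibble::tibble(x = c(32, 50, 10), time = 0)
  expect_equal(leak_count(dd, g, X0 = 32, Ws = 20, w = 4), 2L)
  expect_equal(leak_count(d0, g, X0 = 32, Ws = 20, w = 4), 0L)
})

test_that("crossing counter: parallel lines, single exchange, agreement
           with the brute-force oracle on random walks", {
  mk <- function(id, xs, ys = 0) tibble::tibble(
    frame = seq_along(xs), time = seq_along(xs), id = id, x = xs,
    y = ys + 0 * xs, charge = 0.5)
  two <- dplyr::bind_rows(mk(1, rep(0, 10)), mk(2, rep(5, 10)))
  expect_equal(braid_crossings(two)$count, 0)
  swap <- dplyr::bind_rows(mk(1, seq(0, 10, length.out = 11)),
                           mk(2, seq(10, 0, length.out = 11)))
  expect_equal(braid_crossings(swap)$count, 1)
  set.seed(41)
  rw <- purrr::map_dfr(1:5, function(id) {
    x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
    tibble::tibble(frame = 1:40, time = 1:40, id = id, x = x, y = y,
                   charge = 0.5)
  })
  expect_equal(braid_crossings(rw)$count, brute_crossings(rw))
})

test_that("active-Brownian tracks recover Da = v^2 tau_R / 2 within 10%", {
  v <- 0.4; tau_R <- 8
  tracks <- simulate_abp_tracks(n_tracks = 500, n_frames = 40,
                                dt_frame = 1, v = v, tau_R = tau_R,
                                seed = 17)
  fit <- estimate_diffusion(tracks, max_lag = 15)
  Da_true <- v^2 * tau_R / 2
  expect_lt(abs(fit$Da - Da_true) / Da_true, 0.10)
  expect_lt(abs(fit$tau_R - tau_R) / tau_R, 0.15)
  expect_false(fit$nondecay)
  expect_gt(fit$sd_Da, 0)
})

test_that("diffusion estimator flags ballistic tracks and refuses
           insufficient statistics", {
  tracks <- simulate_abp_tracks(20, 10, 1, v = 0.3, tau_R = 1e6, seed = 2)
  fit <- estimate_diffusion(tracks, min_segments = 50)
  expect_true(fit$nondecay)
  expect_error(estimate_diffusion(tracks[tracks$id <= 2, ]),
               "insufficient")
})

test_that("sinusoid fit recovers parameters exactly for a pure sinusoid,
           within 10% at SNR 3, and flags constant input", {
  f <- 0.01
  t <- seq(0, 10 / f, by = 5)
  D <- 0.3 + 0.2 * sin(2 * pi * f * (t - 30))
  fit <- sinusoid_fit(t, D, f)
  expect_equal(fit$D_bar, 0.3, tolerance = 1e-9)
  expect_equal(fit$Delta_D, 0.2, tolerance = 1e-9)
  expect_equal(fit$tau_D, 30, tolerance = 1e-6)
  set.seed(8)
  Dn <- D + rnorm(length(t), sd = 0.2 / 3)
  fitn <- sinusoid_fit(t, Dn, f)
  expect_lt(abs(fitn$D_bar - 0.3) / 0.3, 0.1)
  expect_lt(abs(fitn$Delta_D - 0.2) / 0.2, 0.1)
  expect_lt(abs(fitn$tau_D - 30), 0.1 / f / (2 * pi) * 2)
  fit0 <- sinusoid_fit(t, rep(0.5, length(t)), f)
  expect_true(fit0$degenerate)
  expect_true(is.na(fit0$tau_D))
  td <- tidy(fitn); gl <- glance(fitn)
  expect_equal(td$term, c("D_bar", "Delta_D", "tau_D"))
  expect_true(gl$r.squared > 0.7)
})
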