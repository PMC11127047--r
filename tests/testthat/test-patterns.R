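g32 <- grid_spec(64, 64, 0.5)

test_that("tweezer profile implements the quadrupolar disc and its
           constraints", {
  tw <- tweezer(-1, R = 5, center = c(16, 16), A = 0, B = 0)
  a <- sample_pattern(tw, g32, 0)
  pol <- actnem:::polar_about(g32, c(16, 16))
  expect_true(all(a[pol$r > 5] == 0))
  expect_true(all(abs(a[pol$r <= 5] + 1) < 1e-12))
  # (A,B) = (1,0) at phi = 3*pi/4: alpha = alpha0 (1 + sin(3 pi/2)) = 0
  tw2 <- tweezer(-1, R = 5, center = c(16, 16), A = 1, B = 0)
  a2 <- sample_pattern(tw2, g32, 0)
  probe <- c(16 + 2 * cos(3 * pi / 4), 16 + 2 * sin(3 * pi / 4))
  i <- round(probe / 0.5) + 1
  expect_lt(abs(a2[i[1], i[2]]), 0.05)   # grid-sampled near the zero locus
  # sign constancy for valid specs over the sampled support
  expect_true(all(a2 <= 1e-12))
  expect_error(tweezer(-1, 5, c(16, 16), A = 0.8, B = 0.8), "sign")
  expect_warning(tweezer(-2, 20, c(16, 16), params = model_params()),
                 "bound")
})

test_that("harmonic discs: n = 0 radial symmetry, n = 2 equals the B = 1
           tweezer, offset bookkeeping", {
  h0 <- harmonic_disc(0, R = 6, alpha0 = -1, center = c(16, 16))
  a0 <- sample_pattern(h0, g32, 0)
  pol <- actnem:::polar_about(g32, c(16, 16))
  expect_true(all(a0[pol$r <= 6] == -1))
  h2 <- harmonic_disc(2, phase = 0, R = 6, alpha0 = -1, center = c(16, 16))
  tw <- tweezer(-1, R = 6, center = c(16, 16), A = 0, B = 1)
  expect_equal(sample_pattern(h2, g32, 0), sample_pattern(tw, g32, 0))
  expect_true(harmonic_disc(1, R = 4, alpha0 = -1, center = c(8, 8),
                            include_offset = FALSE)$sign_constant == FALSE)
})

test_that("strip: interior plateau, exact interfacial slope alpha0/w,
           interface-overlap warning", {
  s <- strip(Ws = 50, w = 15, alpha0 = -5, X0 = 64)
  gx <- grid_spec(256, 8, 0.5)
  a <- sample_pattern(s, gx, 0)
  # logistic tails: interior value -5 * sigma(2 Ws/w) = -4.9934
  expect_lt(a[which.min(abs(gx$x - 64)), 1], -4.99)
  # analytic slope of the logistic with delta = w/4 at |x - X0| = Ws/2
  f <- function(x) -5 * actnem:::logistic((25 - abs(x - 64)) / (15 / 4))
  h <- 1e-5
  slope <- (f(64 + 25 + h) - f(64 + 25 - h)) / (2 * h)
  expect_equal(abs(slope), 5 / 15, tolerance = 1e-6)
  expect_equal(s$meta$alpha_x, 5 / 15)
  expect_warning(strip(50, 40, -5, X0 = 64), "overlap")
})

test_that("oscillating and traveling strips reduce to the static strip in
           their trivial limits", {
  g <- grid_spec(128, 8, 0.5)
  st <- strip(20, 10, -4, X0 = 32)
  osc <- oscillating_strip(20, 10, 10, f = 0.01, alpha0 = -4, X0 = 32)
  expect_equal(sample_pattern(osc, g, 0), sample_pattern(st, g, 0))
  expect_equal(osc$meta$w_bar, 10)
  osc2 <- oscillating_strip(20, 15, 35, f = 0.01, alpha0 = -4, X0 = 32)
  expect_equal(osc2$meta$w_bar, 25)   # (wmin + wmax)/2
  trv <- traveling_strip(20, 10, -4, V = 0, X0 = 32)
  for (t in c(0, 7, 30))
    expect_equal(sample_pattern(trv, g, t), sample_pattern(st, g, t))
  trv2 <- traveling_strip(20, 10, -4, V = 2, X0 = 32)
  a_shift <- sample_pattern(trv2, g, 5)          # moved by 10
  expect_equal(a_shift, sample_pattern(strip(20, 10, -4, X0 = 42), g, 0),
               tolerance = 1e-12)
})

test_that("nucleation patch: ramp schedule and elliptic support", {
  np <- nucleation_patch(c(16, 16), axes = c(4, 2), orientation = 0,
                         alpha_peak = -8, ramp_time = 10, t_off = 20,
                         release_time = 5)
  expect_equal(max(abs(sample_pattern(np, g32, -1))), 0)
  a5 <- sample_pattern(np, g32, 5)
  expect_equal(min(a5), -4, tolerance = 1e-9)      # half ramp
  a15 <- sample_pattern(np, g32, 15)
  expect_equal(min(a15), -8, tolerance = 1e-9)     # held
  expect_equal(max(abs(sample_pattern(np, g32, 40))), 0)  # released
  # support: inside ellipse only (major axis along x)
  expect_lt(a15[round(19 / 0.5) + 1, round(16 / 0.5) + 1], -7)  # (19,16) in
  expect_equal(a15[round(16 / 0.5) + 1, round(19 / 0.5) + 1], 0)  # (16,19) out
  # step ramp
  np0 <- nucleation_patch(c(16, 16), c(4, 2), 0, alpha_peak = -8,
                          ramp_time = 0)
  expect_equal(min(sample_pattern(np0, g32, 1e-9)), -8)
})

test_that("superpose sums pointwise and a pattern plus its negation
           cancels", {
  p1 <- harmonic_disc(0, R = 4, alpha0 = -1, center = c(8, 8))
  p2 <- strip(10, 4, -2, X0 = 20)
  sup <- superpose(p1, p2)
  expect_equal(sample_pattern(sup, g32, 0),
               sample_pattern(p1, g32, 0) + sample_pattern(p2, g32, 0))
  zero <- superpose(p1, scale_pattern(p1, -1))
  expect_equal(max(abs(sample_pattern(zero, g32, 0))), 0)
})

test_that("selection rule table |s-n| = 1 (translate) / 0 (rotate)", {
  expect_equal(predicted_mobility(1, 0), list(can_translate = TRUE,
                                              can_rotate = FALSE))
  expect_equal(predicted_mobility(3, 0), list(can_translate = FALSE,
                                              can_rotate = FALSE))
  expect_equal(predicted_mobility(1, 1), list(can_translate = FALSE,
                                              can_rotate = TRUE))
  expect_equal(predicted_mobility(3, 3), list(can_translate = FALSE,
                                              can_rotate = TRUE))
  pm <- predicted_mobility(c(1, 3), c(2, 2))
  expect_true(all(pm$can_translate))
})

test_that("disjoint tweezers have exponentially screened cross-talk", {
  p <- model_params()   # l_eta = 5
  g <- grid_spec(128, 128, 0.5)
  set.seed(12)
  q <- nematic_field(matrix(rnorm(128^2, sd = 0.2), 128),
                     matrix(rnorm(128^2, sd = 0.2), 128), g)
  tw1 <- harmonic_disc(0, R = 4, alpha0 = -1, center = c(16, 32))
  f0 <- solve_flow(q, 0, p)
  fl1 <- solve_flow(q, sample_pattern(tw1, g, 0), p)
  # activity-driven flow decays with distance on the screening scale (the
  # texture's passive elastic flow is differenced out)
  sp <- sqrt((fl1$ux - f0$ux)^2 + (fl1$uy - f0$uy)^2)
  pol <- actnem:::polar_about(g, c(16, 32))
  near <- max(sp[pol$r < 8])
  far <- max(sp[pol$r > 8 + 3 * p$l_eta])
  expect_lt(far, near * exp(-1.5))
})
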