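test_that("RF operator limits: identity, rotation block, scalar saturation", {
  wm <- wm_tissue()
  p0 <- gaussian_subpulse(0, 2e-3)
  expect_equal(rf_operator(p0, wm), diag(6))
  # free block equals the standard x-rotation for a real pulse
  a <- 40 * pi / 180
  p <- make_multiband(a, 2e-3, 5e-3, 0, "1B", dt = 1e-5)
  R <- rf_operator(p, wm)
  rot <- rbind(c(1, 0, 0),
               c(0, cos(a), sin(a)),
               c(0, -sin(a), cos(a)))
  expect_equal(R[1:3, 1:3], rot, tolerance = 1e-12)
  # semisolid block of a 1B pulse is a scalar exponential on both Zeeman
  # pools (dipolar row untouched)
  W <- saturation_rate(p$band_mean_square, 0, wm$lineshape)
  expect_equal(R[4, 4], exp(-W * p$tau), tolerance = 1e-12)
  expect_equal(R[5, 5], exp(-W * p$tau), tolerance = 1e-12)
  expect_equal(R[6, 6], 1)
  expect_true(R[4, 4] < 1)
})

test_that("relaxation propagator: identity at t=0, fixed point, Bloch limit", {
  wm <- wm_tissue()
  ro0 <- relax_operator(wm, 0)
  expect_equal(ro0$S, diag(6), tolerance = 1e-14)
  expect_equal(ro0$drift, rep(0, 6), tolerance = 1e-14)
  lc <- bmp_lambda(wm)
  ro <- relax_operator(wm, 3e-3)
  expect_equal(as.numeric(ro$S %*% lc$M_eq + ro$drift), lc$M_eq,
               tolerance = 1e-12)
  # single-pool Mz recovery matches the closed form
  sp <- single_pool()
  M0 <- c(0, 0, 0.2, 0, 0, 0)
  ro <- relax_operator(sp, 50e-3)
  expect_equal((ro$S %*% M0 + ro$drift)[3],
               1 - (1 - 0.2) * exp(-sp$R1f * 50e-3), tolerance = 1e-12)
})

test_that("SPGR reduces to the Ernst formula and peaks at the Ernst angle", {
  sp <- single_pool()
  sq <- seq_settings("spgr", TR = 5e-3, tau = 2e-3, TE = 0)
  flips <- seq(2, 20, by = 0.1)
  sig <- vapply(flips, function(f) {
    p <- make_multiband(f * pi / 180, 2e-3, 5e-3, 0, "1B", dt = 1e-5)
    spgr_steady_state(p, sp, sq)$signal
  }, numeric(1))
  expect_equal(sig, ernst_signal(flips * pi / 180, 5e-3, sp$R1f),
               tolerance = 1e-10)
  ernst_deg <- acos(exp(-5e-3 * sp$R1f)) * 180 / pi
  expect_equal(flips[which.max(sig)], ernst_deg, tolerance = 0.1)
  expect_equal(round(ernst_deg, 1), 7.1)
  # zero flip gives zero signal
  p0 <- make_multiband(0, 2e-3, 5e-3, 0, "1B", dt = 1e-5)
  expect_equal(spgr_steady_state(p0, wm_tissue(), sq)$signal, 0)
})

test_that("bSSFP reduces to the single-pool closed form over 10-80 deg", {
  sp <- single_pool()
  sq <- seq_settings("bssfp", TR = 5e-3, tau = 2e-3)
  for (f in seq(10, 80, by = 10)) {
    a <- f * pi / 180
    p <- make_multiband(a, 2e-3, 5e-3, 0, "1B", dt = 1e-5)
    expect_equal(bssfp_steady_state(p, sp, sq)$signal,
                 bssfp_closed_form(a, 5e-3, sp$R1f, sp$R2f),
                 tolerance = 1e-10)
  }
  p0 <- make_multiband(0, 2e-3, 5e-3, 0, "1B", dt = 1e-5)
  expect_equal(bssfp_steady_state(p0, wm_tissue(), sq)$signal, 0,
               tolerance = 1e-12)
})

test_that("steady states are fixed points of one full TR cycle", {
  wm <- wm_tissue()
  ps <- fig_pulses(30)
  sqs <- seq_settings("spgr", TR = 5e-3, tau = 2e-3, TE = 0)
  M <- spgr_steady_state(ps$p2, wm, sqs)$M
  ro <- relax_operator(wm, 5e-3)
  R <- rf_operator(ps$p2, wm)
  Phi <- diag(c(0, 0, 1, 1, 1, 1))
  M1 <- as.numeric(R %*% Phi %*% (ro$S %*% M + ro$drift))
  expect_equal(M1, M, tolerance = 1e-10)
  sqb <- seq_settings("bssfp", TR = 5e-3, tau = 2e-3)
  Mb <- bssfp_steady_state(ps$p2, wm, sqb)$M
  roh <- relax_operator(wm, 2.5e-3)
  Phib <- diag(c(-1, -1, 1, 1, 1, 1))
  M2 <- as.numeric(roh$S %*% (R %*% (Phib %*%
          (roh$S %*% Mb + roh$drift))) + roh$drift)
  expect_equal(M2, Mb, tolerance = 1e-10)
})

test_that("band symmetries of the steady-state model", {
  wm <- wm_tissue()
  sqb <- seq_settings("bssfp", TR = 5e-3, tau = 2e-3)
  a <- 30 * pi / 180
  p2p <- make_multiband(a, 2e-3, 5e-3, 2 * pi * 7e3, "2B_plus",
                        target_b1rms = 5, dt = 1e-5)
  p2m <- make_multiband(a, 2e-3, 5e-3, 2 * pi * 7e3, "2B_minus",
                        target_b1rms = 5, dt = 1e-5)
  expect_equal(bssfp_steady_state(p2p, wm, sqb)$signal,
               bssfp_steady_state(p2m, wm, sqb)$signal, tolerance = 1e-12)
  # S3B = S2B when delta = 0; S3B < S2B when delta > 0
  ps <- fig_pulses(30)
  wm0 <- wm_tissue(delta = 0)
  s2_0 <- bssfp_steady_state(ps$p2, wm0, sqb)$signal
  s3_0 <- bssfp_steady_state(ps$p3, wm0, sqb)$signal
  # equal up to the sub-1e-5 off-band power difference left by the
  # exact-B1rms cross-term renormalization
  expect_equal(s3_0, s2_0, tolerance = 1e-5)
  wm1 <- wm_tissue(delta = 1)
  s2_1 <- bssfp_steady_state(ps$p2, wm1, sqb)$signal
  s3_1 <- bssfp_steady_state(ps$p3, wm1, sqb)$signal
  expect_lt(s3_1, s2_1)
  # S3B independent of delta and of the dipolar relaxation rate
  s3_a <- bssfp_steady_state(ps$p3, wm_tissue(), sqb)$signal
  s3_b <- bssfp_steady_state(ps$p3, wm_tissue(R1Ds = 10), sqb)$signal
  s3_c <- bssfp_steady_state(ps$p3, wm_tissue(delta = 0.1), sqb)$signal
  expect_equal(s3_a, s3_b, tolerance = 1e-10)
  expect_equal(s3_a, s3_c, tolerance = 1e-10)
})

test_that("finite-pulse R2 correction obeys its contract", {
  expect_equal(bieri_scheffler_r2(1.54, 12.5, 0, 5e-3), 12.5)
  taus <- seq(2e-4, 2.5e-3, by = 1e-4)
  r2c <- vapply(taus, function(t) bieri_scheffler_r2(1.54, 12.5, t, 5e-3),
                numeric(1))
  expect_true(all(r2c < 12.5))
  expect_true(all(diff(r2c) < 0))
  expect_error(bieri_scheffler_r2(1.54, 12.5, 6e-3, 5e-3), "tau")
  # equivalent rectangular duration of the Gaussian sub-pulse ~ 0.59 tau
  p <- gaussian_subpulse(pi / 4, 2e-3)
  expect_equal(equivalent_duration(p) / 2e-3, 0.589, tolerance = 0.01)
  expect_equal(equivalent_duration(gaussian_subpulse(0, 2e-3)), 0)
})
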