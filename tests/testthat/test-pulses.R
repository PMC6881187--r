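test_that("gaussian sub-pulse calibration, zero case and linearity", {
  p0 <- gaussian_subpulse(0, 2.2e-3)
  expect_true(all(Mod(p0$samples) == 0))
  p <- gaussian_subpulse(pi / 6, 2.2e-3)
  expect_equal(GAMMA_1H * sum(Re(p$samples)) * p$dt, pi / 6,
               tolerance = 1e-9)
  p2 <- gaussian_subpulse(pi / 3, 2.2e-3)
  expect_equal(Re(p2$samples), 2 * Re(p$samples), tolerance = 1e-12)
  expect_error(gaussian_subpulse(pi / 6, 2.2e-3, dt = 1e-4), "dt too coarse")
})

test_that("sub-pulse spectral width matches the time-bandwidth product", {
  tau <- 2e-3; dt <- 2e-6
  p <- gaussian_subpulse(pi / 4, tau, tbw = 2.26, dt = dt)
  n <- 2^16
  spec <- Mod(stats::fft(c(Re(p$samples), rep(0, n - length(p$samples)))))
  f <- (seq_len(n) - 1) / (n * dt)
  half <- max(spec) / 2
  idx <- which(spec[seq_len(n / 2)] >= half)
  fwhm <- 2 * f[max(idx)]          # symmetric about zero frequency
  expect_equal(fwhm * tau, 2.26, tolerance = 0.05)
})

test_that("sequence B1rms follows its definition and quadrature arithmetic", {
  p0 <- gaussian_subpulse(0, 2e-3)
  expect_equal(b1rms_sequence(p0, 5e-3), 0)
  p <- gaussian_subpulse(pi / 4, 2e-3)
  expect_equal(b1rms_sequence(p, 1e-2), b1rms_sequence(p, 5e-3) / sqrt(2),
               tolerance = 1e-12)
  expect_error(b1rms_sequence(p, 1e-3), "TR")
})

test_that("beta power ratio definition and infeasible targets", {
  expect_equal(beta_power_ratio(3, 9), 0)
  expect_equal(beta_power_ratio(sqrt(2) * 3, 9), 1, tolerance = 1e-12)
  # in vivo arithmetic: total 4.73 uT with on-resonance 0.76 uT
  expect_equal(beta_power_ratio(4.73, 0.76^2), (4.73^2 - 0.76^2) / 0.76^2,
               tolerance = 1e-12)
  expect_error(beta_power_ratio(0.5, 1), "minimum achievable")
})

test_that("multiband synthesis hits the target B1rms and band bookkeeping", {
  a <- 30 * pi / 180
  for (cfg in c("2B_plus", "2B_minus", "3B")) {
    p <- make_multiband(a, 2e-3, 5e-3, 2 * pi * 7e3, cfg, target_b1rms = 5)
    expect_equal(b1rms_sequence(p, 5e-3), 5, tolerance = 1e-3)
    # on-resonance flip is invariant under adding off-resonant bands
    on <- p$bands[[which(p$band_offsets == 0)]]
    expect_equal(Mod(on$coef), 1)
    # band power bookkeeping: sum of per-band mean squares approximates the
    # whole-waveform mean square over tau (cross terms < 0.5 %)
    msq_total <- mean(Mod(p$samples)^2)
    expect_equal(sum(p$band_mean_square), msq_total,
                 tolerance = 5e-3)
  }
  # 1B passthrough
  p1 <- make_multiband(a, 2e-3, 5e-3, 2 * pi * 7e3, "1B")
  expect_equal(p1$band_offsets, 0)
  # 3B splits the off-resonant power equally
  p3 <- make_multiband(a, 2e-3, 5e-3, 2 * pi * 7e3, "3B", target_b1rms = 5)
  off <- p3$band_mean_square[p3$band_offsets != 0]
  expect_equal(off[1], off[2])
  expect_error(make_multiband(a, 2e-3, 5e-3, 0, "3B", target_b1rms = 5),
               "nonzero offset")
  expect_error(make_multiband(60 * pi / 180, 2e-3, 5e-3, 2 * pi * 7e3,
                              "2B_plus", target_b1rms = 0.1),
               "minimum achievable")
})

test_that("2+B and 2-B are complex conjugates; peak B1 ordering holds", {
  a <- 30 * pi / 180
  pp <- make_multiband(a, 2e-3, 5e-3, 2 * pi * 7e3, "2B_plus",
                       target_b1rms = 5)
  pm <- make_multiband(a, 2e-3, 5e-3, 2 * pi * 7e3, "2B_minus",
                       target_b1rms = 5)
  expect_equal(pp$samples, Conj(pm$samples))
  expect_equal(pp$band_mean_square, pm$band_mean_square)
  p1 <- make_multiband(a, 2e-3, 5e-3, 0, "1B")
  p3 <- make_multiband(a, 2e-3, 5e-3, 2 * pi * 7e3, "3B", target_b1rms = 5)
  pk <- c(max(Mod(p1$samples)), max(Mod(pp$samples)), max(Mod(p3$samples)))
  expect_true(pk[3] > pk[2] && pk[2] > pk[1])
})

test_that("peak-B1 map is monotone and self-consistent", {
  m <- max_b1_map(2e-3, TR_grid = c(4e-3, 5e-3, 8e-3),
                  b1rms_grid = c(3, 5), flip_angle = 30 * pi / 180)
  expect_true(all(diff(m$peak_b1[, 2]) > 0))     # increases with TR
  expect_true(all(m$peak_b1[, 2] > m$peak_b1[, 1]))  # increases with b1rms
  expect_true(m$duty_flag[1] == FALSE)
  p <- make_multiband(30 * pi / 180, 2e-3, 5e-3, 2 * pi * 8e3, "3B",
                      target_b1rms = 5)
  expect_equal(m$peak_b1[2, 2], max(Mod(p$samples)), tolerance = 1e-12)
})

test_that("waveform round-trips through CSV and JSON export", {
  p <- make_multiband(30 * pi / 180, 2e-3, 5e-3, 2 * pi * 7e3, "3B",
                      target_b1rms = 5)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_pulse(p, csv); write_pulse(p, js)
  d <- utils::read.csv(csv)
  expect_equal(complex(real = d$re, imaginary = d$im), p$samples)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$band_mean_square, unname(p$band_mean_square))
  expect_equal(j$samples_re, Re(p$samples))
  unlink(c(csv, js))
})
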