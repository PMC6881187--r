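test_that("dataset prediction respects scale, band and no-MT degeneracies", {
  acq <- acquisition_params()
  pl <- tissue_preset("PL161")
  dat <- simulate_phantom_dataset(pl, acq, scale = 100, snr = Inf, seed = 1)
  expect_equal(nrow(dat), 64L)
  expect_equal(predict_dataset(pl, dat, acq, scale = 0), rep(0, 64))
  pr <- predict_dataset(pl, dat, acq, scale = 100)
  expect_equal(pr, dat$truth, tolerance = 1e-12)
  # 2+B and 2-B rows share one prediction
  key <- paste(dat$sequence, dat$flip_deg)
  p2p <- pr[dat$band == "2B_plus"]; p2m <- pr[dat$band == "2B_minus"]
  expect_equal(p2p[order(key[dat$band == "2B_plus"])],
               p2m[order(key[dat$band == "2B_minus"])])
  # no semisolid pool: all four band configurations coincide per flip
  mn <- tissue_preset("MnCl2")
  prm <- predict_dataset(mn, dat, acq)
  sp <- split(prm, key)
  expect_true(all(vapply(sp, function(v) diff(range(v)) < 1e-12,
                         logical(1))))
})

test_that("NRMSE definition and normalizers", {
  obs <- c(4, 5, 6, 5)
  expect_equal(nrmse(obs, obs), 0)
  eps <- 0.05
  expect_equal(nrmse(obs, obs + eps), 100 * eps / sqrt(mean(obs^2)),
               tolerance = 1e-12)
  expect_equal(nrmse(obs, obs + eps, normalizer = "range"),
               100 * eps / 2, tolerance = 1e-12)
  expect_error(nrmse(obs, obs[1:2]), "equal length")
})

test_that("noiseless parameter recovery is essentially exact", {
  acq <- acquisition_params()
  pl <- tissue_preset("PL161")
  dat <- simulate_phantom_dataset(pl, acq, scale = 100, snr = Inf, seed = 1)
  start <- tissue_update(pl, R1f = 0.7, R2f = 18, M0s = 0.10)
  fit <- ihmt_fit(dat, acq, start, free = c("R1f", "R2f", "M0s"),
                  n_starts = 1, seed = 1)
  truth <- c(R1f = pl$R1f, R2f = pl$R2f, M0s = pl$M0s, scale = 100)
  expect_true(all(abs(coef(fit)[names(truth)] - truth) / truth < 5e-3))
  expect_lt(fit$nrmse, 1e-6)
})

test_that("fit is invariant to global rescaling of the data", {
  acq <- acquisition_params()
  pl <- tissue_preset("PL161")
  dat <- simulate_phantom_dataset(pl, acq, scale = 100, snr = 200, seed = 4)
  start <- tissue_update(pl, R1f = 0.7, R2f = 18, M0s = 0.10)
  f1 <- ihmt_fit(dat, acq, start, free = c("R1f", "R2f", "M0s"),
                 n_starts = 1, seed = 1)
  dat2 <- dat; dat2$signal <- dat$signal * 7.3
  f2 <- ihmt_fit(dat2, acq, start, free = c("R1f", "R2f", "M0s"),
                 n_starts = 1, seed = 1)
  nm <- c("R1f", "R2f", "M0s")
  expect_equal(coef(f1)[nm], coef(f2)[nm], tolerance = 1e-6)
  expect_equal(unname(coef(f2)["scale"] / coef(f1)["scale"]), 7.3,
               tolerance = 1e-6)
})

test_that("phantom generator is seeded and carries the stated noise level", {
  acq <- acquisition_params()
  pl <- tissue_preset("PL161")
  d1 <- simulate_phantom_dataset(pl, acq, snr = 100, seed = 11)
  d2 <- simulate_phantom_dataset(pl, acq, snr = 100, seed = 11)
  expect_identical(d1, d2)
  d3 <- simulate_phantom_dataset(pl, acq, snr = 100, seed = 12)
  expect_false(identical(d1$signal, d3$signal))
  # empirical noise close to mean(truth)/snr
  big <- simulate_phantom_dataset(pl, acq, snr = 50, seed = 13)
  expect_equal(sd(big$signal - big$truth), mean(big$truth) / 50,
               tolerance = 0.35)
  # flip/band layout of the protocol
  expect_equal(sort(unique(d1$flip_deg[d1$sequence == "bssfp"])),
               seq(10, 80, by = 10))
  expect_equal(sort(unique(d1$flip_deg[d1$sequence == "spgr"])),
               seq(2, 16, by = 2))
})

test_that("residual bootstrap is seed-deterministic and near zero without
           noise", {
  acq <- acquisition_params()
  pl <- tissue_preset("PL161")
  start <- tissue_update(pl, R1f = 0.6, M0s = 0.12)
  dat0 <- simulate_phantom_dataset(pl, acq, snr = Inf, seed = 1)
  f0 <- ihmt_fit(dat0, acq, start, free = c("R1f", "M0s"), n_starts = 1,
                 seed = 1)
  f0 <- residual_bootstrap(f0, n = 10, seed = 3)
  expect_true(all(f0$bootstrap$se < 1e-6))
  dat <- simulate_phantom_dataset(pl, acq, snr = 100, seed = 5)
  fa <- ihmt_fit(dat, acq, start, free = c("R1f", "M0s"), n_starts = 1,
                 seed = 1)
  b1 <- residual_bootstrap(fa, n = 12, seed = 7)
  b2 <- residual_bootstrap(fa, n = 12, seed = 7)
  expect_identical(b1$bootstrap$se, b2$bootstrap$se)
  expect_true(all(b1$bootstrap$se > 0))
})

test_that("bootstrap standard errors scale with the injected noise", {
  acq <- acquisition_params()
  pl <- tissue_preset("PL161")
  start <- tissue_update(pl, R1f = 0.6)
  ses <- vapply(c(100, 50), function(snr) {
    dat <- simulate_phantom_dataset(pl, acq, snr = snr, seed = 21)
    f <- ihmt_fit(dat, acq, start, free = "R1f", n_starts = 1, seed = 1)
    f <- residual_bootstrap(f, n = 20, seed = 9)
    f$bootstrap$se[["R1f"]]
  }, numeric(1))
  expect_equal(ses[2] / ses[1], 2, tolerance = 0.6)
})

test_that("fit methods: print, summary, predict, residuals, simulate", {
  acq <- acquisition_params()
  pl <- tissue_preset("PL161")
  dat <- simulate_phantom_dataset(pl, acq, snr = 200, seed = 8)
  f <- ihmt_fit(dat, acq, tissue_update(pl, R1f = 0.6, M0s = 0.12),
                free = c("R1f", "M0s"), n_starts = 1, seed = 1)
  expect_output(print(f), "NRMSE")
  s <- summary(f)
  expect_true("as_time" %in% names(s$coefficients))
  expect_equal(s$coefficients["R1f", "as_time"],
               1000 / unname(coef(f)["R1f"]), tolerance = 1e-9)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, dat), fitted(f), tolerance = 1e-12)
  expect_equal(residuals(f), dat$signal - fitted(f))
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(64L, 2L))
  pdf(NULL); plot(f); dev.off()
})

test_that("a material without a semisolid pool fits with M0s fixed at zero", {
  acq <- acquisition_params()
  mn <- tissue_preset("MnCl2")
  dat <- simulate_phantom_dataset(mn, acq, scale = 100, snr = 100, seed = 31)
  # M0s stays fixed at 0 (not in `free`); only the water rates and scale move
  fit <- ihmt_fit(dat, acq, tissue_update(mn, R1f = 0.3, R2f = 2),
                  free = c("R1f", "R2f"), n_starts = 1, seed = 1)
  expect_equal(fit$tissue$M0s, 0)
  noise_floor <- nrmse(dat$signal, dat$truth)
  expect_equal(fit$nrmse, noise_floor, tolerance = 0.25)
  expect_equal(unname(coef(fit)["R1f"]), mn$R1f, tolerance = 0.05)
})

test_that("freeing delta on dipolar-free data does not improve the fit", {
  acq <- acquisition_params()
  bsa <- tissue_preset("BSA")          # delta = 0 material
  dat <- simulate_phantom_dataset(bsa, acq, scale = 100, snr = 100,
                                  seed = 32)
  start <- tissue_update(bsa, R1f = 0.5)
  f_fixed <- ihmt_fit(dat, acq, start, free = "R1f", n_starts = 1, seed = 1)
  f_free <- ihmt_fit(dat, acq, start, free = c("R1f", "delta"),
                     n_starts = 1, seed = 1)
  noise_floor <- nrmse(dat$signal, dat$truth)
  expect_lt(abs(f_free$nrmse - f_fixed$nrmse), 0.25 * noise_floor)
})
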