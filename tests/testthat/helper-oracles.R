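# Shared fixtures and independent oracles.

wm_tissue <- function(...) {
  t <- tissue_preset("white_matter_1p5T")
  if (length(list(...))) t <- tissue_update(t, ...)
  t
}

# single-pool variant of the white-matter set (Bloch limit)
single_pool <- function() wm_tissue(M0s = 0)

# textbook spoiled gradient echo steady state (Ernst formula), signal right
# after the pulse
ernst_signal <- function(alpha, TR, R1) {
  E1 <- exp(-TR * R1)
  sin(alpha) * (1 - E1) / (1 - E1 * cos(alpha))
}

# textbook pi-phase-cycled bSSFP on resonance, magnitude at TE = TR/2
bssfp_closed_form <- function(alpha, TR, R1, R2) {
  E1 <- exp(-TR * R1); E2 <- exp(-TR * R2)
  sin(alpha) * (1 - E1) * sqrt(E2) / (1 - (E1 - E2) * cos(alpha) - E1 * E2)
}

# standard pulse set at the simulation settings
fig_pulses <- function(flip_deg, tau = 2e-3, TR = 5e-3, delta_hz = 7e3,
                       b1rms = 5, dt = 1e-5) {
  a <- flip_deg * pi / 180
  list(
    p1 = make_multiband(a, tau, TR, 0, "1B", dt = dt),
    p2 = make_multiband(a, tau, TR, 2 * pi * delta_hz, "2B_plus",
                        target_b1rms = b1rms, dt = dt),
    p3 = make_multiband(a, tau, TR, 2 * pi * delta_hz, "3B",
                        target_b1rms = b1rms, dt = dt))
}

forward_iterate <- function(X, n = 1000) {
  x <- c(rep(0, 6), 1)
  for (i in seq_len(n)) x <- X %*% x
  as.numeric(x[1:6] / x[7])
}
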