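# Multiband RF pulse synthesis. A pulse is a Gaussian sub-pulse b0(t)
# (the on-resonance band, responsible for flipping water) multiplied by a
# modulation carrying one or two off-resonance saturation bands. Off-band
# amplitudes are set from the power ratio beta and then renormalized by a
# single scalar so the realized whole-sequence B1rms matches the target
# exactly (cross terms between bands absorbed). Fields in uT, times in s,
# offsets in rad/s.

.pulse_time_grid <- function(tau, dt) {
  n <- round(tau / dt)
  if (n < 1L || abs(n * dt - tau) > 1e-9 * max(tau, dt))
    stop("tau must be an integer multiple of dt")
  (seq_len(n) - 0.5) * dt - tau / 2   # midpoint samples, centered on pulse
}

# Analytic Gaussian envelope evaluation (centered time coordinate).
.envelope_eval <- function(env, t_centered) {
  env$amp * exp(-t_centered^2 / (2 * env$sigma^2))
}

#' Gaussian sub-pulse
#'
#' Truncated Gaussian envelope with a given time-bandwidth product, sampled
#' at midpoints of a uniform grid and amplitude-calibrated so that
#' gamma * sum(b) * dt equals the flip angle exactly.
#'
#' @param flip_angle Flip angle in radians (>= 0).
#' @param tau Pulse duration in seconds; must be an integer multiple of `dt`.
#' @param tbw Time-bandwidth product (FWHM of the spectral magnitude times
#'   tau). Default 2.26.
#' @param dt Sample spacing in seconds (default 2 us); must satisfy
#'   dt <= tau/64 for adequate resolution.
#' @return An `"ihmt_pulse"` object: complex `samples` (uT), `dt`, `tau`,
#'   `flip_angle`, a `bands` list (offset rad/s + complex coefficient
#'   multiplying the shared envelope), `band_offsets`, `band_mean_square`
#'   (mean |b_j|^2 over tau, uT^2) and the analytic `envelope` parameters.
#' @export
gaussian_subpulse <- function(flip_angle, tau, tbw = 2.26, dt = 2e-6) {
  if (flip_angle < 0) stop("flip_angle must be >= 0")
  if (tau <= 0) stop("tau must be positive")
  if (dt > tau / 64 + 1e-15)
    stop("dt too coarse: need dt <= tau/64 for waveform resolution")
  t <- .pulse_time_grid(tau, dt)
  # sigma chosen so the (untruncated) spectral magnitude FWHM times tau = tbw
  sigma <- sqrt(2 * log(2)) * tau / (pi * tbw)
  shape <- exp(-t^2 / (2 * sigma^2))
  amp <- if (flip_angle == 0) 0 else flip_angle / (GAMMA_1H * sum(shape) * dt)
  b0 <- amp * shape
  new_ihmt_pulse(
    samples = as.complex(b0), dt = dt, tau = tau, flip_angle = flip_angle,
    bands = list(list(offset = 0, coef = 1 + 0i)),
    envelope = list(amp = amp, sigma = sigma),
    band_config = "1B", TR = NA_real_, target_b1rms = NA_real_,
    beta = 0, delta = 0
  )
}

new_ihmt_pulse <- function(samples, dt, tau, flip_angle, bands, envelope,
                           band_config, TR, target_b1rms, beta, delta) {
  offs <- vapply(bands, `[[`, numeric(1), "offset")
  shape2 <- Mod(.envelope_eval(list(amp = 1, sigma = envelope$sigma),
                               .pulse_time_grid(tau, dt)))^2
  msq <- vapply(bands, function(b) Mod(b$coef)^2 * envelope$amp^2 *
                  mean(shape2), numeric(1))
  structure(list(samples = samples, dt = dt, tau = tau,
                 flip_angle = flip_angle, bands = bands,
                 band_offsets = offs, band_mean_square = msq,
                 envelope = envelope, band_config = band_config, TR = TR,
                 target_b1rms = target_b1rms, beta = beta, delta = delta),
            class = "ihmt_pulse")
}

#' @export
print.ihmt_pulse <- function(x, ...) {
  cat(sprintf(
    "<ihmt_pulse> %s: flip %.1f deg, tau %.3g ms, %d samples (dt %.1f us)\n",
    x$band_config, x$flip_angle * 180 / pi, x$tau * 1e3, length(x$samples),
    x$dt * 1e6))
  cat(sprintf("  bands at %s kHz; peak |B1| %.3g uT\n",
              paste(sprintf("%.3g", x$band_offsets / (2 * pi * 1e3)),
                    collapse = ", "),
              max(Mod(x$samples))))
  invisible(x)
}

#' Whole-sequence RMS B1 of a pulse
#'
#' sqrt((1/TR) * sum(|b|^2) * dt): the root mean square field over a full TR,
#' the SAR-relevant saturation power metric.
#'
#' @param pulse An `"ihmt_pulse"`.
#' @param TR Repetition time in seconds, TR >= tau.
#' @return RMS field in uT.
#' @export
b1rms_sequence <- function(pulse, TR) {
  stopifnot(inherits(pulse, "ihmt_pulse"))
  if (TR < pulse$tau) stop("TR must be >= pulse duration tau")
  sqrt(sum(Mod(pulse$samples)^2) * pulse$dt / TR)
}

#' Off-resonant to on-resonant power ratio beta
#'
#' beta = (<B1^2>_TOT - <B1^2(0)>) / <B1^2(0)>, where <B1^2>_TOT is the
#' square of the target whole-sequence B1rms and <B1^2(0)> is the
#' whole-sequence mean-square field of the on-resonance band alone
#' ((1/TR) * integral of b0^2 over the pulse).
#'
#' @param target_b1rms_total Target whole-sequence RMS B1 in uT.
#' @param onres_mean_square Whole-sequence mean-square field of the
#'   on-resonance band in uT^2.
#' @return Dimensionless beta >= 0.
#' @export
beta_power_ratio <- function(target_b1rms_total, onres_mean_square) {
  tot <- target_b1rms_total^2
  if (onres_mean_square <= 0) {
    if (tot == 0) return(0)
    stop("on-resonance power is zero; beta undefined for a zero sub-pulse")
  }
  if (tot < onres_mean_square * (1 - 1e-12))
    stop(sprintf(paste0(
      "target B1rms %.4g uT is below the on-resonance-only value; minimum ",
      "achievable whole-sequence B1rms is %.4g uT"),
      target_b1rms_total, sqrt(onres_mean_square)))
  max((tot - onres_mean_square) / onres_mean_square, 0)
}

#' Build a multiband pulse hitting a target whole-sequence B1rms
#'
#' The on-resonance Gaussian sub-pulse b0(t) is multiplied by a modulation
#' adding one (2B, offset +Delta or -Delta) or two (3B, +/-Delta) saturation
#' bands. Off-band amplitudes start at sqrt(beta) (2B) or sqrt(beta/2) per
#' band (3B), where beta is the power ratio of [beta_power_ratio()], and the
#' off-resonant component is then rescaled by one scalar so the realized
#' sequence B1rms equals `target_b1rms` exactly. The modulation phase is
#' referenced to the pulse center, making the 3B waveform real and symmetric.
#' The on-resonance band (and hence the water flip angle) is unchanged by the
#' added bands.
#'
#' @param flip_angle Flip angle in radians.
#' @param tau Pulse duration (s).
#' @param TR Repetition time (s), TR >= tau.
#' @param delta Band offset Delta in rad/s (> 0 for multiband configs).
#' @param band_config One of `"1B"`, `"2B_plus"`, `"2B_minus"`, `"3B"`.
#' @param target_b1rms Target whole-sequence RMS B1 in uT (ignored for
#'   `"1B"`, which returns the bare sub-pulse).
#' @param tbw Time-bandwidth product of the sub-pulse.
#' @param dt Sample spacing (s).
#' @return An `"ihmt_pulse"` with per-band bookkeeping.
#' @export
make_multiband <- function(flip_angle, tau, TR, delta,
                           band_config = c("1B", "2B_plus", "2B_minus", "3B"),
                           target_b1rms = NULL, tbw = 2.26, dt = 2e-6) {
  band_config <- match.arg(band_config)
  sp <- gaussian_subpulse(flip_angle, tau, tbw = tbw, dt = dt)
  if (band_config == "1B") {
    sp$TR <- TR
    return(sp)
  }
  if (is.null(target_b1rms))
    stop("target_b1rms is required for multiband configurations")
  if (delta == 0) stop("multiband configuration requires a nonzero offset")
  if (TR < tau) stop("TR must be >= tau")
  if (abs(delta) * tau < 2 * pi * tbw)
    warning("band separation |Delta|*tau is small relative to the pulse ",
            "bandwidth; bands are not well separated")
  t <- .pulse_time_grid(tau, dt)
  b0 <- Re(sp$samples)
  onres_msq_seq <- sum(b0^2) * dt / TR
  beta <- beta_power_ratio(target_b1rms, onres_msq_seq)
  if (beta == 0) {
    samples <- as.complex(b0)
    bands <- sp$bands
    cscale <- 0
  } else {
    off <- switch(band_config,
      "2B_plus"  = sqrt(beta) * b0 * exp(1i * delta * t),
      "2B_minus" = sqrt(beta) * b0 * exp(-1i * delta * t),
      "3B"       = as.complex(sqrt(2 * beta) * b0 * cos(delta * t))
    )
    # solve for scalar c >= 0: int |b0 + c*off|^2 dt = target^2 * TR
    a2 <- sum(Mod(off)^2) * dt
    a1 <- 2 * sum(b0 * Re(off)) * dt
    a0 <- sum(b0^2) * dt - target_b1rms^2 * TR
    disc <- a1^2 - 4 * a2 * a0
    if (disc < 0) stop("infeasible multiband target B1rms")
    cscale <- (-a1 + sqrt(disc)) / (2 * a2)
    samples <- b0 + cscale * off
    bands <- switch(band_config,
      "2B_plus" = list(
        list(offset = 0, coef = 1 + 0i),
        list(offset = delta, coef = cscale * sqrt(beta) + 0i)),
      "2B_minus" = list(
        list(offset = 0, coef = 1 + 0i),
        list(offset = -delta, coef = cscale * sqrt(beta) + 0i)),
      "3B" = list(
        list(offset = 0, coef = 1 + 0i),
        list(offset = delta, coef = cscale * sqrt(beta / 2) + 0i),
        list(offset = -delta, coef = cscale * sqrt(beta / 2) + 0i))
    )
  }
  new_ihmt_pulse(samples = samples, dt = dt, tau = tau,
                 flip_angle = flip_angle, bands = bands,
                 envelope = sp$envelope, band_config = band_config, TR = TR,
                 target_b1rms = target_b1rms, beta = beta, delta = delta)
}

#' Peak-B1 surface for 3-band pulses over (TR, B1rms)
#'
#' For each grid point, builds the 3B pulse reaching the target whole-sequence
#' B1rms and records its peak |B1|. Grid points where TR < 2*tau are flagged
#' (RF duty-cycle limits suggest TR >= 2*tau); infeasible targets give NA.
#'
#' @param tau Pulse duration (s).
#' @param TR_grid Vector of repetition times (s).
#' @param b1rms_grid Vector of target whole-sequence RMS B1 values (uT).
#' @param flip_angle Flip angle in radians.
#' @param delta Band offset (rad/s).
#' @param tbw,dt Passed to [make_multiband()].
#' @return List with `peak_b1` (matrix TR x b1rms, uT) and logical
#'   `duty_flag` marking TR < 2*tau rows.
#' @export
max_b1_map <- function(tau, TR_grid, b1rms_grid, flip_angle,
                       delta = 2 * pi * 8e3, tbw = 2.26, dt = 2e-6) {
  stopifnot(all(TR_grid > 0), all(b1rms_grid > 0), tau > 0)
  pk <- matrix(NA_real_, length(TR_grid), length(b1rms_grid),
               dimnames = list(TR = NULL, b1rms = NULL))
  for (i in seq_along(TR_grid)) for (j in seq_along(b1rms_grid)) {
    p <- tryCatch(
      make_multiband(flip_angle, tau, TR_grid[i], delta, "3B",
                     target_b1rms = b1rms_grid[j], tbw = tbw, dt = dt),
      error = function(e) NULL)
    if (!is.null(p)) pk[i, j] <- max(Mod(p$samples))
  }
  list(peak_b1 = pk, TR = TR_grid, b1rms = b1rms_grid,
       duty_flag = TR_grid < 2 * tau)
}

#' Export a pulse waveform as a two-column CSV or JSON descriptor
#'
#' @param pulse An `"ihmt_pulse"`.
#' @param path Output path; format chosen by extension (`.csv` writes time,
#'   re, im columns; `.json` writes the full descriptor).
#' @return `path`, invisibly.
#' @export
write_pulse <- function(pulse, path) {
  stopifnot(inherits(pulse, "ihmt_pulse"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    desc <- list(
      band_config = pulse$band_config, tau = pulse$tau, dt = pulse$dt,
      flip_angle = pulse$flip_angle, TR = pulse$TR,
      target_b1rms = pulse$target_b1rms, beta = pulse$beta,
      band_offsets = pulse$band_offsets,
      band_mean_square = unname(pulse$band_mean_square),
      samples_re = Re(pulse$samples), samples_im = Im(pulse$samples))
    jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
  } else {
    t <- .pulse_time_grid(pulse$tau, pulse$dt) + pulse$tau / 2
    utils::write.csv(data.frame(time = t, re = Re(pulse$samples),
                                im = Im(pulse$samples)),
                     path, row.names = FALSE)
  }
  invisible(path)
}
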