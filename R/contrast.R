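# Contrast metrics and parameter sweeps. Band-configuration signals: S1B
# (on-resonance band only, variable B1rms), S2B (one off-resonance band; the
# model does not distinguish +Delta from -Delta so a single 2B computation is
# used), S3B (symmetric bands). MTR and ihMTR are reported in percent; note
# this ihMTR definition, (S2B - S3B)/S1B, is a factor ~2 smaller than
# definitions used in some of the ihMT literature that double the difference
# term -- compare across studies with care.

#' Magnetization transfer ratio (percent)
#' @param S1B,S2B Single-band and two-band signals (S1B > 0).
#' @return 100 * (S1B - S2B) / S1B.
#' @export
mtr <- function(S1B, S2B) {
  if (any(S1B <= 0)) stop("reference single-band signal must be positive")
  100 * (S1B - S2B) / S1B
}

#' ihMT difference
#' @param S2B,S3B Two- and three-band signals; for measured data S2B should
#'   be the mean of the +Delta and -Delta acquisitions.
#' @return S2B - S3B (signal units).
#' @export
delta_ihmt <- function(S2B, S3B) S2B - S3B

#' ihMT ratio (percent)
#' @inheritParams mtr
#' @inheritParams delta_ihmt
#' @return 100 * (S2B - S3B) / S1B.
#' @export
ihmtr <- function(S1B, S2B, S3B) {
  if (any(S1B <= 0)) stop("reference single-band signal must be positive")
  100 * (S2B - S3B) / S1B
}

#' Steady-state signal sweep over flip angle and band offset
#'
#' Computes S1B, S2B and S3B over a (flip angle, offset) grid at fixed TR,
#' tau and target whole-sequence B1rms, using the instantaneous-pulse steady
#' states (bSSFP with the finite-pulse correction by default). Multiband
#' pulses are regenerated at every grid point to hold the total B1rms fixed;
#' single-band pulses use only the on-resonance component, so their B1rms
#' varies with flip angle. Grid points where the target B1rms is infeasible
#' (on-resonance power alone exceeds it) are masked with NA and a warning.
#'
#' @param tissue An `"ihmt_tissue"`.
#' @param flips_deg Flip angles in degrees.
#' @param deltas_hz Band offsets in Hz (of Delta/2pi).
#' @param TR,tau Sequence timing (s).
#' @param b1rms Target whole-sequence RMS B1 (uT).
#' @param readout `"bssfp"` or `"spgr"`.
#' @param correct_finite_pulse Apply the R2f correction for bSSFP.
#' @param dt Pulse synthesis sample spacing (s).
#' @return An `"ihmt_sweep"` list: vectors `flips_deg`, `deltas_hz`, vector
#'   `S1B` (per flip), matrices `S2B`, `S3B`, `MTR`, `dihmt`, `ihMTR`
#'   (flip x offset).
#' @export
ihmt_sweep <- function(tissue, flips_deg, deltas_hz, TR = 5e-3, tau = 2e-3,
                       b1rms = 5, readout = c("bssfp", "spgr"),
                       correct_finite_pulse = TRUE, dt = 1e-5) {
  readout <- match.arg(readout)
  nf <- length(flips_deg); nd <- length(deltas_hz)
  S1B <- numeric(nf)
  S2B <- matrix(NA_real_, nf, nd)
  S3B <- matrix(NA_real_, nf, nd)
  sq <- seq_settings(readout, TR = TR, tau = tau, TE = TR / 2)
  n_masked <- 0L
  for (i in seq_len(nf)) {
    fa <- flips_deg[i] * pi / 180
    p1 <- make_multiband(fa, tau, TR, 0, "1B", dt = dt)
    S1B[i] <- steady_state_signal(p1, tissue, sq,
                                  readout == "bssfp" &&
                                    correct_finite_pulse)$signal
    for (j in seq_len(nd)) {
      dl <- 2 * pi * deltas_hz[j]
      sigs <- tryCatch({
        p2 <- make_multiband(fa, tau, TR, dl, "2B_plus",
                             target_b1rms = b1rms, dt = dt)
        p3 <- make_multiband(fa, tau, TR, dl, "3B",
                             target_b1rms = b1rms, dt = dt)
        c(steady_state_signal(p2, tissue, sq,
                              readout == "bssfp" &&
                                correct_finite_pulse)$signal,
          steady_state_signal(p3, tissue, sq,
                              readout == "bssfp" &&
                                correct_finite_pulse)$signal)
      }, error = function(e) c(NA_real_, NA_real_))
      if (anyNA(sigs)) n_masked <- n_masked + 1L
      S2B[i, j] <- sigs[1]; S3B[i, j] <- sigs[2]
    }
  }
  if (n_masked > 0L)
    warning(n_masked, " grid point(s) masked (infeasible target B1rms)")
  structure(list(flips_deg = flips_deg, deltas_hz = deltas_hz,
                 S1B = S1B, S2B = S2B, S3B = S3B,
                 MTR = mtr(S1B, S2B), dihmt = delta_ihmt(S2B, S3B),
                 ihMTR = ihmtr(S1B, S2B, S3B),
                 TR = TR, tau = tau, b1rms = b1rms, readout = readout),
            class = "ihmt_sweep")
}

#' @export
print.ihmt_sweep <- function(x, ...) {
  cat(sprintf(
    "<ihmt_sweep> %s, TR %.3g ms, tau %.3g ms, B1rms %.3g uT\n  %d flips x %d offsets\n",
    x$readout, x$TR * 1e3, x$tau * 1e3, x$b1rms, length(x$flips_deg),
    length(x$deltas_hz)))
  pk <- find_peak(x$dihmt, x$flips_deg, x$deltas_hz / 1e3)
  cat(sprintf("  peak dihMT %.4g at flip %.3g deg, offset %.3g kHz\n",
              pk$value, pk$x, pk$y))
  invisible(x)
}

#' Sweep as a tidy data frame
#'
#' One row per (flip, offset) grid point with the three band signals and the
#' derived contrast metrics.
#' @param sweep An `"ihmt_sweep"`.
#' @return A data.frame.
#' @export
sweep_to_df <- function(sweep) {
  stopifnot(inherits(sweep, "ihmt_sweep"))
  g <- expand.grid(flip_deg = sweep$flips_deg, delta_hz = sweep$deltas_hz)
  data.frame(g,
             S1B = sweep$S1B[match(g$flip_deg, sweep$flips_deg)],
             S2B = as.vector(sweep$S2B), S3B = as.vector(sweep$S3B),
             MTR = as.vector(sweep$MTR), dihmt = as.vector(sweep$dihmt),
             ihMTR = as.vector(sweep$ihMTR))
}

#' Locate a surface maximum with quadratic refinement
#'
#' Grid argmax (ties broken toward the smaller first-axis value, then the
#' smaller second-axis value) refined by a separable local quadratic
#' interpolation through the three points around the maximum along each
#' axis. Refinement is skipped along an axis where the maximum sits on the
#' grid edge.
#'
#' @param surface Numeric matrix (may contain NA for masked points).
#' @param x,y Axis coordinate vectors (rows / columns of `surface`).
#' @return List with refined coordinates `x`, `y`, refined `value`, and the
#'   raw grid argmax `i`, `j`.
#' @export
find_peak <- function(surface, x, y) {
  if (all(is.na(surface))) stop("surface is entirely masked")
  m <- max(surface, na.rm = TRUE)
  idx <- which(surface == m)
  ij <- arrayInd(idx, dim(surface))
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
  i <- ij[1]; j <- ij[2]
  refine <- function(vals, coords, at) {
    if (at <= 1L || at >= length(coords)) return(c(coords[at], vals[at]))
    f <- vals[(at - 1):(at + 1)]
    if (anyNA(f)) return(c(coords[at], vals[at]))
    denom <- f[1] - 2 * f[2] + f[3]
    if (denom >= 0) return(c(coords[at], vals[at]))   # not locally concave
    off <- 0.5 * (f[1] - f[3]) / denom
    h <- coords[at + 1] - coords[at]
    c(coords[at] + off * h, f[2] - 0.25 * (f[1] - f[3]) * off)
  }
  rx <- refine(surface[, j], x, i)
  ry <- refine(surface[i, ], y, j)
  list(x = rx[1], y = ry[1],
       value = m + (rx[2] - m) + (ry[2] - m), i = i, j = j)
}
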