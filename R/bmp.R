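# Evolution operators of the Bloch-McConnell-Provotorov (BMP) system.
# State ordering is fixed: [Mxf, Myf, Mzf, MZs1, MZs2, MDs2], dimensionless
# polarizations with thermal values [0, 0, M0f, (1-delta)M0s, delta*M0s, 0].

.expm <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

#' Relaxation/exchange matrix Lambda and constant vector C
#'
#' Builds the 6x6 generator of RF-free evolution dM/dt = Lambda M + C.
#' Exchange follows detailed balance with intrinsic rate k: the free pool
#' loses at k*M0s and gains at k*M0f from each semisolid Zeeman pool; each
#' semisolid Zeeman pool gains at k*(its fraction of M0s) and decays at
#' k*M0f. Thermal equilibrium M_eq = [0,0,M0f,(1-delta)M0s,delta*M0s,0]
#' satisfies Lambda %*% M_eq + C = 0 exactly.
#'
#' @param tissue An [tissue_params()] object.
#' @param delta_omega Free-pool off-resonance (rad/s).
#' @return List with `Lambda` (6x6), `C` (length 6) and `M_eq`.
#' @export
bmp_lambda <- function(tissue, delta_omega = 0) {
  stopifnot(inherits(tissue, "ihmt_tissue"))
  M0s <- tissue$M0s; M0f <- 1 - M0s; d <- tissue$delta; k <- tissue$k
  L <- matrix(0, 6, 6)
  L[1, 1] <- -tissue$R2f; L[1, 2] <- delta_omega
  L[2, 1] <- -delta_omega; L[2, 2] <- -tissue$R2f
  L[3, 3] <- -(k * M0s + tissue$R1f)
  L[3, 4] <- k * M0f
  L[3, 5] <- k * M0f
  L[4, 3] <- k * (1 - d) * M0s
  L[4, 4] <- -(k * M0f + tissue$R1Zs)
  L[5, 3] <- k * d * M0s
  L[5, 5] <- -(k * M0f + tissue$R1Zs)
  L[6, 6] <- -tissue$R1Ds
  C <- c(0, 0, tissue$R1f * M0f, tissue$R1Zs * (1 - d) * M0s,
         tissue$R1Zs * d * M0s, 0)
  M_eq <- c(0, 0, M0f, (1 - d) * M0s, d * M0s, 0)
  list(Lambda = L, C = C, M_eq = M_eq)
}

#' RF saturation rate of a frequency band
#'
#' W_j = pi * gamma^2 * <b_j^2> * g(Delta_j, T2s), where <b_j^2> is the mean
#' square band amplitude over the pulse duration. The offset argument of the
#' lineshape is taken as the band offset itself (chemical-shift corrections
#' Delta' = Delta - delta_omega are neglected).
#'
#' @param band_mean_square Mean square band amplitude over tau (uT^2).
#' @param delta_j Band offset (rad/s).
#' @param ls An [lineshape()] object.
#' @return Saturation rate in s^-1.
#' @export
saturation_rate <- function(band_mean_square, delta_j, ls) {
  if (any(band_mean_square < 0)) stop("band mean square must be >= 0")
  pi * GAMMA_1H^2 * band_mean_square * lineshape_g(ls, delta_j)
}

# Core Omega builder given on-resonance complex amplitude (uT) and per-band
# saturation rates W_j at offsets Delta_j.
.omega_build <- function(b1_onres, W, offsets, omega_loc) {
  if (omega_loc <= 0) stop("omega_loc must be positive")
  wx <- GAMMA_1H * Re(b1_onres); wy <- GAMMA_1H * Im(b1_onres)
  Om <- matrix(0, 6, 6)
  Om[1, 3] <- -wy; Om[2, 3] <- wx
  Om[3, 1] <- wy;  Om[3, 2] <- -wx
  D <- offsets / omega_loc
  Om[4, 4] <- -sum(W)
  Om[5, 5] <- -sum(W)
  Om[5, 6] <- sum(W * D)
  Om[6, 5] <- sum(W * D)
  Om[6, 6] <- -sum(W * D^2)
  Om
}

#' Time-averaged RF interaction matrix over a pulse
#'
#' Block-diagonal 6x6 generator: the upper-left free-pool block is the Bloch
#' rotation generator from the time-averaged on-resonance band amplitude
#' (only the Delta = 0 band rotates water); the lower-right semisolid block
#' sums the per-band Provotorov saturation terms over ALL bands including
#' Delta = 0: diagonal -W_j on both Zeeman pools, Zeeman--dipolar coupling
#' W_j*Delta_j/omega_loc on the s2 rows/columns, and -W_j*(Delta_j/
#' omega_loc)^2 on the dipolar diagonal. Symmetric bands at +/-Delta cancel
#' the coupling (the ihMT mechanism).
#'
#' @param pulse An `"ihmt_pulse"`.
#' @param tissue An `"ihmt_tissue"`.
#' @return 6x6 matrix <Omega> (time average over tau).
#' @export
omega_mean <- function(pulse, tissue) {
  stopifnot(inherits(pulse, "ihmt_pulse"), inherits(tissue, "ihmt_tissue"))
  t <- .pulse_time_grid(pulse$tau, pulse$dt)
  env <- .envelope_eval(pulse$envelope, t)
  onres <- pulse$bands[[which(pulse$band_offsets == 0)]]$coef * mean(env)
  W <- saturation_rate(pulse$band_mean_square, pulse$band_offsets,
                       tissue$lineshape)
  .omega_build(onres, W, pulse$band_offsets, tissue_omega_loc(tissue))
}
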