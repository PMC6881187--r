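# Closed-form periodic steady states under the instantaneous-pulse
# approximation. The RF pulse acts as R = exp(<Omega> * tau) applied at a
# single instant; free evolution over TR is S = exp(Lambda * TR) with drift
# (S - I) Lambda^-1 C. Spoiling / phase cycling enters through Phi applied
# immediately before each pulse:
#   SPGR : M+ = R Phi (S M+ + d)          (state just after a pulse)
#   bSSFP: M_mid = S_h R Phi (S_h M_mid + d_h) + d_h  (state at TR/2)
# Both are solved as linear fixed points; the printed resolvent forms follow.

#' RF pulse operator under the instantaneous approximation
#'
#' R = exp(<Omega> tau): block-diagonal, a rotation of the free pool by the
#' flip angle about the pulse phase axis and a contraction of the semisolid
#' Zeeman/dipolar block.
#'
#' @param pulse An `"ihmt_pulse"`.
#' @param tissue An `"ihmt_tissue"`.
#' @return 6x6 matrix.
#' @export
rf_operator <- function(pulse, tissue) {
  Om <- omega_mean(pulse, tissue)
  R <- diag(6)
  R[1:3, 1:3] <- .expm_rotation(Om[1:3, 1:3] * pulse$tau)
  R[4:6, 4:6] <- .expm_symmetric(Om[4:6, 4:6] * pulse$tau)
  R
}

# exp of the skew-symmetric free-pool generator (Rodrigues formula)
.expm_rotation <- function(G) {
  th <- sqrt(G[3, 1]^2 + G[3, 2]^2)   # rotation angle
  if (th < 1e-300) return(diag(3))
  diag(3) + (sin(th) / th) * G + ((1 - cos(th)) / th^2) * (G %*% G)
}

# exp of the symmetric semisolid saturation block via eigendecomposition
.expm_symmetric <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Free relaxation/exchange propagator and drift
#'
#' S = exp(Lambda t), drift = (S - I) Lambda^-1 C, so that propagation over
#' time t is M -> S M + drift.
#'
#' @param tissue An `"ihmt_tissue"`.
#' @param t Propagation time (s).
#' @param delta_omega Free-pool off-resonance (rad/s).
#' @return List with `S` (6x6) and `drift` (length 6).
#' @export
relax_operator <- function(tissue, t, delta_omega = 0) {
  lc <- bmp_lambda(tissue, delta_omega)
  S <- .expm(lc$Lambda * t)
  drift <- as.vector((S - diag(6)) %*% solve(lc$Lambda, lc$C))
  list(S = S, drift = drift)
}

.PHI_SPGR <- diag(c(0, 0, 1, 1, 1, 1))
.PHI_BSSFP <- diag(c(-1, -1, 1, 1, 1, 1))

.check_resolvent <- function(A) {
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1 - 1e-12)
    stop("steady-state resolvent does not converge (spectral radius >= 1)")
}

#' SPGR steady state (instantaneous pulses)
#'
#' Perfectly spoiled gradient echo: transverse magnetization is zeroed before
#' each pulse (Phi = diag(0,0,1,1,1,1)). Returns the magnetization
#' immediately after an RF pulse and the echo signal
#' |Mxyf| * exp(-TE * R2f). Reduces exactly to the Ernst single-pool formula
#' when M0s = 0.
#'
#' @param pulse An `"ihmt_pulse"`.
#' @param tissue An `"ihmt_tissue"`.
#' @param seq An [seq_settings()] with `readout = "spgr"`.
#' @param ro Optional precomputed [relax_operator()] over TR (reused across
#'   pulses sharing one tissue/TR).
#' @return List with `M` (length-6 state) and `signal`.
#' @export
spgr_steady_state <- function(pulse, tissue, seq, ro = NULL) {
  stopifnot(inherits(seq, "ihmt_seq"))
  if (seq$readout != "spgr") stop("seq$readout must be 'spgr'")
  if (is.null(ro)) ro <- relax_operator(tissue, seq$TR, seq$delta_omega)
  R <- rf_operator(pulse, tissue)
  RP <- R %*% .PHI_SPGR
  A <- RP %*% ro$S
  .check_resolvent(A)
  M <- solve(diag(6) - A, as.vector(RP %*% ro$drift))
  sig <- sqrt(M[1]^2 + M[2]^2) * exp(-seq$TE * tissue$R2f)
  list(M = M, signal = sig)
}

#' Balanced SSFP steady state (instantaneous pulses)
#'
#' pi-phase-cycled bSSFP (Phi = diag(-1,-1,1,1,1,1) applied once per TR,
#' equivalent to alternating pulse phase). Returns the state at the midpoint
#' between two pulses and the signal |Mxyf| there. With M0s = 0 and
#' delta_omega = 0 this reproduces the single-pool alternating-phase bSSFP
#' closed form.
#'
#' @inheritParams spgr_steady_state
#' @param correct_finite_pulse Apply the finite-pulse (Bieri-Scheffler) R2f
#'   correction of [bieri_scheffler_r2()] before building the propagators.
#' @param ro Optional precomputed [relax_operator()] over TR/2 (must already
#'   reflect any R2f correction; `correct_finite_pulse` is then ignored for
#'   the free propagator but still not applied twice).
#' @return List with `M` and `signal`.
#' @export
bssfp_steady_state <- function(pulse, tissue, seq,
                               correct_finite_pulse = FALSE, ro = NULL) {
  stopifnot(inherits(seq, "ihmt_seq"))
  if (seq$readout != "bssfp") stop("seq$readout must be 'bssfp'")
  if (correct_finite_pulse && is.null(ro))
    tissue <- tissue_update(
      tissue, R2f = bieri_scheffler_r2(tissue$R1f, tissue$R2f,
                                       equivalent_duration(pulse), seq$TR))
  if (is.null(ro)) ro <- relax_operator(tissue, seq$TR / 2, seq$delta_omega)
  R <- rf_operator(pulse, tissue)
  RP <- R %*% .PHI_BSSFP
  A <- ro$S %*% RP %*% ro$S
  .check_resolvent(A)
  b <- as.vector(ro$S %*% RP %*% ro$drift) + ro$drift
  M <- solve(diag(6) - A, b)
  list(M = M, signal = sqrt(M[1]^2 + M[2]^2))
}

#' Steady-state signal dispatcher
#'
#' Convenience wrapper calling [spgr_steady_state()] or
#' [bssfp_steady_state()] according to `seq$readout`.
#'
#' @inheritParams bssfp_steady_state
#' @return List with `M` and `signal`.
#' @export
steady_state_signal <- function(pulse, tissue, seq,
                                correct_finite_pulse = (seq$readout ==
                                                          "bssfp")) {
  if (seq$readout == "spgr") spgr_steady_state(pulse, tissue, seq)
  else bssfp_steady_state(pulse, tissue, seq, correct_finite_pulse)
}

#' Equivalent rectangular duration of a shaped pulse
#'
#' Duration of the rectangular pulse with the same flip angle and the same
#' RF energy as the on-resonance band: tau_eq = (integral of b dt)^2 /
#' integral of b^2 dt. For the Gaussian sub-pulse used here tau_eq is about
#' 0.59 * tau. This is the pulse-duration argument of the finite-pulse
#' correction, whose coefficient set was derived for hard pulses.
#'
#' @param pulse An `"ihmt_pulse"`.
#' @return Equivalent duration in seconds (0 for a zero pulse).
#' @export
equivalent_duration <- function(pulse) {
  stopifnot(inherits(pulse, "ihmt_pulse"))
  t <- .pulse_time_grid(pulse$tau, pulse$dt)
  env <- .envelope_eval(pulse$envelope, t)
  e2 <- sum(env^2) * pulse$dt
  if (e2 == 0) return(0)
  (sum(env) * pulse$dt)^2 / e2
}

#' Finite-pulse correction to the transverse relaxation rate
#'
#' During a finite RF pulse the magnetization is partially locked along the
#' effective field rather than relaxing freely in the transverse plane, so
#' the instantaneous-pulse bSSFP model over-predicts transverse decay. The
#' correction substitutes an effective transverse rate
#' R2' = R2f * (1 - zeta * tau/TR) with
#' zeta = 0.68 - 0.125 * (1 + tau/TR) * T2f/T1f (free-pool rates substituted
#' into the single-pool coefficient set, which was derived for hard pulses).
#' For shaped pulses, pass the flip-and-energy [equivalent_duration()] as
#' `tau`. The correction vanishes as tau/TR -> 0 and always reduces R2f. The
#' coefficient set lives entirely in this function.
#'
#' @param R1f,R2f Free-pool relaxation rates (s^-1).
#' @param tau Hard-pulse (equivalent) duration (s), 0 <= tau < TR.
#' @param TR Repetition time (s).
#' @return Corrected R2f (s^-1).
#' @export
bieri_scheffler_r2 <- function(R1f, R2f, tau, TR) {
  if (tau < 0 || tau >= TR) stop("need 0 <= tau < TR")
  if (tau == 0) return(R2f)
  t2_over_t1 <- R1f / R2f
  zeta <- 0.68 - 0.125 * (1 + tau / TR) * t2_over_t1
  r2c <- R2f * (1 - zeta * tau / TR)
  if (r2c <= 0) stop("finite-pulse correction drove R2f non-positive")
  r2c
}
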