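# Tissue / sample parameter sets for the two-semisolid-pool BMP model.
# Conventions: M0f + M0s = 1; pools s1 (Zeeman only) and s2 (Zeeman +
# dipolar) occupy fractions (1 - delta) and delta of the semisolid
# compartment; k is the intrinsic (not directional) exchange rate; all rates
# in s^-1, times in s.

#' Tissue parameter set for the BMP model
#'
#' @param R1f,R2f Free water longitudinal / transverse relaxation rates
#'   (s^-1).
#' @param R1Zs Semisolid Zeeman longitudinal relaxation rate (s^-1), shared by
#'   pools s1 and s2.
#' @param R1Ds Dipolar order relaxation rate (s^-1); T1D = 1/R1Ds.
#' @param T2s Semisolid transverse relaxation time (s), enters only through
#'   the lineshape.
#' @param k Intrinsic exchange rate between free water and semisolid pools
#'   (s^-1).
#' @param M0s Semisolid pool fraction, 0 <= M0s < 1; M0f = 1 - M0s.
#' @param delta Dipolar-coupled fraction of the semisolid pool, 0 <= delta
#'   <= 1.
#' @param lineshape_kind `"super_lorentzian"` or `"gaussian"`.
#' @param omega_loc Optional local dipolar field strength (rad/s). When `NA`
#'   (default), it is derived from the lineshape second moment via
#'   [local_field_omega()].
#' @return An object of class `"ihmt_tissue"`.
#' @examples
#' wm <- tissue_preset("white_matter_1p5T")
#' wm$M0s
#' @export
tissue_params <- function(R1f, R2f, R1Zs, R1Ds, T2s, k, M0s, delta,
                          lineshape_kind = c("super_lorentzian", "gaussian"),
                          omega_loc = NA_real_) {
  lineshape_kind <- match.arg(lineshape_kind)
  rates <- c(R1f = R1f, R2f = R2f, R1Zs = R1Zs, R1Ds = R1Ds, k = k)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all relaxation/exchange rates must be positive and finite")
  if (T2s <= 0) stop("T2s must be positive")
  if (M0s < 0 || M0s >= 1) stop("M0s must satisfy 0 <= M0s < 1")
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  ls <- lineshape(lineshape_kind, T2s)
  structure(list(R1f = R1f, R2f = R2f, R1Zs = R1Zs, R1Ds = R1Ds, T2s = T2s,
                 k = k, M0s = M0s, delta = delta, lineshape = ls,
                 omega_loc = omega_loc),
            class = "ihmt_tissue")
}

#' @export
print.ihmt_tissue <- function(x, ...) {
  cat("<ihmt_tissue>\n")
  cat(sprintf("  R1f %.4g  R2f %.4g  R1Zs %.4g  R1Ds %.4g s^-1\n",
              x$R1f, x$R2f, x$R1Zs, x$R1Ds))
  cat(sprintf("  k %.4g s^-1  M0s %.4g  delta %.4g  T2s %.3g us (%s)\n",
              x$k, x$M0s, x$delta, x$T2s * 1e6, x$lineshape$kind))
  cat(sprintf("  omega_loc %s rad/s\n",
              if (is.na(x$omega_loc)) sprintf("%.4g (derived)",
                                              tissue_omega_loc(x))
              else sprintf("%.4g (supplied)", x$omega_loc)))
  invisible(x)
}

#' Effective local field strength of a tissue set
#'
#' Returns the supplied `omega_loc` when present, otherwise derives it from
#' the lineshape second moment.
#' @param tissue An `"ihmt_tissue"`.
#' @return Angular frequency (rad/s).
#' @export
tissue_omega_loc <- function(tissue) {
  stopifnot(inherits(tissue, "ihmt_tissue"))
  if (!is.na(tissue$omega_loc)) return(tissue$omega_loc)
  local_field_omega(tissue$lineshape)
}

#' Named tissue presets
#'
#' `"white_matter_1p5T"` is the literature white-matter set used throughout
#' the simulations (internal-capsule values at 1.5 T, super-Lorentzian
#' lineshape). The phantom presets (`"MnCl2"`, `"BSA"`, `"PL161"`, `"HC"`)
#' are the fitted phantom values (rates are the inverses of the reported
#' times; Gaussian lineshape, as used for all phantom fits). MnCl2 has no
#' semisolid pool; nuisance semisolid rates are set to unit placeholders.
#'
#' @param name Preset name.
#' @return An `"ihmt_tissue"`.
#' @export
tissue_preset <- function(name = c("white_matter_1p5T", "MnCl2", "BSA",
                                   "PL161", "HC")) {
  name <- match.arg(name)
  switch(name,
    white_matter_1p5T = tissue_params(
      R1f = 1.54, R2f = 12.5, R1Zs = 1, R1Ds = 154, T2s = 12.5e-6,
      k = 65, M0s = 0.147, delta = 0.65,
      lineshape_kind = "super_lorentzian"),
    MnCl2 = tissue_params(
      R1f = 1 / 2.174, R2f = 1 / 0.683, R1Zs = 1, R1Ds = 1, T2s = 12e-6,
      k = 1, M0s = 0, delta = 0, lineshape_kind = "gaussian"),
    BSA = tissue_params(
      R1f = 1 / 1.643, R2f = 1 / 0.0532, R1Zs = 1 / 0.130, R1Ds = 100,
      T2s = 17.6e-6, k = 70.1, M0s = 0.075, delta = 0,
      lineshape_kind = "gaussian"),
    PL161 = tissue_params(
      R1f = 1 / 1.912, R2f = 1 / 0.0728, R1Zs = 1 / 0.202,
      R1Ds = 1 / 0.0207, T2s = 17.5e-6, k = 46.7, M0s = 0.150, delta = 1,
      lineshape_kind = "gaussian"),
    HC = tissue_params(
      R1f = 1 / 1.975, R2f = 1 / 0.158, R1Zs = 1 / 0.189, R1Ds = 1 / 0.0233,
      T2s = 19.2e-6, k = 67.8, M0s = 0.060, delta = 0.683,
      lineshape_kind = "gaussian")
  )
}

#' Serialize / deserialize tissue parameters
#'
#' Round-trips an `"ihmt_tissue"` through a plain named list suitable for
#' YAML or JSON configuration files.
#'
#' @param tissue An `"ihmt_tissue"`.
#' @return `tissue_to_list()`: a named list; `tissue_from_list()`: an
#'   `"ihmt_tissue"`.
#' @export
tissue_to_list <- function(tissue) {
  stopifnot(inherits(tissue, "ihmt_tissue"))
  list(R1f = tissue$R1f, R2f = tissue$R2f, R1Zs = tissue$R1Zs,
       R1Ds = tissue$R1Ds, T2s = tissue$T2s, k = tissue$k, M0s = tissue$M0s,
       delta = tissue$delta, lineshape = tissue$lineshape$kind,
       omega_loc = if (is.na(tissue$omega_loc)) NULL else tissue$omega_loc)
}

#' @rdname tissue_to_list
#' @param x A named list as produced by `tissue_to_list()` (or parsed from
#'   YAML/JSON), optionally with a `preset` entry naming a base preset whose
#'   fields the list overrides.
#' @export
tissue_from_list <- function(x) {
  if (!is.null(x$preset)) {
    base <- tissue_to_list(tissue_preset(x$preset))
    x$preset <- NULL
    base[names(x)] <- x
    x <- base
  }
  tissue_params(R1f = x$R1f, R2f = x$R2f, R1Zs = x$R1Zs, R1Ds = x$R1Ds,
                T2s = x$T2s, k = x$k, M0s = x$M0s, delta = x$delta,
                lineshape_kind = x$lineshape,
                omega_loc = if (is.null(x$omega_loc)) NA_real_
                            else x$omega_loc)
}

#' Modify fields of a tissue parameter set
#'
#' @param tissue An `"ihmt_tissue"`.
#' @param ... Named scalar fields to replace (any argument of
#'   [tissue_params()], with `lineshape` naming the kind).
#' @return A new `"ihmt_tissue"`.
#' @export
tissue_update <- function(tissue, ...) {
  x <- tissue_to_list(tissue)
  mods <- list(...)
  x[names(mods)] <- mods
  tissue_from_list(x)
}

#' Sequence settings
#'
#' @param readout `"spgr"` (perfectly spoiled gradient echo) or `"bssfp"`
#'   (pi-phase-cycled balanced SSFP).
#' @param TR Repetition time (s).
#' @param tau RF pulse duration (s), tau <= TR.
#' @param TE Echo time (s), TE <= TR; used only by the SPGR echo factor
#'   exp(-TE*R2f). Default TR/2.
#' @param delta_omega Free-pool off-resonance (rad/s); enters the transverse
#'   precession terms only.
#' @return An `"ihmt_seq"` list.
#' @export
seq_settings <- function(readout = c("bssfp", "spgr"), TR, tau,
                         TE = TR / 2, delta_omega = 0) {
  readout <- match.arg(readout)
  if (tau > TR) stop("tau must be <= TR")
  if (TE > TR) stop("TE must be <= TR")
  structure(list(readout = readout, TR = TR, tau = tau, TE = TE,
                 delta_omega = delta_omega),
            class = "ihmt_seq")
}
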