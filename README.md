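# ihmtss — steady-state inhomogeneous magnetization transfer signal modeling

Inhomogeneous magnetization transfer (ihMT) is an MRI contrast mechanism
sensitive to dipolar order in structured semisolids — most prominently
myelin — measured as the signal difference between single-offset and
dual-offset off-resonance saturation. `ihmtss` models ihMT generated
*within* rapid steady-state gradient-echo sequences (spoiled gradient echo
and balanced SSFP) by nonselective multiband RF pulses that excite water on
resonance and saturate the semisolid at one (2B) or two symmetric (3B)
frequency offsets, under a fixed whole-sequence RMS B1. It is aimed at
quantitative-MRI researchers designing or analyzing such sequences.

At its core is the Bloch–McConnell–Provotorov (BMP) system for the state
`M = [Mxf, Myf, Mzf, MZs1, MZs2, MDs2]` — free-water Bloch components, a
classic semisolid Zeeman pool, and a dipolar-coupled pool (fraction
`delta`) holding both Zeeman and dipolar order:

    dM/dt = (Omega + Lambda) M + C

Each RF band `j` saturates the semisolid at
`W_j = pi * gamma^2 * <b_j^2> * g(Delta_j, T2s)` and couples Zeeman to
dipolar order with strength `W_j * Delta_j / omega_loc`; symmetric bands at
`+/-Delta` cancel the coupling, which is the ihMT effect. The package
provides:

* Gaussian and (on-resonance-extrapolated) super-Lorentzian lineshapes and
  the local field `omega_loc` from the lineshape second moment;
* multiband Gaussian pulse synthesis meeting a target whole-sequence B1rms
  exactly, with per-band power bookkeeping and peak-B1 feasibility maps;
* closed-form SPGR / phase-cycled bSSFP steady states under the
  instantaneous-pulse approximation, with a finite-pulse transverse
  relaxation correction;
* an exact periodic steady state for shaped pulses via an augmented (7x7)
  propagator and its unit eigenvector, plus deviation maps quantifying the
  instantaneous approximation;
* MTR / ihMT-difference / ihMTR metrics and flip-angle x offset sweeps with
  quadratic peak refinement;
* `ihmt_fit()`: joint bounded model fitting to multi-sequence signal
  datasets (classic formula-object interface with `print`, `summary`,
  `coef`, `predict`, `plot`, `residuals`, `simulate` methods) and residual
  bootstrap uncertainties, plus a synthetic 64-measurement phantom-protocol
  generator.

## Worked example

White-matter ihMT contrast for a bSSFP sequence (TR 5 ms, 2 ms pulses,
whole-sequence B1rms 5 uT):

```r
library(ihmtss)
wm <- tissue_preset("white_matter_1p5T")
wm
#> <ihmt_tissue>
#>   R1f 1.54  R2f 12.5  R1Zs 1  R1Ds 154 s^-1
#>   k 65 s^-1  M0s 0.147  delta 0.65  T2s 12.5 us (super_lorentzian)
#>   omega_loc 2.066e+04 (derived) rad/s

sw <- ihmt_sweep(wm, flips_deg = seq(5, 80, by = 5),
                 deltas_hz = seq(2e3, 15e3, by = 1e3),
                 TR = 5e-3, tau = 2e-3, b1rms = 5)
sw
#> <ihmt_sweep> bssfp, TR 5 ms, tau 2 ms, B1rms 5 uT
#>   16 flips x 14 offsets
#>   peak dihMT 0.007628 at flip 28.8 deg, offset 7.75 kHz

pk <- find_peak(sw$dihmt, sw$flips_deg, sw$deltas_hz)
sw$ihMTR[pk$i, pk$j]
#> [1] 5.65
```

The ihMT difference `S2B - S3B` peaks near a 29-degree flip angle and a
7.8 kHz offset at about 0.76 % of the total magnetization; the ihMT ratio
there is ~5.7 % of the single-band signal and the classic MTR ~34 % — the
contrast levels expected for white matter with this sequence family.

Fitting the model to a synthetic phantom dataset (64 measurements: bSSFP
10–80 deg, SPGR 2–16 deg, bands 1B/2+B/2-B/3B, SNR 100):

```r
acq <- acquisition_params()        # TR 5 ms, TE 2.5 ms, tau 2.2 ms, 8 kHz, 4.2 uT
pl  <- tissue_preset("PL161")      # lamellar liquid-crystal phantom, delta = 1
dat <- simulate_phantom_dataset(pl, acq, scale = 100, snr = 100, seed = 1)
fit <- ihmt_fit(dat, acq,
                start = tissue_update(pl, R1f = 0.7, R2f = 18, M0s = 0.1),
                free = c("R1f", "R2f", "M0s"), n_starts = 4,
                n_bootstrap = 100, seed = 1)
summary(fit)
#> ihMT steady-state fit: 64 rows, NRMSE 0.749% (rms)
#>         estimate    boot_se  as_time
#> R1f   5.2809e-01 5.0156e-03 1893.634
#> R2f   1.3811e+01 8.6098e-02   72.407
#> M0s   1.5052e-01 9.0611e-04        -
#> scale 1.0002e+02 3.0377e-01        -
#> bootstrap: 100 resamples, 0 failed
```

The generating values (R1f = 0.523 s^-1, R2f = 13.74 s^-1, M0s = 0.150,
scale = 100) are recovered within the bootstrap uncertainty, and the NRMSE
sits at the injected noise floor. Rates are fitted as rates; `as_time`
reports them as milliseconds.

A thin command-line front end (`exec/ihmt`) exposes `simulate`, `sweep`,
`validate-approx`, `fit`, `make-phantom` and `pulse-design` subcommands
over YAML configurations (flip angles in degrees, offsets in kHz, B1 in uT,
times in ms); see `inst/extdata/example_*.yaml`.

## The methods vignette

`vignettes/ihmt-steady-state-model.Rmd` documents the model and its
assumptions, the pulse-design conventions, the finite-pulse correction and
its equivalent-duration treatment for shaped pulses, the integrator, the
fitting machinery, and known limitations.
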