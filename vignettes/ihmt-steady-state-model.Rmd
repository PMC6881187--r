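---
title: "Modeling steady-state ihMT contrast with multiband pulses"
author: "ihmtss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling steady-state ihMT contrast with multiband pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihmtss)
```

## The model

Inhomogeneous magnetization transfer (ihMT) is an MRI contrast mechanism
specific to semisolids whose dipolar-coupled spin reservoir can hold
long-lived dipolar order — lamellar structures such as myelin. `ihmtss`
models ihMT generated *inside* rapid gradient-echo sequences by
spatially nonselective multiband RF pulses that excite water on resonance
while simultaneously saturating the semisolid at one or two symmetric
frequency offsets.

The magnetization state is the six-vector
$M = [M_x^f, M_y^f, M_z^f, M_Z^{s1}, M_Z^{s2}, M_D^{s2}]^T$:
free-water Bloch components, a "classic" semisolid Zeeman pool $s1$
(fraction $1-\delta$ of the semisolid compartment), and a dipolar-coupled
pool $s2$ (fraction $\delta$) carrying both Zeeman and dipolar order. Its
evolution obeys the Bloch–McConnell–Provotorov (BMP) equations

$$\dot M = (\Omega + \Lambda) M + C,$$

where $\Lambda$ and $C$ collect relaxation and exchange: free-pool rates
$R_1^f, R_2^f$, semisolid Zeeman rate $R_1^{Zs}$ (shared by $s1$ and
$s2$), dipolar rate $R_1^{Ds}$ ($T_{1D} = 1/R_1^{Ds}$), and an *intrinsic*
exchange rate $k$ between water and semisolid with fractions
$M_0^f + M_0^s = 1$. Exchange follows detailed balance — the free pool
loses at $k M_0^s$ and gains at $k M_0^f$ from each Zeeman pool — so
thermal equilibrium $[0,0,M_0^f,(1-\delta)M_0^s,\delta M_0^s,0]$ is an
exact stationary point (`bmp_lambda()`; tested at machine precision).

RF interaction is block diagonal (`omega_mean()`): the free pool sees the
usual Bloch rotation from the *on-resonance* band only, while the
semisolid absorbs from **every** band $j$ at rate
$W_j = \pi \gamma^2 \langle b_{\Delta_j}^2 \rangle\, g(\Delta_j, T_2^s)$
with $g$ the absorption lineshape. Off-resonant irradiation at offset
$\Delta_j$ couples Zeeman and dipolar order of $s2$ with strength
$W_j \Delta_j/\omega_\mathrm{loc}$; because the coupling is linear in
$\Delta_j$, symmetric bands at $\pm\Delta$ cancel it. That closed pathway
is the ihMT effect: three-band pulses saturate the Zeeman pool more
efficiently than two-band pulses of equal total power, and the signal
difference $S_{2B} - S_{3B}$ isolates the dipolar reservoir.

## Lineshapes and the local field

Two lineshapes are provided in angular-frequency normalization
($\int g\,d\Delta = 1$ over rad/s, so $g$ has units s/rad): a Gaussian
(used for the phantom materials) and the super-Lorentzian orientation
average (used for white matter), evaluated by 128-node Gauss–Legendre
quadrature over the fiber-orientation angle and checked against adaptive
quadrature in the tests. The super-Lorentzian is singular on resonance;
inside $\pm 1$ kHz it is replaced by an even quadratic matched in value
and one-sided slope at the window edges
(`super_lorentzian_extrapolated()`). Any smooth symmetric interpolant
anchored there is defensible; the choice is isolated in that one function.

The local dipolar field $\omega_\mathrm{loc}$ sets the Zeeman–dipolar
coupling scale. It is derived from the lineshape second moment $M_2$
($1/T_2^{s2}$ Gaussian, $1/(5 T_2^{s2})$ super-Lorentzian) with the
convention $\omega_\mathrm{loc} = \sqrt{M_2/3}$ by default. Conventions
differ across the literature, so `local_field_omega()` also offers
$\sqrt{M_2}$ and every tissue set accepts an explicit `omega_loc`
override; the default convention reproduces the published white-matter
contrast levels (a peak ihMT difference near 0.7 % of $M_0$ and a fully
coupled ihMT ratio near 10 %), which is how we fixed it.

## Multiband pulses

Pulses are Gaussian sub-pulses (time-bandwidth product 2.26, truncated at
the nominal duration $\tau$, sampled at 2 µs by default) multiplied by a
modulation adding bands at $+\Delta$, $-\Delta$, or $\pm\Delta$. The design
constraint is the whole-sequence RMS field
$B_1^\mathrm{rms} = \sqrt{\tfrac{1}{TR}\int_0^\tau |B_1|^2 dt}$, the
SAR-relevant quantity. With
$\beta = (\langle B_1^2\rangle_{TOT} - \langle B_1^2(0)\rangle)/
\langle B_1^2(0)\rangle$ a *power* ratio, the off-band amplitudes are
$\sqrt{\beta}\,b_0(t)$ (2B) or $\sqrt{\beta/2}\,b_0(t)$ per band (3B); a
printed amplitude-scaling reading of the modulation functions would be
dimensionally inconsistent with the power definition of $\beta$, so the
power convention is enforced and a final scalar on the off-resonant
component absorbs the (sub-0.5 %) band cross terms, making the realized
$B_1^\mathrm{rms}$ match the target exactly (`make_multiband()`). The
modulation phase is referenced to the pulse center, so the 3B waveform is
real and symmetric and has the highest peak $B_1$ at equal power
($1 + \sqrt{2\beta}$ versus $1 + \sqrt{\beta}$ relative to the sub-pulse
peak), which is what couples peak-amplitude hardware limits to TR and
$B_1^\mathrm{rms}$ (`max_b1_map()`).

## Steady states

Under the instantaneous-pulse approximation the pulse acts as
$R = \exp(\langle\Omega\rangle\tau)$ and free evolution over $t$ is
$S = \exp(\Lambda t)$ with drift $(S - I)\Lambda^{-1} C$. Spoiling or
$\pi$ phase cycling enters as a diagonal $\Phi$ applied immediately before
each pulse. Because the published resolvent expressions are typeset
ambiguously, both steady states are implemented as the unambiguous fixed
points of the cycle and *verified by one-TR invariance* in the tests:

* SPGR (perfect spoiling, $\Phi = \mathrm{diag}(0,0,1,1,1,1)$):
  $M^+ = (I - R\Phi S)^{-1} R\Phi\,(S-I)\Lambda^{-1}C$, the state just
  after a pulse; the echo signal is $|M_{xy}^f| e^{-TE\,R_2^f}$.
* bSSFP ($\Phi = \mathrm{diag}(-1,-1,1,1,1,1)$): the fixed point of
  midpoint → half-TR relaxation → $\Phi$ → $R$ → half-TR relaxation,
  reported at the midpoint between pulses.

Both reduce to the textbook Ernst and alternating-phase bSSFP formulas at
$M_0^s = 0$ (to 1e-10 in the tests).

### Finite-pulse correction

The pulses here occupy a large fraction of TR (up to 50 %), and during a
pulse the transverse magnetization is partially locked along the effective
field instead of dephasing. For bSSFP this is absorbed by an effective
transverse rate $R_2' = R_2^f\,(1 - \zeta\,\tau_{eq}/TR)$ with
$\zeta = 0.68 - 0.125 (1 + \tau_{eq}/TR)\, T_2^f/T_1^f$
(`bieri_scheffler_r2()`). The coefficient set is a hard-pulse result: with
rectangular pulses our exact integrator reproduces it closely (empirical
optimum 0.64–0.70 over flips 30–90°, against 0.658 from the formula).
Shaped pulses are therefore mapped to their flip-and-energy-equivalent
rectangular pulse, $\tau_{eq} = (\int b\,dt)^2 / \int b^2\,dt \approx
0.59\,\tau$ for this Gaussian (`equivalent_duration()`); with the nominal
$\tau$ instead, the correction overshoots by roughly a factor two. The
coefficients live in a single function so a different published set can be
swapped without touching the rest of the model.

## Exact periodic steady state

To validate the instantaneous approximation, the BMP equations are
integrated through the shaped pulse: the affine system is embedded in a
homogeneous 7-dimensional one, $\tilde A = [[A, C], [0, 0]]$, the one-TR
propagator is the left-multiplied product of per-step matrix exponentials
(step 10 µs; each step's $\Omega$ uses the instantaneous per-band
amplitudes), and the periodic steady state is the eigenvector of that
propagator with unit eigenvalue, normalized so its augmented component is
1 (`one_tr_propagator()`, `steady_state_eigen()`). This replaces forward
iteration over hundreds of TRs and agrees with 1000-TR iteration to 1e-8
in the tests; halving the step changes signals by ~1e-6 relative.
Integration starts at the pulse end for SPGR and at the TR midpoint for
bSSFP, matching the closed-form output points; deviations are quoted
between those natural common points (for SPGR the echo factor is common to
both models and cancels). The 10 µs default is a convergence choice, not a
hardware constraint; `steady_state_eigen()` rejects degenerate cycles with
more than one unit eigenvalue.

A known residual: at the extreme corner of the validation grid (2.5 ms
pulses, $T_{1D}$ = 0.1 ms, 60° bSSFP) the corrected instantaneous model
retains a deviation of about 3.4 % against full integration, of which
~1.5 points is a $T_{1D}$-independent baseline caused by exchange and
saturation acting *simultaneously* during the long pulse — physics that a
single-pool transverse-relaxation correction cannot represent (it vanishes
as $k \to 0$ or $M_0^s \to 0$). The dipolar-specific increment above that
baseline matches the expected short-$T_{1D}$/long-$\tau$ pattern.

## Contrast metrics and sweeps

`mtr()`, `delta_ihmt()` and `ihmtr()` implement
$\mathrm{MTR} = (S_{1B}-S_{2B})/S_{1B}$,
$\Delta\mathrm{ihMT} = S_{2B}-S_{3B}$ and
$\mathrm{ihMTR} = \Delta\mathrm{ihMT}/S_{1B}$ (percent). Note this ihMTR
definition is a factor ~2 smaller than conventions that double the
difference term; compare across studies with care. In measured data
$S_{2B}$ should be the mean of the $+\Delta$ and $-\Delta$ acquisitions;
in simulations the model is exactly symmetric, so `ihmt_sweep()` computes
a single 2B signal. Sweeps regenerate the multiband pulses at every grid
point to hold the total $B_1^\mathrm{rms}$ fixed, while single-band
reference signals use only the on-resonance component (their
$B_1^\mathrm{rms}$ varies with flip angle, as acquired in practice).
Default grid steps (2° in flip, 250 Hz in offset) keep the separable
quadratic refinement of `find_peak()` stable around the white-matter
optimum near 30° and 8 kHz; ties break toward smaller flip, then smaller
offset.

## Fitting

`ihmt_fit()` jointly fits all rows of a multi-sequence dataset (the
synthetic phantom protocol: 64 measurements, bSSFP 10–80° and SPGR 2–16°,
bands 1B/2⁺B/2⁻B/3B at TR 5 ms, TE 2.5 ms, $\tau$ 2.2 ms, 8 kHz,
4.2 µT). Predictions use the corrected bSSFP and echo-scaled SPGR steady
states; 2⁺B/2⁻B rows share one prediction; a common scale factor absorbs
unknown image scaling, making the fit exactly invariant to global
rescaling. Optimization is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) from a seeded Latin-hypercube multi-start inside
the bounds; the default bounds (`default_fit_bounds()`) are plausible
decades around literature phantom values and are explicitly
non-canonical. NRMSE is normalized by the RMS of the observed data by
default (a `"range"` option is provided since the normalizer convention is
not universal). Rates are fitted as rates and additionally reported as
times by `summary()`. `residual_bootstrap()` (default 500 resamples,
refits capped at 25 iterations from the point estimate) provides standard
errors and flags residual autocorrelation, where the residual bootstrap is
less trustworthy. Known degeneracies — notably between $\delta$, $k$ and
the semisolid $T_1$ — mean the recommended presets fix $\delta$ at 0 or 1
unless the data clearly demand otherwise.

## The synthetic phantom generator

`simulate_phantom_dataset()` emulates the tube-averaged signal means of
the phantom experiment: noiseless model signals for a chosen material
preset (MnCl2, BSA, PL161, HC, or any tissue set) scaled by an arbitrary
image scale, plus additive Gaussian noise with standard deviation
mean(signal)/SNR (SNR 100 by default, matching high-quality tube
averages). It does *not* emulate Rician magnitude bias (negligible at
these SNRs; an additive-Gaussian choice keeps the noise model exactly
matched to the least-squares objective), off-resonance banding, B1
inhomogeneity, MT asymmetry from a chemically shifted semisolid line, or
structured residuals from unmodeled pools — so passing recovery tests
demonstrate estimator correctness under the stated model, not robustness
to those real-world effects.

## Problem sizes and numerical choices

Defaults used by the tests and the acceptance script: 8 pulse durations ×
7 dipolar relaxation times for the validation grids (the grid maximum
sits at the corner, so density matters little); a 38 × 53 flip/offset
sweep; 500 bootstrap resamples on the 64-row protocol. Waveforms are
synthesized at 2 µs (10 µs inside sweeps, where only band powers and the
mean on-resonance amplitude enter); integration uses 10 µs steps;
Gauss–Legendre order 128 for the orientation integral; the unit
eigenvalue must lie within 1e-6 (degeneracy test at 1e-9). All
computations are deterministic given the seed.

## Limitations

Single free-water pool and a single semisolid compartment split in two;
no chemical-shift asymmetry of the semisolid line ($\Delta' \approx
\Delta$); perfect SPGR spoiling rather than an RF-spoiling schedule; one
off-resonance value per simulation (no bSSFP banding profiles); no SAR or
hardware modeling beyond peak-$B_1$ arithmetic; fitting assumes the
acquisition constants are known exactly.
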