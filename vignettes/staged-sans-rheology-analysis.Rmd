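---
title: "Staged SANS and rheology analysis of salt-free polyelectrolytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged SANS and rheology analysis of salt-free polyelectrolytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sansrheo)
```

## The system and the model

Salt-free solutions of a charged semiflexible polysaccharide
(carboxymethyl cellulose, degree of substitution ~1.2) are probed by two
complementary measurements. Small-angle neutron scattering sees the
chain cross-section at high q, the interchain correlation peak at
intermediate q, and an unexplained cluster-like upturn at low q.
Steady-shear rheology sees the zero-shear viscosity and the onset of
shear thinning. Polyelectrolyte scaling theory connects the two through
the correlation length $\xi = 2\pi/q^*$.

The scattered intensity is modelled as

$$I(q) = \frac{I_0}{q}\left[\frac{2J_1(q r_p)}{q r_p}\right]^2 P(q)
  + S_\mathrm{inc} + D\,q^{-n},$$

with the following ingredients and assumptions:

* **Chain term.** At length scales below the correlation length the chain
  is assumed locally straight, so its form factor is the rigid-rod
  $1/q$ asymptote times the cross-section factor of a homogeneous
  circular cylinder of radius $r_p$ ($J_1$ is the first-order Bessel
  function). $I_0$ absorbs contrast, concentration and monomer length.
  A Gaussian cross-section profile would change $r_p$ only by a bounded
  shape factor; the step profile is the convention here.
* **Peak multiplier.** The interchain structure factor of salt-free
  polyelectrolytes has no tractable closed form, so the peak is carried
  by a purely descriptive multiplier
  $$P(q) = \frac{1 + m\,e^{-(q-d)^2/2k^2}}{1 + m\,(d/2q)^4},$$
  applied to the coherent chain term only (the background is
  structureless and the upturn is fitted additively afterwards). The
  numerator is a Gaussian bump; the denominator suppresses the factor at
  $q \ll d$, where interchain interference screens single-chain
  scattering — without it the $1/q$ chain term would dominate the model
  below the peak, which measured profiles contradict. $P$ is positive,
  tends to 1 at high q (so the high-q chain fit is unperturbed), has at
  most one maximum, and is identically 1 at the neutral amplitude
  $m = 0$. No physical meaning is attached to $m$, $d$, $k$.
* **Background and upturn.** $S_\mathrm{inc}$ is the flat incoherent
  level; the low-q upturn is a power law with exponent fixed at
  $n = 3.6$ (configurable), a value that describes all concentrations,
  leaving only the amplitude free.

## The staged fit

Real profiles are fitted sequentially, mirroring how the information is
layered in q:

1. **Peak-position guess.** A `D q^-3.6 + A/q + const` trend (upturn,
   rod decay, background) is fitted and subtracted; the running-median
   smoothed remainder must have a significant interior maximum,
   otherwise the profile is declared peakless. The rod term is part of
   the trend basis because its low-q rise otherwise dominates the
   residual and drags the guess to the grid edge.
2. **Stage 1 — chain.** Weighted least squares (weights $1/\sigma_I^2$)
   of the chain term on $q > 1.5\,q^*$, where the peak multiplier has
   decayed to ~1. $r_p$ can be frozen to a consensus value.
3. **Stage 2 — peak.** $m, d, k$ fitted on $[0.3, 1.5]\,q^*$ with the
   chain frozen. A fit whose weighted-cost improvement over the neutral
   factor is below the 99 % point of $\chi^2_3$ is flagged
   `no_significant_peak`.
4. **Stage 3 — upturn.** The model is linear in the amplitude $D$, so
   the weighted estimate is closed-form (truncated at zero).

The three stages are then cycled, each refitting with the others'
current estimates frozen in the model, until the parameter vector is
stationary (relative tolerance $10^{-8}$, at most 12 cycles); the
stage-1 window is re-anchored when the refined peak position moves its
boundary by more than 10 %. On correctly specified noiseless data this
block refinement converges to the generating parameters to better than
$10^{-6}$ relative — the package's basic correctness invariant. The
first re-pass repeats the multi-start search because the initial,
peak-blind chain fit can land in a basin where the cross-section factor
degenerates ($r_p \to 0$ compensated by $I_0$ and $S_\mathrm{inc}$).

Peak descriptors are measured on the *coherent* model curve (background
and upturn removed): $q^*$ is its argmax (refined by golden-section
search between grid points), $I(q^*)$ the full composite intensity
there, and the width is the full width at 75 % of the maximum — the 50 %
level would need extrapolation deep into the upturn-dominated region.
Crossings outside the data range are still computed (on the model) but
flagged as extrapolated. Peak sharpness defaults to $I(q^*)/\mathrm{FW75M}$
and is pluggable, since more than one dimensionless combination is in
use; it is reported as a diagnostic only.

## Rheology

The Carreau model is fitted with $\eta_\infty$ fixed at 0: the measured
window ends far below the infinite-shear limit, so $\eta_\infty$ is not
identifiable and would only destabilise the fit (it can be overridden).
Residuals are taken in log viscosity, matching multiplicative
instrument noise. A curve whose high-shear viscosity stays within 2 %
of its low-shear plateau is treated as Newtonian (plateau-only flag).
For samples with specific viscosity below 10 the zero-shear viscosity
is the plateau mean restricted to shear rates below 100 s⁻¹, because
inertial instabilities masquerade as thickening above that; the plateau
is the longest low-shear run whose rolling 5-point log-log slope stays
within ±0.02 of zero. The 90 %-criterion relaxation time is evaluated
on the fitted Carreau curve, where it has the closed form
$\tau_{90} = \tau / \sqrt{0.9^{2/(p-1)} - 1}$.

The specific-viscosity series is segmented into up to three continuous
power laws in log-log space; continuity makes the crossovers the
intersections of the straight lines. Breakpoints are located by an
exhaustive scan over inter-point gap midpoints followed by Nelder-Mead
(or Brent, for one breakpoint) refinement; infeasible breakpoint moves
(a segment left with fewer than `min_per_segment` points) are rejected
with an infinite penalty. With continuity enforced, two interior points
determine a segment's slope, so `min_per_segment = 2` is the default.
Slopes are free by default; `fixed_scaling` mode imposes the
theoretical 0.5 / 1.5 / 3.75. Both entanglement-crossover conventions
are therefore available, and on data generated with exactly the scaling
slopes the two modes return identical breakpoints. The number of
segments is a user choice, not model-selected: the regime structure is
imposed by theory, and an information criterion on 12 points would be
noise.

## Scaling calculators

All lengths are in Å, concentrations in g/L, with $10^{27}$ Å³/L as the
only unit bridge. The electrostatic blob uses the theta-solvent
relations $g_T = (A^2 b/l_B)^{2/3}$, $\xi_T = b\sqrt{g_T}$ by default —
the hydrophobic cellulose backbone argues for the poor/theta branch,
and the good-solvent branch (provided) changes $\xi_T$ by only a few
percent for these constants. The monomer molar mass is computed from
composition, $162.14 + \mathrm{DS} \times 80.02$ g/mol. The unentangled
viscosity prediction carries the stretching parameter as $B^{-3/2}$;
the entangled one multiplies it by the squared number of entanglements
per chain $((N/g)/n^2)^2$ with $g$ the monomers per correlation blob,
which yields the $c^{3/2}$ law and the $n^{-4}$ sensitivity used to fit
$n$. Absolute normalisations are order-of-magnitude by construction
(prefactors of order one are dropped in the derivations), so only
ratios and exponents are asserted in tests.

The overlap concentration from scattering solves the packing condition
$(c N_A / M_w)\,\xi(c)^3 = 1$ with the measured
$\xi = 296\,c^{-1/2}$ Å, giving $c^* = (N_A P^3 / (M_w \cdot 10^{27}))^2$
— decreasing in $M_w$, as it must be: heavier chains need a larger mesh
to fill space. The viscosity route extrapolates the first-segment power
law to $\eta_{sp} = 1$. The two give lower and upper bounds on $c^*$,
hence upper and lower bounds on the overlaps-per-entanglement number
$n = (c_e/c^*)^{1/4}$.

## The synthetic generator

The generator emulates the study conditions rather than an instrument:
eight log-spaced concentrations (4-40 g/L) on a 150-point logarithmic q
grid (0.003-0.6 Å⁻¹), peak at $q^* = 0.021\sqrt{c}$ Å⁻¹, cross-section
radius 3.4 Å, upturn exponent 3.6, background proportional to the
monomer volume fraction, chain amplitude proportional to
$\phi(1-\phi)$, and independent Gaussian noise with relative σ = 0.02
(SANS) or 0.01 (rheology); flow curves are Carreau with slopes
0.68/1.7/3.4 and breaks 4/14.3 g/L anchored at
$(0.07\ \mathrm{g/L}, \eta_{sp} = 1)$, relaxation time 0.05 s below the
concentrated crossover and $\propto c^3$ above. Values the study does
not pin down were chosen once at realistic magnitudes and documented in
the spec objects: monomer specific volume $6\times10^{-4}$ L/g,
amplitude scales giving backgrounds of 0.04-0.4 cm⁻¹ and peak
intensities below 1 cm⁻¹, peak multiplier amplitude 4 with relative
width 0.15 (a peak-to-valley ratio near 3, typical of semidilute
polyelectrolyte peaks), relaxation time 0.05 s. A residual water mass
fraction (default 0.18) scales all intensity amplitudes down by
$1 - w$, emulating concentrations made up from incompletely dried
powder; the water-recovery analysis inverts exactly this. Peak
positions are mapped from the *nominal* concentration so the series
trend reproduces the 0.021 prefactor by construction; physically the
peak tracks the corrected concentration, but the study conditions are
defined on the nominal scale and the distinction is a constant factor
$\sqrt{1-w}$ absorbed in the prefactor.

What the generator does **not** emulate — hence what passing tests do
not show about real data: instrument resolution smearing and
q-dependent uncertainty structure (time-of-flight vs reactor), the
high-q shoulder seen at low concentrations (unexplained in the source
analysis and deliberately not modelled), inter-instrument calibration
offsets, thixotropy, and inertial artefacts beyond a simple high-shear
viscosity rise. Peak parameters are solved numerically from the target
$q^*$ (stationarity of the coherent log-curve), so fixtures remain
valid if the peak-factor parameterisation changes.

## Numerical choices and degenerate inputs

Nonlinear fits run Levenberg-Marquardt on log-transformed parameters
(positivity by construction) with cost tolerance $10^{-10}$ and a
10-start multi-start whose log-uniform perturbations come from a fixed
internal seed — fits are deterministic and never touch the caller's RNG
stream. Readers drop non-finite or non-positive rows with a warning
naming them and refuse files with fewer than 10 valid rows. Zero-noise
synthetic profiles floor the uncertainty at $10^{-8} I$ so weighted
fitting remains defined; as a consequence, "exact" recovery is asserted
at $10^{-5}$-$10^{-6}$ relative rather than machine precision. The
upturn estimate is truncated at zero; an upturn window with fewer than
5 points returns zero amplitude with a flag.

## Known limitations

* **Cross-section radius is weakly identified per profile.** At 2 %
  noise on a 150-point grid, the high-q window carries ~35 points over
  which the cylinder factor can be traded against $I_0$ and
  $S_\mathrm{inc}$; single-profile estimates scatter by ~±1 Å with a
  flat-likelihood tail toward small radii. This mirrors the ±1 Å
  uncertainty quoted for the measured radius. The robust estimator — and
  the one used in the acceptance checks — is the median over the
  concentration series, after which a consensus value is imposed and
  only the amplitudes refitted.
* **Sequential fitting can park noise in the upturn.** When the true
  upturn is absent, the cyclic fixed point may retain a tiny amplitude
  (two orders of magnitude below physical upturns) absorbing peak-tail
  extrapolation error below the peak window.
* The peak-multiplier form is a repository convention satisfying the
  stated contracts; fitted $m, d, k$ values are not comparable across
  other parameterisations (by design — descriptors $q^*$, $I(q^*)$,
  FW75M are the exchange currency).
* Problem sizes in the shipped tests are the study conditions: 8-12
  concentrations, 150-point profiles, 40-point flow curves, 30-seed
  replicate loops. These finish in about a minute; scaling the
  simulations up is a matter of the spec objects' arguments.

## A minimal run

```{r example, eval = FALSE}
spec <- sans_series_spec(seed = 1)
profiles <- generate_sans_series(spec)
fits <- lapply(profiles, fit_sans_profile)
qstars <- vapply(fits, function(f) f$descriptor$q_star, numeric(1))
trend <- fit_series_trend(qstars, spec$concentrations, fixed_exponent = 0.5)

curves <- generate_flow_curves(rheo_series_spec(seed = 1))
reg <- fit_piecewise_powerlaws(rheo_summary(curves)$concentration,
                               rheo_summary(curves)$eta_sp)

scaling_report(run_config(), xi_prefactor = xi_from_qstar(trend$prefactor),
               c_e = reg$c_e, c_D = reg$c_D,
               c_star_viscosity = reg$c_star_viscosity)
```
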