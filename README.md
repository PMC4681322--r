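# sansrheo

Analysis pipeline for small-angle neutron scattering (SANS) and steady-shear
rheology of salt-free polyelectrolyte solutions, built around the
carboxymethyl cellulose (NaCMC) system: a semiflexible, charged
polysaccharide that dissolves molecularly in water and shows the classic
polyelectrolyte phenomenology — a correlation peak in the structure factor
at `q* ∝ c^(1/2)`, a Fuoss-like specific-viscosity regime, entanglement and
concentrated crossovers, and a low-q scattering upturn.

The package is aimed at scattering/rheology practitioners who want a tested,
scriptable version of the staged analysis rather than instrument-specific
GUI fits: every step from reduced data files to the derived scaling
quantities is an ordinary R function.

## What it computes

**SANS.** Reduced 1-D profiles `I(q)` are fitted with the composite model

    I(q) = (I0/q) [2 J1(q r_p) / (q r_p)]^2 P(q) + S_inc + D q^(-n)

— a locally rigid (wormlike) chain of cross-section radius `r_p` (the 1/q
rod asymptote times a circular cross-section factor), an empirical
correlation-peak multiplier `P(q)` that tends to 1 at high q, a flat
incoherent background `S_inc`, and an additive low-q power-law upturn with
fixed exponent `n = 3.6`. Fitting is sequential, as in the classic staged
procedure: (1) chain term on `q > 1.5 q*`, (2) peak multiplier with the
chain frozen, (3) upturn amplitude, cycled to self-consistency. From the
fitted curve the pipeline extracts the peak position `q*`, the peak
intensity `I(q*)`, the full width at 75 % of the maximum (FW75M), the
correlation length `ξ = 2π/q*`, power-law trends across a concentration
series, and the through-origin consistency regressions of `S_inc` vs the
monomer volume fraction φ and `I0` vs `φ(1-φ)` (which also yield the
residual water content of the polymer).

**Rheology.** Flow curves are fitted with the Carreau model
`η(γ̇) = η0 [1 + (τγ̇)^2]^((p-1)/2)`; relaxation times come from the Carreau
`τ` and from the 90 %-of-plateau criterion; the specific viscosity
`η_sp = (η0 - η_s)/η_s` versus concentration is segmented into continuous
semidilute-unentangled / entangled / concentrated power laws, giving the
crossovers `c_e` and `c_D` and the overlap extrapolation `c*` at
`η_sp = 1`.

**Scaling theory.** Closed-form calculators link the two: Bjerrum length,
Manning condensation (monomers per effective charge `A`), electrostatic
blob size `ξ_T` and monomers per blob `g_T`, the predicted correlation
length `ξ = (B/(b c_n))^(1/2)` and the stretching parameter `B`, overlap
concentrations from scattering and viscosity, overlaps per entanglement
`n = (c_e/c*)^(1/4)`, tube diameter, and scaling predictions for `η_sp` in
each regime.

**Synthetic data.** Because no instrument data are deposited with the
study this package models, a first-class generator produces SANS
concentration series (peak at `0.021 √c` 1/Å, `r_p = 3.4` Å, upturn
exponent 3.6, 2 % noise) and Carreau flow curves whose zero-shear
viscosity follows the three measured power laws (slopes 0.68/1.7/3.4,
breaks at 4 and 14.3 g/L). Every pipeline stage is tested against these
known-truth fixtures.

## Worked example

```r
library(sansrheo)

spec     <- sans_series_spec(seed = 1)          # 8 concentrations, 4-40 g/L
profiles <- generate_sans_series(spec)

fit <- fit_sans_profile(profiles[[6]])          # c = 20.7 g/L
fit$params
#> <composite_params> I0 = 0.018, r_p = 2.58 A, S_inc = 0.1966 1/cm,
#>   peak (m, d, k) = (3.68, 0.09601, 0.01402), D_up = 1.71e-08, n_up = 3.6
fit$descriptor
#> <peak_descriptor> q* = 0.09531 1/A, I(q*) = 0.8999 1/cm, FW75M = 0.02371 1/A

qstars <- sapply(lapply(profiles, fit_sans_profile),
                 function(f) f$descriptor$q_star)
fit_series_trend(qstars, spec$concentrations, fixed_exponent = 0.5)
#> <series_trend> value = 0.02099 * c^0.5 (exponent fixed)

curves <- generate_flow_curves(rheo_series_spec(seed = 1))
summ   <- rheo_summary(curves, run_config())
reg    <- fit_piecewise_powerlaws(summ$concentration, summ$eta_sp)
reg
#> <regime_summary> 3 segment(s) [free]: slopes 0.68, 1.69, 3.4;
#>   crossovers 3.98, 14.3 g/L; c* = 0.0698 g/L

scaling_report(run_config(),
               xi_prefactor = xi_from_qstar(0.02099),
               c_e = reg$c_e, c_D = reg$c_D,
               c_star_viscosity = reg$c_star_viscosity)
#> $l_B 7.15   $A 1.39   $xi_T 5.74   $B 1.08
#> $c_star_scattering 0.00333   $n_from_scattering 5.88
#> $n_from_viscosity 2.75   $xi_at_cD 79.3 ...
```

Reading the output: the single-profile fit recovers the chain radius to
within its (large, ~1 Å) uncertainty and pins the correlation peak; the
series trend reproduces the generator's `q* = 0.021 √c` law to 0.05 %; the
regime fit finds the entanglement and concentrated crossovers at 4.0 and
14.3 g/L; and the scaling report turns the measured `ξ` prefactor into a
stretching parameter `B ≈ 1.1` (a locally rod-like chain) with `n ≈ 3-6`
chain overlaps per entanglement.

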