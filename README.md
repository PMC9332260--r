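# luctherm

Thermal-stability analysis for bacterial luciferases — and, more generally,
for any enzyme studied with the same three instruments plus molecular
dynamics. The package grew out of the comparison of two homologous
luciferases, the "slow" *Vibrio harveyi* enzyme and the "fast"
*Photobacterium leiognathi* enzyme, in buffer and in 30 wt% sucrose, and it
implements the complete quantitative chain of that kind of study:

1. **Flash kinetics** (`flash_params`, `fit_flash_decay`). A single-turnover
   bioluminescence assay produces a flash-shaped light trace; the package
   extracts the peak intensity I_max, the total light yield
   Q\* = ∫ I(t) dt, and the first-order decay constant k_decay from a
   nonlinear fit of I = B·e^(−k·t) on the decay phase (default window from
   80% down to 5% of the peak).
2. **Thermal inactivation** (`remaining_activity`, `segment_phases`,
   `fit_inactivation`, `arrhenius`). Remaining activity
   R = 100·Q\*/Q\*₀ versus incubation time is segmented into an induction
   lag (heated enzyme still recovers on cooling), the single-exponential
   phase, and an optional late slow phase (aggregation); the rate constant k
   comes from fitting R = A·e^(−kt) on the exponential phase only, and the
   activation energy from the Arrhenius slope of ln k versus 1/T,
   E_a = −R·d(ln k)/d(1/T).
3. **Scanning calorimetry** (`excess_heat_capacity`,
   `denaturation_params`). DSC thermograms are reduced to excess heat
   capacity by subtracting linearly extrapolated native/denatured baselines
   blended by the unfolding progress α (the self-consistent "sigmoid
   baseline"), then summarised as the transition temperature T_m, the
   calorimetric enthalpy ΔH_cal (peak area), the half-width ΔT_1/2 (FWHM)
   and the heat asymmetry ΔQ₋/ΔQ₊ about T_m.
4. **Trajectory statistics** (`kabsch_superpose`, `rmsd_series`,
   `radius_of_gyration`, `sasa`, `rmsf`, `delta_rmsf`,
   `profile_correlation`, `mddf`, `residue_density_map`). Structural
   analysis of MD output: optimal superposition (Kabsch), backbone RMSD,
   radius of gyration, Shrake–Rupley solvent-accessible surface area,
   per-residue RMSF and its temperature difference
   ΔRMSF = RMSF_T − RMSF_ref, minimum-distance distribution functions of a
   cosolvent, and residue-resolved first-shell (1.5–3.5 Å) cosolvent
   density maps.

Because the original instrument files and 100-ns trajectories are not
publicly deposited, the package ships first-class synthetic generators
(`sim_flash_trace`, `sim_inactivation_series`, `sim_thermogram`,
`sim_trajectory`, `sim_solvated_trajectory`) that emulate each data type
with known ground truth, so every estimator is validated end-to-end by
parameter recovery. All fitting functions return classed S3 objects with
`print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods as
applicable.

## Worked example

```r
library(luctherm)

# a noisy single-turnover flash trace with true decay constant 0.32 1/s
tr <- sim_flash_trace(amplitude = 1, k_rise = 10, k_decay = 0.32,
                      noise_sd = 0.02, dt = 0.01, duration = 20,
                      temperature = 25, solvent = "buffer", seed = 101)
flash_params(tr)
#> Single-turnover flash parameters
#>   I_max   = 0.8841 a.u. at t = 0.34 s
#>   Q*      = 3.048 a.u.*s
#>   k_decay = 0.3207 1/s (r2 = 0.9893)

# an inactivation course at 50 C: true rate 1.36 1/min, 1-min induction lag
s <- sim_inactivation_series(k = 1.36, t_lag = 1, noise_sd = 0.02,
                             times = seq(1/3, 4, 1/3), temperature = 50,
                             solvent = "buffer", seed = 42)
summary(fit_inactivation(s))
#> Thermal-inactivation fit: k = 1.362 1/min, A = 394.9%, r2 = 0.9999
#>   phases: 3 induction / 9 exponential / 0 slow point(s)
#>   inactivation half-life: 0.509 min
#>   incubation temperature: 50 C

# activation energy from a 45-55 C rate table
arrhenius(c(0.15, 0.71, 1.36, 1.63, 2.69), c(45, 48, 50, 52, 55))
#> Arrhenius fit (5 points): E_a = 241.6 +/- 46.2 kJ/mol

# a DSC thermogram with T_m = 318.5 K, dH_cal = 997 kJ/mol, 1% noise
tg <- sim_thermogram(T_m = 318.5, dH_cal = 997, dH_vH = 708,
                     native_baseline = c(30, 0.08),
                     denatured_baseline = c(38, 0.03),
                     noise_sd = 2.1, seed = 7)
denaturation_params(excess_heat_capacity(tg))
#> Thermal-denaturation parameters
#>   T_m       = 318.48 K (45.33 C)
#>   dT_1/2    = 4.20 K (FWHM)
#>   dH_cal    = 1004 kJ/mol
#>   dQ-/dQ+   = 0.99
```

The k_decay of 0.321 1/s, the inactivation rate of 1.362 1/min, the E_a of
242 kJ/mol, and the (318.48 K, 1004 kJ/mol, 4.20 K) calorimetric summary
each recover the known truths (0.32, 1.36, the 237 ± 30 published value,
and 318.5 / 997 / 4.2) within the uncertainty of the generated noise.

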