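# enzstab

Design and analysis of long-term enzyme storage-stability studies, with
accelerated-stability (Arrhenius) inference, Michaelis–Menten kinetics,
and molecular-dynamics trajectory fluctuation analysis.

## The problem

Producers of enzyme concentrates (the motivating case is a recombinant
fungal laccase assayed with ABTS) need to know how long a preparation
keeps its activity at each candidate storage temperature, and they need
that answer with a stated statistical precision. enzstab covers the whole
workflow:

* **Study design.** A pilot study's per-group SDs are pooled,
  `n0 = (z·s/d)²` with a finite-population correction gives the sample
  size for a target CI half-width `d`, and the sample is allocated across
  production batches (strata) proportionally with largest-remainder
  integerization. Stratified means and CIs, a 75%-loss stop rule, and
  temperature-log summaries complete the design module.
* **Deactivation kinetics.** Per-isotherm first-order fits
  (`ln(E/E0) = -k_d t`), the Arrhenius regression
  `ln k_d = ln A − E_d/(RT)`, and the derived report: half-life
  `t½ = ln2/k_d`, `ΔH = E_d − RT`, `ΔG = −RT ln(k_d h/(k_B T))`,
  `ΔS = (ΔH − ΔG)/T`.
* **Michaelis–Menten kinetics.** Hanes–Woolf linearization
  (`S/V0 = S/Vmax + Km/Vmax`) for starting values, then nonlinear least
  squares.
* **Trajectory analysis.** Kabsch superposition, per-frame RMSD,
  per-residue backbone RMSF, ΔRMSF against a base temperature with a
  0.5 Å SD cutoff, fluctuating-region detection, and Cα-covariance PCA
  with per-residue contributions. Multi-model PDB and XYZ I/O included.
* **Synthetic data.** Generators for every input above with known ground
  truth, used throughout the tests for parameter-recovery validation.

See the methods vignette
(`vignettes/enzyme-stability-methods.Rmd`) for model assumptions,
conventions (notably the k_d unit entering ΔG), and limitations.

## Worked example

The packaged example inputs hold per-temperature deactivation constants
(month⁻¹) and a deactivation energy for a laccase concentrate stored for
a year at five temperatures:

```r
library(enzstab)
inp <- stability_example_inputs()
tab <- thermo_table(inp$temperature_K, inp$kd_per_month, inp$Ed_J_mol)
print(tab, digits = 4)
#>   temperature_K kd_per_month t_half_months dH_kJ_mol dG_kJ_mol dS_J_mol_K
#> 1         241.0        0.003       231.049     39.40     70.23     -127.9
#> 2         277.4        0.015        46.210     39.09     77.46     -138.3
#> 3         297.5        0.055        12.603     38.93     80.04     -138.2
#> 4         303.3        0.135         5.134     38.88     79.36     -133.5
#> 5         309.6        0.400         1.733     38.83     78.27     -127.4
```

Read: at refrigeration (277.4 K) the concentrate loses half its activity
in about 46 months; at 309.6 K in under two. Positive ΔG (deactivation is
not spontaneous on the transition-state reading, with k_d in month⁻¹ —
see the vignette for this convention) and negative ΔS (a compact,
inactivation-resistant state) characterize a stable enzyme.

The same analysis runs end-to-end from raw vial measurements. With the
synthetic generator standing in for a real study (three batches, noise
SD 96.6 U L⁻¹, true k_d as above):

```r
study <- generate_study(study_spec(seed = 42))
fit_stability_study(study)
#> Accelerated-stability analysis
#>   E0 = 16575.50 U/L, 5 isotherm(s)
#>   E_d = 39.56 kJ/mol (R^2 = 0.891)
#>   temperature_K kd_per_month t_half_months dH_kJ_mol dG_kJ_mol dS_J_mol_K
#> 1         241.0      0.00314       220.781     37.55     70.14     -135.2
#> 2         277.4      0.01495        46.376     37.25     77.46     -145.0
#> 3         297.5      0.05477        12.656     37.08     80.05     -144.4
#> 4         303.3      0.13494         5.137     37.04     79.37     -139.6
#> 5         309.6      0.39762         1.743     36.98     78.29     -133.4
```

Every true k_d is recovered within a few percent. Kinetics, same pattern:

```r
d <- generate_mm_dataset(0.0102, 0.0466, s_grid = c(0.05, 0.1, 0.3, 1, 3))
mm_nls_fit(d$S_mM, d$V0_mM_min)
#> Michaelis-Menten fit (nls)
#>   Vmax = 0.0102 +/- 0 mM min^-1
#>   Km   = 0.0466 +/- 0 mM
#>   RSS  = 0
```

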