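---
title: "Methods: designed stability studies, deactivation thermodynamics and trajectory fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designed stability studies, deactivation thermodynamics and trajectory fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzstab)
```

enzstab analyses long-term enzyme storage-stability studies of the kind run
for industrial enzyme concentrates (the motivating case is a recombinant
fungal laccase stored for a year at several temperatures): a statistically
designed sampling plan, per-isotherm first-order deactivation fits, an
Arrhenius accelerated-stability model with transition-state thermodynamics,
Michaelis–Menten kinetics of the stored samples, and post-processing of
molecular-dynamics trajectories that probe the same temperatures in silico.
This vignette records the models, the defaults and why they were chosen,
and the places where a convention had to be fixed.

## Sampling design

A pilot study at several temperatures provides per-group activity SDs.
Under homogeneity of variance these are pooled,
$s_p = \sqrt{\sum_i (n_i-1)s_i^2 / \sum_i (n_i-1)}$ (`pooled_sd()`), and the
pooled value drives the sample size for estimating a mean activity with
absolute precision $d$ (the CI half-width, in U L$^{-1}$) at confidence
$1-\alpha$:

$$n_0 = \left(\frac{z_{1-\alpha/2}\, s_p}{d}\right)^2,\qquad
  n = \left\lceil \frac{n_0}{1 + n_0/N} \right\rceil,$$

with the finite-population correction for a vial population of size $N$
(`required_sample_size()`). Two conventions are deliberate and documented
rather than inherited:

* the standard-normal quantile $z$ (1.96 at 95%), not Student's *t* — the
  design targets the large-sample estimator that an absolute-precision
  statement implies, and with the default conditions ($N=1200$,
  $s_p = 96.6$, $d = 21.8$) the resulting $n = 71$ is large enough that
  the distinction is immaterial;
* integerization by ceiling for $n$ and by largest remainder for the
  proportional allocation $n_h \propto N_h$ (`allocate_proportional()`),
  with remainder ties broken toward the lower stratum index so the
  allocation is deterministic. The allocation conserves $n$ exactly.

Estimation uses the standard stratified estimator with population weights
$W_h = N_h/N$ and the finite-population-corrected variance
$\sum_h W_h^2 (1-n_h/N_h) s_h^2/n_h$ (`stratified_mean_ci()`). A stratum
sampled exhaustively contributes no variance; a stratum needing a variance
with $n_h < 2$ is an error, not a silent NA. The test suite checks the
estimator against exhaustive enumeration of all stratified samples of a
toy population: design-unbiasedness of the mean holds exactly, and the
variance estimator's expectation equals the exact design variance.

**Stop rule.** Sampling stops at the first month whose stratified-mean
relative activity falls below 25% remaining (≈75% loss), with two
refinements: the truncated schedule is extended toward a minimum of five
sampling times when the schedule allows, but the extension is abandoned
when activity at the crossing month has already collapsed below a floor
(default 10% remaining) — continuing to sample an essentially inactive
preparation yields no usable isotherm points, which is also how the
motivating study behaved when an isotherm collapsed in its first month.
The floor is a package choice; the threshold and minimum-five aim are the
study conventions.

## Activity calculations

Volumetric activity from a chromogenic oxidase assay is
$\mathrm{U\,L^{-1}} = \Delta A \cdot V_t \cdot 10^{6} / (\varepsilon\, d\, V_s)$
(`volumetric_activity()`). Written without the $10^6$ the expression is a
molar rate; the factor converts mol to µmol so one unit is 1 µmol of
substrate per minute per litre. The ABTS extinction coefficient defaults
to 36,000 M$^{-1}$cm$^{-1}$ at 420 nm — an external constant that should
be replaced by the assay's calibrated value. Relative activity is a plain
percentage of the initial activity and is *not* clamped at 100%: apparent
activation during refrigerated storage is a real observation, and clamping
would silently bias deactivation fits.

## Deactivation kinetics and thermodynamics

Each storage isotherm is modelled as first-order decay,
$E(t) = E_0 e^{-k_d t}$, fitted as OLS of $\ln(E/E_0)$ on time in months
(`fit_kd()`). The regression keeps a free intercept by default because
$E_0$ is itself a noisy measurement; forcing the line through the origin
is available behind a flag for sensitivity checks. A non-positive fitted
$k_d$ is reported as "no deactivation observed", not an error, and such
isotherms are excluded (with a warning) from the Arrhenius step — an
activity *increase* at refrigeration temperature is informative about
stability but carries no thermal-deactivation signal.

The temperature dependence is $\ln k_d = \ln A - E_d/(RT)$
(`arrhenius_fit()`, at least three positive-$k_d$ isotherms), and derived
quantities are

$$t_{1/2} = \frac{\ln 2}{k_d},\qquad
  \Delta H = E_d - RT,\qquad
  \Delta G = -RT \ln\!\frac{k_d h}{k_B T},\qquad
  \Delta S = \frac{\Delta H - \Delta G}{T}.$$

Two conventions matter here:

* **The unit of $k_d$ in $\Delta G$.** The Eyring-type expression is
  dimensionally sensitive to the time unit of $k_d$. Stability reports
  for stored biologics conventionally insert $k_d$ in the study's native
  unit (month$^{-1}$); that is the default (`kd_unit = "month"`) and is
  what reproduces the published tables this package is validated against.
  The SI-consistent alternative (`kd_unit = "second"`, 30-day months)
  yields $\Delta G$ larger by $RT\ln(2.592\times 10^6)$ — about
  36 kJ mol$^{-1}$ at 298 K — and is provided because the convention
  changes the scientific reading. Every emitted table records which mode
  produced it.
* **Constants precision.** `physical_constants()` defaults to the
  truncated values conventional in such reports
  ($R = 8.314$, $h = 6.626\times10^{-34}$, $k_B = 1.38\times10^{-23}$),
  keeping derived tables bit-stable against hand calculation; a
  `"codata"` mode switches to full precision. The difference is below the
  last printed digit of any tabulated quantity.

`thermo_table()` assembles the per-temperature report and preserves the
internal identities $t_{1/2} k_d = \ln 2$ and
$\Delta S = (\Delta H - \Delta G)/T$ exactly. With fewer than three usable
isotherms the $E_d$-dependent columns are NA and the table is flagged
rather than partially filled.

**A caution on extrapolation.** `predict_half_life()` evaluates the fitted
Arrhenius line at an arbitrary temperature. When an individual isotherm
departs from that line — which happens in real studies; in the motivating
data the refrigerated isotherm's $k_d$ sits a factor of ~2 off the line
fitted to all five temperatures ($R^2 \approx 0.9$) — the prediction at
that temperature legitimately disagrees with $\ln 2/k_d$ of the isotherm
itself. The prediction is only as Arrhenius-consistent as the data.

## Michaelis–Menten kinetics

`hanes_woolf_fit()` regresses $S/V_0$ on $S$ (slope $1/V_{max}$, intercept
$K_M/V_{max}$); it is exact on noiseless data and supplies starting values
for `mm_nls_fit()`, an unweighted Levenberg–Marquardt least-squares fit of
$V_0 = V_{max}S/(K_M+S)$ with parameter SDs from the curvature at the
optimum. Unweighted least squares is deliberate: no error model for the
assay replicates is published, and weighting would be an invention. The
default synthetic substrate grid is log-spaced over the 0.1–3 mM assay
range; note that $K_M$ values near 0.04 mM lie *below* this range, so
$K_M$ is then identified mostly by the lowest grid points and its
uncertainty grows accordingly — the generator accepts an extended grid
when sharper identification is wanted. The test suite checks the
optimizer against a brute-force grid search and a closed-form two-point
inversion, not against another fitting routine.

## Trajectory fluctuation analysis

The trajectory operators reproduce standard MD post-processing on a
frames × atoms × 3 container (`md_trajectory()`), with multi-model PDB and
whitespace-XYZ readers and writers. Conventions:

* **Superposition** is the Kabsch algorithm (SVD with determinant
  correction, proper rotations only); degenerate selections (fewer than 3
  atoms, collinear or coincident) are errors.
* **Reference structure** for RMSF and PCA is the time-average after one
  iterative pass (fit to frame 1, average, refit to the average). Whether
  fluctuation is measured about the time-average or the first frame is
  often unstated in reports; the time-average is the variance-minimizing
  choice and is documented here.
* **Hydrogens** are excluded everywhere by an atom-name filter.
* **RMSF** is computed per backbone atom (N, CA, C) and averaged per
  residue; residue numbering follows the input file verbatim.
* **ΔRMSF** against a base temperature (default: the lowest label) is a
  plain difference of per-residue RMSF profiles. Flagging computes, per
  residue, the SD across the set of ΔRMSF profiles and selects SD > 0.5 Å.
  Flagged residues merge into regions allowing gaps ≤ 2 with a minimum
  span of 2 — "vicinity" made into a rule, since published region calls
  are verbal.
* **PCA** superposes frames on all heavy atoms, builds the 3N × 3N
  covariance of the Cα coordinates, and reports the top-k eigenpairs,
  variance proportions $\lambda_i/\sum\lambda$, and per-residue
  contributions (squared norm of each residue's three eigenvector
  components, normalized per component). The eigendecomposition is checked
  against an independent SVD of the centered coordinate matrix to 1e-8.

A numerical consequence of superposition worth knowing: rigid-body fitting
absorbs 6 degrees of freedom, so measured RMSF underestimates the true
per-atom fluctuation by a relative $\sim 1/M$ for $M$ fitted atoms (plus
$\sim 1/(2F)$ from mean estimation over $F$ frames). Validation sizes are
chosen so this bias is well inside the assertion tolerances.

## The synthetic generator

`generate_study()` emulates the study design the package analyses: batches
are strata with initial activities drawn once per batch
(default 16,575.50 ± 268.92 U L$^{-1}$), decay is exactly first-order with
a known per-temperature $k_d$ map (defaults: 0.003, 0.015, 0.055, 0.135,
0.400 month$^{-1}$ at 240.98–309.58 K), measurement noise is additive
Gaussian on the activity scale (default SD 96.6 U L$^{-1}$, the pooled
pilot estimate) truncated at zero with a recorded count, and the schedule
is monthly to month 6 then bimonthly to month 12. Defaults are the study
conditions, not tuning knobs. `generate_trajectory()` produces frames as a
reference structure plus independent isotropic Gaussian displacements with
a per-residue amplitude profile, optionally composed with a random global
rotation/translation per frame to exercise superposition; displacement
noise is drawn before any rigid-body draws so a seed fixes the internal
motions regardless of the jitter flag.

What the generator does *not* emulate: correlated motions (every residue
fluctuates independently, so PCA of generated trajectories has no
low-dimensional collective structure), non-first-order or multi-phase
decay, batch-by-temperature interactions, assay drift, and humidity
effects. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated noise model, not robustness to real-data
pathologies.

## Validation problem sizes

The shipped tests and the acceptance script use: 100 generated studies
(3 batches × 5 vials × 9 sampling months × 5 temperatures) for
deactivation recovery; 2,000 simulated populations of 1,200 vials for CI
coverage; 200 replicate kinetics datasets at the assay noise scale; and
1,000-frame, 50-residue trajectories for the RMSF moment identity. These
sizes put Monte-Carlo error comfortably below the assertion tolerances
while keeping the whole suite fast on a single CPU.

## Known limitations

* The Arrhenius model assumes a single rate-limiting deactivation step;
  enzymes with parallel inactivation routes need a different model.
* $\Delta G$ depends on the $k_d$ unit convention (above); compare values
  across studies only within one convention.
* The stop rule operates on the stratified mean; with very few vials a
  noisy month can truncate a schedule early.
* Trajectory I/O targets well-formed multi-model PDB / XYZ; it is not a
  general-purpose structure parser (no altLoc, insertion codes, or chains
  beyond a single ID).
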