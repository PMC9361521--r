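# camdyn

Quantitative analysis of ligand-induced compaction of calmodulin — and of
two-state conformational collapse in flexible multidomain proteins
generally — from four complementary solution measurements: SEC-SAXS, NMR
relaxation and chemical shifts, differential HDX-MS, and isothermal
titration calorimetry, plus structure-level mapping of the results onto
coordinates.

Calcium-loaded calmodulin (holo-CaM) is a dumbbell: two EF-hand lobes
joined by a flexible linker. Binding of a single antagonist molecule such
as calmidazolium collapses it into a compact globule. `camdyn` implements
the complete quantitative toolchain with which such a collapse is
established and characterized, and ships synthetic-data generators with
the statistical structure each analysis assumes, so the entire pipeline is
testable offline.

## What it computes

**SAXS shape analysis** (`guinier_fit`, `dimensionless_kratky`, `ift_pr`,
`estimate_dmax`, `debye_scattering`, `reduced_chi2`, `cormap_compare`,
`ensemble_select`):

- Guinier fit of ln *I* vs *q*², with the self-consistent range
  *q*·*R*g ≤ 1.3; *R*g = √(−3·slope), *I*(0) = e^intercept.
- Dimensionless Kratky transform (*qR*g)²·*I*/*I*(0) vs *qR*g. A compact
  globular particle peaks at (√3, 3/e ≈ 1.104); extension and flexibility
  displace the peak up and right.
- *P*(*r*) by regularized indirect Fourier transform of
  *I*(*q*) = 4π ∫ *p*(*r*) sinc(*qr*) d*r*, with a Dmax scan scored on fit
  quality, positivity and endpoint behaviour.
- Vacuum Debye forward scattering
  *I*(*q*) = ΣᵢΣⱼ *f*ᵢ*f*ⱼ sin(*qr*ᵢⱼ)/(*qr*ᵢⱼ) for bead or atomic models,
  exact or histogram-accelerated.
- CorMap-style frame comparison: exact tail probability of the longest
  same-sign run of point-wise differences.
- Genetic-algorithm selection of conformer ensembles whose averaged
  scattering fits the data (tournament selection, uniform crossover,
  elitism, multiple independent runs).

**NMR dynamics** (`fit_decay`, `tract_tauc`, `sed_tauc`,
`viscosity_correct`, `csp`, `classify_csp`, `noe_analysis`): exponential
rate fitting with 1000-replicate Monte Carlo errors; TRACT rotational
correlation times from the ¹⁵N doublet rate difference
*R*β − *R*α = 2*η*ₓᵧ(*τ*c); Stokes–Einstein–Debye predictions
*τ*c = 4π*η*(*r*dry + *h*)³/(3*k*B*T*); viscosity extrapolation to 100%
H₂O; chemical shift perturbations CSP = √((0.159·Δδ_N)² + Δδ_HN²) with
two-threshold classification; heteronuclear nOe differences with error
propagation.

**Differential HDX-MS** (`deuterium_fraction`, `max_exchangeable`,
`fractional_uptake`, `delta_uptake`, `wald_fdr`): deuterium bookkeeping
through sequential mixing; RFU = 100·uptake/(max_D·*d*-fraction); per-
peptide state differences and their time average; two Wald tests per
peptide (magnitude and kinetics) on a fixed-effects linear model, with
Benjamini–Hochberg FDR control.

**ITC** (`one_site_heats`, `one_site_fit`): the one-site Wiseman isotherm
with perfusion-cell volume bookkeeping, nonlinear least-squares fitting,
covariance-based errors and c-value reliability warnings.

**Structures** (`read_structure`, `kabsch_rmsd`, `ligand_contacts`,
`paint_residue_values`): PDB atom tables, closed-form Kabsch
superposition RMSD, heavy-atom ligand contacts at a 3.9 Å cutoff, and
painting per-residue results into the B-factor column.

Every generator in the `simulate_*` family is a pure function of its
parameters and seed, and `run_pipeline()` chains all stages into a
reproducible synthetic demonstration.

## Worked example

```r
library(camdyn)

# a compact two-lobe bead pool and its synthetic SEC-SAXS curve
pool  <- make_two_lobe_conformers(4, compact = TRUE, seed = 42)
q     <- seq(0.008, 0.35, length.out = 70)
curve <- simulate_saxs(pool, q, noise_scale = 0.01, seed = 42)

guinier_fit(curve)
#> <guinier_fit> Rg = 16.401 +/- 0.147 A, I(0) = 1.596e+04 +/- 68 (15 pts, qRg <= 1.27)

pk <- kratky_peak(dimensionless_kratky(curve, guinier_fit(curve)), smooth = TRUE)
#> Kratky peak: x = 2.11, y = 1.17        # near the globular (1.73, 1.104) reference

estimate_dmax(curve, grid = seq(30, 70, by = 5))$dmax
#> [1] 60                                  # a ~52 A globule, to one grid step

# one-site ITC at the study's concentrations (8 uM cell, 200 uM syringe)
tit <- simulate_itc(kd = 3e-6, n = 1.2, dh = -5000, noise_sd = 0.3, seed = 42)
one_site_fit(tit)
#> <binding_fit> KD = 2.14e-06 +/- 8e-07 M, n = 1.14 +/- 0.082, dH = -4409 cal/mol (c = 4.26)

# TRACT: rates generated at tau_c = 5.2 ns, 600 MHz, inverted back
eta <- tract_eta_xy(5.2, 600)
tract_tauc(25 - eta, 25 + eta, field = 600, r_alpha_err = 0.2, r_beta_err = 0.2)
#> <tract_fit> tau_c = 5.200 ns (95% CI 4.602-5.834), R_alpha = 21.93, R_beta = 28.07 /s at 600 MHz
```

The Guinier fit recovers the pool's 16.4 Å radius of gyration; the Kratky
peak sits near the globular reference; the Dmax scan brackets the
globule's ~52 Å extent; the ITC fit returns a low-micromolar KD with
n ≈ 1.2 at a Wiseman c of ~4 (where parameter scatter is expected); and
the TRACT inversion returns exactly the correlation time that generated
the rates, with a Monte Carlo confidence interval.

Fitted objects carry broom-style `tidy()`/`glance()` methods and
`autoplot()` figures; `run_pipeline(seed = 1)` writes a complete
synthetic run (curves, per-stage CSV reports, a JSON summary) into a run
directory.

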