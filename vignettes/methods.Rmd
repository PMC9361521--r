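---
title: "Models and methods behind camdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind camdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camdyn)
```

`camdyn` quantifies a two-state conformational collapse — calmodulin's
dumbbell-to-globule transition upon antagonist binding is the motivating
case — from four independent solution measurements. This vignette is the
package's own account of the models it fits, the parameters that matter,
the design decisions taken where the design was genuinely open, and what
the synthetic generators do and do not emulate.

## SAXS shape analysis

### Guinier fitting

At low angle, `ln I(q) = ln I(0) − q²Rg²/3`. `guinier_fit()` performs a
weighted linear fit of `ln I` on `q²` (weights `(I/σ)²`, the first-order
variance of a log-transformed intensity) over a self-consistently chosen
range: starting from the smallest usable `q`, the window is iterated until
`q_max·Rg ≤ 1.3`. The 1.3 bound is the standard limit for globular
particles; it is a tunable argument (`qRg_limit`) because elongated
particles warrant a stricter bound (~1.0). Uncertainties follow from the
fit covariance by the delta method (`dRg/dslope = −3/(2Rg)`). A
non-negative slope raises an error ("no Guinier region") rather than
returning a complex radius.

### Dimensionless Kratky transform

`dimensionless_kratky()` maps a curve to `(x, y) = (qRg, (qRg)² I/I(0))`.
For a curve that follows the Guinier law exactly, `y = x² e^(−x²/3)` has
its interior maximum at `x = √3`, `y = 3/e ≈ 1.104` — the reference
crosshairs for a compact globule. `kratky_peak()` refines the discrete
maximum with a three-point parabola so the reported ordinate is
grid-independent; for noisy experimental curves an optional lowess
smoothing (`smooth = TRUE`) suppresses the high-`q` noise that the `x²`
factor amplifies, at the cost of a slight outward bias on flat-topped
profiles. Real compact particles (including the package's two-lobe
compact models, which are mildly prolate) peak slightly above the ideal
point; the analytic constant is reserved for the Guinier-law reference.

### P(r) by indirect Fourier transform

`ift_pr()` discretizes `I(q) = 4π ∫₀^Dmax p(r) sinc(qr) dr` on a 101-point
`r`-grid (trapezoid quadrature), pins `p(0) = p(Dmax) = 0` by dropping the
endpoint unknowns, and solves the σ-weighted normal equations with a
second-difference (curvature) penalty `α‖Dp‖²`. No positivity constraint
is imposed; negativity is instead diagnosed (and penalized in the Dmax
scan). When `α` is not given it is chosen at the corner of the L-curve —
the point of maximum distance from the chord in the
(log residual, log roughness) plane over 28 logarithmically spaced
candidates, referenced to `tr(AᵀA)/tr(DᵀD)`. Real-space invariants
`Rg² = ∫r²p / (2∫p)` and `I(0) = 4π∫p` are reported; on noiseless
globular data they agree with the Guinier estimates to well under 5%.

`estimate_dmax()` scans candidate `Dmax` values with a single shared `α`
(chosen once at the largest, most flexible candidate, so the profile
compares like with like) and scores each fit as

`score = χ²/min(χ²) − 1 + 20·(negative mass fraction) + 4·(endpoint mass)
+ 0.2·(size fraction)`.

The first term punishes the systematic misfit of an under-sized `Dmax`;
the negativity and endpoint terms stand in for the perceptual criteria of
classical IFT software; the mild size term selects the smallest `Dmax` on
the χ² plateau (an over-sized support fits equally well, so parsimony
must break the tie). On a 40 Å sphere the scan returns 40 ± one grid step
with and without noise. The score weights were fixed against that
analytic oracle and are exposed as arguments.

### Debye forward scattering

`debye_scattering()` evaluates the exact vacuum double sum with identical
unit form factors — shape-only modelling, no hydration shell. Absolute χ²
values against experimental curves are therefore indicative only; model
ranking is meaningful. The histogram acceleration bins pairwise distances
at 0.05 Å and uses the weight-averaged distance per bin
(first-moment-preserving), which keeps the maximum relative deviation
from the exact sum below 0.1% on 500-bead models.

### χ², frame similarity, ensemble selection

`reduced_chi2()` interpolates the model onto the data grid and uses the
analytically optimal scale (plus, optionally, a constant offset), with
the nuisance-parameter count removed from the degrees of freedom. The
statistic is invariant under rescaling of the model, and averages 1.0
over noise replicates of a self-fit.

`cormap_compare()` reduces two curves on a common grid to the longest run
of consecutive same-sign differences and computes the exact tail
probability under the fair-coin null from the run-composition recursion
(evaluated in probability space, so `n = 100` does not overflow). Zero
differences get alternating signs — a conservative tie-break that cannot
manufacture a long run; it makes identical curves maximally compatible
with the null.

`ensemble_select()` represents an ensemble as a multiset of conformer
indices (so weights are multiples of `1/size`), scores it by the
reduced χ² of the optimally scaled average curve, and evolves a
population by tournament selection (size 2), uniform crossover, per-gene
mutation and elitism. Defaults — population 100, 200 generations,
mutation 0.1/gene, elitism 2, 10 independent runs — were chosen so that
the GA provably matches exhaustive enumeration on every instance small
enough to enumerate (pool ≤ 20, ensemble size 2); the tests run reduced
settings that still achieve this. Repeated runs return the run-wise best
and the pooled distribution of selected-conformer radii of gyration,
which is the quantity of scientific interest for a flexible protein.

## NMR dynamics

### TRACT correlation times

The fast and slow ¹⁵N doublet components relax at
`R_β = R₂ + η_xy`, `R_α = R₂ − η_xy`, so the measured difference isolates
the DD/CSA cross-correlation rate
`η_xy = 2 p δ_N P₂(cosθ)(4J(0) + 3J(ω_N))` with
`p = μ₀γ_Hγ_Nħ/(16π√2 r³_NH)`, `δ_N = γ_N B₀ Δσ_N/(3√2)` and
`J(ω) = (2/5)τ_c/(1 + (ωτ_c)²)`. `tract_tauc()` inverts the measured
`R_β − R_α` by bounded scalar minimization on [0.1, 100] ns (the rate
difference is strictly increasing in `τ_c` over the physically relevant
range, so the minimum is unique); the contract is the returned `τ_c`,
not the optimizer. Constants default to `r_NH = 1.02 Å`,
`Δσ_N = −160 ppm`, `θ = 17°` — the values of the TRACT literature — and
are configurable. Magnitudes of `γ_N` and `Δσ_N` are used so the rate is
returned positive. Confidence intervals come from Monte Carlo resampling
of the two rates within their errors (draws violating `R_β > R_α` are
dropped).

The forward generator (`simulate_relaxation()` in TRACT mode) adds
`±η_xy(τ_c)` to a baseline rate `r2_base` (default 25 s⁻¹, a plausible
amide-envelope decay rate); the round trip
generator → `fit_decay()` → `tract_tauc()` is the identity to 10⁻³ ns
noise-free.

### Rates, SED, viscosity, CSP, nOe

`fit_decay()` fits `A e^(−Rt)` (log-linear start, Levenberg–Marquardt
refinement; exact closed form at two points) and reports Monte Carlo
errors from refits of the perturbed fitted curve — the error therefore
scales linearly with the stated noise SD and vanishes with it.

`sed_tauc()` computes `r_dry = (3Mv̄/4πN_A)^{1/3}` and
`τ_c = 4πη(r_dry + h)³/(3k_BT)`. With `M = 16706 g/mol`, `v̄ = 0.73
cm³/g`, 37 °C water (0.6913 mPa s) and a 2.8 Å hydration shell this gives
5.2 ns — the compact-sphere reference for the bound state; the value
stays in [4.9, 5.5] ns for hydration 2.8–3.2 Å.

`viscosity_correct()` rescales a measured `τ_c` by
`η_H₂O(T)/η_mix(T)`, with mixture viscosity modelled as volume-fraction-
linear in the embedded H₂O, D₂O and DMSO tables (0–60 °C, linear in T).
Linear mixing is a first-order model — aqueous DMSO in particular shows a
positive viscosity excess — so corrections at high co-solvent fractions
are approximate; at the few-percent fractions typical of NMR samples the
error is negligible.

`csp()` uses `CSP = √((0.159·Δδ_N)² + Δδ_HN²)`; the 0.159 weight is
applied to ppm values. Classification is inclusive at both thresholds
(`≥ 0.14` very strong, `[0.07, 0.14)` strong). Unmatched residues are
carried as explicit missing records — the unassigned list is itself a
result (its regional partition via `partition_regions()`, linker window
75–81 by default, summarizes where exchange broadening concentrates).

`noe_analysis()` propagates the spectral noise to first order
(`σ_noe/noe = √((σ/I_sat)² + (σ/I_unsat)²)`, accurate to ~10% against
Monte Carlo at SNR ≥ 10). The banding thresholds (≥ 0.18 very high,
[0.10, 0.16] high) leave (0.16, 0.18) undefined; such values are reported
as `"unclassified"` rather than silently assigned to a band.

## Differential HDX-MS

Deuterium bookkeeping is volume-weighted sequential mixing: the standard
labeling protocol (30 µL protein + 120 µL deuterated buffer at 99.98%)
gives a 0.80 labeling excess, and the quench step (20 + 40 µL) a 0.27
final D₂O fraction. The labeling excess (0.80), not the post-quench
fraction, is the denominator correction for fractional uptake — the
exchange competition happens during labeling; this is configurable.

`max_exchangeable()` uses the `N − 1 − Pro(2..N)` convention (drop each
peptide's first residue, which back-exchanges during analysis, and
prolines, which have no backbone amide) — the default of common
processing software. No back-exchange correction is applied anywhere;
all uptake is relative.

`wald_fdr()` fits per peptide the fixed-effects model
`RFU ~ state + time + state:time` with time categorical and sum-to-zero
contrasts, so the state main effect is the time-averaged shift
("magnitude") and the interaction block is a change of exchange kinetics.
Both Wald statistics are referred to χ² distributions; Benjamini–Hochberg
correction is applied across peptides separately per family, and a
peptide is called significant if either family passes the FDR (5%
default). A fixed-effects model (rather than a mixed model with replicate
random effects) is a deliberate simplification defensible at 3
replicates; with many strongly affected peptides, BH leniency lets a
truly null peptide through occasionally — the package therefore reports
effect sizes (`avg_delta`) alongside calls, and the "unchanged linker"
conclusion in the demo rests on the effect size. Zero-residual-variance
peptides (exact ties) return `NA` p-values with a `degenerate` flag.
Overlapping peptides are not consolidated to residue resolution;
`residue_map()` paints each residue with its shortest covering peptide.

The generator `simulate_hdx()` uses two-state kinetics
`1 − exp(−(k_int/PF)·t)` per residue with a single configurable intrinsic
rate (default 1 s⁻¹ at the study's pD/temperature scale) instead of
sequence-dependent intrinsic-rate tables — a documented simplification
that preserves the statistical structure (per-peptide sums, replicate
noise, protection contrasts) while forgoing per-residue kinetic realism.
EX1 bimodality, isotope envelopes and back-exchange are not emulated, so
passing tests say nothing about those phenomena.

## ITC

`one_site_heats()` implements the one-site isotherm: bound fraction from
the quadratic in `(1 + X/nM + K_D/nM)`, cumulative heat
`Q = nΘM ΔH V₀`, perfusion-cell dilution of both concentrations in the
injected volume, and per-injection heats with the mean-value displacement
correction plus an optional constant dilution offset. `one_site_fit()`
fits `(log₁₀K_D, n, ΔH, offset)` by Levenberg–Marquardt (log-K_D keeps
the constant positive; the K_D error is mapped back by the delta method).
When a blank titration is supplied its heats are subtracted point-wise
and the offset is fixed at zero. `n` is fitted free by default — a
reported stoichiometry of 1.2 ± 0.5 implies a free `n`. The Wiseman
`c = n[M]/K_D` is reported with a warning outside [1, 1000]; at the
study's own design (8 µM cell, 200 µM syringe, K_D 3 µM) `c ≈ 3`, so
individual fits scatter substantially while the ensemble median across
100 simulated titrations recovers K_D and `n` well inside the reported
uncertainty bands — which is exactly what the tests assert.

## Structures

PDB parsing is delegated to `bio3d`; the atom table keeps blank/`'A'`
altlocs only (occupancy-weighted averaging was rejected for determinism).
`kabsch_rmsd()` matches atoms by `(chain, residue, atom name)` and uses
the closed-form SVD superposition with the determinant correction that
forbids reflections; it agrees with an independent superposition routine
to 10⁻⁹ Å and is symmetric and rigid-motion invariant by construction.
Contacts are heavy-atom minimum distances at a 3.9 Å default cutoff (the
conventional non-bonded contact limit). `paint_residue_values()` writes
per-residue scalars into the B-factor column, clamped to the PDB field
range on output (2-decimal precision — round trips are exact to 0.01).

## Synthetic conformers

`make_two_lobe_conformers()` builds each lobe as a random sequential
packing of 60 beads (excluded-volume diameter 3.8 Å, Cα scale) in a 12 Å
sphere; extended conformers join the lobes with a 6-bead self-avoiding
persistent walk (3.8 Å steps, ≤ 40° per-step deflection), compact
conformers place the lobes at a 27.5 Å centre separation with a collapsed
linker. These defaults were fixed against the exact coordinate Rg
(`Rg² = Σrᵢ²/N` about the centroid) so that extended pools average
21–24 Å and compact pools 16–18 Å — the scale of the dumbbell-to-globule
collapse. The models are shape-only: no side chains, no hydration layer,
uniform scattering weights; they support shape statistics (Rg, Dmax,
Kratky, ensemble selection) but not atomic-detail comparisons.

## Problem sizes and numerical tolerances

The test suite runs in well under two minutes on one CPU with: 1000-bead
sphere oracles for Guinier/IFT (2% tolerance against `√(3/5)·R`);
100-replicate χ² and CorMap null simulations; exhaustive enumeration of
all 2²⁰ sign sequences as the CorMap oracle; GA-vs-exhaustive equality on
20-member pools at ensemble size 2; 100 null HDX datasets of 40 peptides
× 7 times × 3 replicates for FDR control; 100 noisy ITC titrations at
the study's concentrations; and a full synthetic pipeline run. TRACT
inversion is checked to 10⁻³ ns; Kabsch symmetry to 10⁻⁹ Å; report
round-trips to 6 significant digits.

## Known limitations

- Debye scattering is vacuum-only; absolute χ² against absolute-scale
  experimental data embeds a systematic hydration-shell offset.
- The IFT Dmax score is a stated substitute for perceptual criteria of
  classical software; it is calibrated on spheres and two-lobe shapes.
- The HDX intrinsic rate is a single constant; protection factors are
  therefore only defined up to that scale.
- Linear viscosity mixing underestimates the excess viscosity of
  water/DMSO mixtures at high DMSO fractions.
- The synthetic two-lobe models are coarse beads; their compact state is
  mildly prolate, so its Kratky peak sits slightly above (√3, 3/e).
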