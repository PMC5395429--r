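---
title: "Models and methods behind seascaper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seascaper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seascaper joins two ways of measuring how connected sea urchin
(*Paracentrotus lividus*) populations are across a coastal basin: a
biophysical simulation of where drifting larvae can go, and a
population-genomics analysis of whether the genomes of settled adults
record any of that structure. This vignette explains the models, the
tunable parameters, the synthetic data that stand in for external inputs,
and the numerical choices a maintainer would want spelled out.

## The biophysical dispersal model

Larvae are passive Lagrangian particles advected at fixed depth through
gridded daily mean fields of horizontal velocity and temperature.

**Spawning.** Spawning happens daily from April 1 to July 31, but only on
days when water temperature at the release site does not exceed 18 °C.
The gate temperature is read at the site's nearest wet cell, shallowest
stored depth level, from the daily mean — the choice of where "water
temperature" is read is a genuine free choice; the shallowest level is
the natural one for an intertidal spawner.

**Release.** Each spawning day, each site releases 1,000 particles
(`particles_per_day`), spread horizontally by an isotropic Gaussian
kernel with 1 km standard deviation (resampled until wet, at most 100
tries), uniformly in depth over 0.5–10 m. Each particle draws a pelagic
larval duration (PLD) from a Gaussian with mean 30 and SD 5 days,
truncated to [1, 60] days — the truncation guards against the unbounded
tails of the Gaussian and touches well under 0.1% of draws.

**Advection.** Positions step forward with the classical fourth-order
Runge–Kutta scheme at a 6-minute step. Degrees convert to metres by the
local equirectangular approximation (1° lat = 111,320 m; 1° lon =
111,320·cos φ m), adequate for a domain spanning a few degrees. Fields
are interpolated bilinearly in the horizontal, linearly in depth, and
linearly in time between daily means stamped at 12:00 (linear-in-time is
an assumption; nothing sub-daily is resolved). Velocity at dry neighbour
nodes contributes 0 m/s — a free-slip coast that avoids extrapolating
flow onto land — while temperature renormalises its weights over wet
nodes, since a land temperature of 0 °C would be meaningless.

**Beaching and loss.** A step that would land on a dry cell is cancelled
and the particle stalls for that step; a step that samples outside the
domain marks the particle lost (it counts as released, never as
arrived). Stalling was chosen over killing because the coastline here is
the 10-m isobath of the source bathymetry, and beaching against it is a
numerical artefact more than a biological fate.

**Mortality.** Above 18 °C larvae die at rate μ = 3 d⁻¹, i.e. 5%
survival per day above threshold. The default accounting is
deterministic: each particle carries a survival weight
`exp(-μ · τ)` where τ is its cumulative time above threshold. This has
exactly the same expectation as Bernoulli killing (available with
`mortality_mode = "bernoulli"`) at far lower Monte Carlo variance. The
per-day rate is applied continuously per step, which reproduces the 5%
daily survival figure exactly.

**Arrival.** At the end of its PLD (no early settlement), a particle
arrives if its final position lies within 5 km great-circle distance of a
site; ties go to the nearest site, then alphabetically.

### Connectivity products

From the per-year fluxes the package computes:

* **Effectiveness** — mean over years of (survival-weighted arrivals /
  releases from the origin). Mean-of-annual-ratios, not ratio-of-totals,
  so that the averaging matches the persistence definition, which also
  operates on annual fluxes. Two normalisations are tagged: by *actual*
  release (spawning days only — the default, consistent with the
  success-rate decomposition) and by *potential* release (all season
  days).
* **Persistence** — the stabilization coefficient, mean/SD of the annual
  flux with the sample (n−1) SD. This convention makes a flux positive
  in exactly one year of ten equal 1/√10 = 0.316, the repeated minimum
  seen in persistence tables. All-zero fluxes are undefined (NA);
  constant nonzero fluxes are reported as +Inf.
* **Rate decomposition** — per origin: release rate (actual/potential),
  survival rate (mean survival weight of released larvae), arrival rate
  (weight-free fraction reaching any buffer), success rate
  (survival-weighted arrivals over actual release).
* **Interannual trends** — a modified Mann–Kendall test with the
  Hamed–Rao variance correction for serial correlation. Lags enter the
  correction when the rank autocorrelation of the Sen-detrended series
  exceeds the two-sided 5% normal bound `z₀.₉₇₅/√(n−lag)` — the original
  method leaves this cutoff open, and this is the conventional choice.
  Alongside S, the corrected variance, z and p, the Theil–Sen and OLS
  slopes are reported.

## The population-genomics stage

**Filtering** mirrors a RAD-SNP quality pipeline: (1) loci carrying 2–3
SNPs keep only the SNP with the highest whole-dataset expected
heterozygosity (ties to the lowest position in the tag); (2) loci must be
typed in at least 80% of individuals (boundary inclusive) and be
polymorphic; (3) individuals missing more than 30% of retained loci are
dropped (exactly 30% is kept). The locus filter is *not* re-applied
after step 3 — individuals are excluded a posteriori, and re-filtering
would silently change the locus panel.

**Diversity.** Observed heterozygosity, Nei's unbiased expected
heterozygosity `2n/(2n−1)·(1−Σp²)`, and allelic richness rarefied to
g = 2·16 gene copies via exact hypergeometric expectations.

**F-statistics.** The Weir–Cockerham θ estimator is implemented as a
method-of-moments nested ANOVA on allele indicators of gene copies
(population / individual / copy), with a fourth level (group) providing
the hierarchical AMOVA statistics F_CT, F_SC, F_ST. All coefficients are
computed from locus-specific cell sizes, so missing genotypes are
handled by locus-wise deletion, and per-locus variance components are
summed before forming any ratio (ratio-of-sums). Negative estimates are
reported as-is, never clamped. The three-level case is algebraically
identical to the textbook θ formulas, and the test suite checks it
against an independently transcribed implementation of those formulas to
1e-9.

Inference: permutation tests (individuals among populations for
F_ST/θ; whole populations among groups for F_CT; individuals among
populations within groups for F_SC; default 10,023 permutations — an odd
count so the +1-corrected p-value never hits 0) and a percentile
bootstrap over loci (default 1,000 resamples) for the CI of θ.

**Partition search.** All partitions of the populations into exactly 2
or 3 nonempty groups are enumerated (511 + 9,330 candidates for 10
populations) and ranked by F_CT. The scan refuses more than 12
populations — beyond that, exhaustive enumeration stops being honest
about its cost.

**Multiple testing** uses Benjamini–Hochberg via `p.adjust`.

## Forward-time simulation and power

A multi-deme Wright–Fisher engine drives both the drift/migration
scenarios and the power analysis. Each generation: binomial (biallelic)
or multinomial (haplotypic) resampling of 2N gene copies, then
deterministic island-model migration `p′ = (1−m/N)p + (m/N)·mean(p)`,
then symmetric mutation (default 0; scenario rates 2.5e-8 and 1e-6 are
accepted and make no practical difference on these timescales).

**The 2N convention.** Published mtDNA power tables are reproducible
only if the entered "haploid female" size N_f drives a drift increment
of 1/(2N_f) per generation — i.e. the original tool ran its diploid
machinery on mtDNA. The engine therefore always resamples 2N copies for
the entered N, for both marker types; a `strict_haploid` flag (increment
1/N) exists for comparison but is not the default.

Under pure drift the expected differentiation is
`F_ST(t) = 1 − (1 − 1/(2N))^t`; the sampled mean θ from the engine is
checked against this closed form across a grid of (N, t) — the engine's
core oracle. Power follows the POWSIM protocol: drift t generations,
sample the study's per-deme sizes, build per-locus allele-count
contingency tables, sum chi-square statistics and degrees of freedom
over polymorphic loci, and report the fraction of 200 replicates
significant at α = 0.05. Stationarity of the migration scenarios is
declared when a Mann–Kendall test on the last 50 sampled generations is
non-significant (p > 0.5) twice in a row — a pragmatic package choice,
since the original tools state none.

## Synthetic data: what it emulates, and what it does not

No external reanalysis fields or archived genotypes are needed; both are
emulated:

* **Ocean fields** (`make_synthetic_field`): divergence-free velocities
  from a discrete streamfunction (superposed Gaussian gyres; optional
  white noise), and a sinusoidal annual temperature cycle (defaults:
  winter 13 °C, summer 26 °C, peak at day 225) that crosses the 18 °C
  spawning gate in late spring, as in the study region. A solid-body
  rotation field provides the analytic trajectory oracle; its stored
  eastward velocity carries a cos(lat) factor that cancels the metric
  conversion, making the degree-space ODE exactly linear and the circle
  oracle exact.
* **Genotypes** (`simulate_genotype_dataset`): defaults emulate the
  study panel — 1,122 polymorphic loci split 261/420/441 into 1/2/3-SNP
  tags (2,424 SNPs in exact-count mode), 8 samples of 25–31 individuals,
  per-individual missingness at the locus level. Population frequencies
  follow the Balding–Nichols Beta model around ancestral frequencies at
  a chosen target F_ST, giving a known truth for estimator tests. The
  ancestral minor-allele spectrum defaults to uniform on (0, 0.5] —
  the source panel's spectrum is unpublished, so no quantitative claim
  in the tests depends on this choice beyond bounded-away-from-zero
  polymorphism.

What the synthetic data do *not* emulate: real bathymetry and
coastlines, mesoscale circulation beyond idealised gyres, linkage
disequilibrium between loci, selection, and demographic change. Passing
tests therefore demonstrate correctness of the algorithms under known
truth, not oceanographic realism of any particular connectivity matrix.

## Numerical choices and problem sizes

* RK4 order is verified on the rotation oracle over steps of 24, 12, 6,
  3 minutes (log–log slope 4 ± 0.3); the solid-body grid default (1/200°)
  keeps bilinear interpolation error well below time-stepping error.
* Survival weights satisfy `weight = exp(−μ·τ)` against step-wise
  accumulation to 1e-9.
* The test suite and the acceptance script run the drift ladder at 300
  loci, 4 demes and 30 sampled individuals per deme (the estimator's
  mean is unbiased in all of N, t, locus count), the power analysis at
  the full 1,122-locus panel in the acceptance script and at 300 loci in
  the tests, and the dispersal property checks on small domains with
  shortened spawning windows and PLDs — sizes chosen so the whole suite
  runs comfortably on a laptop core while leaving every estimator's
  sampling distribution wide enough for honest 3-SE checks.
* Permutation p-values use the add-one convention (b+1)/(m+1).
* Degenerate inputs: empty site lists, single-year persistence, >12
  population scans, monomorphic loci, all-dry interpolation queries and
  absent GENEPOP POP blocks all raise early, named errors rather than
  propagating NaN.

## Known limitations

Two-dimensional advection only (no vertical migration or behaviour); no
stepping-stone seeding of unsampled habitat, so connectivity estimates
are conservative and isolation estimates optimistic; the AMOVA
permutation scheme for F_CT permutes whole populations, which is coarse
when populations are few; the equilibrium-detection heuristic is
pragmatic, not optimal; and GENEPOP support is deliberately restricted
to the biallelic 2/3-digit dialects this pipeline produces.
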