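---
title: "Homozygosity, demography and selection scans: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity, demography and selection scans: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models behind each stage, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology left room.

## The analysis and its data model

The pipeline targets diploid autosomal biallelic SNP-array genotypes from
structured livestock populations — the motivating setting is a ~50K goat
chip across six breeds split into high- and low-fecundity groups. All stages
share one container, the `genotype_matrix`: a samples × markers matrix of
counted-allele dosages (0/1/2/`NA`) plus a marker map (chromosome, id, cM,
bp), a population label per sample and the counted/other allele per marker.
Phased data live in a `haplotype_set` (two binary rows per sample, no
missingness). Coordinates are 1-based inclusive throughout (the PLINK
convention); every exported BED interval passes through a single conversion
function (`to_bed()`), so the off-by-one rule exists in exactly one place.
When a map carries no genetic positions, stages that need them (HBD, Ne,
XP-EHH) impute 1 cM/Mb and say so — a standard assumption for livestock
chips without a fitted linkage map.

PLINK text and binary dialects are both read and written; the binary codec
follows the published 2-bit SNP-major layout, with the `.bim` allele-1
column as the counted allele and no re-polarization. Text input cannot carry
a counted-allele designation, so the reader takes the lexicographically
smaller observed allele (deterministic) and marks the unobservable second
allele of monomorphic markers as `"0"`; round trips therefore preserve the
genotype information exactly, and the codes bit-for-bit in the binary
dialect.

## Quality control

Filters run in a fixed, logged order: samples above 10% missingness first,
then markers — sex-chromosome, call rate < 95%, MAF < 5%, exact-test
Hardy–Weinberg p < 1e-5. Each marker is attributed to the first filter that
catches it, so the ledger categories are mutually exclusive and the ledger
identity `initial = remaining + Σ removals` holds by construction. Marker
statistics are computed on post-sample-removal data, matching the
sample-before-marker convention of the standard tools. The HWE rule is
implemented as an exclusion at p < 1e-5 (the tabulated form), resolving the
ambiguity of stating it as a keep rule. The exact test conditions on the
observed allele counts and sums the probabilities of all heterozygote counts
no more probable than the observed one (no mid-p), with probabilities from
the standard parity recurrence computed in log space.

## Runs of homozygosity and inbreeding

A run is a maximal stretch of consecutive markers with at most one
heterozygote and one missing genotype, kept if it has ≥ 15 SNPs and spans
≥ 1 Mb (length = end bp − start bp, not +1). Length classes are half-open:
0–3, 3–5, 5–10, 10–20, 20–30, > 30 Mb. Two design points the consecutive-run
literature leaves open are fixed here for determinism: (i) maximality is
defined against the het/missing bounds only, with the SNP-count and length
thresholds applied afterwards; (ii) where two maximal runs overlap (possible
around an allowed heterozygote), the longer wins, ties to the leftmost, so
one sample's runs never overlap. A brute-force enumeration of all maximal
windows serves as the testing oracle for the linear-time scanner.

`F_ROH = L_ROH / L_AUTO` with `L_AUTO` defaulting to 2399.4 Mb (the goat
autosome; configurable — simulations pass their own genome length). The
per-class decomposition sums to the total by construction. `F_HOM` is the
excess-homozygosity coefficient `(O − E)/(N − E)` with the expected
heterozygosity small-sample corrected by `2n/(2n−1)` per marker — the
behavior of the standard `--het` implementation, stated here because the
tools themselves only name it. Per-chromosome ROH coverage uses the carrier
convention (summed ROH length over individuals having ≥ 1 ROH there, divided
by chromosome length); per-class breed means divide by the full breed size.
ROH islands are maximal runs of consecutive SNPs whose ROH occurrence across
individuals exceeds 45%.

## The homozygosity-by-descent model

Each individual's genome is modelled as a hidden Markov chain over K = 10
classes: nine HBD classes with rates R_k = 2^1 … 2^9 per Morgan and one
non-HBD class sharing the most ancient rate 2^9. Segment lengths in class k
are exponential with mean 1/R_k Morgans, so R_k is roughly twice the number
of generations to the common ancestor of that class. Between markers
separated by d Morgans the chain stays with probability `exp(−R_k d)`,
otherwise the segment ends and a new class is drawn from the mixing
coefficients M.

The emission model is not fully pinned down by the model family's
description, so the package adopts the natural one and makes it
configurable: an HBD class emits the two homozygotes at `(1−ε)p` and
`(1−ε)q` and a heterozygote only through genotyping error ε (default 0.001);
the non-HBD class emits Hardy–Weinberg frequencies; missing genotypes emit 1
everywhere. Rates stay on the fixed grid; only M is estimated, per
individual (the per-individual reading matches partitioned-autozygosity
displays of this model family), by EM with a scaled forward–backward E-step
(compiled), uniform initialization, tolerance 1e-6 on the log-likelihood and
a 1000-iteration cap; per-site scaling prevents underflow. Monomorphic
markers carry no information and are dropped before fitting. Allele
frequencies default to the analyzed sample. `F_G–T` accumulates the realized
autozygosity of classes with R_k ≤ T; it is non-decreasing in T and plateaus
at the total HBD fraction.

The forward algorithm is verified against an exhaustive sum over all K^L
state paths on small instances (10^4 paths at K = 10, L = 4; 6561 at K = 3,
L = 8) — sizes where enumeration is exact while still exercising the full
transition structure.

## Effective population size from LD decay

Within-chromosome marker pairs are binned by genetic distance (default 20
log-spaced bins over [0.0005, 0.25] Morgan); each bin's mean squared dosage
correlation (composite LD on unphased dosages, pairwise-complete), corrected
for sample size by `r² − 1/(2n)`, is inverted through Sved's relation
`E(r²) = 1/(1 + 4 Ne c)` at the bin midpoint, with the time depth `T =
1/(2c)` generations. Markers below MAF 0.05 within the analyzed population
are excluded. No mutation-rate adjustment is applied — the relation is used
verbatim. The bin scheme, MAF floor and phasing treatment are declared
defaults of this package, not inferences from any particular study; the
estimator is validated by exact analytic inversion and by recovering the
size of constant Wright–Fisher populations (and the qualitative
recent-versus-ancient contrast after a simulated bottleneck).

## Differentiation and structure

*Reynolds distance.* The coancestry estimator uses an unbiased moment
numerator — the squared allele-frequency difference summed over both
alleles, minus its sampling variance estimate `h_i/(2n_i − 1)` per
population — over the average unbiased heterozygosity, aggregated across
markers as a ratio of sums, with `D_R = −ln(1 − θ)`. It is zero in
expectation for identical populations, one for fixed differences, and is
cross-checked in the tests against an independently coded per-marker
implementation.

*Pairwise differentiation.* The between-breed table pairs Reynolds distances
(upper triangle) with global Weir–Cockerham θ between each population pair
(lower triangle) — the reading under which a "pairwise difference" is the
pairwise F_ST. The Weir–Cockerham estimator is the standard biallelic
variance-component form (a, b, c), per marker as `a/(a+b+c)` and globally as
a ratio of summed components; markers monomorphic overall are undefined and
excluded from summaries and Z-standardization.

*AMOVA.* Two-level variance partition from pairwise squared dosage distances
(`Σ (g_i − g_j)²/2`, rescaled for missing pairs), with the usual
sums-of-squares decomposition and Φ significance from permuting sample
labels (default 100 permutations, `p = (#Φ_perm ≥ Φ_obs + 1)/(n_perm + 1)`).

*PCA and pruning.* PLINK-style greedy LD pruning (50-SNP windows, step 10,
r² > 0.1 removes the later marker of a pair; deterministic), then markers
centered at 2p and scaled by √(p(1−p)), missing values at the marker mean,
eigendecomposition of the sample covariance; variance fractions are
eigenvalues over their sum.

*Trees.* Sample or population 1−IBS allele-sharing distances feed
Saitou–Nei neighbour joining (via ape). Negative branch lengths — possible
on non-additive input — are clamped to zero with the deficit moved to the
adjacent branch, preserving paths through the parent node. NJ recovers
additive matrices of 4–8 taxa exactly in the tests.

## Selection scan

The scan contrasts a high and a low group per SNP with three statistics:

- **F_ST / ZF_ST** — Weir–Cockerham θ between the groups; Z uses the
  population (n-denominator) standard deviation over scanned SNPs, a
  convention this package fixes explicitly.
- **π ratio** — per-site unbiased diversity `2k(2n−k)/(2n(2n−1))` in each
  group, oriented as π_low/π_high so that elevated values flag diversity
  loss in the high group; the log2 ratio is also emitted. π is compared per
  SNP with no windowing.
- **XP-EHH** — `ln(I_A/I_B)`, with I the trapezoid integral of EHH over
  genetic distance in both directions from the core, truncated where the
  combined-population EHH falls below 0.05 and at a 2.5 Mb physical bound,
  then standardized to zero mean and unit variance across cores. EHH is
  computed jointly over all haplotypes of a population (the unstandardized
  cross-population variant). The package defines EHH(core) = 1 — the core is
  the origin of the extension, and its allele enters the shared-prefix
  comparison at the first step outward; the alternative (starting from the
  core-site homozygosity) conflicts with the boundary condition the integral
  requires.

Outliers are the empirical top 1% of F_ST, top 1% of the π ratio and top
0.1% of standardized XP-EHH, each as the `ceiling(q·n)` largest values (a
deterministic rank rule rather than an interpolated quantile, so constructed
inputs give exact counts). Candidate SNPs — the F_ST-and-π intersection plus
the XP-EHH outliers — are extended ±100 kb, merged when overlapping, clipped
at chromosome ends, and intersected with a supplied gene table (BED read
directly; GFF via rtracklayer). Group membership is configuration, not code.

## The synthetic-data generator

The generator provides every stage with data of known truth, at a scale a
test suite can afford: by default two 100-Mb chromosomes at 1 cM/Mb with one
marker per 50 kb (≈ 4,000 markers) and 35–100 individuals per population —
dense enough for 15-SNP ROH calls, small enough for minutes-scale runs.
Genotyping error defaults to 0.001 and missingness to 0.01, inside the QC
tolerances.

- `simulate_balding_nichols()` draws ancestral frequencies uniform on
  [0.05, 0.95] and population frequencies from the Balding–Nichols Beta
  distribution with divergence F — the standard backing model for F_ST,
  Reynolds, PCA and AMOVA checks.
- `simulate_wright_fisher()` runs discrete-generation random mating with
  Poisson-per-Morgan crossovers (compiled kernel, R RNG, so seeded runs are
  reproducible), producing realized LD for the Ne stage; a size trajectory
  with a step models a bottleneck.
- `simulate_haplotypes_iid()` is the outbred, LD-free background for
  planted-truth tests: any homozygous run or haplotype-sharing signal beyond
  chance is the planted one.
- `plant_autozygosity()` copies one haplotype over the other in
  exponential-length tracts until a target fraction of the genetic map is
  covered, recording every tract; `plant_sweep()` overwrites a fraction of a
  population's haplotypes with a founder haplotype around a core, with
  optional exponential copy-fidelity decay.

What the generator does **not** emulate: real ascertainment bias of chip
panels, mutation, gene conversion, variable recombination maps, overlapping
generations, migration, or the joint presence of deep pedigree structure and
chip noise. Consequently, passing recovery tests shows the estimators are
correct on their own model assumptions — it does not certify behavior on
real data with those extra features. The Balding–Nichols cohort in the
analysis scripts carries no within-population LD, which is why the Ne stage
demonstrates on dedicated Wright–Fisher populations instead.

## Numerical choices and degenerate inputs

- HWE probabilities via a log-space recurrence; ties in the "no more
  probable" rule absorbed with a 1e-12 relative slack.
- HBD forward–backward with per-site scaling; EM mixing coefficients floored
  at 1e-12 before renormalization; non-convergence returns a flagged result
  rather than an error.
- Undefined quantities are `NA`, never silently zero: r² with < 2 complete
  pairs or zero variance, Ne with adjusted r² outside (0, 1), F_HOM when
  N = E, per-marker F_ST at monomorphic sites, XP-EHH when an EHH integral
  is zero (with a logged message).
- Standardizations (ZF_ST, XP-EHH) refuse constant input (sd = 0) rather
  than returning zeros.
- The ROH overlap rule, the LD-pruning removal rule (later marker of an
  offending pair) and the outlier rank rule are all deterministic by
  construction; pipeline runs with a fixed seed and config reproduce
  byte-identical tables.

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations for
single-CPU runs: 200-marker instances (×1000) for the ROH oracle; K ≤ 10
with L ≤ 8 markers for exhaustive HMM enumeration; 20 replicates of a
100-diploid, 200-generation Wright–Fisher population (2 × 50 Mb at 25 kb
spacing) for Ne; 10,000 markers × 200 samples for the Balding–Nichols θ
check; 20 replicates of a 50-individual two-group panel with a planted sweep
for XP-EHH. These sizes are the package's declared study conditions for its
synthetic checks; they are not tuned to any particular outcome.

## Known limitations

- ROH calling is the consecutive-run method only; no sliding-window
  (heuristic) variant, no ROH-based association.
- The HBD model fixes the rate grid (as the motivating model family does)
  and fits individuals independently; no joint or hierarchical estimation.
- Ne inference is the Sved inversion of binned LD; no coalescent machinery,
  and confidence is by replicate scatter only.
- Phasing is assumed done elsewhere; XP-EHH consumes phased input and is
  skipped (with a status note) when none is supplied.
- Model-based clustering (ADMIXTURE-style) is out of scope; the package only
  exports the pruned PLINK fileset such tools consume.
- Gene-function interpretation and enrichment analysis are out of scope;
  annotation stops at interval intersection.
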