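---
title: "Simulating genomic selection for crossbred performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic selection for crossbred performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crossim)
```

## The problem

In pig and poultry production the animals that generate revenue are
crossbreds, but selection operates within the pure parental breeds. Crossbred
performance (CP) decomposes into the average of the parental breed means (BA)
and heterosis (H): CP = BA + H. Selection criteria that target purebred
performance improve BA; criteria that target crossbred performance also
exploit H, mainly by driving the two breeds toward different allele
frequencies at dominant and over-dominant loci. The package simulates a
two-way crossbreeding program under genomic selection to quantify this
trade-off over many generations.

Candidates in each breed are ranked by the selection criterion

$$SC_i = (1 - w)\,\mathrm{GEBV}_{iP} + w\,\mathrm{GEBV}_{iC},$$

an affine blend (no re-standardization; both components share the same
estimated marker effects, so their scales are directly comparable) of the
genomic breeding value for purebred performance and the one for crossbred
performance. `w = 0` is classical within-breed selection; `w = 1` selects
purebreds explicitly for the performance of their crossbred offspring.

## Model components

### Genome and historical population

The default genome is deliberately compact: 4 chromosomes of 1 Morgan, 8800
candidate biallelic loci, from which 4000 SNPs and 400 QTL (1000 and 100 per
chromosome) are drawn after the historical phase, restricted to loci with
minor allele frequency above 0.05. The historical population (2000
individuals, equal sex numbers) mates at random for 2000 generations from
uniform(0, 1) starting frequencies in linkage equilibrium; recurrent
symmetric allele-flip mutation at 2.5e-5 per locus per gamete keeps enough
loci segregating. Mutation is applied *only* during the historical phase:
its sole purpose is to deliver the required number of polymorphic loci, and
leaving it on during breeding would let fixed QTL re-segregate, which the
fixation statistics assume cannot happen.

Meiosis uses a Poisson number of crossovers per chromosome (mean = length in
Morgans), uniform crossover positions and no interference — the Haldane
model. This is the standard choice when the original description leaves the
recombination model open; the recombinant fraction between loci 1 Morgan
apart is (1 − e^-2)/2 ≈ 0.432, which the test suite verifies empirically.

### Trait architecture

Absolute additive effects |a| are gamma(shape 0.4, scale 1.66): many small
effects, a few large ones. The (shape, scale) reading of the two parameters
follows the convention of the breeding-simulation literature; the
alternative (shape, rate) reading would shrink all effects by a factor
~2.76, which the variance scaling would simply undo, so the choice is
inconsequential after calibration. The sign of a is random — either allele
is equally likely to be the increasing one, since a is defined as half the
homozygote difference without a sign convention. Dominance enters through a
degree of dominance h ~ N(0.5, 1) with d = h·|a|, so large-effect QTL also
tend to have large dominance deviations, and a QTL is over-dominant when
|h| > 1 (about 37.5% of raw draws).

Three genetic models are predefined: model 1 (dominance variance 0.1,
over-dominance allowed), model 2 (0.05), model 3 (0.1 but over-dominance
suppressed by setting d = |a| for QTL sampled beyond the homozygote range).

Effects are rescaled to the target variance components at the
generation-2000 historical allele frequencies (the common ancestor of both
breeds, so one architecture serves both): additive variance
σ²a = Σ 2pqα² with α = a + (q − p)d, dominance variance σ²d = Σ (2pqd)².
Because α couples a and d, a one-shot rescaling is inexact; the package
alternates multiplicative updates of d and a until both variances are within
a relative tolerance of 1e-4 (default cap 5000 iterations — each iteration
is a few hundred floating-point operations, and convergence near the
no-over-dominance clamp can be slow). After calibration to (0.3, 0.1) about
a quarter of QTL remain over-dominant under model 1, and about a tenth under
model 2 — an emergent consequence of the variance targets, not a tuned
quantity.

One genuine corner was found during development: under model 3 the
constraint |d| ≤ |a| caps the attainable dominance variance, and for roughly
a third of effect draws that cap falls below 0.1 (the attainable maximum —
every QTL at complete dominance — has median ≈ 0.107 across draws). When the
target is unreachable the scaler converges the additive variance, saturates
the dominance variance at its maximum, and returns with a warning and a
`dominance_saturated` attribute. A hard failure would make a third of
model-3 replicates unusable for a shortfall of a few percent.

The residual variance is σ²p − σ²a − σ²d (0.6 for models 1/3, 0.65 for
model 2) rather than a literal unit variance, because σ²p = 1 and h² = 0.3
are jointly incompatible with a N(0, 1) residual; the literal option remains
available behind `trait_config(literal_standard_normal_residual = TRUE)` for
sensitivity analysis.

### Populations and selection

Two breeds are founded as disjoint random samples of 100 individuals from
the historical population, randomly mated at size 100 for 100 generations,
then expanded in one round of random mating to 1000 selection candidates
each. Each generation of the program: candidates are phenotyped
(y = genotypic value + residual), marker effects are estimated, candidates
are scored, the top 100 males and 200 females per breed are kept (ties
broken by ascending id), and the selected parents produce 1000 purebred
replacements per breed plus 1000 crossbred progeny from A sires × B dams.
Sexes are assigned deterministically (alternating), so the 100/200 selection
is always feasible — the original description silently assumes availability.
Mating draws an independent uniform (sire, dam) pair per offspring: no
litter structure is imposed because none is specified.

Reported rows compare contemporaneous cohorts: the crossbreds produced by
the generation-t selection are compared against the purebred replacement
cohorts born at the same time, so H = CP − BA is a like-for-like contrast of
cohorts descending from the same selected parents. Because the phenotypic H
of a few hundred animals carries sampling noise of the same order as the
between-criteria differences at desk scale, the per-generation statistics
also include `H_expected` = Σ d(p_A − p_B)², the allele-frequency-divergence
component of heterosis, which is nearly noise-free and tracks the mechanism
the selection criteria act on.

### Breeding values

The true breeding value of a candidate is the expected genotypic value of
its offspring under random mating to a reference population: the own breed
for TBV-P, the opposite breed for TBV-C. Per locus the contribution is
x(pa + qd) + (1 − x)(−qa + pd) with x ∈ {1, ½, 0} the candidate's allele-1
share and (p, q) the reference frequencies, recomputed every generation from
all current candidates of the relevant breed (stated for SNPs in the source
design; applied to QTL symmetrically). GEBVs evaluate the same sum over the
4000 SNPs with estimated effects. Frequencies of 0 or 1 are legal — the
terms remain defined — and no flooring is applied. With no dominance the
substitution effect is frequency-free and GEBV-P and GEBV-C differ only by a
candidate-independent constant (identical rankings); the purebred–crossbred
genetic correlation r_pc, the correlation between TBV-P and TBV-C within a
breed, is then exactly 1 and falls below 1 as dominance and allele-frequency
divergence accumulate.

### Marker-effect estimation

The estimator is a Bayesian ridge regression with two effect classes,

$$y_i = \mu + \sum_j X_{ij} a_j + \sum_j Z_{ij} d_j + e_i,$$

with X the 0/1/2 dosage, Z the heterozygosity indicator, Gaussian priors per
class and scaled-inverse-chi-square hyperpriors (df 5) on the two class
variances and the residual. Hyperprior scales assume the markers capture
half the phenotypic variance, split equally between classes — the de facto
default of Bayesian ridge implementations; the original study names the
method but not its hyperparameters. The Gibbs sampler performs single-site
sweeps (intercept, all additive, all dominance effects per iteration);
columns are centered internally, which decorrelates the intercept from the
effects and markedly improves mixing without changing the posterior of
(a, d). The production chain is 20000 iterations with 3000 burn-in; the test
suite and the desk-scale acceptance runs use 2000/500 with correspondingly
relaxed tolerances. Convergence of the monitored chains (intercept and the
three variance components) is summarized by the Geweke diagnostic,
implemented with AR-spectral variance estimates at frequency zero; a
constant chain returns z = 0 via a variance floor. With variance components
held fixed the posterior mean equals the closed-form joint ridge solution,
which is the central correctness oracle of the test suite (max abs
difference ~4e-3 at 10⁴ iterations against a tolerance of 1e-2).

Purebred training fits one model per breed on that breed's 1000 current
candidates. Crossbred training fits a single model on 2000 current
crossbreds and applies it to both breeds; the program therefore doubles the
crossbred cohort to 2000 in that mode (resolving the 1000-versus-2000
ambiguity in the source design), and generates an initial crossbred cohort
from randomly selected parents so that a training set exists in the first
generation.

### LD phase correlation

Linkage-disequilibrium r between SNP pairs is the signed Pearson correlation
of allele indicators across the 2n phased gametes of a population, under one
global allele labelling, for all within-chromosome pairs up to 10 cM with
MAF > 0.01 in the population. The phase correlation R_XY between two
populations is the Pearson correlation of paired r values over the shared
pair set, in half-open 0.1 cM bins; bins with fewer than three shared pairs
are reported missing. Phased haplotypes (available in simulation) are used
rather than genotypic composite LD because sign consistency is what phase
correlation measures. Crossbreds enter this analysis as the generation-1 F1
cohort. Note one subtlety verified by the test suite: relabelling the
alleles of a *single* SNP flips its r in both populations and perturbs R_XY
only through the (near-zero) bin means of r; relabelling all SNPs leaves
R_XY exactly unchanged.

## Randomness and reproducibility

All randomness flows through R's RNG (the compiled kernels draw from the
same stream), so `set.seed()` makes any pipeline stage reproducible. A
replicate derives its seed from the master seed and its index; each
(replicate, w) scenario re-seeds from the replicate seed and w, and all w
scenarios of a replicate share one base state (common random numbers): the
architecture, base populations and generation-0 phenotypes are identical
across w, and trajectories diverge only through selection decisions. This
sharpens the contrasts between selection criteria at a given number of
replicates, which is how the study design compares criteria against the
w = 0 reference.

## Problem sizes

The package ships two profiles. `study_profile("paper")` is the full design:
50 replicates × 40 generations, 4000 SNPs/400 QTL, 1000 candidates per
breed, 20000-iteration chains — intended for a cluster.
`study_profile("test")` preserves the qualitative program behaviour at desk
scale: 400 SNPs/40 QTL, 300 candidates (30 + 60 selected), 300 crossbreds,
2000/500 chains, 5 replicates × 15 generations, and a smaller historical
population (500 individuals × 300 generations). The acceptance suite runs
the base-population statistics (LD phase, architecture calibration, r_pc,
first-generation accuracy) at the full base-population scale with 5
replicate seeds, and the program-behaviour orderings at the test profile.

## What the generator does and does not emulate

The synthetic populations capture drift, recombination, mutation-drift
balance, ascertainment of common SNPs, dominance and over-dominance, and the
LD structure that arises from a shared ancestral population — the features
the method consumes. They do not emulate sequence-level variation, variable
recombination maps, selection in the historical population, genotype-by-
environment interaction, or epistasis (the last two are deliberately outside
the simulated genetic model). Conclusions from passing tests therefore
concern the behaviour of the selection criteria under the stated genetic
models, not the magnitude of these effects in any real livestock population.

## Numerical choices and degenerate inputs

* Truncation-selection ties break by ascending id, making selection
  deterministic given scores.
* A constant training phenotype is legal: effects shrink to ~0 and the
  intercept to the constant.
* SNPs with no heterozygotes keep a dominance estimate of exactly 0.
* Monomorphic SNPs are excluded from LD tables (their r is undefined), and
  empty percentage denominators in fixation summaries yield missing values,
  never zeros.
* Architecture sampling fails with an explicit shortfall message when a
  chromosome lacks enough polymorphic loci.

## Known limitations

* Model 3's dominance-variance target is capped by the no-over-dominance
  constraint for a substantial fraction of effect draws (see above); the
  realized σ²d is then slightly below 0.1 and flagged.
* The post-scaling over-dominant fraction is an emergent quantity controlled
  by the QTL frequency spectrum at scaling time: near-intermediate
  frequencies give ~23–25% under model 1, while the drift-U-shaped
  generation-2000 spectrum this simulator produces gives ~32% (and ~15%
  instead of ~10% under model 2). The variance targets themselves are always
  met exactly, so this fraction has no free parameter.
* The between-population LD phase correlations produced by this
  implementation are systematically higher than the values the original
  study prints (e.g. breed-versus-F1 near 0.8 below 0.5 cM): a pooled-gamete
  F1 necessarily shares roughly the average of its parents' LD phase, and
  within-population r² here matches neutral drift theory (Sved's
  1/(1 + 4Nc)) at all distances, so the discrepancy appears to stem from an
  unstated detail of the original LD analysis rather than from the
  population simulation.
* Generations are discrete and non-overlapping; no inbreeding control, mate
  allocation or migration is modelled.
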