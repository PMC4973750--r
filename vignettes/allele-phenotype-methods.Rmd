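---
title: "Methods: population genetics on mixed-ploidy allele phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics on mixed-ploidy allele phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopop)
```

## The data model and why it looks the way it does

Capillary SSR profiles of polyploids show which allele bins amplified, not
how many copies of each an individual carries. Dosage-calling methods exist
but are unreliable at high or unknown ploidy, so the defensible record is
the **allele phenotype**: the set of observed alleles per locus. `phenopop`
therefore treats allele labels as opaque text compared only by equality (bin
reassignment from fragment sizes is a human scoring task, out of scope), and
codes a genotype table into one 0/1 column per `(locus, allele)` pair.

Missingness is per `(individual, locus)`, never per allele column: a total
absence of peaks at a primer pair means the locus failed, so *all* its
columns are `NA` for that individual. This keeps "masked" distinct from
"absent", which matters because the Dice distance deliberately ignores
shared absences. Individuals with an empty-but-unmasked locus are rejected
at parse rather than coerced. Missing-data filters are strict (`<` the
threshold), with both conventional ceilings exposed as parameters: 0.30 for
structure analyses and 0.20 for distance analyses. The two thresholds are
independent parameters rather than a nested pair, because the stricter
subset used for distances is simply the same mask applied at 0.20.

Breeding years map into 15 temporal classes — before 1700, the 18th
century, eleven decades of 1800–1909, 1910–1914, and after 1914 — chosen so
the "long 19th century" of intensive breeding is finely resolved. The scheme
partitions all integers; unknown years stay in the dataset and drop out of
temporal analyses only.

## Diversity indices under unknown dosage

All indices are carriage-based, with denominators `N_α` = individuals
*genotyped at that locus* (not the full collection):

* `Am_α = Σ_k n_kα / N_α`, the mean number of alleles carried;
* `Ae_α = 1 / Σ_i (N_iα / N_α)²`, an effective allele number built from
  carriage proportions. Because carriage proportions need not sum to one,
  `Ae` can fall below 1 when many individuals share many alleles — that is a
  feature of the definition, not a bug, and the package reports it as is;
* rare alleles are those carried by strictly less than 1% of `N_α`
  (threshold and denominator both exposed; the `N_α` denominator is the
  default because the index is per locus and individuals not genotyped
  there carry no information about the allele).

The totals row of `diversity_table()` sums `Ao` and rare counts but
*averages* `Am`, `Ae` and the missing fraction, since sums of those have no
interpretation. Full precision is kept everywhere; rounding is a display
concern.

## The Dice distance

For a pair of individuals, over the allele columns of loci observed in
both: `d = 1 − 2a/(2a + b + c)` with `a` shared presences and `b`, `c` the
one-sided presences. Shared absences never enter, which is why this
coefficient is preferred for dominant/binary data where an absent peak is
weak evidence. Three choices deserve a note:

* **Pairwise-complete loci.** No imputation is done for distances; each
  pair is compared on the intersection of its observed loci and the count
  of loci used is recorded per pair. Pairs with no commonly observed locus
  are flagged incomparable, not silently zeroed.
* **Pooled columns.** The coefficient is computed over all allele columns
  pooled, not averaged per locus — consistent with operating "on the
  presence/absence matrix". (A per-locus average would weight loci equally
  regardless of allele count; pooling weights by observed alleles.)
* **Bootstraps resample loci**, not columns: allele columns within a locus
  are strongly dependent (they share the mask and at least one is 1), so
  whole-locus blocks are the exchangeable unit. Bootstrap means and
  standard deviations are reported as support; point estimates are never
  smoothed. The bootstrap mean is a resampling mean of ratios and so
  carries a small bias relative to the point estimate; it is reported for
  spread, not as a replacement estimate.

## DAPC: clustering without Hardy–Weinberg

Allele-phenotype data violate every assumption of admixture-model
clustering (unknown dosage, mixed ploidy, uncertain inheritance, related
individuals), so group discovery uses K-means on principal components and a
discriminant step — no equilibrium assumptions anywhere.

* **PCA imputation.** Masked loci are imputed with the per-column mean over
  unmasked individuals, so after centring they contribute exactly zero to
  the projection.
* **The K scan** runs K-means for K = 2–35 on PCs covering ≥95% of the
  variance and scores each partition with `BIC(K) = N·ln(WSS_K/N) +
  K·ln(N)`. The criterion is stated explicitly because "BIC" alone does not
  pin down a formula; this is the spherical equal-variance likelihood with
  one penalty unit per cluster. Its behaviour depends on the within-cluster
  variance being spread over many components — exactly the situation for
  binary genotype matrices — and the parameter-recovery tests exercise it
  only in that regime. Because each K-means run is stochastic, the per-run
  BIC-minimising K is recorded over many runs (1000 by default, 50 in
  reduced/test mode) and the modal value is kept, ties broken toward the
  smaller K (parsimony).
* **The discriminant step** retains `n_pc` components (chosen by the
  a-score: observed reassignment success minus its mean under group-label
  permutation, argmax with ties to fewer PCs) and fits linear discriminant
  axes. Membership probabilities are softmax-normalised negative half
  squared Euclidean distances to group centroids in the sphered
  discriminant space — with equal priors this equals the Gaussian
  equal-covariance posterior, and is documented as an approximation of the
  reference posterior. When groups are perfectly separated the pooled
  within-group scatter is singular and the LDA engine fails; the package
  then solves the ridge-regularised generalised eigenproblem directly,
  which leaves well-separated memberships saturated at 1 as expected.
* An individual is **well assigned** when its maximum membership is ≥0.8
  (the threshold is a parameter). The ≥ convention keeps the natural
  boundary reading that a membership of exactly 1 is always well assigned.

## AMOVA and PhiPT

The variance partition is distance-based and uses **squared** Dice
distances — the standard construction for binary data, stated explicitly
because "AMOVA on a Dice matrix" underdetermines it:

```
SS_total  = (1/N) Σ_{i<j} d²_ij
SS_within = Σ_g (1/n_g) Σ_{i<j∈g} d²_ij
σ²_W = MS_W;  σ²_A = (MS_A − MS_W)/n₀;  n₀ = (N − Σ n_g²/N)/(G−1)
PhiPT = σ²_A / (σ²_A + σ²_W)
```

A negative among-group component is clamped to zero before PhiPT (the
convention of the reference implementations). Significance comes from
permuting individuals across groups, with the add-one estimator
`p = (b+1)/(m+1)` so p is never exactly zero — with 1000 permutations the
smallest attainable p is ≈0.001, which is why two-star conventions for
these matrices sit at p ≤ 0.002. Pairwise PhiPT analyses each group pair in
isolation and permutes labels only within the two groups concerned. No
multiple-testing correction is applied by default (matrices of raw p-values
with fixed star thresholds are the field's display convention); a
Bonferroni switch exists.

MPD (a group's mean pairwise PhiPT against all others) and nSSWG
(within-group sum of squares over group size) summarise relative
differentiation and intragroup variability.

## Temporal analyses

`temporal_phipt_matrix()` delegates to the pairwise PhiPT machinery with
breeding-year classes ordered chronologically and a reference pool appended;
classes under a minimum size (default 5) are dropped by name rather than
silently — the analogous empirical tables keep only classes large enough to
test.

`detect_shifted_alleles()` implements the frequency-shift rule with strict
inequalities: carriage >20% in one pool and <10% (zero included — "null or
low") in the other, both directions reported. Pool membership is
caller-defined on purpose: whether "bred before 1800" includes the pre-1700
material is a curatorial decision, not an algorithmic one.

For trajectory comparison, the observation unit is one allele's carriage
frequency in one class (each allele contributes one value per class), and
classes are compared by one-way ANOVA followed by Tukey HSD compact letters
at α = 0.01. This matches the boxplot-over-alleles reading of such figures;
the alternative (individual-level observations) would confound allele and
individual replication. The 15-class scheme is the default partition, with
a 7-period pooled preset (`default_periods()`) for coarser displays.

## The simulation framework

The ploidy-bias question — *does mixing ploidy levels create spurious
genetic structure under presence/absence coding?* — is answered on data
where the truth is known. The design: 10 subpopulations of constant size
500, split from one ancestral population 50 generations ago, 32 unlinked
SSR loci, 100 haploid allele copies sampled per subpopulation, and from
each sample 20 individuals of every ploidy 2x–6x assembled under panmixia
and strict polysomic inheritance (a p-ploid is p independent draws with
replacement; duplicate draws collapse in the binary coding).

Implementation choices, documented because the original description leaves
them open:

* **Forward Wright–Fisher, not coalescent.** Each locus is a pool of
  2×500 allele copies resampled multinomially each generation with strict
  stepwise mutation at 5×10⁻⁴ per copy per generation (the conventional
  default of SSR simulators), reflected at repeat count 1. The ancestral
  population is equilibrated by a burn-in of 10× the population size in
  generations before the split. This is an approximation of the original
  coalescent machinery; the 20%/4% variance-split checks accordingly carry
  a stochastic tolerance.
* **"A sample set of 100 individuals"** is read as 100 *per subpopulation*
  (20 per ploidy per subpopulation, 1000 individuals in all): the reported
  among-10-origins AMOVA and the per-ploidy membership summaries require
  within-cell replication that the literal total-100 reading cannot supply.
* **Population size counts diploid individuals**, so 1000 allele copies
  drift per locus.

On this default design the package reproduces the qualitative and
quantitative findings: grouping the simulated individuals by origin
explains ≈20% of molecular variance, regrouping the *same* individuals by
ploidy explains far less (≈4–8% across seeds), and mean membership in the
true group rises with ploidy level (higher ploidy samples more alleles and
so carries more information about its source population).

The **parameter-recovery checks** (modal K equals the planted number of
subpopulations, ≥95% of individuals confidently assigned to their planted
origin) use diploid-only samples at strong divergence
(population 400, 150 generations): mixing ploidy levels deliberately
injects a secondary clustering axis, and measuring that axis is the job of
the bias experiment, not of the recovery check.

The **rose-like generator** is artifact plumbing for the temporal modules:
two pools whose loci carry two shared alleles (equal frequency in both
pools) and two private alleles each (frequency mass 0.6 per pool), six
decade classes whose pool-B admixture rises linearly 0→1, a pure pool-B
reference sample, 3% missingness, and a rose-like ploidy mix (60% 4x,
30% 2x, 10% 3x). Private alleles at frequency 0.3 give diploid carriage
≈0.5 in their own pool and exactly 0 in the other, so the planted shift
truth is unambiguous, while shared alleles can only violate the 20%/10%
rule through sampling noise (vanishingly unlikely at the default class
sizes of 30). These defaults were fixed once, as a clear planted-truth
design; they emulate the *structure* of a real collection (two diverged
pools, monotone introgression, mixed ploidy, missing data) but not its
shallower differentiation, unequal class sizes, or genotyping artefacts —
so passing tests demonstrate correct machinery, not field-calibrated power.

## Determinism and problem sizes

Every stochastic routine takes an integer seed and restores the caller's
RNG state; a pipeline master seed fans out to fixed per-stage child seeds
so stages can be rerun individually. The test suite runs the full-size
simulation design (1000 individuals) for the variance-split checks with 10
seeds and reduced permutation counts (49–199) — permutations affect only
p-value resolution, never the variance percentages or PhiPT values under
test — and scaled-down configurations (3 subpopulations of 60) for the
mechanical properties. The temporal-recovery checks use 20 seeds of the
rose-like generator at its defaults.

## Known limitations

* `Ae < 1` is possible by construction; consumers expecting a classical
  effective allele number should read the definition first.
* The BIC scan's modal K inherits K-means' limitations: in low-dimensional
  or strongly non-spherical coordinate spaces it can over-split; the
  package runs it on PCA coordinates of binary data, the regime it is
  validated in.
* Membership probabilities are a centroid-distance posterior, not a full
  admixture model; "admixed" flags mean "not confidently assigned", not an
  ancestry estimate.
* The Wright–Fisher substitute for the original coalescent simulator
  matches its design parameters but not its exact mutation-model defaults;
  variance-split results agree at stochastic tolerance only.
* No linkage: loci are simulated and resampled as independent, as in the
  32-autosomal-marker design.
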