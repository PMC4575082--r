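---
title: "Marker-set design and Bayesian structure inference for SSR germplasm collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-set design and Bayesian structure inference for SSR germplasm collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structscan)
```

## The problem

Germplasm collections — here, European pear (*Pyrus communis*) accessions as
the motivating case — are routinely fingerprinted with small panels of
microsatellite (SSR) markers. The same genotype tables are then reused to
infer *genetic structure* with Bayesian admixture models, although panels
optimised for telling accessions apart were never designed for inferring
populations. `structscan` implements the machinery needed to study this gap
quantitatively: fingerprinting statistics and linkage-group-aware marker
ordering, a Structure-type admixture sampler for multi-allelic genotypes of
mixed ploidy, Evanno's ΔK model selection over replicate runs, cross-analysis
stability indices, ploidy-aware F~ST~ with permutation tests, and an F-model
simulator that provides collections with known truth.

## Data model

A `GenotypeTable` stores, for each individual × locus cell, the unordered
multiset of allele sizes (bp) observed there. Individuals are diploid or
triploid; a cell may carry fewer copies than the ploidy (a dosage-ambiguous
or partly missing call) or be empty (missing). Missing data are coded `-9`
on disk, following the Structure convention, and as empty multisets in
memory. Allele labels are raw fragment sizes; no binning is applied, because
sizing is assumed to have happened once upstream. Individual order is
preserved exactly as read and all membership matrices index by it.

Three plain-text dialects are supported: a wide CSV (one row per individual,
one column per allele copy, with the table-wide maximum ploidy determining
the column count — diploids leave the third column at the missing code, so
one rectangular layout serves mixed ploidy), a Structure-style layout (one
row per allele copy, so a triploid occupies three rows), and a
spreadsheet-export layout for unique-genotype supplements (a CSV whose
header row carries locus names and whose cells join alleles with `/`; the
identifier and ploidy columns are configurable because such supplements do
not follow a single fixed layout).

## Fingerprinting statistics

The *banding pattern* of an individual at a locus is the multiset of alleles
it displays; dosage-ambiguous cells count as their observed multiset, which
matches the phenotype-level notion of a pattern. The discrimination power of
a locus is

$$DP = 1 - \sum_{i=1}^{I} p_i^2,$$

where $p_i$ is the frequency of the $i$-th banding pattern among scored
individuals — the probability that two random individuals differ at the
locus. `cumulativeDiscrimination()` counts distinct multilocus profiles
along an ordered locus list, comparing profiles as tuples of per-locus
multisets with missing equal only to missing.

`orderMarkers()` implements the round-robin inclusion rule used when
building panels: loci are ranked by a criterion (DP, or per-locus F~ST~
between inferred populations), but a linkage group already represented is
not drawn from again until every group that still has unused loci has been
represented in the current round. Ties in the criterion break by locus name
ascending; with the published pear-panel statistics this tie-break
reproduces the printed inclusion order (it places CH01d08 before CH03g07 at
DP 0.943). The published order follows the strict rule for positions 1–21;
its last four positions deviate from it (the lowest-DP locus CH04e03, the
only remaining representative of its linkage group, is printed last rather
than completing the second round), and no additional rule reproducing that
tail is stated anywhere we could find — `structscan` follows the strict
rule and documents the divergence. "Least discriminant" selection honours
the same linkage-group constraint as "most", with the criterion negated.

`DP` is computed over whatever table is supplied; the package does not
decide between accession-level and unique-genotype-level input — callers
choose (published panels have used both).

## The admixture sampler

The model is the standard admixture model for multi-allelic codominant
markers: individual $i$ has membership vector $q_i \sim
\mathrm{Dirichlet}(\alpha)$, cluster $k$ has allele frequencies $p_{kl}
\sim \mathrm{Dirichlet}(\lambda)$ at locus $l$, and every observed allele
copy draws a latent source cluster $z \sim \mathrm{Categorical}(q_i)$ and
then its allele from $p_{z l}$. The Gibbs sweep updates $z \mid p, q$, then
$p \mid z$, then $q \mid z$. Mixed ploidy is handled naturally: each
individual contributes as many copies as its ploidy, and missing copies are
simply absent.

Triploid dosage ambiguity (a triploid showing two distinct alleles) is
treated by letting the unobserved copy be missing at random. A genotype
ambiguity model with recessive alleles would instead integrate over the
possible dosages; we chose the missing-at-random approximation because it
keeps the sampler exact and simple, and because the synthetic data used in
all recovery studies carries known dosage, so the approximation's cost is
measurable rather than hidden.

Defaults: α is inferred by a Metropolis step with a uniform prior on
$(0, 10)$ (starting value 0.5), mirroring Structure's default of inferring
the admixture parameter; $\lambda = 1$; the independent-allele-frequency
prior. Inferring α matters for model selection, not just fit: when
individuals are nearly unadmixed, a fixed α = 0.5 forces membership mass
onto spurious extra clusters, flattening the evidence curve so that ΔK can
peak at the major division (K = 2) instead of the true K — in the
model-selection study below, switching from fixed to inferred α turned
occasional K = 2 selections into decisive correct choices (ΔK at the true
K rising from ~100 to ~200–400 while ΔK(2) collapsed to single digits).
A fixed α remains available (`updateAlpha = FALSE`). The
correlated-frequencies prior and linkage model are out of scope. In
*popflag* mode, individuals flagged with a population label are pinned:
their copies always originate from the labelled cluster and their $q$ row
stays at the indicator vector, so they act as pure training members — the
flags are used to anchor groups discovered earlier, not to model migrant
ancestry.

The model evidence per K is estimated from the recorded log-likelihood
trace as $\hat L(K) = \overline{\ln L} - \mathrm{var}(\ln L)/2$, the
harmonic-style estimator conventional for this model family. Replicate runs
at one K are label-aligned to the first run (by seed order) with an exact
optimal assignment on the K×K column squared-distance matrix — the exact
counterpart of greedy CLUMPP-style alignment — and averaged. Evanno's
statistic is then

$$\Delta K = \frac{|\bar L(K+1) - 2\bar L(K) + \bar L(K-1)|}{\mathrm{sd}\,L(K)},$$

defined for interior K with positive sd; an interior K with zero sd yields
a flagged undefined row, which best-K selection skips with a warning. The
default K sweep starts at 1 so that ΔK is defined at K = 2 — analyses that
sweep from 2 upwards cannot evaluate a two-group structure, which published
collections frequently have.

The sampler is written in C++ with a self-contained xoshiro256++ generator
seeded per run, so results are bit-reproducible for a given seed and input
across platforms, and replicate runs are cheap (a 150-individual, 12-locus,
K = 6 run of 2&nbsp;000 + 5&nbsp;000 sweeps takes about a second). The
scaled-down default of 2&nbsp;000 burn-in / 5&nbsp;000 recorded sweeps is
used in all simulation studies; full-scale settings
(7.5·10^4^ / 2·10^5^) remain available through `modelConfig()` for real
collections.

## Stability and differentiation

Two analyses of the same genotypes (different marker sets, criteria, or
seeds) are compared after aligning cluster labels. The per-genotype
discrepancy is the root-mean-square membership difference

$$D_i = \sqrt{\frac{1}{K}\sum_k (q_{ik} - q'_{ik})^2},
\qquad D = 1 - \frac{1}{n}\sum_i D_i.$$

The index is sometimes printed without the radical; both conventions keep
$D \in [0,1]$ and both are implemented (`convention = "squared"`), with RMS
the default since it keeps each $D_i$ on the membership scale. The aligning
permutation minimises $\sum_i D_i$ itself — under the squared convention
that is an assignment problem solved exactly; under the RMS convention the
square root couples columns, so the optimum is found by enumeration for
K ≤ 7 (the practical range) with the assignment solution as fallback.
When two analyses have different K the narrower matrix is zero-padded and
the result flagged; the main use compares analyses at a common K.
`reassignmentReport()` counts the genotypes whose modal cluster changes,
over all genotypes and over those strongly assigned (max membership ≥ 0.8,
the conventional `strong_q` threshold) in the reference analysis.

F~ST~ uses Weir–Cockerham-style variance components generalised to mixed
ploidy: for each locus and allele, an indicator over allele copies is
decomposed by unbalanced nested ANOVA into among-group,
among-individual-within-group and within-individual components, with each
individual contributing its own observed copies. Estimates combine loci as
a ratio of summed components (ratio of averages, never average of ratios).
We did not reproduce any particular program's AMOVA algebra: the questions
the package addresses depend on relative F~ST~ levels, not the estimator
brand, and the generalisation above reduces to the classic diploid
estimator when all individuals are diploid. Negative estimates are reported
as computed (a clamp is available), and significance uses permutation of
individuals between the pair's groups with $p = (1 + \#\{F^{perm} \ge
F^{obs}\})/(1 + n_{perm})$, 10^3^ permutations by default. Per-locus
multi-group F~ST~ doubles as a marker-ranking criterion; whether a
published ranking used multi-group or averaged pairwise values is usually
unstated, so the multi-group form is the default and a pairwise-mean option
is exposed.

## Nested pipeline

`formSubgroups()` implements the device that keeps subgroup composition
fixed across marker sets: the subgroup of cluster c contains *all*
genotypes except those strongly assigned (Q ≥ 0.8) to another cluster, so
weakly assigned genotypes are analysed in several subgroups and any change
in the nested structure is attributable to the loci used.
`finalStructureWithPriors()` then re-infers the whole collection with the
strongly assigned genotypes flagged as prior population members.
Sub-structure exploration recurses one level (K then K~S~), which matches
how such analyses are published; the depth is configurable.

`incrementalMarkerExperiment()` walks an inclusion order from 2 loci to the
full panel, at each prefix running the replicate K sweep, choosing K by ΔK,
summarising memberships (Q~m~, the strongly assigned fraction), computing D
against the previous prefix — at the smaller count's chosen K for both
analyses, since D is only meaningful at a common K — and estimating
pairwise F~ST~ over the strongly assigned genotypes.
`criterionValidationExperiment()` crosses the two sorting criteria with the
two choosing scenarios at configurable set sizes and compares each cell
against the full-panel reference analysis.

One deliberate difference from single-analysis inference: pipeline
experiments hold the admixture parameter α fixed (default 0.5) across the
analyses they compare, while `modelConfig()` infers α by default. The
experiments' whole point is to attribute differences between analyses to
the marker sets used; letting each analysis re-infer α adds a second
moving part, and in the weak-structure regime an inflated α flattens all
memberships so that consecutive analyses look spuriously similar. Holding
the prior fixed isolates the marker effect (`pipelineConfig(updateAlpha =
TRUE)` restores inference if wanted).

The master seed spawns per-run seeds through a fixed counter scheme
(`spawnSeeds`), so adding runs or K values never reshuffles earlier ones
and the whole experiment tree is byte-reproducible. Independent runs are
order-independent by construction, so they may be executed concurrently
without changing results. The package's interface is its exported functions
(driven from R scripts); no shell entry point is shipped.

## The synthetic-data generator

`simulateCollection()` draws, per locus, ancestral allele frequencies from
a symmetric Dirichlet and population frequencies from
$\mathrm{Dirichlet}\!\left(p_{anc}(1-F_k)/F_k\right)$ — the F-model, chosen
because it matches the correlated-frequency worldview of Structure-type
samplers and because its drift parameter F directly tunes realized
differentiation: the generator's F ≈ 0.10 emulates a major division of the
germplasm, ≈ 0.06 a moderate sub-structure and ≈ 0.03 a weak but
significant one, the three regimes germplasm studies report. Individuals
draw each allele copy from the q-mixture of population frequencies;
admixed individuals (optional) draw q from a symmetric Dirichlet. Clonal
duplicates repeat a founder's complete genotype (and triploidy) under a new
id; triploids carry three copies; per-cell missingness erases emitted calls
while the truth sidecar keeps the dosage-complete genotype, true q, true
population frequencies and the clone map. Allele labels are emitted as
plausible fragment sizes (start + 2·index) for format realism.

What the generator does *not* emulate: stepwise mutation structure among
allele sizes, linkage disequilibrium along chromosomes, pedigree
relationships, and genotyping artefacts (stutter, null alleles, allele
drop-out beyond random missingness). Recovery results on these collections
therefore show that the inference machinery is correct under the model's
own assumptions, not that any particular real collection satisfies them.

## Study sizes and numerical choices

The simulation studies exercised by the test suite and by
`scripts/acceptance.R` use these sizes, chosen as the smallest that give
stable, interpretable outcomes:

* **Model selection / assignment recovery** — K~true~ = 3, F = 0.15, 150
  diploids, 12 loci, 10 alleles per locus; K swept 1–6 with 10 runs per K
  at 2&nbsp;000 + 5&nbsp;000 sweeps; 10 replicate collections. ΔK selects
  K = 3 in the large majority of replicates (occasionally the major split
  at K = 2 wins, a known behaviour of the ΔK heuristic when several
  partitions are strong), and mean modal-assignment accuracy after
  alignment exceeds 0.9.
* **F~ST~ recovery** — two populations, F = 0.10, 50 + 50 diploids, 15
  loci; 20 replicates; the estimator's mean tracks the realized
  variance-component F~ST~ of the generator truth to well within ±0.02.
  Null calibration: 200 random splits of a single population, 200
  permutations each; the p ≤ 0.05 rate stays at or below its nominal
  level within binomial error.
* **Stability trend** — K~true~ = 2, F = 0.03 (the weak regime), 120
  diploids, 15 loci, fixed K = 2, 4 runs per prefix; 5 replicate
  collections. D between consecutive marker counts averaged over the
  10–14-locus range exceeds the 3–7-locus average in every replicate.

Numerical details worth knowing: Dirichlet draws guard against all-zero
gamma vectors at tiny concentrations; the log-likelihood floors
zero-probability alleles at a configurable epsilon instead of returning
−∞ (relevant when evaluating a state against a table containing alleles
the state has never seen); monomorphic loci score a per-locus F~ST~ of 0
(their components are identically zero); and loci with fewer than two
scored individuals in a group are dropped from F~ST~ with a warning rather
than failing the analysis.

## Known limitations

* The dosage-ambiguity approximation treats unobserved triploid copies as
  missing at random; collections with many triploids and strong dosage
  information will lose some power relative to a full genotype-ambiguity
  model.
* ΔK is undefined at the sweep boundaries and degenerates when replicate
  runs agree exactly (sd = 0); the implementation flags rather than hides
  these rows.
* The F-model generator and the sampler share a worldview; recovery
  studies are therefore internal-consistency checks, deliberately so.
* With K > 7 the RMS-optimal stability alignment falls back to the
  squared-loss assignment, which can differ in rare, nearly-tied cases.
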