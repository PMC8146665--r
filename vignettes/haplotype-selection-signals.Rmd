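---
title: "Haplotype-level selection signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-level selection signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

haplosignal asks one question of phased haplotypes around a candidate gene:
is the haplotype structure there shaped by recent positive selection, or by
demography alone? It answers it with four complementary views — amino-acid
changing variants and their cohort frequencies, Hamming-distance haplotype
clusters, signed linkage disequilibrium, median-joining networks — and with
extended haplotype homozygosity (EHH) decay as the selection-sensitive
statistic, plus a forward-time simulator that generates cohorts where the
truth is known.

## Coordinates and containers

All positions are 1-based as in VCF; every interval is half-open
`[start, end)`, so a gene printed with endpoints 6,928,858 and 6,930,547
spans exactly 1,689 bases, a site at `start` is inside and a site at `end`
is not. Phased diploids contribute exactly two haplotype columns each to
the binary allele matrix (`HaplotypeSet`); only biallelic SNPs are kept,
and records that are multiallelic or carry any unphased or missing genotype
are skipped with a logged count, never split or imputed — partial
imputation would silently change every downstream statistic. Cohorts are
population-by-species strata throughout, because sibling species sampled in
one country behave as distinct gene pools.

Offsets to downstream genes take an explicit anchor argument. "x bases
downstream of the gene" is ambiguous between the gene's own end and the end
of an enclosing gene cluster, and the two readings differ by tens of
kilobases; making the anchor a parameter keeps both reproducible.

## Variant effects and the high-frequency filter

The effect annotator handles the single-transcript case: CDS intervals on
either strand, codon lookup under the standard genetic code, labels in the
usual `I359V` style (reference amino acid, codon number, alternate). On the
minus strand both alleles are complemented and positions mapped through the
reversed interval stack. The annotator refuses a site whose stated
reference allele contradicts the gene model's coding sequence — that is a
data-integrity failure, not something to paper over.

Cohort allele frequencies are haplotype counts over cohort haplotype
totals. The pooled `All` column is haplotype-weighted (total alternate
count over total haplotypes), not the mean of cohort frequencies; a
cohort-mean alternative is available behind a flag since published tables
do not always say which was used. The high-frequency filter keeps a variant
when it strictly exceeds the threshold (default 5%) in at least one cohort;
the strict inequality matches the usual "> 5%" phrasing, and the boundary
case is pinned by a test.

## Haplotype clustering

Distances between haplotypes are Hamming counts over the biallelic sites of
a region — SNP units, not per-base rates, so a "seven SNP" cut threshold is
applied directly. Clustering is agglomerative; single linkage is the
default because its flat clusters at cut height *h* are exactly the
connected components of the graph joining pairs at distance ≤ *h*, a
semantics that is easy to reason about and to verify against an independent
graph-components oracle. Complete and average linkage are selectable.
Clusters at or above 1% frequency are named `C1, C2, ...` by decreasing
size (ties broken by lowest member index, for reproducibility); everything
else is wild type (`wt`). One global dendrogram is cut, not one per
population, so cluster labels are comparable across cohorts.

## Linkage disequilibrium

Signed Lewontin's D′ is computed from phased gametes: `D = pAB − pA·pB`,
normalised by `min(pA(1−pB), (1−pA)pB)` when `D > 0` and by
`min(pA·pB, (1−pA)(1−pB))` when `D < 0`. The sign is kept — +1 means the
alternate alleles travel together as far as their frequencies allow, −1
that they are never seen on one haplotype. A site monomorphic within the
analysed cohort leaves D′ *undefined*, reported as `NA`, never as 0:
in stratified analyses (the package provides per-population D′ precisely
because pooled associations can be artefacts of structure) conflating
"undefined" with "no association" corrupts the interpretation.

## Median-joining networks

The network module implements the Bandelt–Forster–Röhl construction for
binary haplotypes. The spanning phase keeps every edge that belongs to some
minimum spanning tree, relaxed by a parameter ε (default 0, the sparsest
network); the criterion used is that an edge's weight not exceed the
minimax-path weight between its endpoints by more than ε. The median phase
scans connected triplets in lexicographic order and adds the per-site
majority consensus as an inferred node whenever it strictly reduces the
cost of connecting the triplet; inserted medians are deduplicated and
sorted, so reruns are bit-identical. After convergence, inferred nodes of
degree < 3 are obsolete and removed iteratively. Components are then taken
after dropping edges heavier than a maximum edge distance (default 2 SNPs),
so each component contains only closely related haplotypes.

Concordance between network components and hierarchical clusters is
plurality matching: each component takes the cluster label held by the
plurality of its haplotypes (ties to the larger cluster, then
alphabetical), and concordance is the fraction of haplotypes whose matched
label equals their cluster label. A greedy one-to-one variant is available.
The metric is declared rather than asserted to be the one used in any
particular published figure — published concordance percentages rarely
state their formula.

## EHH

A core region defines core-haplotype groups: haplotypes identical across
every core site. EHH of a group at distance *x* is the probability that two
randomly drawn members are identical over the whole stretch from the core
edge to *x*:

$$EHH(x) = \frac{\sum_s \binom{e_s}{2}}{\binom{c}{2}}$$

with `c` the group size and `e_s` the sizes of the identity subgroups at
reach *x*. Identity is cumulative from the core edge (the classic
definition), so the curve starts at 1 and never increases; it is evaluated
at polymorphic site positions (constant between them, since only variant
sites are observed), truncated at the first zero or at a maximum reach
(default 200 kb). Groups of one are skipped — `C(1,2) = 0` leaves EHH
undefined. The decay area (trapezoidal integral over genomic distance, in
bp) summarises a curve; left and right areas are summed.

## The simulator

The generator is a forward-time Wright–Fisher model on a fixed lattice of
SNP positions with genomic coordinates — deliberately not a coalescent:
it is simple, exactly reproducible, and sufficient to create LD decay with
distance, drift, bottlenecks and sweeps. Each offspring haplotype is a
crossover mosaic of one parent's two haplotypes (crossover probability
`1 − exp(−r·gap)` per inter-site gap), with per-site mutation flips, and
parents drawn with fitness weight `(1+s)` per focal-allele copy. Founders
are drawn from a neutral-like site frequency spectrum (derived-allele count
k with probability ∝ 1/k). Demes are simulated independently (no
migration) and pooled over a shared site table.

Default study conditions, stated once and used by the tests and the
acceptance script: 200 diploids, 20 founders, 144 lattice sites (60 per
200 kb flank, 24 inside the 1,689 bp gene), `mu = 1e-5` per site and
`r = 1e-6` per base per generation, 12 selected generations. The rates are
scaled up relative to per-generation biological values to compensate for
the compressed timescale and small cohort a desk-scale simulation can
afford; what matters for the statistics is the product of rate and time.

**Why a burn-in.** A cohort founded a handful of generations ago is
uniformly young: every rare haplotype class is a recent clade with
near-perfect flanking identity, and sweep-like EHH is everywhere. Real
cohorts are old; a sweep stands out because the swept lineage is
anomalously young *for its frequency*. The two-phase driver therefore runs
a 200-generation neutral burn-in and only then plants the focal allele and
applies selection. Without this the planted-sweep recovery experiment is
uninformative (we measured it: the carrier group essentially never ranks
first on raw decay area in a young cohort).

**Why standing-class planting, and why at 6%.** The focal allele is
planted on every copy of an existing core-haplotype class near 6%
frequency, and selection runs for 12 generations. Under neutrality the
carrier class is then an ordinary standing class — exchangeable with any
other class of its size — which pins the null of the recovery comparison
at one half. Two failure modes shaped these numbers. A de novo single-copy
mode exists, but a *surviving* new mutant is conditioned to be young and
wins well over half its comparisons even without selection. The same
conditioning bias reappears, more subtly, whenever the planted class is
rare enough that "still above the 1% group floor at the end" is a
selective event: at this cohort size drift is strong, and calibration runs
showed neutral win rates of 0.60–0.65 for 2–4% planting over 20
generations, against 0.50 (150 replicates) for 6% planting over 12
generations, where the conditioning rejects almost nothing. Conversely,
planting too common (10%) lets the sweep overrun the cohort and consume
the very standing classes the comparison needs. The 6%/12-generation point
keeps the null exactly calibrated while leaving a strong sweep effect
(measured 0.83 against a 0.50 null over calibration replicates).

**The recovery statistic.** Per replicate, the carrier core group's decay
area is compared with the *size-matched* wild-type group. Size matching is
essential: EHH area falls with group size under neutrality (small classes
are young), so "largest area among all groups" is dominated by the smallest
clades and is not frequency-fair — under a sweep the (large) carrier group
practically never ranks first on raw area, and under neutrality the rank-1
probability is roughly one over the number of groups, not one half. Both
win definitions are computed and reported; the matched one is the
declared recovery criterion (sweep arm ≈ 0.83, neutral arm ≈ 0.5 at the
packaged conditions and calibration seeds).

**The bottleneck confound.** A severe bottleneck (5% of the cohort for 15
generations, under the defaults) inflates EHH without selection. The
discriminating summary is the *haplotype-weighted* mean area — the expected
decay area of the group a random haplotype belongs to. A bottleneck
concentrates haplotypes into few large recently-coalesced groups, raising
the per-haplotype area sharply, while the per-group mean is diluted by the
small young clades present in every cohort (measured: complete separation
over 16 calibration pairs on the weighted summary, and no separation on the
unweighted one).

Conditioning: replicates whose focal allele is lost (or fixes) rerun the
selection phase with the next seed, reusing the burn-in; every rerun is
logged. Survival bounds are `[0.01, 0.995]` final frequency — the lower
bound is the 1% core-group floor below which the carrier group would not be
formed anyway.

## What the simulations do and do not show

The generator reproduces the *mechanisms* the analysis relies on — LD decay
with distance, allele-frequency drift, founder structure, sweep-elevated
haplotype homozygosity, bottleneck-compressed genealogies — at deliberately
small scale (hundreds of haplotypes, 144 sites, tens of generations).
It does not emulate real sample sizes or site densities, gene conversion,
migration between demes, overlapping generations, or mutation models beyond
symmetric flips; passing tests demonstrate that the statistics recover
planted signals under the model's assumptions, not that any particular
field cohort is or is not under selection.

## Numerical choices and degenerate inputs

* Dendrogram cut heights are inclusive (`<= h`), matching the
  threshold-graph semantics; distances are integers so boundary behaviour
  is exact.
* Monomorphic sites: D′ undefined (`NA` or error, caller's choice); the
  frequency table simply reports 0 or 1; the annotator does not care.
* Tie-breaks are deterministic everywhere: cluster naming by size then
  lowest member index, median insertion in lexicographic order, concordance
  ties to the larger cluster then alphabetical, size-matching ties to the
  first (largest) group. Reruns of any pipeline are bit-identical, manifest
  hashes included.
* Empty regions: restricting to a region with no sites yields a valid
  zero-site haplotype set; distance and EHH computations on it raise
  explicit validation errors rather than returning vacuous values.
* The planted gene model draws codons from the 61 sense codons, so internal
  stops are impossible by construction; when lattice sites force reference
  bases, any codon those constraints turn into a stop is repaired at an
  unconstrained position (and it is an error if all three are constrained).

## Problem sizes used by the packaged experiments

The recovery experiment runs 20 sweep and 200 neutral replicates of the
(200-diploid, 144-site, 200 + 12 generation) configuration; the bottleneck
experiment runs 20 pairs of (100-diploid, 30-generation) cohorts; the
oracle cross-checks run on 50–100 random instances of up to 50 haplotypes
by 200 sites. These sizes were chosen so the whole suite runs comfortably
on a laptop while leaving the Monte-Carlo margins interpretable.

## Known limitations

* Single-transcript gene models only; no splice variants or UTR effects.
* The median-joining search enumerates triplets, which is fine for the
  hundreds of distinct haplotypes a gene-sized region yields but not for
  chromosome-scale inputs.
* EHH is reported raw, as decay curves and areas; no cross-population
  standardisation (iHS/XP-EHH) is attempted.
* The simulator's selection model is a single additive-fitness biallelic
  site; no dominance, epistasis or fluctuating selection.
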