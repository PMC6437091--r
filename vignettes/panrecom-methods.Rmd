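---
title: "Methods: pan-genome structure and recombination bias with panrecom"
author: "panrecom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome structure and recombination bias with panrecom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panrecom)
```

# What the package computes

`panrecom` characterizes gene-content variation within a bacterial species
and the pattern of homologous recombination that helps generate it. Its
inputs are the standard artifacts of a pan-genome workflow — a gene
presence/absence matrix from an ortholog-clustering tool, per-family
nucleotide alignments, 12-column tabular sequence-search output, and
recombination-event tables from a mosaicism scanner — and its outputs are
the classical summary statistics of that literature: category counts and
accumulation curves, the Heaps' law decay parameter, genomic fluidity,
ortholog-mean average nucleotide identity (ANI), the pairwise homoplasy
index (PHI) with its permutation test, donor assignments and recombination
highways, fragment-size statistics, and biosynthetic gene cluster (BGC)
presence calls.

# Pan-genome composition and openness

## Occupancy classification

A family present in $k$ of $N$ genomes is classified by its occupancy
fraction $k/N$: *core* at $\ge 0.99$, *soft core* in $[0.95, 0.99)$,
*shell* in $[0.15, 0.95)$ and *cloud* below $0.15$. All comparisons are
performed in exact rational arithmetic ($k \cdot 10^6 \ge t \cdot 10^6
\cdot N$ on integers), never on floats: boundary cases such as $19/21$
against $0.90$ or $19/20$ against $0.95$ must be decided deterministically.
At $N = 32$ the core rule admits only $32/32$; $31/32$ (96.9%) is soft
core. Figure captions in the field sometimes use the looser "present in at
least $N-1$ strains" reading for the core *curve*; the accumulation
function exposes this as `core_min_count` while the classifier keeps the
single canonical 99% rule.

## Accumulation curves and Heaps' law

`accumulation_curves()` adds genomes in random order and records, at each
step $g$, the pan-genome size, the strict-intersection core size, the
number of new families contributed by the $g$-th genome, and the number of
families seen exactly once. `fit_heaps()` models
$\text{new}(g) = \kappa\, g^{-\alpha}$ and fits $(\kappa, \alpha)$ by
nonlinear least squares on the raw counts pooled over all permutations for
$g \ge 2$. Fitting on the raw scale (with a log–log regression on per-$g$
means used only to initialize) is deliberate: late in the curve many
permutations contribute zero new genes, which a log-scale fit cannot
accommodate. $\alpha < 1$ is reported as an open pan-genome, $\alpha > 1$
as closed, with a $10^{-9}$ tolerance band labelled `boundary`. A matrix
of identical genomes yields no new genes beyond $g = 1$; that degenerate
case returns verdict `closed` with $\alpha = \infty$ and a warning rather
than an error.

## Genomic fluidity

For genomes $k, l$ with family sets of sizes $M_k, M_l$ and unique counts
$U_k, U_l$, the pair fluidity is $\varphi_{kl} = (U_k + U_l)/(M_k + M_l)$,
and $\varphi$ is the mean over pairs — 0 for identical gene content, 1 for
disjoint. `all_pairs` mode uses all $N(N-1)/2$ pairs; `subsample` mode
draws pairs uniformly *with replacement*, which keeps the estimator an
unbiased mean with a simple variance. The sample variance of the pair
values is always reported, since the spread across pairs is itself
informative about heterogeneity.

# Average nucleotide identity

The ANI of a genome pair is defined here literally as the mean percent
identity over all ortholog families in which both genomes have a sequence
(ortholog-mean ANI, not fragment-mapping ANI). Identities come from global
end-to-end alignment (match $+1$, mismatch $-1$, gap open $-2$, gap extend
$-1$); identity is matches over alignment columns, excluding
terminal-overhang gap columns so that ragged gene boundaries in draft
assemblies do not depress identity, while internal gaps count as
non-matches and `N` matches nothing. The family mean is unweighted by
default — the simplest reading of "average over shared genes" — with a
`length_weighted` switch. Each pair is computed once and mirrored, so the
matrix is symmetric by construction; pairs sharing fewer than `min_shared`
families are masked as `NA`. The conventional 95% species cutoff is a
reporting flag (`below_cutoff`), not a filter, and the threshold is a
parameter so the looser inter-species cutoffs can be explored.

# The PHI recombination test

## Statistic

A column is parsimony-informative if, ignoring gaps and `N`, it has at
least two states each carried by at least two sequences. For two sites the
*refined incompatibility* is the parsimony lower bound on extra mutations:
with vertices the observed states at each site (after pairwise deletion of
sequences gapped at either column) and one edge per distinct observed
joint state pair, the score is $E - V + C$. For binary sites this reduces
to the four-gamete test. $\Phi_w$ is the mean score over all unordered
informative-site pairs at most $w$ alignment columns apart. The window is
measured in original alignment columns (not informative-site rank) with
default $w = 100$; both the width and the fallback (all pairs, with a
warning, when no pair qualifies) are explicit. Implementation note:
binary–binary pairs — the overwhelming majority — are scored in bulk from
four indicator cross-products, so the score matrix over hundreds of
informative sites costs a few matrix multiplications; only pairs involving
a site with three or more observed states take the general
union–find path. The same scores also back an exhaustive-parsimony
cross-check in the test suite (minimum over all unrooted topologies of the
two-site Fitch score), which they must reproduce exactly.

## Permutation test

Permuting the *positions* of the informative sites leaves all pairwise
scores unchanged and only reshuffles which pairs fall inside the window,
so each permutation is a cheap re-indexing of the precomputed score
matrix. The test is one-sided toward *small* observed $\Phi_w$: under
clonality incompatibility is distance-independent, while recombination
leaves nearby pairs relatively compatible and lets distant pairs
accumulate conflicting histories. The p-value uses the add-one estimator
$p = (1 + b)/(1 + m)$, which is a valid permutation p-value and never
reports an exact zero; a run reporting "p = 0.0" should be read as
$p < 1/(1+m)$.

# Recombination post-processing

Donor assignment filters an event's hits to fragment coverage
$\ge 50\%$ (alignment length over fragment length, capped at 1 — the only
coverage measure available from 12-column output) and identity
$\ge 99\%$, then takes the maximum bit score. An exact bit-score tie
across distinct genomes is reported `ambiguous` with the lexicographically
smallest candidate recorded, never silently broken; no survivor is
`unresolved`. Assignment is deliberately invariant to hit order.

The donor–recipient network counts assigned events per *directed* pair.
The highway rule follows the "at least one standard deviation above the
pairwise average" convention: mean and sample ($n-1$) SD are computed over
pairs with at least one observed event (configurable in principle to all
ordered pairs; the observed-pair population is the default because an
average of events per pair is most naturally taken over pairs that
recombine at all). When every count is equal the SD is zero and nothing is
"above the average", so ties are not highways; a single edge likewise
yields none.

Fragment-size summaries use the lower-middle median for even counts so the
reported median is an observed integer length (`median_mode = "midpoint"`
restores the textbook average), the fraction of events strictly below the
500-nt micro/macro-recombination cutoff, and the exponential
maximum-likelihood rate $1/\bar{x}$.

# BGC presence screening

A cluster gene counts as hit in a genome if any of its protein hits
reaches the e-value ceiling ($10^{-10}$ by default); duplicate hits count
once, and calls are independent of hit order. The cluster is present when
the hit fraction reaches 90%, compared as exact rationals: for the 21-gene
oxytetracycline cluster the minimum is therefore 19 genes
($19/21 = 0.9048$), and $18/21$ is absent. Only the e-value criterion is
applied by default because that is the canonical screening rule; an
optional identity floor exists but is off. Hits anywhere in the genome
count — the screen does not require the genes to be co-located, which is a
known simplification relative to true cluster prediction.

# The synthetic-data generators

The generators exist so that every stage is exercisable, and every
calibration claim testable, without any external data. They are pure
functions of their arguments and seed.

## Presence/absence matrices

`simulate_pangenome()` must produce matrices whose openness is *tunable
and recoverable*: fitting Heaps' law to accumulation curves of the output
should return the planted $\alpha$. A construction that simply hands the
$g$-th *constructed* genome $\kappa g^{-\alpha}$ brand-new families, with
earlier accessory families retained with some fixed probability, does not
have this property: once genome order is randomized, the first-seen counts
no longer follow the planted decay for any retention value (the fitted
exponent is strongly compressed toward a retention-dependent constant).
The default `"spectrum"` method therefore works directly in the space
where accumulation lives: for a family carried by a uniform random subset
of $c$ genomes, the probability that its first carrier sits at position
$g$ of a random ordering is $\binom{N-g}{c-1}/\binom{N}{c}$, so the
expected new-family curve is linear in the occupancy spectrum
$(n_1, \dots, n_N)$, and the spectrum reproducing
$\kappa g^{-\alpha}$ is found by non-negative least squares (residuals at
the default scales are below $10^{-6}$). Parameter recovery then holds to
about $\pm 0.01$ at $N = 30$, $\kappa = 500$, 20 permutations — the
scale at which the recovery property is asserted (within $\pm 0.1$) in the
tests. The sequential-retention construction remains available as
`method = "sequential"`; its realized new-family counts in construction
order equal `round(kappa * g^(-alpha))` exactly, which is also tested.

`make_fixture_matrix()` builds a matrix with an exact occupancy
composition (so printed compositions such as 1,945 core of 22,114 families
across 32 genomes can be reproduced as fixtures), assigning carriers by
seeded draw; `summarize_pangenome()` on its output returns the request
identically.

## Alignments

Clonal alignments draw a random coalescent genealogy (`ape::rcoal`),
rescale it so the mean pairwise distance equals the requested divergence,
and scatter Poisson numbers of substitutions along branches at uniform
positions; every site then shares one history and homoplasy arises only
from recurrent mutation, which is exactly the null the PHI permutation
test assumes. Mosaic alignments consist of two internally uniform groups
at the requested divergence, with single-recipient segment transfers of
geometric length between group backgrounds; overlapping transfers into
different recipients create the incompatibility-at-distance signal the
test detects. The default divergence of 0.05 is used consistently for
both the null and the alternative: it is a realistic deep within-species
divergence and produces enough recurrent mutation (of order 30 doubly-hit
sites at $n = 20$, $L = 2000$) for the permutation null to have a
reasonably smooth distribution. What these generators deliberately omit:
rate heterogeneity across sites, indel processes, within-group diversity
in the mosaic mode, and gene conversion tracts shorter than the alignment;
calibration results on them say nothing about model misspecification on
real data, only that the statistic and test behave correctly when their
assumptions hold.

## Recombination scenarios

`simulate_recomb_scenario()` draws event counts per directed genome pair
as Poisson with planted rate multipliers, fragment lengths as geometric —
the discrete analogue of the approximately exponential size distributions
reported for real recombination fragments (note a geometric with mean $m$
has median $\approx m \ln 2$, not $m$) — and emits, per event, a hit
table in which the true donor has the top bit score at full coverage and
the stated identity, with decoy hits at 90–98.5% identity and partial
coverage. Decoys sit below the 99% identity filter by design: the planted
scenario verifies the *bookkeeping* (filtering, top-bit-score selection,
network counting, highway thresholding) rather than the discriminative
power of sequence search, which is out of scope.

# Problem sizes and numerical choices

The test suite asserts, among others: type-I error of the PHI test within
$[0.01, 0.10]$ at nominal 0.05 over 200 clonal alignments ($n = 20$,
$L = 2000$, 99 permutations each) and power $\ge 0.8$ over 50 mosaic
alignments (10 transfers of mean 300 nt); Heaps recovery within
$\pm 0.1$ for $\alpha \in \{0.6, 0.9, 1.2\}$; exact recovery of a planted
$10\times$ highway over a 20-pair background at Poisson mean 3; and
$\ge 95\%$ planted-donor recovery. These sizes were chosen as the
smallest at which the binomial noise of the calibration estimates is
comfortably inside the asserted bands.

Seeds are explicit arguments everywhere randomness occurs and are recorded
in results and pipeline reports. Permutation p-values use the add-one
estimator; occupancy and hit-fraction thresholds are compared as exact
rationals; the Heaps fit bounds $\kappa, \alpha > 0$ and reports its
residual sum of squares so competing fits can be compared.

# Known limitations

* Ortholog-mean ANI is not comparable in absolute value to
  fragment-mapping ANI estimators; only the method contract (mean over
  shared orthologs, global alignment) is implemented.
* The PHI implementation covers the windowed homoplasy statistic and its
  permutation test only, not companion statistics of the original
  program.
* Donor assignment resolves to whatever granularity the subject-id parsing
  yields (genome by default); it does not re-infer lineages.
* The BGC screen is presence-by-homology genome-wide; it is not a cluster
  predictor and does not check gene adjacency.
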