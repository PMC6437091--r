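# panrecom

Pan-genome openness, fluidity and recombination bias in bacterial
populations.

Closely related bacterial strains of one species can differ enormously in
gene content, and part of that variation is created by homologous
recombination that is itself biased — some strains donate or receive DNA
far more often than others, and some pairs are linked by "highways" of
exchange. `panrecom` packages the statistics used to quantify both sides
of this picture for a set of conspecific genomes (for example, a set of
RefSeq assemblies of an antibiotic-producing *Streptomyces* species),
starting from the standard artifacts of a pan-genome workflow rather than
from raw reads:

* **Pan-genome structure** — reads Roary-style `gene_presence_absence.csv`
  / `.Rtab` matrices; classifies families into core (occupancy ≥ 99%),
  soft core (95–99%), shell (15–95%) and cloud (< 15%) with exact rational
  boundary handling; builds gene accumulation curves over random genome
  orderings; fits Heaps' law `new(g) = κ·g^(−α)` by nonlinear least
  squares (α < 1 ⇒ open pan-genome); and computes genomic fluidity
  `φ_kl = (U_k + U_l)/(M_k + M_l)` averaged over genome pairs.
* **ANI** — ortholog-mean average nucleotide identity from global
  alignments of shared gene families, with the conventional 95%
  same-species cutoff as a per-pair flag.
* **Recombination detection** — the pairwise homoplasy index Φ_w (mean
  refined-incompatibility score, `E − V + C`, over informative-site pairs
  within a column window) with a one-sided site-permutation test.
* **Recombination post-processing** — consumes recent/ancestral event
  tables and 12-column BLAST tabular hit tables; assigns donors (top bit
  score among hits with ≥ 50% fragment coverage and ≥ 99% identity);
  builds the directed donor→recipient network; flags highways (pairs at
  least one standard deviation above the mean event count); counts events
  per gene; and summarizes fragment sizes (median, exponential MLE rate).
* **BGC screening** — presence calls for a defined biosynthetic gene
  cluster (e.g., the 21-gene oxytetracycline cluster) from protein hit
  tables: present iff ≥ 90% of cluster genes have a hit at e ≤ 1e−10,
  compared as exact rationals (19/21 is present, 18/21 is not).
* **Synthetic data** — seeded generators for presence/absence matrices
  with recoverable planted openness, clonal/mosaic alignments for
  calibrating the PHI test, and recombination scenarios with planted
  highways and donors, so the whole pipeline runs and is tested without
  any downloads.

## Worked example

Everything below runs offline on simulated data:

```r
library(panrecom)

pm <- simulate_pangenome(n_genomes = 30, kappa = 500, alpha = 0.83,
                         core_size = 1500, seed = 42)
summarize_pangenome(pm)
#> Pan-genome of 4100 gene families
#>   core         1512  (36.9%)
#>   soft core      12  (core+soft 37.2%)
#>   shell         934
#>   cloud        1642  (singletons 891, 21.7%)
#>   core fraction per genome: 0.74-0.77

fit_heaps(accumulation_curves(pm, n_permutations = 100, seed = 42))
#> Heaps' law fit: new(g) = 504.4 * g^(-0.834)
#>   alpha = 0.834 -> open pan-genome (2900 points, RSS 198132.8)

genomic_fluidity(pm)
#> Genomic fluidity phi = 0.1406 (all_pairs, 435 pairs, var 2e-05)

aln <- simulate_alignment(20, 2000, divergence = 0.05, n_events = 10,
                          seed = 42)
phi_test(aln, w = 100, n_permutations = 999, seed = 42)
#> PHI test: Phi_w = 0.0194 (w = 100, 99 informative sites, 463 pairs)
#>   p = 0.001 from 999 permutations (seed 42)
```

The Heaps fit recovers the planted decay parameter (α̂ = 0.834 against a
planted 0.83, an open pan-genome), the fluidity says that on average ~14%
of two genomes' combined gene families are unique to one of them, and the
mosaic alignment is correctly declared recombinant (small Φ_w, p ≈ 0.001:
near pairs of sites are more compatible than the permutation null
expects).

A `panrecom` command-line dispatcher over the same functions is installed
under `exec/` (subcommands `run`, `pangenome`, `fluidity`, `phi`,
`recomb`, `bgc`, `convert`); `run_pipeline()` orchestrates whole analyses
from a YAML config with pre-flight input validation and per-stage JSON
reports.

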