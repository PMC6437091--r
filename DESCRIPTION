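Package: panrecom
Title: Pan-Genome Openness, Fluidity and Recombination Bias in Bacterial
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize the structure of a bacterial pan-genome
    and the pattern of homologous recombination within a species. Reads
    Roary-style gene presence/absence matrices, per-family alignments,
    BLAST tabular hit tables and recombination-event tables; classifies
    gene families into core/soft-core/shell/cloud, builds gene
    accumulation curves, fits Heaps' law to estimate pan-genome openness,
    and computes genomic fluidity; calculates ortholog-based average
    nucleotide identity with the 95 percent species cutoff; implements the
    pairwise homoplasy index (PHI) permutation test for recombination;
    post-processes inferred recombination events into donor assignments,
    donor-recipient networks with highway detection, per-gene counts and
    fragment-size statistics; and calls presence of biosynthetic gene
    clusters from protein hit tables. A synthetic-data module generates
    presence/absence matrices with tunable openness, clonal and mosaic
    alignments, and recombination scenarios with planted donor biases so
    that every stage can be exercised without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
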