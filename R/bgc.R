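# Biosynthetic gene cluster presence calls from protein hit tables.

#' Define a biosynthetic gene cluster
#'
#' @param name Cluster name (e.g., `"oxytetracycline"`).
#' @param gene_ids Ordered character vector of unique gene identifiers
#'   making up the cluster (e.g., the 21 oxytetracycline genes).
#' @return An object of class `bgc_definition`.
#' @export
bgc_definition <- function(name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 1L) param_error("a BGC needs at least one gene")
  if (anyDuplicated(gene_ids))
    param_error("duplicate gene id(s) in BGC ", name)
  structure(list(name = name, gene_ids = gene_ids), class = "bgc_definition")
}

#' Read a BGC definition from a TSV file
#'
#' One gene id per line, optional tab-separated description column;
#' `#`-comment lines skipped.
#'
#' @param path Path to the definition file.
#' @param name Cluster name; defaults to the file name without extension.
#' @return A [bgc_definition()].
#' @export
read_bgc_definition <- function(path, name = NULL) {
  lines <- read_body_lines(path)
  if (length(lines) == 0L) format_error("no genes in ", path)
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  bgc_definition(name %||% tools::file_path_sans_ext(basename(path)),
                 trimws(ids))
}

#' Call presence of a BGC in each genome
#'
#' A cluster gene counts as hit in a genome iff at least one of its hits
#' in that genome has `evalue <= max_evalue` (duplicate hits on the same
#' gene count once). The cluster is called present when the fraction of
#' cluster genes hit reaches `min_fraction`; the comparison is made in
#' exact rational arithmetic, so with 21 genes and the default 90% rule
#' the minimum is 19 hits (19/21 = 0.9048 is present, 18/21 is absent).
#'
#' @param hits A `blast_hits` data frame; `query_id` identifies the BGC
#'   gene and `subject_genome` the genome searched (see
#'   [read_blast_tab()]).
#' @param bgc A [bgc_definition()].
#' @param max_evalue Maximum qualifying e-value (default `1e-10`).
#' @param min_fraction Minimum fraction of cluster genes hit (default
#'   0.90).
#' @param roster Optional character vector of all genomes screened;
#'   genomes without any hit then receive absent calls.
#' @param min_identity Optional percent-identity floor on qualifying hits
#'   (off by default; only the e-value criterion applies).
#' @return A data frame of class `bgc_calls`, one row per genome:
#'   `genome`, `bgc`, `n_genes_hit`, `fraction_hit`, `present`.
#' @export
call_bgc_presence <- function(hits, bgc, max_evalue = 1e-10,
                              min_fraction = 0.9, roster = NULL,
                              min_identity = NULL) {
  stopifnot(inherits(bgc, "bgc_definition"))
  k <- length(bgc$gene_ids)
  qual <- hits$evalue <= max_evalue & hits$query_id %in% bgc$gene_ids
  if (!is.null(min_identity))
    qual <- qual & hits$percent_identity >= min_identity
  hq <- hits[qual, , drop = FALSE]
  genomes <- sort(unique(c(hits$subject_genome, roster)))
  if (length(genomes) == 0L)
    param_error("no genomes in hit table or roster")
  n_hit <- vapply(genomes, function(g) {
    length(unique(hq$query_id[hq$subject_genome == g]))
  }, integer(1L))
  present <- frac_ge(n_hit, k, min_fraction)
  out <- data.frame(genome = genomes, bgc = bgc$name,
                    n_genes_hit = n_hit, fraction_hit = n_hit / k,
                    present = present, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("bgc_calls", "data.frame")
  out
}
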