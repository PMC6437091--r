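# Ortholog-based average nucleotide identity.

# Scoring for the global alignment behind pairwise_identity: match +1,
# mismatch -1, N matches nothing. Gap costs are given to pairwiseAlignment
# as positive penalties (a length-k gap costs open + k * extend).
.ani_submat <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5L, 5L, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
})

#' Percent identity of two sequences under global alignment
#'
#' Aligns two nucleotide sequences end to end (Needleman-Wunsch; match +1,
#' mismatch -1, gap open -2, gap extend -1) and reports
#' `100 * matches / columns`, where columns exclude terminal-overhang gap
#' columns at either end of the alignment (so length differences between
#' draft gene calls do not depress identity), internal gap columns count
#' as non-matches, and `N` matches nothing.
#'
#' @param seq_a,seq_b Non-empty nucleotide sequences (character scalars,
#'   case-insensitive).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    param_error("sequences must be non-empty")
  a <- toupper(seq_a)
  b <- toupper(seq_b)
  if (a == b) return(100)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .ani_submat, gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gap <- pa == "-" | pb == "-"
  L <- length(pa)
  lead <- if (gap[1L]) rle(gap)$lengths[1L] else 0L
  trail <- if (gap[L]) rev(rle(gap)$lengths)[1L] else 0L
  keep <- seq.int(lead + 1L, L - trail)
  if (length(keep) == 0L) return(0)
  matches <- sum(pa[keep] == pb[keep] & pa[keep] %in% c("A", "C", "G", "T"))
  100 * matches / length(keep)
}

#' Average nucleotide identity over shared ortholog families
#'
#' For every genome pair, ANI is the unweighted mean of
#' [pairwise_identity()] over all ortholog families in which both genomes
#' have a sequence (optionally length-weighted). Pairs sharing fewer than
#' `min_shared` families get `NA`. Pairs with ANI below `cutoff` (default
#' the conventional 95% species threshold) are flagged.
#'
#' @param orthologs An ortholog set: a named list mapping family id to a
#'   named character vector of nucleotide sequences (genome id -> sequence,
#'   at most one per genome), e.g. from [read_ortholog_dir()].
#' @param min_shared Minimum number of shared families per pair.
#' @param cutoff Species-delineation ANI threshold in percent.
#' @param length_weighted Weight family identities by mean sequence length.
#' @return An object of class `ani_matrix`: symmetric percent-identity
#'   matrix `values` (diagonal 100), shared-family counts `n_shared`, and
#'   logical `below_cutoff` flags.
#' @export
ani_matrix <- function(orthologs, min_shared = 1L, cutoff = 95,
                       length_weighted = FALSE) {
  genomes <- sort(unique(unlist(lapply(orthologs, names))))
  n <- length(genomes)
  if (n < 2L) param_error("ANI needs at least 2 genomes in the ortholog set")
  values <- matrix(NA_real_, n, n, dimnames = list(genomes, genomes))
  shared <- matrix(0L, n, n, dimnames = list(genomes, genomes))
  diag(values) <- 100
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ids <- numeric(0)
      wts <- numeric(0)
      for (fam in orthologs) {
        sa <- unname(fam[genomes[i]])
        sb <- unname(fam[genomes[j]])
        if (is.na(sa) || is.na(sb)) next
        ids <- c(ids, pairwise_identity(sa, sb))
        wts <- c(wts, (nchar(sa) + nchar(sb)) / 2)
      }
      shared[i, j] <- shared[j, i] <- length(ids)
      if (length(ids) >= min_shared) {
        v <- if (length_weighted) stats::weighted.mean(ids, wts) else mean(ids)
        values[i, j] <- values[j, i] <- v       # computed once, mirrored
      }
    }
  }
  structure(list(genome_ids = genomes, values = values, n_shared = shared,
                 below_cutoff = !is.na(values) & values < cutoff,
                 cutoff = cutoff),
            class = "ani_matrix")
}

#' @export
print.ani_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat("ANI matrix over", length(x$genome_ids), "genomes\n")
  cat(sprintf("  pairwise ANI range: %.2f-%.2f; %d pair(s) below %.0f%% cutoff\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE),
              sum(x$below_cutoff[upper.tri(x$below_cutoff)]), x$cutoff))
  invisible(x)
}

#' Read an ortholog set from a directory of FASTA files
#'
#' Each file holds one ortholog family; sequence ids are genome ids. The
#' family id is the file name without extension.
#'
#' @param dir Directory of FASTA files (`.fa`, `.fasta`, `.fna`).
#' @return A named list suitable for [ani_matrix()].
#' @export
read_ortholog_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (length(files) == 0L) format_error("no FASTA files in ", dir)
  out <- lapply(files, function(f) {
    ss <- Biostrings::readBStringSet(f)
    ids <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(ids))
      format_error("more than one sequence per genome in ", f)
    stats::setNames(as.character(ss), ids)
  })
  names(out) <- tools::file_path_sans_ext(basename(files))
  out
}

#' Long-format pair table from an ANI matrix
#'
#' @param x An `ani_matrix`.
#' @return Data frame with one row per unordered genome pair: `genome_a`,
#'   `genome_b`, `ani`, `n_shared`, `same_species`.
#' @export
ani_pairs <- function(x) {
  stopifnot(inherits(x, "ani_matrix"))
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  data.frame(genome_a = x$genome_ids[idx[, 1L]],
             genome_b = x$genome_ids[idx[, 2L]],
             ani = x$values[idx],
             n_shared = x$n_shared[idx],
             same_species = !x$below_cutoff[idx] & !is.na(x$values[idx]),
             stringsAsFactors = FALSE)
}
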