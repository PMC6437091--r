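# Equal-length sequence alignments and concatenation of per-family blocks.

#' Construct a site alignment
#'
#' An equal-length set of nucleotide sequences over `{A,C,G,T,-,N}`
#' (case-insensitive), the substrate of the PHI recombination test.
#'
#' @param ids Unique sequence (genome) labels.
#' @param seqs Character vector of equal-length sequences, parallel to
#'   `ids`.
#' @param blocks Optional data frame recording per-source-file block
#'   boundaries (`file`, `start`, `end`), as produced by
#'   [concat_alignments()].
#' @return An object of class `site_alignment`.
#' @export
site_alignment <- function(ids, seqs, blocks = NULL) {
  if (length(ids) != length(seqs)) param_error("ids and seqs differ in length")
  if (length(ids) < 2L) param_error("an alignment needs at least 2 sequences")
  if (anyDuplicated(ids)) format_error("duplicate sequence id(s)")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) format_error("sequences are not all the same length")
  if (L < 1L) format_error("zero-length alignment")
  seqs <- toupper(seqs)
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 length = L, blocks = blocks),
            class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", x$length, "columns\n")
  if (!is.null(x$blocks)) cat("  concatenated from", nrow(x$blocks), "blocks\n")
  invisible(x)
}

# n x L character matrix view of the alignment
alignment_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$ids), byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Read one FASTA alignment
#'
#' Wrapped or single-line FASTA, case-insensitive nucleotides, `-` gaps.
#' All sequences must have equal length.
#'
#' @param path Path to a FASTA file.
#' @return A [site_alignment()]; sequence ids are taken to be genome ids.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) format_error("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) format_error("no sequences in ", path)
  if (length(unique(Biostrings::width(ss))) != 1L)
    format_error("sequences in ", path, " are not all the same length")
  ids <- sub("\\s.*$", "", names(ss))
  site_alignment(ids, as.character(ss))
}

#' Write an alignment as FASTA
#'
#' @param aln A [site_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), path)
  invisible(path)
}

#' Concatenate per-family alignments into one long alignment
#'
#' Joins equal-length FASTA alignments end to end (e.g., all core-gene
#' alignments into a single core alignment). The total length is the sum
#' of the per-file lengths and per-file block boundaries are recorded.
#'
#' @param paths Character vector of FASTA alignment files.
#' @param missing_policy `"error"`: every genome must appear in every
#'   file, otherwise an error names the genome and file. `"gap_fill"`:
#'   the alignment covers the union of genome ids and a genome's missing
#'   blocks are all-gap.
#' @return A [site_alignment()] over the union (or common set) of genome
#'   ids, with a `blocks` data frame mapping each input file to its column
#'   range.
#' @export
concat_alignments <- function(paths, missing_policy = c("error", "gap_fill")) {
  missing_policy <- match.arg(missing_policy)
  if (length(paths) < 1L) param_error("no alignment files given")
  parts <- lapply(paths, read_fasta_alignment)
  all_ids <- unique(unlist(lapply(parts, `[[`, "ids")))
  if (missing_policy == "error") {
    for (i in seq_along(parts)) {
      absent <- setdiff(all_ids, parts[[i]]$ids)
      if (length(absent))
        format_error("genome ", absent[1L], " is missing from ", paths[i])
    }
  }
  lens <- vapply(parts, `[[`, integer(1L), "length")
  ends <- cumsum(lens)
  blocks <- data.frame(file = as.character(paths),
                       start = c(1L, utils::head(ends, -1L) + 1L),
                       end = ends, stringsAsFactors = FALSE)
  pieces <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    out <- rep(strrep("-", p$length), length(all_ids))
    out[match(p$ids, all_ids)] <- p$seqs
    out
  }, character(length(all_ids)))
  if (length(all_ids) == 1L) pieces <- matrix(pieces, nrow = 1L)
  site_alignment(all_ids, apply(pieces, 1L, paste, collapse = ""),
                 blocks = blocks)
}
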