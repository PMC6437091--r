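# 12-column tabular sequence-search output (BLAST outfmt 6).

#' Read a 12-column BLAST tabular hit file
#'
#' Parses standard tabular output (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore). Lines starting with `#` are skipped; any other line
#' with a different column count is a format error citing its line number.
#' The subject's genome of origin is extracted from the subject id as the
#' prefix before the first `genome_delim` (the whole id when the delimiter
#' does not occur).
#'
#' @param path Path to the tab-separated hit file.
#' @param genome_delim Single character separating the genome label from
#'   the rest of the subject id; default `"|"`.
#' @return A data frame of class `blast_hits`, one row per hit, in file
#'   order, with columns `query_id`, `subject_id`, `subject_genome`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `evalue`,
#'   `bitscore`.
#' @export
read_blast_tab <- function(path, genome_delim = "|") {
  lines <- read_body_lines(path)
  nums <- attr(lines, "line_numbers")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    format_error("line ", nums[bad[1L]], " of ", path, " has ",
                 lengths(fields)[bad[1L]], " columns, expected 12")
  raw <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(raw[, 3:12, drop = FALSE], 2L, as.numeric))
  if (length(lines) == 1L) num <- matrix(num, nrow = 1L)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1L]
    format_error("unparsable numeric field on line ", nums[bad], " of ", path)
  }
  hits <- blast_hits(
    query_id = raw[, 1L], subject_id = raw[, 2L],
    percent_identity = num[, 1L], alignment_length = num[, 2L],
    mismatches = num[, 3L], gap_opens = num[, 4L],
    query_start = num[, 5L], query_end = num[, 6L],
    subject_start = num[, 7L], subject_end = num[, 8L],
    evalue = num[, 9L], bitscore = num[, 10L],
    genome_delim = genome_delim)
  # keep the verbatim fields so a write-back is byte-identical
  attr(hits, "raw_fields") <- raw
  hits
}

#' Build a hit table in memory
#'
#' @param query_id,subject_id Character vectors.
#' @param percent_identity,alignment_length,mismatches,gap_opens,query_start,query_end,subject_start,subject_end,evalue,bitscore
#'   Numeric vectors, recycled to a common length.
#' @param genome_delim Delimiter used to derive `subject_genome` from
#'   `subject_id`.
#' @return A `blast_hits` data frame.
#' @export
blast_hits <- function(query_id, subject_id, percent_identity,
                       alignment_length, mismatches = 0, gap_opens = 0,
                       query_start = 1, query_end = alignment_length,
                       subject_start = 1, subject_end = alignment_length,
                       evalue = 0, bitscore = 0, genome_delim = "|") {
  df <- data.frame(query_id = query_id, subject_id = subject_id,
                   subject_genome = subject_genome_of(subject_id, genome_delim),
                   percent_identity = percent_identity,
                   alignment_length = alignment_length,
                   mismatches = mismatches, gap_opens = gap_opens,
                   query_start = query_start, query_end = query_end,
                   subject_start = subject_start, subject_end = subject_end,
                   evalue = evalue, bitscore = bitscore,
                   stringsAsFactors = FALSE)
  if (any(df$query_start > df$query_end))
    format_error("hit with query_start > query_end")
  if (any(df$percent_identity < 0 | df$percent_identity > 100))
    format_error("percent identity outside [0, 100]")
  if (any(df$alignment_length < 1))
    format_error("hit with alignment length < 1")
  if (any(df$evalue < 0)) format_error("negative e-value")
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' @rdname read_blast_tab
#' @param subject_id Character vector of subject sequence ids.
#' @export
subject_genome_of <- function(subject_id, genome_delim = "|") {
  vapply(strsplit(subject_id, genome_delim, fixed = TRUE), `[[`, "", 1L)
}

#' Write a hit table as 12-column tabular text
#'
#' Hit tables read by [read_blast_tab()] are written back with the exact
#' numeric text of the input (loss-free round trip); tables built in code
#' use default numeric formatting.
#'
#' @param hits A `blast_hits` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  raw <- attr(hits, "raw_fields")
  if (is.null(raw)) {
    cols <- c("query_id", "subject_id", "percent_identity",
              "alignment_length", "mismatches", "gap_opens", "query_start",
              "query_end", "subject_start", "subject_end", "evalue",
              "bitscore")
    raw <- vapply(cols, function(cl) {
      v <- hits[[cl]]
      if (is.numeric(v)) format(v, trim = TRUE, scientific = NA) else v
    }, character(nrow(hits)))
    if (nrow(hits) == 1L) raw <- matrix(raw, nrow = 1L)
  }
  writeLines(apply(raw, 1L, paste, collapse = "\t"), path)
  invisible(path)
}
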