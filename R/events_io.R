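# Recombination-event tables (fastGEAR-style TSV dialect).

# Accepted header spellings for each canonical column; matching is
# case-insensitive after stripping non-alphanumerics, so close variants of
# the recombination-table dialect are read without preprocessing.
.event_col_synonyms <- list(
  gene_id       = c("gene", "geneid", "genename", "alignment"),
  start         = c("start", "begin", "startposition", "start_pos"),
  end           = c("end", "stop", "endposition", "end_pos"),
  donor_lineage = c("donorlineage", "donor", "lineage", "origin"),
  recipient     = c("recipient", "strain", "strainname", "recipientstrain"))

# optional column carrying a stable event label (used to key hit tables)
.event_id_synonyms <- c("eventid", "id", "fragment", "fragmentid")

#' Read a recombination-event table
#'
#' Tab-separated with named columns `gene`, `start`, `end`,
#' `donor_lineage`, `recipient` (close header variants accepted;
#' `#`-comment lines skipped). Coordinates are 1-based inclusive within
#' the gene alignment, so the fragment length is `end - start + 1`.
#'
#' @param path Path to the TSV file.
#' @param kind Either `"recent"` (events affecting a few strains) or
#'   `"ancestral"` (events affecting entire lineages); every returned
#'   event is tagged with this kind.
#' @return A data frame of class `recomb_events` with columns `gene_id`,
#'   `recipient`, `donor_lineage`, `start`, `end`, `length`, `kind`.
#' @export
read_event_table <- function(path, kind = c("recent", "ancestral")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) format_error("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  key <- gsub("[^a-z0-9]", "", tolower(names(df)))
  idx <- vapply(.event_col_synonyms, function(syn) {
    m <- which(key %in% syn)
    if (length(m)) m[1L] else NA_integer_
  }, integer(1L))
  missing <- names(idx)[is.na(idx)]
  if (length(missing))
    format_error("missing column(s) in ", path, ": ",
                 paste(missing, collapse = ", "))
  out <- data.frame(gene_id = as.character(df[[idx[["gene_id"]]]]),
                    recipient = as.character(df[[idx[["recipient"]]]]),
                    donor_lineage = as.character(df[[idx[["donor_lineage"]]]]),
                    start = as.integer(df[[idx[["start"]]]]),
                    end = as.integer(df[[idx[["end"]]]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    format_error("non-numeric coordinates in ", path)
  bad <- which(out$end < out$start)
  if (length(bad))
    format_error("row ", bad[1L], " of ", path, " has end < start")
  id_col <- which(key %in% .event_id_synonyms)
  recomb_events(out$gene_id, out$recipient, out$donor_lineage,
                out$start, out$end, kind,
                event_id = if (length(id_col))
                  as.character(df[[id_col[1L]]]) else NULL)
}

#' Build a recombination-event table in memory
#'
#' @param gene_id,recipient,donor_lineage Character vectors.
#' @param start,end 1-based inclusive alignment coordinates.
#' @param kind `"recent"` or `"ancestral"`, recycled.
#' @param event_id Optional unique event labels; generated when absent.
#' @return A `recomb_events` data frame.
#' @export
recomb_events <- function(gene_id, recipient, donor_lineage, start, end,
                          kind = "recent", event_id = NULL) {
  if (any(end < start)) param_error("event with end < start")
  df <- data.frame(gene_id = gene_id, recipient = recipient,
                   donor_lineage = donor_lineage,
                   start = as.integer(start), end = as.integer(end),
                   length = as.integer(end) - as.integer(start) + 1L,
                   kind = kind, stringsAsFactors = FALSE)
  df$event_id <- event_id %||%
    paste0(df$gene_id, ":", df$start, "-", df$end, ":", df$recipient,
           ":", seq_len(nrow(df)))
  class(df) <- c("recomb_events", "data.frame")
  df
}

#' Write a recombination-event table
#'
#' The `event_id` column is included so that a round trip through
#' [read_event_table()] preserves the keys linking events to their hit
#' tables.
#'
#' @param events A `recomb_events` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(
    data.frame(gene = events$gene_id, start = events$start,
               end = events$end, donor_lineage = events$donor_lineage,
               recipient = events$recipient, event_id = events$event_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
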