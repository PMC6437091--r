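# Gene presence/absence matrices: construction, dialect readers, writer.

#' Construct a gene presence/absence matrix
#'
#' The `pan_matrix` object is the substrate of all pan-genome statistics: a
#' genomes-by-families logical incidence matrix, optionally accompanied by
#' per-cell multiplicities (number of gene copies a genome contributes to a
#' family, as recorded by the clustering tool).
#'
#' @param presence Logical matrix with genome ids as row names and gene
#'   family ids as column names. Every family must be present in at least
#'   one genome and ids must be unique.
#' @param multiplicity Optional non-negative integer matrix of the same
#'   shape giving per-cell gene copy counts.
#' @return An object of class `pan_matrix`.
#' @seealso [read_presence_matrix()], [summarize_pangenome()]
#' @export
pan_matrix <- function(presence, multiplicity = NULL) {
  if (!is.matrix(presence) || !is.logical(presence))
    param_error("`presence` must be a logical matrix (genomes x families)")
  if (nrow(presence) < 1L || ncol(presence) < 1L)
    format_error("empty presence/absence matrix")
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    param_error("presence matrix requires genome row names and family column names")
  dup_g <- unique(rownames(presence)[duplicated(rownames(presence))])
  if (length(dup_g))
    format_error("duplicate genome id(s): ", paste(dup_g, collapse = ", "))
  dup_f <- unique(colnames(presence)[duplicated(colnames(presence))])
  if (length(dup_f))
    format_error("duplicate family id(s): ", paste(dup_f, collapse = ", "))
  empty <- colSums(presence) == 0L
  if (any(empty))
    format_error("families present in no genome: ",
                 paste(utils::head(colnames(presence)[empty], 5L), collapse = ", "))
  if (!is.null(multiplicity)) {
    if (!is.matrix(multiplicity) || !all(dim(multiplicity) == dim(presence)))
      param_error("`multiplicity` must match the shape of `presence`")
    storage.mode(multiplicity) <- "integer"
    dimnames(multiplicity) <- dimnames(presence)
  }
  structure(list(presence = presence, multiplicity = multiplicity),
            class = "pan_matrix")
}

#' @export
print.pan_matrix <- function(x, ...) {
  cat("Gene presence/absence matrix:",
      nrow(x$presence), "genomes x", ncol(x$presence), "gene families\n")
  occ <- colSums(x$presence)
  cat("  families per genome:", paste(range(rowSums(x$presence)), collapse = "-"),
      " occupancy range:", paste(range(occ), collapse = "-"), "\n")
  invisible(x)
}

#' @rdname pan_matrix
#' @param x A `pan_matrix`.
#' @export
genome_ids <- function(x) rownames(x$presence)

#' @rdname pan_matrix
#' @export
family_ids <- function(x) colnames(x$presence)

# Fixed metadata columns of Roary's gene_presence_absence.csv; every other
# column is taken to be a genome.
.roary_meta_cols <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC", "Min group size nuc",
  "Max group size nuc", "Avg group size nuc")

#' Read a gene presence/absence matrix
#'
#' Understands the two common dialects emitted by Roary-style pan-genome
#' pipelines: the quoted `gene_presence_absence.csv` (families as rows,
#' fixed metadata columns, then one column per genome whose cells list the
#' member gene ids) and the binary `.Rtab` (tab-separated 0/1, families as
#' rows, genomes as columns). In the CSV dialect a family is present in a
#' genome iff the cell is non-empty; cells holding several
#' whitespace-separated gene ids count as present once, with the copy
#' number retained in the `multiplicity` slot.
#'
#' @param path Path to the matrix file.
#' @param dialect One of `"auto"` (sniff from the header), `"roary_csv"`,
#'   or `"rtab"`.
#' @return A [pan_matrix()] (genomes as rows, families as columns).
#' @export
read_presence_matrix <- function(path, dialect = c("auto", "roary_csv", "rtab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error("file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (grepl(",", header) && grepl("Gene", header, fixed = TRUE) &&
                   !grepl("\t", header, fixed = TRUE)) "roary_csv" else "rtab"
  }
  if (dialect == "roary_csv") .read_roary_csv(path) else .read_rtab(path)
}

.check_dup_genomes <- function(ids, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    format_error("duplicate genome column(s) in ", path, ": ",
                 paste(dup, collapse = ", "))
}

.read_roary_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "")
  if (nrow(df) == 0L) format_error("empty matrix in ", path)
  genome_cols <- setdiff(names(df), .roary_meta_cols)
  if (!("Gene" %in% names(df)) || length(genome_cols) == 0L)
    format_error(path, " lacks the standard gene_presence_absence.csv header")
  .check_dup_genomes(genome_cols, path)
  fams <- df[["Gene"]]
  dupf <- unique(fams[duplicated(fams)])
  if (length(dupf))
    format_error("duplicate family id(s) in ", path, ": ",
                 paste(dupf, collapse = ", "))
  cells <- as.matrix(df[genome_cols])          # families x genomes
  mult <- matrix(lengths(strsplit(trimws(cells), "\\s+")),
                 nrow = nrow(cells), dimnames = dimnames(cells))
  mult[trimws(cells) == ""] <- 0L
  presence <- t(mult > 0L)                     # genomes x families
  colnames(presence) <- fams
  rownames(presence) <- genome_cols
  multiplicity <- t(mult)
  colnames(multiplicity) <- fams
  pan_matrix(presence, multiplicity)
}

.read_rtab <- function(path) {
  lines <- read_body_lines(path)
  if (length(lines) < 2L) format_error("empty matrix in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  genomes <- header[-1L]
  .check_dup_genomes(genomes, path)
  body <- fields[-1L]
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    format_error("line ", attr(lines, "line_numbers")[bad[1L] + 1L], " of ",
                 path, " has ", lengths(body)[bad[1L]], " columns, expected ",
                 length(header))
  fams <- vapply(body, `[[`, "", 1L)
  dupf <- unique(fams[duplicated(fams)])
  if (length(dupf))
    format_error("duplicate family id(s) in ", path, ": ",
                 paste(dupf, collapse = ", "))
  vals <- vapply(body, function(f) as.integer(f[-1L]), integer(length(genomes)))
  if (length(genomes) == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals) || !all(vals %in% c(0L, 1L)))
    format_error(path, ": Rtab cells must be 0 or 1")
  presence <- vals == 1L                       # genomes x families
  rownames(presence) <- genomes
  colnames(presence) <- fams
  pan_matrix(presence)
}

#' Write a presence/absence matrix in Rtab dialect
#'
#' Families as rows, genomes as columns, tab-separated 0/1. Re-reading the
#' file with [read_presence_matrix()] reproduces the presence matrix
#' exactly.
#'
#' @param x A [pan_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rtab <- function(x, path) {
  stopifnot(inherits(x, "pan_matrix"))
  m <- t(x$presence) * 1L                      # families x genomes
  lines <- c(paste(c("Gene", rownames(x$presence)), collapse = "\t"),
             paste(rownames(m), apply(m, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
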