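# Post-processing of recombination events: donor assignment, the
# donor-recipient network, highways, per-gene counts, fragment sizes.

#' Assign a donor genome to a recombination event
#'
#' Filters the event's hits to those covering at least `min_coverage` of
#' the recombination fragment length (coverage = alignment length /
#' fragment length, capped at 1) with at least `min_identity` percent
#' nucleotide identity, then takes the hit with the highest bit score as
#' the donor. An exact top-bitscore tie across distinct subject genomes
#' yields status `ambiguous` (with the lexicographically smallest subject
#' genome recorded as candidate); no surviving hit yields `unresolved`.
#'
#' @param event One row of a `recomb_events` data frame (or any list with
#'   a `length` field).
#' @param hits A `blast_hits` data frame of searches of the event's
#'   fragment.
#' @param min_coverage Minimum fragment coverage (default 0.50).
#' @param min_identity Minimum percent identity (default 99.0).
#' @return An object of class `donor_assignment` with fields `event`,
#'   `status` (`assigned`/`unresolved`/`ambiguous`), `donor_genome`,
#'   `candidate_genome` and `best_hit`.
#' @export
assign_donor <- function(event, hits, min_coverage = 0.5,
                         min_identity = 99) {
  frag_len <- event$length
  if (is.null(frag_len) || is.na(frag_len) || frag_len < 1L)
    param_error("event has no valid fragment length")
  res <- list(event = event, status = "unresolved",
              donor_genome = NA_character_, candidate_genome = NA_character_,
              best_hit = NULL)
  class(res) <- "donor_assignment"
  if (is.null(hits) || nrow(hits) == 0L) return(res)
  cov <- pmin(1, hits$alignment_length / frag_len)
  keep <- cov >= min_coverage & hits$percent_identity >= min_identity
  if (!any(keep)) return(res)
  surv <- hits[keep, , drop = FALSE]
  top <- surv[surv$bitscore == max(surv$bitscore), , drop = FALSE]
  top_genomes <- sort(unique(top$subject_genome))
  if (length(top_genomes) > 1L) {
    res$status <- "ambiguous"
    res$candidate_genome <- top_genomes[1L]
  } else {
    res$status <- "assigned"
    res$donor_genome <- top_genomes[1L]
    res$best_hit <- top[order(top$subject_id), , drop = FALSE][1L, ]
  }
  res
}

#' Assign donors to a table of events
#'
#' Matches each event to its hits by `query_id == event_id` and applies
#' [assign_donor()].
#'
#' @param events A `recomb_events` data frame with an `event_id` column.
#' @param hits A `blast_hits` data frame whose `query_id` values are event
#'   ids.
#' @inheritParams assign_donor
#' @return A list of `donor_assignment` objects, one per event.
#' @export
assign_donors <- function(events, hits, min_coverage = 0.5,
                          min_identity = 99) {
  by_event <- split(seq_len(nrow(hits)), hits$query_id)
  lapply(seq_len(nrow(events)), function(i) {
    idx <- by_event[[events$event_id[i]]]
    assign_donor(events[i, ], if (is.null(idx)) NULL
                 else hits[idx, , drop = FALSE],
                 min_coverage, min_identity)
  })
}

#' Build the donor-recipient recombination network
#'
#' Counts assigned events per directed (donor genome, recipient) pair.
#' The mean and sample (n-1) standard deviation of the counts are
#' computed over the pairs with at least one event; they define the
#' highway threshold used by [detect_highways()].
#'
#' @param assignments List of `donor_assignment` objects.
#' @return An object of class `recomb_network` with fields `nodes`,
#'   `edges` (data frame `donor`, `recipient`, `count`), `mean_count`,
#'   `sd_count` and `n_assigned`.
#' @export
build_network <- function(assignments) {
  ok <- vapply(assignments, function(a) a$status == "assigned", logical(1L))
  donors <- vapply(assignments[ok], `[[`, "", "donor_genome")
  recips <- vapply(assignments[ok], function(a) a$event$recipient, "")
  if (length(donors) == 0L) {
    return(structure(list(nodes = character(0),
                          edges = data.frame(donor = character(0),
                                             recipient = character(0),
                                             count = integer(0)),
                          mean_count = NA_real_, sd_count = NA_real_,
                          n_assigned = 0L),
                     class = "recomb_network"))
  }
  tab <- table(donor = donors, recipient = recips)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("donor", "recipient", "count")
  df <- df[df$count > 0L, , drop = FALSE]
  df <- df[order(-df$count, df$donor, df$recipient), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(nodes = sort(unique(c(df$donor, df$recipient))),
                 edges = df,
                 mean_count = mean(df$count),
                 sd_count = if (nrow(df) > 1L) stats::sd(df$count) else NA_real_,
                 n_assigned = sum(df$count)),
            class = "recomb_network")
}

#' @export
print.recomb_network <- function(x, ...) {
  cat("Recombination network:", length(x$nodes), "genomes,",
      nrow(x$edges), "directed pairs,", x$n_assigned, "assigned events\n")
  if (nrow(x$edges) > 1L)
    cat(sprintf("  events per pair: mean %.2f, sd %.2f\n",
                x$mean_count, x$sd_count))
  invisible(x)
}

#' Detect highways of recombination
#'
#' A directed pair is a highway when its event count is at least one
#' standard deviation above the mean count over pairs with at least one
#' event (`count >= mean + sd`). With fewer than two pairs, or when all
#' counts are equal (sd = 0, no dispersion "above the average"), there
#' are no highways.
#'
#' @param network A `recomb_network` from [build_network()].
#' @return The highway subset of `network$edges`, with the numeric
#'   threshold attached as attribute `"threshold"`.
#' @export
detect_highways <- function(network) {
  stopifnot(inherits(network, "recomb_network"))
  edges <- network$edges
  none <- edges[0L, , drop = FALSE]
  if (nrow(edges) < 2L || is.na(network$sd_count) || network$sd_count <= 0)
    return(structure(none, threshold = NA_real_))
  thr <- network$mean_count + network$sd_count
  structure(edges[edges$count >= thr, , drop = FALSE], threshold = thr)
}

#' Per-gene recent and ancestral recombination counts
#'
#' @param events A `recomb_events` data frame (any mix of kinds).
#' @return Data frame with one row per gene appearing in `events`:
#'   `gene_id`, `recent`, `ancestral`.
#' @export
gene_recombination_counts <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    return(data.frame(gene_id = character(0), recent = integer(0),
                      ancestral = integer(0), stringsAsFactors = FALSE))
  tab <- table(factor(events$gene_id),
               factor(events$kind, levels = c("recent", "ancestral")))
  data.frame(gene_id = rownames(tab),
             recent = as.integer(tab[, "recent"]),
             ancestral = as.integer(tab[, "ancestral"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fragment-size statistics of recombination events
#'
#' Median (lower-middle convention for even counts, keeping the value an
#' observed integer length; `median_mode = "midpoint"` for the usual
#' average), maximum, the fraction of events shorter than the
#' micro/macro-recombination cutoff, the maximum-likelihood exponential
#' rate `1/mean`, and a histogram.
#'
#' @param events A `recomb_events` data frame with at least one event.
#' @param micro_macro_cutoff Length in nt separating micro- from
#'   macro-recombinations (default 500).
#' @param median_mode `"lower"` (default) or `"midpoint"`.
#' @param breaks Histogram breaks, passed to [graphics::hist()].
#' @return An object of class `size_stats` with fields `n_events`,
#'   `median_length`, `max_length`, `fraction_below_cutoff`, `cutoff`,
#'   `exp_rate` and `histogram` (`breaks`, `counts`).
#' @export
size_statistics <- function(events, micro_macro_cutoff = 500L,
                            median_mode = c("lower", "midpoint"),
                            breaks = "Sturges") {
  median_mode <- match.arg(median_mode)
  if (is.null(events) || nrow(events) == 0L)
    param_error("size statistics need at least one event")
  len <- sort(as.numeric(events$length))
  n <- length(len)
  med <- if (n %% 2L == 1L) len[(n + 1L) %/% 2L]
         else if (median_mode == "lower") len[n %/% 2L]
         else (len[n %/% 2L] + len[n %/% 2L + 1L]) / 2
  h <- graphics::hist(len, breaks = breaks, plot = FALSE)
  structure(list(n_events = n, median_length = med, max_length = max(len),
                 fraction_below_cutoff = mean(len < micro_macro_cutoff),
                 cutoff = micro_macro_cutoff,
                 exp_rate = 1 / mean(len),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "size_stats")
}

#' @export
print.size_stats <- function(x, ...) {
  cat(sprintf(paste0("Fragment sizes: n = %d, median %s nt, max %s nt; ",
                     "%.1f%% below %d nt; exponential rate %.5f (mean %.0f nt)\n"),
              x$n_events, format(x$median_length), format(x$max_length),
              100 * x$fraction_below_cutoff, x$cutoff, x$exp_rate,
              1 / x$exp_rate))
  invisible(x)
}
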