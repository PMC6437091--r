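# Synthetic data with the statistical structure the analyses assume:
# presence/absence matrices with tunable openness, clonal and mosaic
# alignments, and recombination scenarios with planted donor biases.
# Every generator is a pure function of its arguments and seed.

#' Simulate a pan-genome presence/absence matrix with tunable openness
#'
#' The default `"spectrum"` method draws accessory families from an
#' occupancy spectrum chosen (by non-negative least squares over the
#' first-seen probabilities of a c-carrier family under a random genome
#' ordering) so that the expected number of previously unseen families
#' contributed by the g-th genome of a random ordering equals
#' `kappa * g^(-alpha)`; carriers of each family are a uniform random
#' subset. Heaps' law fits on [accumulation_curves()] of such a matrix
#' therefore recover the planted decay parameter. The `"sequential"`
#' method instead introduces `round(kappa * g^(-alpha))` brand-new
#' families with the g-th genome (in construction order), carrying each
#' previously seen accessory family forward independently with
#' probability `retention`; its realized new-family counts in
#' construction order match the target exactly, but its first-seen curve
#' under random orderings does not follow the planted decay.
#'
#' @param n_genomes Number of genomes (>= 3).
#' @param kappa Heaps scale parameter (expected accessory novelty of the
#'   first genome).
#' @param alpha Planted decay parameter; `alpha < 1` simulates an open
#'   pan-genome.
#' @param core_size Number of families present in every genome.
#' @param retention Carry-forward probability of previously seen
#'   accessory families (`"sequential"` method only).
#' @param seed Integer seed; identical arguments give bit-identical
#'   matrices.
#' @param method `"spectrum"` (default) or `"sequential"`.
#' @return A [pan_matrix()].
#' @export
simulate_pangenome <- function(n_genomes, kappa = 500, alpha = 0.8,
                               core_size = 1000L, retention = 0.1,
                               seed = 1L, method = c("spectrum",
                                                     "sequential")) {
  method <- match.arg(method)
  if (n_genomes < 3L) param_error("simulate_pangenome needs >= 3 genomes")
  set.seed(seed)
  N <- n_genomes
  if (method == "spectrum") {
    target <- kappa * (1:N)^(-alpha)
    # first-seen probability of a c-carrier family at ordering position g
    A <- outer(1:N, 1:N, function(g, c) choose(N - g, c - 1) / choose(N, c))
    spectrum <- round(pracma::lsqnonneg(A, target)$x)
    occ <- rep(1:N, spectrum)
    pres <- matrix(FALSE, N, core_size + length(occ))
    if (core_size > 0L) pres[, seq_len(core_size)] <- TRUE
    for (f in seq_along(occ))
      pres[sample.int(N, occ[f]), core_size + f] <- TRUE
  } else {
    new_counts <- c(round(kappa), round(kappa * (2:N)^(-alpha)))
    origin <- rep(seq_len(N), new_counts)
    pres <- matrix(FALSE, N, core_size + length(origin))
    if (core_size > 0L) pres[, seq_len(core_size)] <- TRUE
    for (g in seq_len(N)) {
      pres[g, core_size + which(origin == g)] <- TRUE
      prev <- core_size + which(origin < g)
      if (length(prev))
        pres[g, prev] <- stats::runif(length(prev)) < retention
    }
    pres <- pres[, colSums(pres) > 0L, drop = FALSE]
  }
  rownames(pres) <- sprintf("genome%03d", seq_len(N))
  colnames(pres) <- sprintf("fam%06d", seq_len(ncol(pres)))
  pan_matrix(pres)
}

#' Build a presence/absence matrix with an exact occupancy composition
#'
#' Constructs a matrix containing exactly the requested number of
#' families at each occupancy (number of carrier genomes), assigning
#' carriers by seeded draw. Useful to reproduce a printed pan-genome
#' composition exactly, e.g. 1,945 families in all 32 genomes, 1,874 in
#' 31, 9,646 singletons and the remainder spread over intermediate
#' occupancies.
#'
#' @param n_genomes Number of genomes.
#' @param occupancy_counts Named integer vector: `names` are occupancies
#'   (1..n_genomes), values are family counts.
#' @param seed Integer seed for carrier assignment.
#' @return A [pan_matrix()] for which [summarize_pangenome()] returns the
#'   requested composition.
#' @export
make_fixture_matrix <- function(n_genomes, occupancy_counts, seed = 1L) {
  occ_levels <- as.integer(names(occupancy_counts))
  counts <- as.integer(occupancy_counts)
  if (anyNA(occ_levels) || any(occ_levels < 1L) || any(occ_levels > n_genomes))
    param_error("occupancies must be integers in 1..n_genomes")
  if (anyNA(counts) || any(counts < 0L) || sum(counts) < 1L)
    param_error("infeasible occupancy request")
  if (n_genomes == 1L && any(occ_levels != 1L))
    param_error("single-genome matrix admits only occupancy 1")
  set.seed(seed)
  occ <- rep(occ_levels, counts)
  pres <- matrix(FALSE, n_genomes, length(occ))
  for (f in seq_along(occ)) {
    pres[if (occ[f] == n_genomes) seq_len(n_genomes)
         else sample.int(n_genomes, occ[f]), f] <- TRUE
  }
  rownames(pres) <- sprintf("genome%03d", seq_len(n_genomes))
  colnames(pres) <- sprintf("fam%06d", seq_len(ncol(pres)))
  pan_matrix(pres)
}

.bases <- c("A", "C", "G", "T")

# descendant tip indices of every node of an ape phylo tree
.tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]
    sets[[p]] <- c(sets[[p]], sets[[tree$edge[e, 2L]]])
  }
  sets
}

#' Simulate a clonal or mosaic nucleotide alignment
#'
#' Clonal mode (`n_events = 0`): a random bifurcating coalescent genealogy
#' is drawn, scaled so the mean pairwise distance equals `divergence`, and
#' Poisson numbers of substitutions are scattered over its branches at
#' uniform positions, so every site shares one history (homoplasy arises
#' only from recurrent mutation of the same site on different branches).
#' Mosaic mode (`n_events > 0`): sequences form two groups at the given
#' pairwise divergence; `n_events` segments with geometrically distributed
#' lengths of mean `event_mean_length` are then copied from one group's
#' background into single recipient sequences of the other group at
#' uniform positions, creating the distance-dependent compatibility
#' pattern that the PHI test detects.
#'
#' @param n_sequences Number of sequences (>= 4; mosaic mode splits them
#'   into two equal groups).
#' @param length Alignment length in nucleotides.
#' @param divergence Mean pairwise divergence (clonal) or between-group
#'   divergence (mosaic), as a fraction of sites.
#' @param n_events Number of recombination segment transfers (0 = clonal).
#' @param event_mean_length Mean transferred-segment length in nt.
#' @param seed Integer seed; identical arguments give bit-identical
#'   alignments.
#' @return A [site_alignment()].
#' @export
simulate_alignment <- function(n_sequences, length, divergence = 0.05,
                               n_events = 0L, event_mean_length = 300L,
                               seed = 1L) {
  if (n_sequences < 4L) param_error("simulate_alignment needs >= 4 sequences")
  set.seed(seed)
  L <- as.integer(length)
  ids <- sprintf("seq%03d", seq_len(n_sequences))
  if (n_events == 0L) {
    tree <- ape::rcoal(n_sequences, tip.label = ids)
    dmat <- ape::cophenetic.phylo(tree)
    tree$edge.length <- tree$edge.length *
      divergence / mean(dmat[upper.tri(dmat)])
    sets <- .tip_sets(tree)
    root <- sample(.bases, L, replace = TRUE)
    m <- matrix(rep(root, each = n_sequences), n_sequences, L)
    # preorder: each edge mutates the current state of its whole clade
    cw <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(cw$edge))) {
      n_mut <- stats::rpois(1L, cw$edge.length[e] * L)
      if (n_mut == 0L) next
      tips <- sets[[cw$edge[e, 2L]]]
      for (s in sample.int(L, n_mut, replace = TRUE)) {
        cur <- m[tips[1L], s]
        m[tips, s] <- sample(setdiff(.bases, cur), 1L)
      }
    }
  } else {
    half <- n_sequences %/% 2L
    grp_a <- seq_len(half)
    grp_b <- seq.int(half + 1L, n_sequences)
    anc_a <- sample(.bases, L, replace = TRUE)
    anc_b <- anc_a
    flip <- which(stats::runif(L) < divergence)
    anc_b[flip] <- vapply(anc_a[flip],
                          function(b) sample(setdiff(.bases, b), 1L), "")
    m <- matrix("", n_sequences, L)
    m[grp_a, ] <- matrix(rep(anc_a, each = half), half, L)
    m[grp_b, ] <- matrix(rep(anc_b, each = length(grp_b)), length(grp_b), L)
    for (e in seq_len(n_events)) {
      recip <- sample.int(n_sequences, 1L)
      seg_len <- min(L, stats::rgeom(1L, 1 / event_mean_length) + 1L)
      start <- sample.int(L - seg_len + 1L, 1L)
      cols <- seq.int(start, start + seg_len - 1L)
      donor_bg <- if (recip %in% grp_a) anc_b else anc_a
      m[recip, cols] <- donor_bg[cols]
    }
  }
  site_alignment(ids, apply(m, 1L, paste, collapse = ""))
}

#' Simulate a recombination scenario with planted donor biases
#'
#' Event counts per directed (donor, recipient) genome pair are Poisson
#' with mean `base_rate` times the pair's rate multiplier (1 for
#' unlisted pairs), fragment lengths are geometric (discrete exponential)
#' with the given mean, and each event gets a 12-column hit table in
#' which the true donor has the top bit score at the stated identity with
#' full fragment coverage, plus lower-identity/partial-coverage decoy
#' hits from other genomes.
#'
#' @param genomes Character vector of genome labels (>= 4).
#' @param base_rate Poisson mean event count of an unplanted directed
#'   pair.
#' @param planted_pairs Optional data frame `donor`, `recipient`,
#'   `multiplier` of pairs with elevated rates.
#' @param fragment_mean Mean fragment length in nt.
#' @param identity_of_true_donor Percent identity of the true donor's hit.
#' @param seed Integer seed.
#' @param n_genes Size of the gene pool events are placed on.
#' @param n_decoys Decoy hits per event.
#' @return A list with components `events` (a `recomb_events` data frame,
#'   kind `"recent"`) and `hits` (a `blast_hits` data frame keyed by
#'   `query_id == event_id`).
#' @export
simulate_recomb_scenario <- function(genomes, base_rate = 3,
                                     planted_pairs = NULL,
                                     fragment_mean = 230L,
                                     identity_of_true_donor = 99.5,
                                     seed = 1L, n_genes = 100L,
                                     n_decoys = 2L) {
  if (length(genomes) < 4L) param_error("scenario needs >= 4 genomes")
  set.seed(seed)
  pairs <- expand.grid(donor = genomes, recipient = genomes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$donor != pairs$recipient, ]
  pairs$rate <- base_rate
  if (!is.null(planted_pairs)) {
    key <- paste(pairs$donor, pairs$recipient, sep = "\r")
    pk <- paste(planted_pairs$donor, planted_pairs$recipient, sep = "\r")
    hit <- match(key, pk)
    pairs$rate[!is.na(hit)] <-
      base_rate * planted_pairs$multiplier[hit[!is.na(hit)]]
  }
  pairs$n <- stats::rpois(nrow(pairs), pairs$rate)
  donors <- rep(pairs$donor, pairs$n)
  recips <- rep(pairs$recipient, pairs$n)
  n_ev <- length(donors)
  if (n_ev == 0L) param_error("no events drawn; increase base_rate")
  lens <- pmax(1L, stats::rgeom(n_ev, 1 / fragment_mean) + 1L)
  starts <- sample.int(5000L, n_ev, replace = TRUE)
  events <- recomb_events(
    gene_id = sprintf("gene%04d", sample.int(n_genes, n_ev, replace = TRUE)),
    recipient = recips, donor_lineage = donors,
    start = starts, end = starts + lens - 1L, kind = "recent",
    event_id = sprintf("ev%05d", seq_len(n_ev)))
  decoy_pool <- function(truth) sample(setdiff(genomes, truth),
                                       n_decoys, replace = TRUE)
  hit_rows <- lapply(seq_len(n_ev), function(i) {
    truth <- donors[i]
    dec <- decoy_pool(truth)
    data.frame(
      query_id = events$event_id[i],
      subject_id = paste0(c(truth, dec), "|contig1"),
      percent_identity = c(identity_of_true_donor,
                           round(stats::runif(n_decoys, 90, 98.5), 2L)),
      alignment_length = c(lens[i],
                           pmax(1L, round(lens[i] *
                                          stats::runif(n_decoys, 0.3, 0.9)))),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, hit_rows)
  bits <- 2 * tab$alignment_length * tab$percent_identity / 100
  hits <- blast_hits(query_id = tab$query_id, subject_id = tab$subject_id,
                     percent_identity = tab$percent_identity,
                     alignment_length = tab$alignment_length,
                     mismatches = round(tab$alignment_length *
                                        (1 - tab$percent_identity / 100)),
                     evalue = 1e-50, bitscore = round(bits, 1L))
  list(events = events, hits = hits)
}
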