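# Shared fixture builders and independent brute-force oracles.

# random presence/absence matrix with no all-absent family
toy_pan_matrix <- function(n_genomes, n_families, seed, p = 0.5) {
  set.seed(seed)
  pres <- matrix(stats::runif(n_genomes * n_families) < p,
                 n_genomes, n_families)
  empty <- colSums(pres) == 0L
  for (f in which(empty)) pres[sample.int(n_genomes, 1L), f] <- TRUE
  rownames(pres) <- sprintf("g%02d", seq_len(n_genomes))
  colnames(pres) <- sprintf("f%03d", seq_len(n_families))
  pan_matrix(pres)
}

# per-family category by direct threshold check (floating-point tolerant
# reference: computed on integer counts, so exact for the cases used)
oracle_classify <- function(pres) {
  n <- nrow(pres)
  vapply(seq_len(ncol(pres)), function(f) {
    k <- sum(pres[, f])
    if (k * 100 >= 99 * n) "core"
    else if (k * 100 >= 95 * n) "soft_core"
    else if (k * 100 >= 15 * n) "shell"
    else "cloud"
  }, "")
}

# mean pair fluidity by explicit double loop
oracle_fluidity <- function(pres) {
  n <- nrow(pres)
  vals <- c()
  for (k in seq_len(n - 1L)) {
    for (l in seq.int(k + 1L, n)) {
      uk <- sum(pres[k, ] & !pres[l, ])
      ul <- sum(pres[l, ] & !pres[k, ])
      vals <- c(vals, (uk + ul) / (sum(pres[k, ]) + sum(pres[l, ])))
    }
  }
  mean(vals)
}

# minimum extra mutations for two sites over all unrooted topologies
# (exhaustive parsimony search; independent of the E - V + C path)
oracle_incompatibility <- function(site_i, site_j) {
  stopifnot(requireNamespace("phangorn", quietly = TRUE))
  n <- length(site_i)
  m <- rbind(site_i, site_j)
  colnames(m) <- paste0("t", seq_len(n))
  dat <- phangorn::phyDat(t(m), type = "DNA")
  trees <- phangorn::allTrees(n, rooted = FALSE,
                              tip.label = colnames(m))
  best <- min(vapply(trees, function(tr) phangorn::parsimony(tr, dat),
                     numeric(1L)))
  min_changes <- (length(unique(site_i)) - 1L) +
    (length(unique(site_j)) - 1L)
  best - min_changes
}

# alignment from explicit columns (list of per-site character vectors)
alignment_from_columns <- function(cols, ids = NULL) {
  m <- do.call(cbind, cols)
  ids <- ids %||% sprintf("s%02d", seq_len(nrow(m)))
  site_alignment(ids, apply(m, 1L, paste, collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
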