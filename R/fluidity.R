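# Genomic fluidity: gene-content dissimilarity between genome pairs.

#' Genomic fluidity
#'
#' For a pair of genomes k and l, the pair fluidity is
#' `phi_kl = (U_k + U_l) / (M_k + M_l)`, where `U_k` is the number of
#' families in genome k absent from l and `M_k` the number of families in
#' k. `phi` is the mean pair fluidity: 0 means identical gene content, 1
#' disjoint. `all_pairs` mode averages over all `N(N-1)/2` unordered
#' pairs; `subsample` mode averages over `n_pairs` pairs drawn uniformly
#' with replacement from a seeded generator.
#'
#' @param x A [pan_matrix()] with at least 2 genomes.
#' @param mode `"all_pairs"` (default) or `"subsample"`.
#' @param n_pairs Number of sampled pairs (subsample mode).
#' @param seed Integer seed (subsample mode).
#' @return An object of class `fluidity_result` with fields `phi`, `mode`,
#'   `n_pairs_used`, `pair_variance` and `seed`.
#' @export
genomic_fluidity <- function(x, mode = c("all_pairs", "subsample"),
                             n_pairs = 1000L, seed = 1L) {
  stopifnot(inherits(x, "pan_matrix"))
  mode <- match.arg(mode)
  pres <- x$presence
  n <- nrow(pres)
  if (n < 2L) param_error("fluidity needs at least 2 genomes")
  m <- rowSums(pres)
  shared <- tcrossprod(pres * 1)               # N x N common-family counts
  msum <- outer(m, m, "+")
  phi_mat <- (msum - 2 * shared) / msum
  if (mode == "all_pairs") {
    vals <- phi_mat[upper.tri(phi_mat)]
    seed_used <- NA_integer_
  } else {
    if (n_pairs < 1L) param_error("n_pairs must be >= 1 in subsample mode")
    set.seed(seed)
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)             # uniform over ordered pairs
    vals <- phi_mat[cbind(i, j)]
    seed_used <- seed
  }
  structure(list(phi = mean(vals), mode = mode, n_pairs_used = length(vals),
                 pair_variance = if (length(vals) > 1L) stats::var(vals) else 0,
                 seed = seed_used),
            class = "fluidity_result")
}

#' @export
print.fluidity_result <- function(x, ...) {
  cat(sprintf("Genomic fluidity phi = %.4f (%s, %d pairs, var %.2g)\n",
              x$phi, x$mode, x$n_pairs_used, x$pair_variance))
  invisible(x)
}
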