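# Pairwise homoplasy index (PHI) and its permutation test.

# Nucleotide codes: A=1 C=2 G=3 T=4; gaps, N and anything else are 0 and
# are ignored (pairwise deletion when sites are compared).
.aln_codes <- function(aln) {
  m <- alignment_matrix(aln)
  codes <- match(m, c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L
  dim(codes) <- dim(m)
  codes
}

#' Parsimony-informative sites of an alignment
#'
#' A column is informative iff, ignoring gaps and N, it carries at least
#' two distinct states each observed in at least two sequences.
#'
#' @param aln A [site_alignment()].
#' @return Integer vector of 1-based column positions.
#' @export
informative_sites <- function(aln) {
  stopifnot(inherits(aln, "site_alignment"))
  codes <- .aln_codes(aln)
  tallies <- vapply(1:4, function(s) colSums(codes == s),
                    numeric(ncol(codes)))
  if (ncol(codes) == 1L) tallies <- matrix(tallies, nrow = 1L)
  which(rowSums(tallies >= 2L) >= 2L)
}

#' Refined incompatibility score of two alignment columns
#'
#' The parsimony lower bound on extra mutations needed to explain the two
#' sites on one genealogy: build the bipartite graph whose vertices are
#' the states observed at each site (after pairwise deletion of sequences
#' with a gap or N at either column) and whose edges are the distinct
#' observed joint state pairs; the score is `E - V + C` (edges minus
#' vertices plus connected components). For two binary sites it is 1
#' exactly when all four gametes occur (the classic four-gamete test),
#' else 0; compatible sites always score 0.
#'
#' @param site_i,site_j Character vectors: two columns of the same
#'   alignment (one entry per sequence).
#' @return Non-negative integer score, or `NA` when fewer than two
#'   sequences remain after pairwise deletion.
#' @export
refined_incompatibility <- function(site_i, site_j) {
  ci <- match(toupper(site_i), c("A", "C", "G", "T"))
  cj <- match(toupper(site_j), c("A", "C", "G", "T"))
  ci[is.na(ci)] <- 0L
  cj[is.na(cj)] <- 0L
  .ri_pair(ci, cj)
}

.ri_pair <- function(ci, cj) {
  ok <- ci > 0L & cj > 0L
  if (sum(ok) < 2L) return(NA_real_)
  joint <- unique(ci[ok] * 5L + cj[ok])
  ja <- joint %/% 5L
  jb <- joint %% 5L
  va <- unique(ja)
  vb <- unique(jb)
  nv <- length(va) + length(vb)
  # connected components of the bipartite state graph (tiny; union-find)
  parent <- seq_len(nv)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_along(joint)) {
    ra <- root(match(ja[e], va))
    rb <- root(length(va) + match(jb[e], vb))
    if (ra != rb) parent[rb] <- ra
  }
  comps <- length(unique(vapply(seq_len(nv), root, integer(1L))))
  length(joint) - nv + comps
}

# S x S symmetric matrix of incompatibility scores over the given
# informative-site columns (codes: n x S). Binary-by-binary pairs are
# scored by the vectorized four-gamete test (crossproducts of state
# indicators); pairs involving a site with >2 observed states fall back to
# the general E - V + C computation. NA marks pairs with < 2 usable
# sequences.
.phi_score_matrix <- function(codes) {
  S <- ncol(codes)
  n_states <- vapply(seq_len(S), function(s) {
    length(unique(codes[codes[, s] > 0L, s]))
  }, integer(1L))
  sm <- matrix(NA_real_, S, S)
  bin <- which(n_states == 2L)
  if (length(bin) >= 2L) {
    Mm <- Pm <- matrix(0, nrow(codes), length(bin))
    for (k in seq_along(bin)) {
      col <- codes[, bin[k]]
      st <- sort(unique(col[col > 0L]))
      cnt <- c(sum(col == st[1L]), sum(col == st[2L]))
      minor <- st[which.min(cnt)]
      Mm[, k] <- col == minor
      Pm[, k] <- col > 0L & col != minor
    }
    n11 <- crossprod(Mm)
    n12 <- crossprod(Mm, Pm)
    n22 <- crossprod(Pm)
    tot <- n11 + n12 + t(n12) + n22
    sc <- (n11 > 0) * (n12 > 0) * (t(n12) > 0) * (n22 > 0)
    sc[tot < 2] <- NA_real_
    sm[bin, bin] <- sc
  }
  multi <- which(n_states > 2L)
  for (u in multi) {
    for (v in seq_len(S)) {
      if (v == u) next
      sm[u, v] <- sm[v, u] <- .ri_pair(codes[, u], codes[, v])
    }
  }
  diag(sm) <- 0
  sm
}

# informative positions, their codes and the score matrix, shared by
# phi_statistic and phi_test
.phi_prepare <- function(aln) {
  pos <- informative_sites(aln)
  if (length(pos) < 2L)
    analysis_error("PHI undefined: fewer than 2 informative sites")
  codes <- .aln_codes(aln)[, pos, drop = FALSE]
  list(pos = pos, scores = .phi_score_matrix(codes))
}

# index pairs (u < v) of informative sites whose column distance is <= w;
# falls back to all pairs (with a warning) when none qualify
.phi_window_pairs <- function(pos, w) {
  S <- length(pos)
  idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  near <- abs(pos[idx[, 2L]] - pos[idx[, 1L]]) <= w
  if (!any(near)) {
    warning("no informative-site pair within window w = ", w,
            "; using all pairs")
    return(idx)
  }
  idx[near, , drop = FALSE]
}

#' The pairwise homoplasy index
#'
#' `Phi_w` is the mean [refined_incompatibility()] score over all
#' unordered pairs of informative sites whose distance in original
#' alignment columns is at most `w`. Under clonal evolution all sites
#' share one genealogy and nearby pairs are no more compatible than
#' distant ones; recombination makes nearby sites relatively compatible
#' while distant pairs accumulate conflicting histories.
#'
#' @param aln A [site_alignment()] with at least two informative sites.
#' @param w Window width in alignment columns (default 100).
#' @return The observed statistic (non-negative real).
#' @export
phi_statistic <- function(aln, w = 100L) {
  prep <- .phi_prepare(aln)
  pairs <- .phi_window_pairs(prep$pos, w)
  mean(prep$scores[pairs], na.rm = TRUE)
}

#' Permutation test of recombination with the PHI statistic
#'
#' Recomputes `Phi_w` after uniformly permuting the positions of the
#' informative sites (their pairwise scores are unchanged; only the
#' distances are reshuffled), `n_permutations` times. The p-value is
#' one-sided toward small observed values,
#' `p = (1 + #\{permuted Phi_w <= observed\}) / (1 + n_permutations)`,
#' so `p` is always in `(0, 1]`.
#'
#' @inheritParams phi_statistic
#' @param n_permutations Number of site permutations (>= 1; default 1000).
#' @param seed Integer seed for the permutation generator.
#' @return An object of class `phi_result` with fields `phi_observed`,
#'   `window_w`, `n_informative`, `n_pairs`, `p_value`, `n_permutations`
#'   and `seed`.
#' @export
phi_test <- function(aln, w = 100L, n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 1L) param_error("n_permutations must be >= 1")
  prep <- .phi_prepare(aln)
  pairs <- .phi_window_pairs(prep$pos, w)
  obs <- mean(prep$scores[pairs], na.rm = TRUE)
  S <- length(prep$pos)
  set.seed(seed)
  perm_vals <- vapply(seq_len(n_permutations), function(.) {
    p <- sample.int(S)
    mean(prep$scores[cbind(p[pairs[, 1L]], p[pairs[, 2L]])], na.rm = TRUE)
  }, numeric(1L))
  b <- sum(perm_vals <= obs + 1e-12)
  structure(list(phi_observed = obs, window_w = w, n_informative = S,
                 n_pairs = nrow(pairs),
                 p_value = (1 + b) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("PHI test: Phi_w = %.4f (w = %d, %d informative sites, %d pairs)\n",
              x$phi_observed, x$window_w, x$n_informative, x$n_pairs))
  cat(sprintf("  p = %.4g from %d permutations (seed %d)\n",
              x$p_value, x$n_permutations, x$seed))
  invisible(x)
}
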