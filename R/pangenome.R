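# Gene-family classification, pan-genome summary and accumulation curves.

#' Classify gene families by occupancy
#'
#' A family present in `k` of `N` genomes is `core` when `k/N >= 0.99`,
#' `soft_core` when `0.95 <= k/N < 0.99`, `shell` when
#' `0.15 <= k/N < 0.95` and `cloud` when `k/N < 0.15` (defaults; the
#' breakpoints are configurable). Comparisons are made in exact rational
#' arithmetic so boundary occupancies are decided deterministically: at
#' `N = 32`, core means 32/32 genomes and 31/32 (96.9%) is soft core.
#'
#' @param x A [pan_matrix()].
#' @param thresholds Named numeric breakpoints
#'   `c(cloud = 0.15, soft_core = 0.95, core = 0.99)`; must be strictly
#'   increasing within `(0, 1]`.
#' @return A factor over families with levels
#'   `core, soft_core, shell, cloud`.
#' @export
classify_families <- function(x, thresholds = c(cloud = 0.15, soft_core = 0.95,
                                                core = 0.99)) {
  stopifnot(inherits(x, "pan_matrix"))
  t <- thresholds[c("cloud", "soft_core", "core")]
  if (anyNA(t) || any(t <= 0) || any(t > 1) || any(diff(t) <= 0))
    param_error("thresholds must satisfy 0 < cloud < soft_core < core <= 1")
  k <- colSums(x$presence)
  n <- nrow(x$presence)
  cat <- ifelse(frac_ge(k, n, t[["core"]]), "core",
         ifelse(frac_ge(k, n, t[["soft_core"]]), "soft_core",
         ifelse(frac_ge(k, n, t[["cloud"]]), "shell", "cloud")))
  factor(cat, levels = c("core", "soft_core", "shell", "cloud"))
}

#' Summarize pan-genome composition
#'
#' Counts families per occupancy category (at the default thresholds of
#' [classify_families()] unless overridden), singletons (families in
#' exactly one genome), category percentages of the pan-genome, and each
#' genome's fraction of core families.
#'
#' @inheritParams classify_families
#' @return An object of class `pangenome_summary` with fields `n_core`,
#'   `n_soft_core`, `n_shell`, `n_cloud`, `n_pan`, `n_singletons`,
#'   `pct_core`, `pct_core_plus_soft`, `pct_singletons` and
#'   `per_genome_core_fraction`.
#' @export
summarize_pangenome <- function(x, thresholds = c(cloud = 0.15,
                                                  soft_core = 0.95,
                                                  core = 0.99)) {
  cls <- classify_families(x, thresholds)
  counts <- table(cls)
  n_pan <- ncol(x$presence)
  occ <- colSums(x$presence)
  core_cols <- cls == "core"
  per_genome <- rowSums(x$presence[, core_cols, drop = FALSE]) /
    rowSums(x$presence)
  out <- list(
    n_core = unname(counts[["core"]]),
    n_soft_core = unname(counts[["soft_core"]]),
    n_shell = unname(counts[["shell"]]),
    n_cloud = unname(counts[["cloud"]]),
    n_pan = n_pan,
    n_singletons = sum(occ == 1L),
    pct_core = 100 * counts[["core"]] / n_pan,
    pct_core_plus_soft = 100 * (counts[["core"]] + counts[["soft_core"]]) / n_pan,
    pct_singletons = 100 * sum(occ == 1L) / n_pan,
    per_genome_core_fraction = per_genome,
    thresholds = thresholds)
  class(out) <- "pangenome_summary"
  out
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat("Pan-genome of", x$n_pan, "gene families\n")
  cat(sprintf("  core       %6d  (%.1f%%)\n", x$n_core, x$pct_core))
  cat(sprintf("  soft core  %6d  (core+soft %.1f%%)\n", x$n_soft_core,
              x$pct_core_plus_soft))
  cat(sprintf("  shell      %6d\n", x$n_shell))
  cat(sprintf("  cloud      %6d  (singletons %d, %.1f%%)\n", x$n_cloud,
              x$n_singletons, x$pct_singletons))
  cat(sprintf("  core fraction per genome: %.2f-%.2f\n",
              min(x$per_genome_core_fraction),
              max(x$per_genome_core_fraction)))
  invisible(x)
}

#' Gene accumulation curves over random genome orderings
#'
#' For each of `n_permutations` random orderings of the genomes, tracks as
#' genomes are added one at a time: the pan-genome size (families seen so
#' far), the core size (families present in every genome so far, strict
#' intersection), the number of new families contributed by the g-th
#' genome, and the number of families seen in exactly one genome so far.
#'
#' @param x A [pan_matrix()].
#' @param n_permutations Number of random orderings (>= 1).
#' @param seed Integer seed for the ordering generator.
#' @param core_min_count Optional integer: relax the core curve so that at
#'   step `g` a family counts as core when carried by at least
#'   `g - (N - core_min_count)` of the first `g` genomes (e.g.,
#'   `core_min_count = N - 1` reproduces the "present in at least N-1
#'   strains" reading). `NULL` (default) is strict intersection.
#' @return An object of class `accumulation_curves` holding
#'   `n_permutations x N` matrices `pan_sizes`, `core_sizes`, `new_genes`
#'   and `unique_genes`.
#' @export
accumulation_curves <- function(x, n_permutations = 100L, seed = 1L,
                                core_min_count = NULL) {
  stopifnot(inherits(x, "pan_matrix"))
  if (n_permutations < 1L) param_error("n_permutations must be >= 1")
  pres <- x$presence
  n <- nrow(pres)
  allow <- if (is.null(core_min_count)) 0L else {
    if (core_min_count < 1L || core_min_count > n)
      param_error("core_min_count must be in 1..N")
    n - as.integer(core_min_count)
  }
  pan <- core <- newg <- uniq <- matrix(0L, n_permutations, n)
  set.seed(seed)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n)
    cum <- apply(pres[ord, , drop = FALSE], 2L, cumsum)  # g x G carrier counts
    if (n == 1L) cum <- matrix(cum, nrow = 1L)
    g <- seq_len(n)
    pan[p, ] <- rowSums(cum > 0L)
    core[p, ] <- rowSums(cum >= pmax(1L, g - allow))
    uniq[p, ] <- rowSums(cum == 1L)
    newg[p, ] <- c(pan[p, 1L], diff(pan[p, ]))
  }
  structure(list(n_permutations = n_permutations, seed = seed,
                 pan_sizes = pan, core_sizes = core, new_genes = newg,
                 unique_genes = uniq),
            class = "accumulation_curves")
}

#' @export
print.accumulation_curves <- function(x, ...) {
  n <- ncol(x$pan_sizes)
  cat("Accumulation curves:", x$n_permutations, "permutations of", n,
      "genomes (seed", paste0(x$seed, ")\n"))
  cat(sprintf("  mean pan size at N: %.1f; mean core at N: %.1f\n",
              mean(x$pan_sizes[, n]), mean(x$core_sizes[, n])))
  invisible(x)
}
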