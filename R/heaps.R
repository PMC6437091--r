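# Heaps' law fit: openness of the pan-genome from new-gene decay.

#' Fit Heaps' law to new-gene counts
#'
#' Models the number of previously unseen gene families contributed by the
#' g-th genome as `new(g) = kappa * g^(-alpha)` and fits kappa and the
#' decay parameter alpha by nonlinear least squares on the raw counts,
#' pooling the points `(g, new_genes[g])` for `g >= 2` across all
#' permutations of an [accumulation_curves()] object. The fit is
#' initialized from a log-log regression on the per-g mean counts (zero
#' means are excluded from the initialization only). `alpha < 1` indicates
#' an open pan-genome (unbounded growth under Heaps' law), `alpha > 1` a
#' closed one.
#'
#' @param curves An [accumulation_curves()] object over at least 3
#'   genomes.
#' @return An object of class `heaps_fit` with fields `kappa`, `alpha`,
#'   `verdict` (`"open"`, `"closed"` or `"boundary"`), `n_points` and
#'   `residual_ss`.
#' @export
fit_heaps <- function(curves) {
  stopifnot(inherits(curves, "accumulation_curves"))
  n <- ncol(curves$new_genes)
  if (n < 3L) param_error("Heaps fit needs at least 3 genomes")
  g <- rep(2:n, each = nrow(curves$new_genes))
  y <- as.vector(curves$new_genes[, 2:n])
  if (all(y == 0)) {
    warning("no new genes beyond the first genome; pan-genome is trivially closed")
    return(structure(list(kappa = 0, alpha = Inf, verdict = "closed",
                          n_points = length(y), residual_ss = 0,
                          degenerate = TRUE),
                     class = "heaps_fit"))
  }
  ybar <- tapply(y, g, mean)
  gg <- as.numeric(names(ybar))
  pos <- ybar > 0
  init <- stats::lm(log(ybar[pos]) ~ log(gg[pos]))
  start <- list(kappa = exp(stats::coef(init)[[1L]]),
                alpha = max(1e-3, -stats::coef(init)[[2L]]))
  fit <- minpack.lm::nlsLM(y ~ kappa * g^(-alpha), start = start,
                           lower = c(kappa = 1e-9, alpha = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  alpha <- est[["alpha"]]
  tol <- 1e-9
  verdict <- if (alpha < 1 - tol) "open" else if (alpha > 1 + tol) "closed"
             else "boundary"
  structure(list(kappa = est[["kappa"]], alpha = alpha, verdict = verdict,
                 n_points = length(y),
                 residual_ss = sum(stats::resid(fit)^2),
                 degenerate = FALSE),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps' law fit: new(g) = %.1f * g^(-%.3f)\n", x$kappa, x$alpha))
  cat(sprintf("  alpha = %.3f -> %s pan-genome (%d points, RSS %.1f)\n",
              x$alpha, x$verdict, x$n_points, x$residual_ss))
  invisible(x)
}
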