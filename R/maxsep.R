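## MAX SEP: reduce linear degeneracy among trained components by maximal
## pairwise subtraction, yielding "simple structure" PMFs attributable to
## physical sub-spectra.

#' Subtract the maximum feasible amount of one PMF from another
#'
#' Finds `alpha = max{a >= 0 : target - a * other >= 0 in every bin}` and
#' returns the renormalised difference.  If the subtraction would leave
#' less than `mass_floor` of the target's probability mass (near-duplicate
#' components), the target is returned unchanged with `alpha = 0`.
#'
#' @param target,other Numeric PMF vectors of equal length (sum to 1).
#' @param mass_floor Minimum surviving mass fraction, in `(0, 1)`.
#' @return A list with `pmf` (the new PMF) and `alpha` (fraction
#'   subtracted).
#' @export
max_subtract <- function(target, other, mass_floor = 0.05) {
  target <- as.numeric(target)
  other <- as.numeric(other)
  if (length(target) != length(other)) stop("dimension mismatch")
  check_pmf_matrix(cbind(target, other))
  sup <- other > 0
  if (!any(sup)) return(list(pmf = target, alpha = 0))
  alpha <- min(target[sup] / other[sup])
  if (alpha <= 0) return(list(pmf = target, alpha = 0))
  residual <- pmax(target - alpha * other, 0)
  mass <- sum(residual)
  if (mass < mass_floor) return(list(pmf = target, alpha = 0))
  list(pmf = residual / mass, alpha = alpha)
}

#' Separate components by repeated maximal pairwise subtraction (MAX SEP)
#'
#' Sweeps over all ordered component pairs, subtracting from each component
#' the maximum feasible amount of every other, until the largest
#' subtraction in a sweep drops below `tol` or `max_sweeps` is reached.
#' Outputs remain valid PMFs and span the same fitted model hyperplane
#' (each input is a non-negative combination of the outputs), so corpus
#' likelihood is preserved on refit; the zero-bin structure becomes
#' monotonically sparser, moving components towards the "simple structure"
#' criteria of factor analysis.
#'
#' @param components Bins x K matrix of component PMFs, K >= 2.
#' @param weights Optional total fitted weight per component; pairs are
#'   swept in descending weight order (dominant structure first).  Default
#'   is column order.
#' @param max_sweeps Maximum full sweeps.
#' @param tol Convergence threshold on the largest `alpha` in a sweep.
#' @param mass_floor Passed to [max_subtract()].
#' @return Bins x K matrix of separated PMFs, with attribute `sweeps`.
#' @export
max_sep <- function(components, weights = NULL, max_sweeps = 100,
                    tol = 1e-6, mass_floor = 0.05) {
  P <- check_pmf_matrix(components)
  K <- ncol(P)
  if (K < 2L) stop("at least two components required")
  ord <- if (is.null(weights)) seq_len(K) else order(weights,
                                                     decreasing = TRUE)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    max_alpha <- 0
    for (j in ord) {
      for (k in ord) {
        if (j == k) next
        res <- max_subtract(P[, j], P[, k], mass_floor = mass_floor)
        P[, j] <- res$pmf
        max_alpha <- max(max_alpha, res$alpha)
      }
    }
    if (max_alpha < tol || sweeps >= max_sweeps) break
  }
  ## snap numerically negligible probabilities to exact zeros so the
  ## zero-structure criteria (and downstream empty-bin handling) are clean
  P[P < PMF_SNAP] <- 0
  P <- sweep(P, 2L, colSums(P), "/")
  attr(P, "sweeps") <- sweeps
  P
}

#' Simple-structure diagnostics for a component set
#'
#' Reports, per component, the count of (near-)zero bins, and per ordered
#' pair, the count of contrast bins (zero loading in one component, large
#' loading - above that component's mean bin probability - in the other),
#' together with flags for the factor-analysis simple-structure criteria:
#' every component has at least K zero bins, and every pair has at least
#' one contrast bin each way.
#'
#' @param components Bins x K matrix of component PMFs.
#' @param zero_tol Probability below which a bin counts as zero.
#' @return A list with `zeros` (per-component zero counts), `contrast`
#'   (K x K matrix; entry jk counts bins zero in j and large in k),
#'   `zeros_ok`, `contrast_ok`, `criteria_met`.
#' @export
simplicity_report <- function(components, zero_tol = 1e-6) {
  P <- check_pmf_matrix(components)
  K <- ncol(P)
  zero <- P < zero_tol
  large <- sweep(P, 2L, colMeans(P), ">")
  contrast <- matrix(0L, K, K)
  for (j in seq_len(K)) for (k in seq_len(K)) {
    if (j != k) contrast[j, k] <- sum(zero[, j] & large[, k])
  }
  zeros <- colSums(zero)
  zeros_ok <- all(zeros >= K)
  contrast_ok <- K < 2L ||
    all(contrast[upper.tri(contrast)] > 0 | t(contrast)[upper.tri(contrast)] > 0)
  list(zeros = zeros, contrast = contrast, zeros_ok = zeros_ok,
       contrast_ok = contrast_ok,
       criteria_met = zeros_ok && contrast_ok)
}

#' Apply MAX SEP to a trained model and refit its training weights
#'
#' @param model An `lpm_model`.
#' @param corpus The training corpus (for weight-ordered sweeps and the
#'   refit).
#' @param ... Passed to [max_sep()].
#' @return A new `lpm_model` with separated components and refitted
#'   weights/goodness-of-fit.
#' @export
max_sep_model <- function(model, corpus, ...) {
  stopifnot(inherits(model, "lpm_model"))
  w <- if (is.null(model$weights)) NULL else colSums(model$weights)
  P <- max_sep(model$components, weights = w, ...)
  refit <- fit_corpus(corpus, P)
  H <- corpus_counts(corpus)
  Q <- do.call(rbind, lapply(refit$fits, function(f) f$weights))
  out <- model
  out$components <- P
  out$weights <- Q
  out$loglik <- refit$loglik
  out$chi2_per_dof <- refit$chi2_per_dof
  out
}
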