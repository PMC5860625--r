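## Linear Poisson Models: histograms modelled as non-negative weighted sums
## of probability-mass-function components with independent Poisson bin
## noise, estimated by expectation-maximisation.

PMF_FLOOR <- 1e-12     # probability floor during EM iterations
PMF_SNAP <- 1e-7       # final hard-zero threshold; must clear the EM
                       # probability floor even after MAX SEP
                       # renormalisations inflate it
WEIGHT_SNAP <- 1e-8    # relative weight below which a boundary (zero)
                       # EM solution is snapped to exact zero
CHI2_FLOOR <- 1e-6     # denominator floor in the goodness-of-fit

#' Expected histogram under a Linear Poisson Model
#'
#' `m_i = sum_k Q_k P(i|k)`: the model-predicted events per bin for given
#' component weights.  Because every component sums to one,
#' `sum(m) == sum(Q)` exactly.
#'
#' @param weights Non-negative weight per component (events).
#' @param components Bins x K matrix of component PMFs (columns sum to 1).
#' @return Numeric vector of expected events per bin.
#' @export
expected_histogram <- function(weights, components) {
  P <- check_pmf_matrix(components)
  if (length(weights) != ncol(P))
    stop("one weight per component required")
  if (any(weights < 0)) stop("weights must be non-negative")
  as.numeric(P %*% weights)
}

#' Poisson log-likelihood of a histogram given expected values
#'
#' Returns `sum_i [h_i log(m_i) - m_i]` (constant `-log(h_i!)` terms
#' dropped), with the convention `0 * log(0) = 0`.  A bin with `m_i = 0`
#' but `h_i > 0` yields `-Inf`.
#'
#' @param counts Observed events per bin, >= 0.
#' @param expected Model-expected events per bin, >= 0.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
poisson_loglik <- function(counts, expected) {
  if (length(counts) != length(expected))
    stop("counts and expected must have equal length")
  if (any(counts < 0) || any(expected < 0))
    stop("counts and expected must be non-negative")
  if (any(counts > 0 & expected == 0)) return(-Inf)
  pos <- counts > 0
  sum(counts[pos] * log(expected[pos])) - sum(expected)
}

## Internal vectorised EM weight update for fixed components.
## H: S x I counts, P: I x K pmfs, Q: S x K weights. One multiplicative step.
em_weight_step <- function(H, P, Q) {
  M <- Q %*% t(P)
  R <- ifelse(M > 0, H / M, 0)
  Q * (R %*% P)
}

#' Fit non-negative component weights to one histogram by EM
#'
#' Maximises the Poisson likelihood of the histogram over non-negative
#' component weights with the components held fixed, using the canonical
#' multiplicative EM update (responsibilities
#' `r_ik = Q_k P(i|k) / sum_j Q_j P(i|j)`, then `Q_k <- sum_i h_i r_ik`),
#' which never decreases the likelihood.  The weight covariance is the
#' inverse observed Fisher information at the solution (see
#' [propagate_weight_errors()]), optionally scaled by a goodness-of-fit.
#'
#' @param histogram A [peak_histogram()] or a numeric count vector.
#' @param components Bins x K matrix of component PMFs.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param chi2_scale Goodness-of-fit used to scale the covariance when it
#'   exceeds 1 (default 1: pure Poisson covariance).
#' @param trace Record the log-likelihood at every EM iteration (returned
#'   as `loglik_trace`).
#' @return An object of class `spectrum_fit`: `weights`, `expected`,
#'   `loglik`, `covariance`, `chi2_per_dof` (per-spectrum, dof = bins - K),
#'   `iterations`, `converged`.
#' @export
fit_weights <- function(histogram, components, tol = 1e-10,
                        max_iter = 10000, chi2_scale = 1, trace = FALSE) {
  h <- if (inherits(histogram, "peak_histogram")) histogram$counts
       else as.numeric(histogram)
  P <- check_pmf_matrix(components)
  if (nrow(P) != length(h)) stop("bin dimension mismatch")
  if (any(colSums(P > 0) == 0))
    stop("component with zero probability everywhere")
  K <- ncol(P)
  total <- sum(h)
  if (total == 0) {
    fit <- list(weights = numeric(K), expected = numeric(length(h)),
                loglik = 0, covariance = matrix(0, K, K),
                chi2_per_dof = 0, iterations = 0L, converged = TRUE)
    class(fit) <- "spectrum_fit"
    return(fit)
  }
  Pf <- pmax(P, PMF_FLOOR)
  H <- matrix(h, nrow = 1L)
  Q <- matrix(total / K, nrow = 1L, ncol = K)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  ll_trace <- if (trace) numeric(0) else NULL
  while (it < max_iter) {
    it <- it + 1L
    Q <- em_weight_step(H, Pf, Q)
    ll <- poisson_loglik(h, as.numeric(Pf %*% Q[1L, ]))
    if (trace) ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  w <- as.numeric(Q[1L, ])
  ## multiplicative EM approaches boundary (zero-weight) optima only
  ## asymptotically; move a small weight to the exact boundary when the
  ## likelihood gradient there is non-positive (zero is the optimum)
  for (k in order(w)) {
    if (w[k] == 0 || w[k] >= 1e-3 * sum(w)) next
    w_try <- w
    w_try[k] <- 0
    m_try <- as.numeric(P %*% w_try)
    if (any(h > 0 & m_try <= 0)) next
    use <- m_try > 0 & h > 0
    grad <- sum(P[use, k] * h[use] / m_try[use]) - 1
    if (grad <= 0) w <- w_try
  }
  expd <- as.numeric(P %*% w)
  chi2 <- chi2_stat(h, expd)
  dof <- length(h) - K
  cov <- propagate_weight_errors(h, P, w, chi2_scale = chi2_scale)
  fit <- list(weights = w, expected = expd,
              loglik = poisson_loglik(h, as.numeric(Pf %*% w)),
              covariance = cov,
              chi2_per_dof = if (dof > 0) chi2 / dof else NA_real_,
              iterations = it, converged = converged,
              loglik_trace = ll_trace)
  class(fit) <- "spectrum_fit"
  fit
}

## Pearson chi-square statistic with a floored denominator.
chi2_stat <- function(h, m, floor = CHI2_FLOOR) {
  sum((h - m)^2 / pmax(m, floor))
}

#' Train LP-ICA components on a corpus of histograms
#'
#' Jointly estimates K shared component PMFs and per-spectrum non-negative
#' weights maximising the summed Poisson likelihood over the corpus, by
#' alternating multiplicative EM updates (the Poisson-compatible form of
#' independent component analysis).  Components are initialised from the
#' corpus-mean PMF with seeded Dirichlet-style jitter; the corpus
#' log-likelihood is non-decreasing across iterations and the result is a
#' deterministic function of `seed`.
#'
#' @param corpus List of [peak_histogram()] objects on shared bins.
#' @param K Model order (number of components), `1 <= K <= bins`.
#' @param seed Integer RNG seed for the initialisation.
#' @param tol Relative corpus log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param trace Record the corpus log-likelihood at every EM iteration
#'   (returned as `loglik_trace`).
#' @return An object of class `lpm_model`: `components` (bins x K matrix),
#'   `centroids`, `K`, `weights` (S x K training weights), `loglik`,
#'   `chi2_per_dof` (training goodness-of-fit), `seed`, `iterations`,
#'   `converged`.
#' @export
train_components <- function(corpus, K, seed = 1, tol = 1e-8,
                             max_iter = 10000, trace = FALSE) {
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  H <- corpus_counts(corpus)
  I <- ncol(H)
  S <- nrow(H)
  if (K < 1L || K > I) stop("K must lie in [1, number of bins]")
  mean_pmf <- colSums(H)
  if (sum(mean_pmf) == 0) stop("corpus carries no events")
  mean_pmf <- mean_pmf / sum(mean_pmf)
  with_seed(seed, {
    P <- vapply(seq_len(K), function(k) {
      p <- mean_pmf * stats::rgamma(I, shape = 5, rate = 5)
      p <- pmax(p, ifelse(mean_pmf > 0, PMF_FLOOR, 0))
      p / sum(p)
    }, numeric(I))
    P <- matrix(P, nrow = I, ncol = K)
    Q <- matrix(rowSums(H) / K, nrow = S, ncol = K)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    ll_trace <- if (trace) numeric(0) else NULL
    while (it < max_iter) {
      it <- it + 1L
      M <- Q %*% t(P)
      R <- ifelse(M > 0, H / M, 0)
      Q <- Q * (R %*% P)
      M <- Q %*% t(P)
      R <- ifelse(M > 0, H / M, 0)
      ## constrained M-step: P(i|k) proportional to the responsibility-
      ## weighted counts, renormalised to a PMF (sum(m) = sum(Q) is
      ## preserved because every column still sums to 1)
      P <- P * (t(R) %*% Q)
      cs <- colSums(P)
      cs[cs == 0] <- 1
      P <- sweep(P, 2L, cs, "/")
      P <- pmax(P, ifelse(matrix(mean_pmf > 0, I, K), PMF_FLOOR, 0))
      P <- sweep(P, 2L, colSums(P), "/")
      M <- Q %*% t(P)
      ll <- corpus_loglik(H, M)
      if (trace) ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-300)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    ## hard-zero pass so simple-structure (zero-bin) criteria are meaningful
    P[P < PMF_SNAP] <- 0
    P <- sweep(P, 2L, colSums(P), "/")
    for (r in 1:3) Q <- em_weight_step(H, pmax(P, PMF_FLOOR), Q)
    M <- Q %*% t(P)
    chi2 <- sum((H - M)^2 / pmax(M, CHI2_FLOOR))
    dof <- lpm_dof(S, I, K)
    model <- list(components = P, centroids = corpus[[1L]]$centroids,
                  K = K, weights = Q,
                  loglik = corpus_loglik(H, M),
                  chi2_per_dof = chi2 / dof, seed = seed,
                  iterations = it, converged = converged,
                  loglik_trace = ll_trace)
    class(model) <- "lpm_model"
    model
  })
}

corpus_loglik <- function(H, M) {
  pos <- H > 0
  if (any(pos & M == 0)) return(-Inf)
  sum(H[pos] * log(M[pos])) - sum(M)
}

## Degrees of freedom: total bins minus free parameters
## (K shared PMFs with I-1 free bins each, plus K weights per spectrum).
lpm_dof <- function(S, I, K) {
  dof <- S * I - K * (I - 1L) - K * S
  if (dof <= 0) stop("over-parameterised model: dof <= 0")
  dof
}

#' @export
print.lpm_model <- function(x, ...) {
  cat(sprintf(
    "lpm_model: K = %d components over %d bins, chi2/dof = %.3f (seed %d)\n",
    x$K, nrow(x$components), x$chi2_per_dof, x$seed))
  invisible(x)
}

#' Corpus goodness-of-fit per degree of freedom
#'
#' `sum over spectra and bins of (h_i - m_i)^2 / max(m_i, floor)`, divided
#' by the degrees of freedom `S*I - K*(I-1) - K*S` (shared PMF bins plus
#' per-spectrum weights are free parameters).  For pure Poisson counts at
#' gain g this converges to approximately g.
#'
#' @param corpus List of [peak_histogram()] objects.
#' @param model An `lpm_model`.
#' @param fits List of `spectrum_fit` objects, one per corpus spectrum.
#' @param floor Denominator floor preventing division by zero.
#' @return Scalar goodness-of-fit.
#' @export
chi2_per_dof <- function(corpus, model, fits, floor = CHI2_FLOOR) {
  if (length(fits) != length(corpus))
    stop("fits must correspond one-to-one with corpus")
  H <- corpus_counts(corpus)
  chi2 <- sum(vapply(seq_along(fits), function(s) {
    chi2_stat(H[s, ], fits[[s]]$expected, floor)
  }, numeric(1L)))
  chi2 / lpm_dof(nrow(H), ncol(H), model$K)
}

#' Fit every spectrum of a corpus against a trained model
#'
#' Runs [fit_weights()] for each histogram, computes the corpus
#' goodness-of-fit, and scales every weight covariance by the corpus
#' chi-square per degree of freedom when it exceeds 1 (never deflating
#' below the Poisson floor).
#'
#' @param corpus List of [peak_histogram()] objects.
#' @param model An `lpm_model` (or a bins x K PMF matrix).
#' @param tol,max_iter Passed to [fit_weights()].
#' @return A list with `fits` (list of `spectrum_fit`), `chi2_per_dof`,
#'   and `loglik` (summed).
#' @export
fit_corpus <- function(corpus, model, tol = 1e-10, max_iter = 10000) {
  P <- if (inherits(model, "lpm_model")) model$components else model
  fits <- lapply(corpus, fit_weights, components = P, tol = tol,
                 max_iter = max_iter)
  H <- corpus_counts(corpus)
  chi2 <- sum(vapply(seq_along(fits), function(s)
    chi2_stat(H[s, ], fits[[s]]$expected), numeric(1L)))
  dof <- lpm_dof(nrow(H), ncol(H), ncol(P))
  scale <- max(1, chi2 / dof)
  fits <- lapply(fits, function(f) {
    f$covariance <- f$covariance * scale
    f
  })
  list(fits = fits, chi2_per_dof = chi2 / dof,
       loglik = sum(vapply(fits, function(f) f$loglik, numeric(1L))))
}

#' Train with random restarts and keep the best local solution
#'
#' @param corpus List of [peak_histogram()] objects.
#' @param K Model order.
#' @param restarts Number of seeded attempts.
#' @param seed Base seed; attempt r uses `seed + r - 1`.
#' @param ... Passed to [train_components()].
#' @return A list with `best` (highest corpus log-likelihood `lpm_model`)
#'   and `models` (all attempts).
#' @export
train_restarts <- function(corpus, K, restarts = 50, seed = 1, ...) {
  models <- lapply(seq_len(restarts), function(r)
    train_components(corpus, K, seed = seed + r - 1L, ...))
  lls <- vapply(models, function(m) m$loglik, numeric(1L))
  list(best = models[[which.max(lls)]], models = models)
}

## Plateau rule: the curve has reached a minimum or flattened - the first
## order whose relative chi2/dof improvement to the next order falls below
## plateau_tol (a rise counts as a minimum reached).
plateau_select <- function(K_values, chi2_values, plateau_tol = 0.05) {
  stopifnot(length(K_values) == length(chi2_values), length(K_values) > 0)
  n <- length(K_values)
  for (j in seq_len(n - 1L)) {
    rel_impr <- (chi2_values[j] - chi2_values[j + 1L]) / chi2_values[j]
    if (rel_impr < plateau_tol) return(K_values[j])
  }
  K_values[n]
}

#' Select the LP-ICA model order by the goodness-of-fit plateau rule
#'
#' Trains models over `K_range` (best of `restarts` seeded attempts per
#' order) and returns the smallest order at which the chi-square per
#' degree of freedom has reached a minimum or flattened onto a plateau:
#' the first order whose relative improvement to the next order drops
#' below `plateau_tol`.
#'
#' @param corpus List of [peak_histogram()] objects.
#' @param K_range Ascending candidate model orders.
#' @param restarts Seeded training attempts per order.
#' @param seed Base seed.
#' @param plateau_tol Relative tolerance defining the plateau.
#' @param ... Passed to [train_components()].
#' @return A list with `K` (selected order), `curve` (data frame `K`,
#'   `chi2_per_dof`, `loglik`), and `model` (best model at the selected
#'   order).
#' @export
select_model_order <- function(corpus, K_range, restarts = 5, seed = 1,
                               plateau_tol = 0.05, ...) {
  stopifnot(length(K_range) > 0, !is.unsorted(K_range))
  best_models <- vector("list", length(K_range))
  for (j in seq_along(K_range)) {
    best_models[[j]] <- train_restarts(corpus, K_range[j],
                                       restarts = restarts,
                                       seed = seed + 1000L * (j - 1L),
                                       ...)$best
  }
  curve <- data.frame(
    K = K_range,
    chi2_per_dof = vapply(best_models, function(m) m$chi2_per_dof,
                          numeric(1L)),
    loglik = vapply(best_models, function(m) m$loglik, numeric(1L)))
  Kstar <- plateau_select(curve$K, curve$chi2_per_dof, plateau_tol)
  list(K = Kstar, curve = curve,
       model = best_models[[match(Kstar, K_range)]])
}
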