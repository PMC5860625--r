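## Error theory: Poisson sampling noise propagated to weight covariances,
## pull-distribution validation, and Bland-Altman power-law noise
## characterisation.

#' Propagate Poisson bin noise to a component-weight covariance
#'
#' The covariance of the fitted weights is the inverse of the observed
#' Fisher information of the Poisson likelihood evaluated at the solution,
#' `J_kl = sum_i h_i P(i|k) P(i|l) / m_i^2`, optionally inflated by the
#' model goodness-of-fit when it exceeds 1 (accounting for residual
#' unmodelled structure; never deflated below the Poisson floor).  A
#' singular information matrix falls back to the Moore-Penrose
#' pseudo-inverse with a warning, flagged in attribute `pseudo_inverse`.
#'
#' @param histogram A [peak_histogram()] or numeric count vector.
#' @param components Bins x K matrix of component PMFs.
#' @param weights Fitted weights (a likelihood stationary point).
#' @param chi2_scale Goodness-of-fit; the covariance is multiplied by
#'   `max(1, chi2_scale)`.
#' @return Symmetric K x K covariance matrix (events squared).
#' @export
propagate_weight_errors <- function(histogram, components, weights,
                                    chi2_scale = 1) {
  h <- if (inherits(histogram, "peak_histogram")) histogram$counts
       else as.numeric(histogram)
  P <- check_pmf_matrix(components)
  stopifnot(length(weights) == ncol(P), nrow(P) == length(h))
  m <- as.numeric(P %*% weights)
  use <- h > 0 & m > 0
  K <- ncol(P)
  if (!any(use)) return(matrix(0, K, K))
  A <- P[use, , drop = FALSE] * (sqrt(h[use]) / m[use])
  J <- crossprod(A)
  Jinv <- tryCatch({
    if (rcond(J) < 1e-12) stop("ill-conditioned")
    solve(J)
  }, error = function(e) {
    warning("singular Fisher information: using pseudo-inverse")
    structure(MASS::ginv(J), pseudo = TRUE)
  })
  flagged <- isTRUE(attr(Jinv, "pseudo"))
  cov <- max(1, chi2_scale) * (Jinv + t(Jinv)) / 2
  attr(cov, "pseudo_inverse") <- flagged
  cov
}

#' Pull statistics of predictions against ground truth
#'
#' `pull_i = (predicted_i - truth_i) / predicted_error_i`.  An unbiased
#' estimator gives mean 0; correctly predicted precision gives standard
#' deviation 1 (sample, n-1 convention).
#'
#' @param predicted,truth Equal-length numeric vectors.
#' @param predicted_errors Positive per-measurement predicted errors.
#' @return An object of class `pull_stats`: `mean`, `std`, `n`, `pulls`.
#' @export
pull_statistics <- function(predicted, truth, predicted_errors) {
  stopifnot(length(predicted) == length(truth),
            length(predicted) == length(predicted_errors))
  if (any(predicted_errors <= 0))
    stop("predicted_errors must be positive")
  pulls <- (predicted - truth) / predicted_errors
  out <- list(mean = mean(pulls),
              std = if (length(pulls) >= 2L) stats::sd(pulls) else NA_real_,
              n = length(pulls), pulls = pulls)
  class(out) <- "pull_stats"
  out
}

#' @export
print.pull_stats <- function(x, ...) {
  cat(sprintf("pull_stats: mean %.3f, std %.3f (n = %d)\n",
              x$mean, x$std, x$n))
  invisible(x)
}

#' Bland-Altman points from a fitted corpus
#'
#' One point per (spectrum, bin) with positive expected value: x is the
#' model-expected bin value on the intensity scale (`expected * gain`), y
#' is the residual `(observed - expected) * gain`.  The scatter of y
#' against x diagnoses how noise grows with signal.
#'
#' @param corpus List of [peak_histogram()] objects.
#' @param model An `lpm_model` (unused beyond validation; expected values
#'   come from the fits).
#' @param fits List of `spectrum_fit` objects matching the corpus.
#' @return A data frame of class `bland_altman_points` with columns
#'   `expected` and `residual`.
#' @export
bland_altman_points <- function(corpus, model, fits) {
  if (length(fits) != length(corpus))
    stop("fits must correspond one-to-one with corpus")
  xs <- list()
  ys <- list()
  for (s in seq_along(corpus)) {
    g <- corpus[[s]]$gain
    m <- fits[[s]]$expected * g
    r <- corpus[[s]]$counts * g - m
    keep <- m > 0
    xs[[s]] <- m[keep]
    ys[[s]] <- r[keep]
  }
  structure(data.frame(expected = unlist(xs), residual = unlist(ys)),
            class = c("bland_altman_points", "data.frame"))
}

#' Fit a power-law noise model to Bland-Altman points
#'
#' Models the residual variance as `Var(x) = a * x^b` by regressing the
#' log sample variance within `n_bands` equal-count quantile bands of the
#' expected value on the log band centre.  `b = 1` indicates Poisson-style
#' growth (residual standard deviation growing with the square root of the
#' signal) with `a` the intensity units per Poisson event; `b = 0`
#' indicates uniform Gaussian noise with `a` its variance.
#'
#' @param points A [bland_altman_points()] data frame.
#' @param n_bands Number of quantile bands (default 20).
#' @return An object of class `power_law_fit`: `a`, `b`, `a_err`, `b_err`,
#'   and the `bands` data frame (`center`, `variance`, `n`).
#' @export
fit_power_law <- function(points, n_bands = 20) {
  stopifnot(is.data.frame(points))
  n <- nrow(points)
  if (n < n_bands * 10)
    stop("at least 10 points per band are required")
  ord <- order(points$expected)
  idx <- ceiling(seq_along(ord) / (n / n_bands))
  idx[idx > n_bands] <- n_bands
  bands <- do.call(rbind, lapply(seq_len(n_bands), function(b) {
    sel <- ord[idx == b]
    data.frame(center = mean(points$expected[sel]),
               variance = stats::var(points$residual[sel]),
               n = length(sel))
  }))
  bands <- bands[is.finite(bands$variance) & bands$variance > 0 &
                   bands$center > 0 & bands$n >= 3, , drop = FALSE]
  if (nrow(bands) < 3L)
    stop("fewer than 3 non-degenerate bands")
  fit <- stats::lm(log(variance) ~ log(center), data = bands)
  co <- summary(fit)$coefficients
  out <- list(a = exp(co[1L, 1L]), b = co[2L, 1L],
              a_err = exp(co[1L, 1L]) * co[1L, 2L], b_err = co[2L, 2L],
              bands = bands)
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: Var(x) = a * x^b with a = %.3g +/- %.2g, b = %.3f +/- %.3f\n",
              x$a, x$a_err, x$b, x$b_err))
  invisible(x)
}
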