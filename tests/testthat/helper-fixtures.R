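## Shared fixtures and independent oracles, all built in code.

## Small two-class design used by the fast unit tests.
tiny_pmfs <- function(seed = 42) {
  make_class_pmfs(n_bins = 24, n_peaks_per_class = 14,
                  overlap_fraction = 0.3, seed = seed,
                  n_peaks_contamination = 4)
}

tiny_sim <- function(seed = 7, gain = 1, contamination_level = 0.05,
                     efficiency_B = 0.5, replicates = 3,
                     proportions = seq(0, 1, by = 0.25),
                     total_events_range = c(1000, 4000)) {
  generate_corpus(tiny_pmfs(), proportions = proportions,
                  replicates = replicates,
                  total_events_range = total_events_range, gain = gain,
                  contamination_level = contamination_level,
                  efficiency_B = efficiency_B, seed = seed)
}

## Independent brute-force oracle for two-component weight fits: exhaustive
## grid search of the Poisson likelihood over (Q1, Q2).
grid_fit_oracle <- function(h, P, step = 0.1, qmax = NULL) {
  stopifnot(ncol(P) == 2L)
  if (is.null(qmax)) qmax <- 1.5 * sum(h) + 1
  q <- seq(0, qmax, by = step)
  best <- c(NA, NA)
  best_ll <- -Inf
  for (q1 in q) {
    m <- outer(P[, 1L] * q1, rep(1, length(q))) +
      outer(P[, 2L], q)
    hl <- h * log(pmax(m, 1e-300))
    hl[h == 0, ] <- 0
    ll <- colSums(hl) - colSums(m)
    j <- which.max(ll)
    if (ll[j] > best_ll) {
      best_ll <- ll[j]
      best <- c(q1, q[j])
    }
  }
  list(weights = best, loglik = best_ll)
}

## Central finite-difference Hessian of a scalar function.
fd_hessian <- function(f, x, eps = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    e_i <- e_j <- numeric(n)
    e_i[i] <- eps
    e_j[j] <- eps
    H[i, j] <- (f(x + e_i + e_j) - f(x + e_i - e_j) -
                  f(x - e_i + e_j) + f(x - e_i - e_j)) / (4 * eps^2)
  }
  (H + t(H)) / 2
}

## Total-variation distance between two PMF vectors.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

## Minimal spectrum_fit stub for quantify-level tests that construct
## weight matrices directly.
fit_stub <- function(weights, covariance = NULL) {
  if (is.null(covariance)) covariance <- diag(length(weights))
  structure(list(weights = as.numeric(weights),
                 covariance = covariance),
            class = "spectrum_fit")
}

## A profile spectrum with Gaussian peaks on a flat-or-ramp background.
profile_with_peaks <- function(mz = seq(600, 900, by = 0.05),
                               centers = c(700, 760, 820),
                               areas = c(400, 900, 250),
                               sd = 0.5, background = function(x) 0) {
  y <- background(mz)
  for (j in seq_along(centers))
    y <- y + areas[j] * dnorm(mz, centers[j], sd) * diff(mz[1:2])
  raw_spectrum(mz, pmax(y, 0))
}
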