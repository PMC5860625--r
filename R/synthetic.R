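#' Generate class sub-spectrum PMFs for a binary mixture design
#'
#' Builds the probability mass functions of two class sub-spectra (A and B)
#' plus a contamination sub-spectrum, on a shared set of peak bins.  The two
#' classes share `overlap_fraction` of their peak positions (common
#' molecular constituents) with independent intensities; the contaminant is
#' a separate small set of peaks uncorrelated with either class.
#'
#' @param n_bins Number of retained peak bins.
#' @param n_peaks_per_class Peaks carrying mass in each class PMF.
#' @param overlap_fraction Fraction of each class's peaks shared with the
#'   other class, in `[0, 1]`.
#' @param seed Integer RNG seed; output is a pure function of it.
#' @param n_peaks_contamination Peaks in the contamination PMF.
#' @param window Analysis window (Da) used to place bin centroids.
#' @return A list with elements `pmf_A`, `pmf_B`, `contamination` (numeric
#'   vectors of length `n_bins` summing to 1), `centroids` (Da) and the
#'   peak index sets `peaks_A`, `peaks_B`.
#' @export
make_class_pmfs <- function(n_bins = 60, n_peaks_per_class = 35,
                            overlap_fraction = 0.3, seed = 1,
                            n_peaks_contamination = 8,
                            window = c(650, 850)) {
  if (n_peaks_per_class < 1L) stop("n_peaks_per_class must be >= 1")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  n_shared <- round(overlap_fraction * n_peaks_per_class)
  n_unique <- n_peaks_per_class - n_shared
  if (n_shared + 2L * n_unique > n_bins)
    stop("peak positions exceed the number of bins")
  if (n_peaks_contamination > n_bins)
    stop("n_peaks_contamination exceeds the number of bins")
  with_seed(seed, {
    pos <- sample.int(n_bins, n_shared + 2L * n_unique)
    shared <- pos[seq_len(n_shared)]
    only_a <- pos[n_shared + seq_len(n_unique)]
    only_b <- pos[n_shared + n_unique + seq_len(n_unique)]
    peaks_a <- sort(c(shared, only_a))
    peaks_b <- sort(c(shared, only_b))
    rand_pmf <- function(idx) {
      p <- numeric(n_bins)
      p[idx] <- stats::rgamma(length(idx), shape = 2, rate = 1)
      p / sum(p)
    }
    pmf_a <- rand_pmf(peaks_a)
    pmf_b <- rand_pmf(peaks_b)
    cont <- rand_pmf(sample.int(n_bins, n_peaks_contamination))
    step <- diff(window) / n_bins
    centroids <- window[1L] + (seq_len(n_bins) - 0.5) * step
    list(pmf_A = pmf_a, pmf_B = pmf_b, contamination = cont,
         centroids = centroids, peaks_A = peaks_a, peaks_B = peaks_b)
  })
}

#' Simulate a binary-mixture histogram corpus
#'
#' Emulates a dilution-series design: for every mixture proportion and
#' replicate, a total event count is drawn uniformly from
#' `total_events_range`, the expected histogram is the contamination-mixed,
#' efficiency-weighted combination of the class PMFs, and observed counts
#' are gain-scaled independent Poisson draws.  The default design is 11
#' proportions from 0 to 1 in 0.1 steps with 8 replicates (88 spectra).
#'
#' The expected histogram for proportion `p` (by mass of class A) is
#' `N * [(1 - c) * (p * pmf_A + (1 - p) * e_B * pmf_B) / (p + (1 - p) * e_B)
#'  + c * contamination]`
#' with contamination level `c` and relative detection efficiency `e_B` of
#' class B (class A has efficiency 1).  Recorded counts are
#' `gain * Poisson(expected)`: they sit on the intensity scale, and the
#' histograms' `gain` slot is left at 1 (the analyst's uncorrected
#' units-per-event assumption), so that the goodness-of-fit and the
#' Bland-Altman power-law scale both recover `gain`.
#'
#' @param pmfs Output of [make_class_pmfs()].
#' @param proportions Ground-truth proportions of class A in `[0, 1]`.
#' @param replicates Replicates per proportion.
#' @param total_events_range Length-2 range of per-spectrum total events.
#' @param gain Intensity units per Poisson event in the recorded counts.
#' @param contamination_level Fraction of total events from contamination.
#' @param efficiency_B Detection efficiency of class B relative to A.
#' @param seed Integer RNG seed.
#' @return A list with `corpus` (list of [peak_histogram()]) and `truth`
#'   (data frame `sample_id`, `fraction_A`).
#' @export
generate_corpus <- function(pmfs, proportions = seq(0, 1, by = 0.1),
                            replicates = 8,
                            total_events_range = c(2000, 20000),
                            gain = 1, contamination_level = 0.05,
                            efficiency_B = 0.5, seed = 1) {
  if (length(proportions) == 0L) stop("proportions must be non-empty")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (gain <= 0) stop("gain must be positive")
  cc <- contamination_level
  eb <- efficiency_B
  with_seed(seed, {
    corpus <- list()
    ids <- character(0)
    fr <- numeric(0)
    for (p in proportions) {
      norm <- p + (1 - p) * eb
      mix <- (1 - cc) * (p * pmfs$pmf_A + (1 - p) * eb * pmfs$pmf_B) / norm +
        cc * pmfs$contamination
      for (r in seq_len(replicates)) {
        n_events <- stats::runif(1, total_events_range[1L],
                                 total_events_range[2L])
        counts <- gain * stats::rpois(length(mix), n_events * mix)
        id <- sprintf("p%03d_r%d", round(100 * p), r)
        corpus[[length(corpus) + 1L]] <-
          peak_histogram(pmfs$centroids, counts, gain = 1,
                         sample_id = id, replicate = r)
        ids <- c(ids, id)
        fr <- c(fr, p)
      }
    }
    list(corpus = corpus,
         truth = data.frame(sample_id = ids, fraction_A = fr,
                            stringsAsFactors = FALSE))
  })
}

#' Render a histogram as a raw profile spectrum with acquisition artifacts
#'
#' Turns binned counts into Gaussian-shaped peaks on a fine profile axis,
#' adds a smooth baseline plus zero-mean Gaussian noise, and applies a
#' global m/z shift drawn with standard deviation `jitter_sd` - the
#' artifacts that the preprocessing stage is designed to remove.
#'
#' @param histogram A [peak_histogram()].
#' @param baseline_amplitude Peak amplitude of the smooth baseline
#'   (intensity units).
#' @param baseline_noise_sd Standard deviation of additive Gaussian noise.
#' @param jitter_sd Standard deviation of the global m/z shift (Da).
#' @param seed Integer RNG seed.
#' @param peak_sd Gaussian peak width (Da); default an eighth of the bin
#'   spacing.
#' @param step Profile axis spacing (Da); default a twentieth of the bin
#'   spacing.
#' @param pad Axis padding beyond the outer centroids (Da).
#' @return A [raw_spectrum()]; the applied shift is attached as attribute
#'   `shift`.
#' @export
add_profile_artifacts <- function(histogram, baseline_amplitude = 0,
                                  baseline_noise_sd = 0, jitter_sd = 0,
                                  seed = 1, peak_sd = NULL, step = NULL,
                                  pad = 10) {
  stopifnot(inherits(histogram, "peak_histogram"))
  if (baseline_amplitude < 0 || baseline_noise_sd < 0 || jitter_sd < 0)
    stop("artifact parameters must be non-negative")
  cents <- histogram$centroids
  spacing <- if (length(cents) > 1L) min(diff(sort(cents))) else 1
  if (is.null(peak_sd)) peak_sd <- spacing / 8
  if (is.null(step)) step <- spacing / 20
  with_seed(seed, {
    shift <- if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
    mz <- seq(min(cents) - pad, max(cents) + pad, by = step)
    intensity <- numeric(length(mz))
    active <- which(histogram$counts > 0)
    for (j in active) {
      intensity <- intensity + histogram$counts[j] * histogram$gain *
        stats::dnorm(mz, cents[j] + shift, peak_sd) * step
    }
    if (baseline_amplitude > 0) {
      x <- (mz - mz[1L]) / (mz[length(mz)] - mz[1L])
      intensity <- intensity +
        baseline_amplitude * (0.6 + 0.4 * cos(pi * x))
    }
    if (baseline_noise_sd > 0)
      intensity <- intensity + stats::rnorm(length(mz), 0, baseline_noise_sd)
    ## keep the invariant intensity >= 0 of raw spectra
    intensity <- pmax(intensity, 0)
    out <- raw_spectrum(mz, intensity, sample_id = histogram$sample_id,
                        replicate = histogram$replicate)
    attr(out, "shift") <- shift
    out
  })
}
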