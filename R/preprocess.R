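#' Align a spectrum to a reference by cross-correlation
#'
#' Estimates the global m/z displacement of `spectrum` relative to
#' `reference` by maximising the cross-correlation over integer axis steps,
#' refines it to sub-step precision by parabolic interpolation, and returns
#' the spectrum resampled (linear interpolation) onto the reference axis
#' with the displacement removed.
#'
#' @param spectrum,reference [raw_spectrum()] objects sharing an axis
#'   spacing over their common range.
#' @param max_shift Largest displacement searched (Da), > 0.
#' @return A list with `spectrum` (aligned, on the reference axis) and
#'   `shift`, the m/z offset added to the spectrum's axis; a spectrum
#'   displaced by `+d` relative to the reference yields `shift = -d`.  An
#'   all-zero spectrum is returned resampled with `shift = 0` and a
#'   warning.
#' @export
align_spectrum <- function(spectrum, reference, max_shift) {
  stopifnot(inherits(spectrum, "raw_spectrum"),
            inherits(reference, "raw_spectrum"))
  if (max_shift <= 0) stop("max_shift must be positive")
  if (min(spectrum$mz) >= max(reference$mz) ||
      max(spectrum$mz) <= min(reference$mz))
    stop("alignment failure: spectra m/z ranges do not overlap")
  step <- stats::median(diff(reference$mz))
  resample <- function(offset) {
    y <- stats::approx(spectrum$mz + offset, spectrum$intensity,
                       xout = reference$mz, rule = 1)$y
    y[is.na(y)] <- 0
    y
  }
  if (all(spectrum$intensity == 0)) {
    warning("all-zero spectrum: returning zero shift")
    out <- raw_spectrum(reference$mz, resample(0),
                        spectrum$sample_id, spectrum$replicate)
    return(list(spectrum = out, shift = 0))
  }
  s0 <- resample(0)
  lag_max <- max(1L, floor(max_shift / step))
  lags <- -lag_max:lag_max
  n <- length(s0)
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(reference$intensity[seq_len(n - l)] * s0[(1L + l):n])
    else sum(reference$intensity[(1L - l):n] * s0[seq_len(n + l)])
  }, numeric(1L))
  i <- which.max(cc)
  delta <- 0
  if (i > 1L && i < length(cc)) {
    denom <- cc[i - 1L] - 2 * cc[i] + cc[i + 1L]
    if (denom < 0) delta <- 0.5 * (cc[i - 1L] - cc[i + 1L]) / denom
    delta <- max(-0.5, min(0.5, delta))
  }
  ## displacement of the spectrum relative to the reference, in Da
  disp <- (lags[i] + delta) * step
  disp <- max(-max_shift, min(max_shift, disp))
  out <- raw_spectrum(reference$mz, resample(-disp),
                      spectrum$sample_id, spectrum$replicate)
  list(spectrum = out, shift = -disp)
}

#' Subtract a smooth baseline estimated beneath the peaks
#'
#' The baseline is an iteratively refined running median spanning
#' `smoothness` Da: after an initial running-median estimate, regions more
#' than two robust standard deviations above the current baseline (the
#' peaks) are masked and bridged by linear interpolation from the flanking
#' background before the median is re-estimated, so peaks do not drag the
#' baseline upward.  For zero-mean symmetric background
#' noise the running median is unbiased, so corrected background regions
#' keep mean approximately zero; negative residuals are retained, not
#' clipped.
#'
#' @param spectrum A [raw_spectrum()].
#' @param smoothness Baseline window width in Da; must exceed the axis
#'   spacing and should be several times the widest peak.
#' @param iterations Clip-and-refit passes after the initial estimate.
#' @return A list-like `raw_spectrum` whose intensity is the corrected
#'   signal; because corrected values may be negative it is returned as a
#'   plain list with the same fields plus class `corrected_spectrum`.
#' @export
baseline_correct <- function(spectrum, smoothness, iterations = 3) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  step <- stats::median(diff(spectrum$mz))
  if (smoothness <= step)
    stop("smoothness must exceed the axis spacing")
  y <- spectrum$intensity
  k <- round(smoothness / step)
  k <- max(3L, k + (1L - k %% 2L))          # odd window length
  k <- min(k, length(y) - (1L - length(y) %% 2L))
  base <- stats::runmed(y, k, endrule = "median")
  for (i in seq_len(iterations)) {
    sigma <- stats::mad(y - base)
    mask <- y - base > 2 * sigma
    if (any(mask)) {
      ## dilate so peak tails just under threshold do not leak into the
      ## bridge anchors
      d <- max(3L, round(k / 8))
      idx <- unique(pmin(pmax(rep(which(mask), each = 2L * d + 1L) +
                                (-d):d, 1L), length(y)))
      mask[idx] <- TRUE
    }
    if (all(mask) || !any(mask)) break
    bridged <- y
    bridged[mask] <- stats::approx(spectrum$mz[!mask], y[!mask],
                                   xout = spectrum$mz[mask],
                                   rule = 2)$y
    base <- stats::runmed(bridged, k, endrule = "median")
  }
  ks <- max(3L, round(k / 5))
  ks <- ks + (1L - ks %% 2L)
  kern <- rep(1 / ks, ks)
  sm <- stats::filter(base, kern, sides = 2)
  base <- ifelse(is.na(sm), base, as.numeric(sm))
  out <- spectrum
  out$intensity <- spectrum$intensity - base
  class(out) <- c("corrected_spectrum", "raw_spectrum")
  attr(out, "baseline") <- base
  out
}

#' Detect significant-peak bins across a corpus
#'
#' Scans the corpus-mean spectrum inside the analysis window for regions
#' whose intensity exceeds `significance` times a robust (median absolute
#' deviation) estimate of the background noise, and returns one half-open
#' bin `[low, high)` per contiguous significant region, extended outward to
#' the 1-sigma contour, with intensity-weighted centroids.  Inter-peak gaps
#' are excluded.
#'
#' @param corpus List of aligned, baseline-corrected [raw_spectrum()]
#'   objects on a common axis.
#' @param window Length-2 analysis window (Da), e.g. `c(650, 850)`.
#' @param significance Threshold as a multiple of background noise.
#' @param min_width Minimum significant run length, in axis samples, for a
#'   region to count as a peak (suppresses single-sample noise spikes).
#' @return A [peak_bin_set()]; empty (zero rows) when nothing is
#'   significant.
#' @export
detect_peak_bins <- function(corpus, window, significance = 5,
                             min_width = 3) {
  if (length(corpus) == 0L) stop("corpus must contain at least one spectrum")
  mz <- corpus[[1L]]$mz
  for (s in corpus)
    if (length(s$mz) != length(mz) || any(abs(s$mz - mz) > 1e-9))
      stop("all spectra must share a common m/z axis")
  m <- rowMeans(do.call(cbind, lapply(corpus, function(s) s$intensity)))
  inside <- mz >= window[1L] & mz < window[2L]
  if (!any(inside)) stop("window contains no m/z samples")
  mzw <- mz[inside]
  mw <- m[inside]
  centre <- stats::median(mw)
  sigma <- stats::mad(mw)
  if (sigma == 0) sigma <- stats::sd(mw) * 0.01 + .Machine$double.eps
  mask <- mw - centre > significance * sigma
  if (!any(mask))
    return(peak_bin_set(numeric(0), numeric(0), numeric(0), window))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  runs <- runs[runs[, 2L] - runs[, 1L] + 1L >= min_width, , drop = FALSE]
  if (!nrow(runs))
    return(peak_bin_set(numeric(0), numeric(0), numeric(0), window))
  ## grow each run outward to the 1-sigma contour
  low_sig <- mw - centre > sigma
  for (j in seq_len(nrow(runs))) {
    while (runs[j, 1L] > 1L && low_sig[runs[j, 1L] - 1L])
      runs[j, 1L] <- runs[j, 1L] - 1L
    while (runs[j, 2L] < length(mw) && low_sig[runs[j, 2L] + 1L])
      runs[j, 2L] <- runs[j, 2L] + 1L
  }
  ## merge runs that became adjacent or overlapping
  keep <- matrix(numeric(0), ncol = 2L)
  for (j in seq_len(nrow(runs))) {
    if (nrow(keep) && runs[j, 1L] <= keep[nrow(keep), 2L] + 1L)
      keep[nrow(keep), 2L] <- max(keep[nrow(keep), 2L], runs[j, 2L])
    else keep <- rbind(keep, runs[j, , drop = FALSE])
  }
  half <- stats::median(diff(mzw)) / 2
  low <- mzw[keep[, 1L]] - half
  high <- mzw[keep[, 2L]] + half
  centroid <- vapply(seq_len(nrow(keep)), function(j) {
    idx <- keep[j, 1L]:keep[j, 2L]
    stats::weighted.mean(mzw[idx], pmax(mw[idx] - centre, 0))
  }, numeric(1L))
  low <- pmax(low, window[1L])
  high <- pmin(high, window[2L])
  peak_bin_set(low, high, centroid, window)
}

#' Integrate a spectrum over peak bins
#'
#' Sums baseline-corrected intensity over each half-open bin `[low, high)`,
#' divides by `gain` to convert to Poisson events, and clips at zero.
#' Inter-bin gaps contribute nothing.
#'
#' @param spectrum An aligned, baseline-corrected [raw_spectrum()].
#' @param bins A [peak_bin_set()].
#' @param gain Intensity units per Poisson event, > 0.
#' @return A [peak_histogram()].
#' @export
integrate_peaks <- function(spectrum, bins, gain = 1) {
  stopifnot(inherits(spectrum, "raw_spectrum"),
            inherits(bins, "peak_bin_set"))
  if (gain <= 0) stop("gain must be positive")
  if (nrow(bins) &&
      (min(bins$low) < min(spectrum$mz) - 1e-9 ||
       max(bins$high) > max(spectrum$mz) + stats::median(diff(spectrum$mz))))
    stop("bins lie outside the spectrum m/z range")
  counts <- vapply(seq_len(nrow(bins)), function(j) {
    idx <- spectrum$mz >= bins$low[j] & spectrum$mz < bins$high[j]
    max(0, sum(spectrum$intensity[idx]) / gain)
  }, numeric(1L))
  peak_histogram(bins$centroid, counts, gain = gain,
                 sample_id = spectrum$sample_id,
                 replicate = spectrum$replicate)
}

#' Filter spectra by total signal
#'
#' Rejects low-signal spectra (poor signal-to-noise) and high-signal
#' spectra (saturated peaks), keeping those with
#' `low_total <= sum(counts) <= high_total`.
#'
#' @param histograms List of [peak_histogram()] objects.
#' @param low_total,high_total Event-count thresholds, `low_total <
#'   high_total`.
#' @return A list with `kept`, `rejected_low`, `rejected_high`: an
#'   exhaustive, disjoint partition of the input.
#' @export
filter_spectra <- function(histograms, low_total, high_total) {
  if (low_total >= high_total) stop("low_total must be < high_total")
  totals <- vapply(histograms, function(h) sum(h$counts), numeric(1L))
  list(kept = histograms[totals >= low_total & totals <= high_total],
       rejected_low = histograms[totals < low_total],
       rejected_high = histograms[totals > high_total])
}
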