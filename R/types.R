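#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Raw profile mass spectrum
#'
#' A profile-mode spectrum: intensity sampled on a strictly increasing m/z
#' axis, as acquired before any binning.
#'
#' @param mz Numeric vector of m/z values in Da, strictly increasing.
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param sample_id Opaque sample label.
#' @param replicate Integer replicate index.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, sample_id = "", replicate = 1L) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) < 2L || any(diff(mz) <= 0))
    stop("mz must be strictly increasing with at least two samples")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be finite and non-negative")
  structure(list(mz = mz, intensity = intensity,
                 sample_id = as.character(sample_id),
                 replicate = as.integer(replicate)),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw_spectrum '%s' (rep %d): %d samples, m/z %.2f-%.2f Da\n",
              x$sample_id, x$replicate, length(x$mz),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Set of peak integration bins
#'
#' Non-overlapping half-open m/z intervals `[low, high)` covering
#' significant peaks inside an analysis window, with intensity-weighted
#' centroids.
#'
#' @param low,high,centroid Numeric vectors in Da defining the bins.
#' @param window Length-2 numeric, the analysis window `(min_mz, max_mz)`.
#' @return An object of class `peak_bin_set` (a data frame with columns
#'   `low`, `high`, `centroid` and a `window` attribute).
#' @export
peak_bin_set <- function(low, high, centroid, window) {
  bins <- data.frame(low = as.numeric(low), high = as.numeric(high),
                     centroid = as.numeric(centroid))
  if (nrow(bins)) {
    ord <- order(bins$low)
    bins <- bins[ord, , drop = FALSE]
    if (any(bins$high <= bins$low))
      stop("each bin must satisfy low < high")
    if (nrow(bins) > 1L &&
        any(bins$low[-1L] < bins$high[-nrow(bins)] - 1e-9))
      stop("bins must be pairwise disjoint")
    if (any(bins$centroid < bins$low | bins$centroid > bins$high))
      stop("centroid must lie within [low, high]")
    if (any(bins$low < window[1L] | bins$high > window[2L]))
      stop("all bins must lie inside the analysis window")
  }
  rownames(bins) <- NULL
  structure(bins, window = as.numeric(window),
            class = c("peak_bin_set", "data.frame"))
}

#' Binned peak histogram
#'
#' One spectrum reduced to integrated peak bins: `counts` are events per
#' retained peak on the Poisson counting scale implied by `gain`
#' (intensity divided by gain).
#'
#' @param centroids Peak centroid m/z per bin (Da).
#' @param counts Non-negative events per bin.
#' @param gain Intensity units per Poisson event used for the conversion
#'   (default 1, i.e. counts are raw intensities).
#' @param sample_id,replicate Sample metadata.
#' @return An object of class `peak_histogram`.
#' @export
peak_histogram <- function(centroids, counts, gain = 1,
                           sample_id = "", replicate = 1L) {
  centroids <- as.numeric(centroids)
  counts <- as.numeric(counts)
  if (length(centroids) != length(counts))
    stop("centroids and counts must have equal length")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (!is.finite(gain) || gain <= 0)
    stop("gain must be positive")
  structure(list(centroids = centroids, counts = counts, gain = gain,
                 sample_id = as.character(sample_id),
                 replicate = as.integer(replicate)),
            class = "peak_histogram")
}

#' @export
print.peak_histogram <- function(x, ...) {
  cat(sprintf(
    "peak_histogram '%s' (rep %d): %d bins, %.0f events, gain %g\n",
    x$sample_id, x$replicate, length(x$counts), sum(x$counts), x$gain))
  invisible(x)
}

#' Coerce a corpus (list of peak histograms) to an S x I count matrix
#' @param corpus List of [peak_histogram()] objects on shared bins.
#' @return Numeric matrix, one row per spectrum, rownames = sample ids.
#' @export
corpus_counts <- function(corpus) {
  stopifnot(length(corpus) >= 1L)
  cents <- corpus[[1L]]$centroids
  for (h in corpus) {
    if (length(h$centroids) != length(cents) ||
        any(abs(h$centroids - cents) > 1e-9))
      stop("all histograms in a corpus must share the same bins")
  }
  H <- do.call(rbind, lapply(corpus, function(h) h$counts))
  rownames(H) <- vapply(corpus, function(h) h$sample_id, character(1L))
  H
}

corpus_gains <- function(corpus) {
  vapply(corpus, function(h) h$gain, numeric(1L))
}

#' @rdname corpus_counts
#' @export
corpus_ids <- function(corpus) {
  vapply(corpus, function(h) h$sample_id, character(1L))
}

## Validate a bins x K matrix of component PMFs.
check_pmf_matrix <- function(P, tol = 1e-9) {
  P <- as.matrix(P)
  if (any(P < 0)) stop("component probabilities must be non-negative")
  s <- colSums(P)
  if (any(abs(s - 1) > tol))
    stop("each component must sum to 1")
  P
}
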