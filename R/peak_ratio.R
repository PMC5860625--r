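## Single-peak benchmark: peaks normalised to a reference peak, ranked by
## how well a linear predictor calibrated against ground truth performs.

#' Normalise peak counts to a reference peak
#'
#' Divides every peak by the reference peak in each spectrum.  By default
#' the reference is the largest mean peak across the corpus.  Spectra whose
#' reference count is zero cannot be normalised and are flagged and
#' excluded.
#'
#' @param histograms List of [peak_histogram()] objects on shared bins.
#' @param reference_centroid Reference peak m/z; `NULL` selects the
#'   largest mean peak.
#' @return A list with `ratios` (kept spectra x peaks matrix, columns
#'   named by centroid), `centroids`, `reference_centroid`,
#'   `reference_index`, `kept` (row indices into the input) and
#'   `excluded`.
#' @export
compute_ratios <- function(histograms, reference_centroid = NULL) {
  H <- corpus_counts(histograms)
  cents <- histograms[[1L]]$centroids
  ref <- if (is.null(reference_centroid)) which.max(colMeans(H))
         else which.min(abs(cents - reference_centroid))
  if (!is.null(reference_centroid) &&
      abs(cents[ref] - reference_centroid) > 1e-6)
    warning("reference_centroid matched to nearest bin centroid")
  ok <- H[, ref] > 0
  if (!all(ok))
    warning(sprintf("%d spectra excluded: zero reference count",
                    sum(!ok)))
  ratios <- H[ok, , drop = FALSE] / H[ok, ref]
  colnames(ratios) <- format(cents, trim = TRUE)
  list(ratios = ratios, centroids = cents,
       reference_centroid = cents[ref], reference_index = ref,
       kept = which(ok), excluded = which(!ok))
}

#' Rank peaks by calibrated single-peak precision
#'
#' For every peak, fits the least-squares linear predictor mapping its
#' normalised ratio to the ground-truth proportion, and scores the peak by
#' the standard deviation of the calibrated predictions around truth (the
#' attainable single-peak measurement precision).  Optionally scores by
#' leave-one-out prediction error, since in-sample precision is
#' optimistic.
#'
#' @param ratios Result of [compute_ratios()].
#' @param truth Ground-truth proportions aligned with the *kept* spectra:
#'   numeric vector or data frame with `fraction_A` (subset with
#'   `ratios$kept` if needed).
#' @param loo Use leave-one-out residuals for the precision.
#' @return A list with `best` (a `peak_ratio_calibration`: fields
#'   `reference_centroid`, `peak_centroid`, `slope`, `intercept`,
#'   `precision`) and `ranking` (data frame sorted by precision).
#' @export
rank_and_calibrate <- function(ratios, truth, loo = FALSE) {
  t <- truth_vector(truth)
  R <- ratios$ratios
  if (length(t) != nrow(R)) stop("truth must align with kept spectra")
  if (length(unique(t)) < 3L)
    stop("at least 3 distinct truth values required")
  peaks <- setdiff(seq_len(ncol(R)), ratios$reference_index)
  rows <- lapply(peaks, function(j) {
    x <- R[, j]
    if (stats::sd(x) == 0)
      return(data.frame(centroid = ratios$centroids[j], slope = 0,
                        intercept = mean(t), precision = stats::sd(t)))
    fit <- stats::lm(t ~ x)
    res <- if (loo) stats::residuals(fit) / (1 - stats::hatvalues(fit))
           else stats::residuals(fit)
    data.frame(centroid = ratios$centroids[j],
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               precision = stats::sd(res))
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(ranking$precision), , drop = FALSE]
  rownames(ranking) <- NULL
  best <- as.list(ranking[1L, ])
  best$reference_centroid <- ratios$reference_centroid
  best$peak_centroid <- best$centroid
  best$centroid <- NULL
  class(best) <- "peak_ratio_calibration"
  list(best = best, ranking = ranking)
}

#' @export
print.peak_ratio_calibration <- function(x, ...) {
  cat(sprintf(
    "peak_ratio_calibration: peak m/z %.2f / ref %.2f, precision %.4f\n",
    x$peak_centroid, x$reference_centroid, x$precision))
  invisible(x)
}

#' Predict a proportion from a normalised peak ratio
#'
#' @param ratio Normalised peak value(s).
#' @param calibration A `peak_ratio_calibration`.
#' @return A list with `proportion` (clipped to `[0, 1]`), `unclipped`
#'   and `clipped` flag(s).
#' @export
predict_from_ratio <- function(ratio, calibration) {
  stopifnot(inherits(calibration, "peak_ratio_calibration"))
  unclipped <- calibration$slope * ratio + calibration$intercept
  proportion <- pmin(1, pmax(0, unclipped))
  list(proportion = proportion, unclipped = unclipped,
       clipped = proportion != unclipped)
}
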