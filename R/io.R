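## Readers and writers for the plain-text interchange formats: histogram
## corpora and truth tables as CSV, models and calibrations as JSON.

#' Write a histogram corpus to CSV
#'
#' One row per spectrum: `sample_id`, `replicate`, `gain`, then one column
#' per peak centroid (named `mz_<centroid>`) holding the counts.
#'
#' @param corpus List of [peak_histogram()] objects on shared bins.
#' @param file Output path.
#' @export
write_histograms <- function(corpus, file) {
  H <- corpus_counts(corpus)
  cents <- corpus[[1L]]$centroids
  df <- data.frame(sample_id = corpus_ids(corpus),
                   replicate = vapply(corpus, function(h) h$replicate,
                                      integer(1L)),
                   gain = corpus_gains(corpus),
                   stringsAsFactors = FALSE)
  counts <- as.data.frame(H)
  names(counts) <- sprintf("mz_%.6g", cents)
  utils::write.csv(cbind(df, counts), file, row.names = FALSE)
}

#' Read a histogram corpus written by [write_histograms()]
#' @param file Input path.
#' @return List of [peak_histogram()] objects.
#' @export
read_histograms <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE,
                        stringsAsFactors = FALSE)
  mzcols <- grep("^mz_", names(df))
  cents <- as.numeric(sub("^mz_", "", names(df)[mzcols]))
  lapply(seq_len(nrow(df)), function(i)
    peak_histogram(cents, as.numeric(df[i, mzcols]), gain = df$gain[i],
                   sample_id = df$sample_id[i],
                   replicate = df$replicate[i]))
}

#' Write/read a ground-truth table (`sample_id`, `fraction_A`)
#' @param truth Data frame with columns `sample_id` and `fraction_A`.
#' @param file Path.
#' @export
write_truth <- function(truth, file) {
  utils::write.csv(truth[, c("sample_id", "fraction_A")], file,
                   row.names = FALSE)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "fraction_A") %in% names(df)))
  df
}

#' Serialise an LP-ICA model to JSON
#' @param model An `lpm_model`.
#' @param file Path.
#' @export
write_model <- function(model, file) {
  stopifnot(inherits(model, "lpm_model"))
  doc <- list(centroids = model$centroids,
              components = lapply(seq_len(model$K), function(k)
                model$components[, k]),
              K = model$K, chi2_per_dof = model$chi2_per_dof,
              loglik = model$loglik, seed = model$seed)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
}

#' Read an LP-ICA model written by [write_model()]
#' @param file Path.
#' @return An `lpm_model` (without training weights).
#' @export
read_model <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  P <- if (is.matrix(doc$components)) t(doc$components)
       else do.call(cbind, lapply(doc$components, as.numeric))
  model <- list(components = check_pmf_matrix(P),
                centroids = as.numeric(doc$centroids), K = doc$K,
                weights = NULL, loglik = doc$loglik,
                chi2_per_dof = doc$chi2_per_dof, seed = doc$seed,
                iterations = NA_integer_, converged = NA)
  class(model) <- "lpm_model"
  model
}

#' Serialise a class calibration to JSON
#' @param calibration A [calibrate()] result.
#' @param file Path.
#' @export
write_calibration <- function(calibration, file) {
  stopifnot(inherits(calibration, "class_calibration"))
  doc <- calibration[c("assignment", "efficiency", "slope", "intercept",
                       "precision")]
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
}

#' Read a class calibration written by [write_calibration()]
#' @param file Path.
#' @return A `class_calibration` (without residual vectors).
#' @export
read_calibration <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  doc$efficiency <- as.numeric(doc$efficiency)
  doc$residuals <- NULL
  class(doc) <- "class_calibration"
  doc
}

#' Read a two-column (m/z, intensity) spectrum file
#'
#' Accepts CSV or TSV with or without a header line.
#'
#' @param file Path.
#' @param sample_id,replicate Metadata attached to the spectrum.
#' @return A [raw_spectrum()].
#' @export
read_spectrum_csv <- function(file, sample_id = basename(file),
                              replicate = 1L) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- !grepl("^[0-9eE+.,\t -]+$", first)
  df <- utils::read.table(file, sep = sep, header = header)
  raw_spectrum(df[[1L]], df[[2L]], sample_id = sample_id,
               replicate = replicate)
}

#' Read a manifest of spectrum files
#'
#' The manifest is a CSV with columns `file`, `sample_id`, `replicate` and
#' optionally `fraction_A`; relative paths resolve against the manifest's
#' directory.
#'
#' @param file Manifest path.
#' @return A list with `spectra` (list of [raw_spectrum()]) and `truth`
#'   (data frame or `NULL`).
#' @export
read_manifest <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("file", "sample_id", "replicate") %in% names(df)))
  dir <- dirname(file)
  paths <- ifelse(file.exists(df$file), df$file,
                  file.path(dir, df$file))
  spectra <- lapply(seq_len(nrow(df)), function(i)
    read_spectrum_csv(paths[i], df$sample_id[i], df$replicate[i]))
  truth <- if ("fraction_A" %in% names(df))
    df[, c("sample_id", "fraction_A")] else NULL
  list(spectra = spectra, truth = truth)
}

#' Write a peak bin set to CSV (`low`, `high`, `centroid`)
#' @param bins A [peak_bin_set()].
#' @param file Path.
#' @export
write_bins <- function(bins, file) {
  utils::write.csv(as.data.frame(bins), file, row.names = FALSE)
}

#' @rdname write_bins
#' @param window Analysis window to attach on read.
#' @export
read_bins <- function(file, window = NULL) {
  df <- utils::read.csv(file)
  if (is.null(window))
    window <- c(min(df$low), max(df$high))
  peak_bin_set(df$low, df$high, df$centroid, window)
}
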