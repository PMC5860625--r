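make_shifted <- function(ref, d) {
  ## the same peak pattern displaced by +d Da, sampled on the same axis
  raw_spectrum(ref$mz, approx(ref$mz + d, ref$intensity, xout = ref$mz,
                              rule = 2)$y)
}

test_that("alignment recovers constructed shifts", {
  ref <- profile_with_peaks()
  step <- diff(ref$mz[1:2])
  ## identity
  res <- align_spectrum(ref, ref, max_shift = 2)
  expect_equal(res$shift, 0, tolerance = 1e-9)
  ## exact +2 axis steps: estimated correction is -2 steps
  res2 <- align_spectrum(make_shifted(ref, 2 * step), ref, max_shift = 1)
  expect_equal(res2$shift, -2 * step, tolerance = 0.05 * step)
  expect_equal(sum(res2$spectrum$intensity), sum(ref$intensity),
               tolerance = 1e-3)
  ## sub-bin shift of half a step, recovered within a quarter step
  res3 <- align_spectrum(make_shifted(ref, 0.5 * step), ref, max_shift = 1)
  expect_lt(abs(res3$shift + 0.5 * step), 0.25 * step)
  ## aligned spectrum matches the reference up to interpolation error
  expect_lt(max(abs(res2$spectrum$intensity - ref$intensity)) /
              max(ref$intensity), 0.05)
})

test_that("alignment error and degenerate cases", {
  ref <- profile_with_peaks()
  other <- raw_spectrum(ref$mz + 1000, ref$intensity)
  expect_error(align_spectrum(other, ref, 2), "overlap")
  flat <- raw_spectrum(ref$mz, rep(0, length(ref$mz)))
  expect_warning(res <- align_spectrum(flat, ref, 2), "zero")
  expect_equal(res$shift, 0)
  expect_error(align_spectrum(ref, ref, max_shift = 0), "positive")
})

test_that("baseline correction leaves zero-mean background and keeps peaks", {
  mz <- seq(600, 900, by = 0.05)
  set.seed(31)
  noise <- rnorm(length(mz), 0, 2)
  flat <- raw_spectrum(mz, pmax(100 + noise, 0))
  out <- baseline_correct(flat, smoothness = 20)
  expect_lt(abs(mean(out$intensity)), 3 * 2 / sqrt(length(mz)) + 0.1)
  ## negative residuals retained
  expect_gt(sum(out$intensity < 0), 0)
  ## ramp + 3 Gaussian peaks: integrated peak areas preserved within 5%
  areas <- c(400, 900, 250)
  centers <- c(700, 760, 820)
  ramp <- profile_with_peaks(mz, centers, areas, sd = 0.5,
                             background = function(x) 50 + 0.2 * (x - 600))
  cor <- baseline_correct(ramp, smoothness = 20)
  for (j in 1:3) {
    sel <- abs(mz - centers[j]) < 4
    expect_equal(sum(cor$intensity[sel]), areas[j],
                 tolerance = 0.05)
  }
  ## all-zero spectrum stays all-zero
  z <- raw_spectrum(mz, rep(0, length(mz)))
  expect_equal(baseline_correct(z, 20)$intensity, rep(0, length(mz)))
  expect_error(baseline_correct(flat, smoothness = 0.01), "spacing")
})

test_that("peak-bin detection finds constructed peaks and nothing in noise", {
  mz <- seq(640, 860, by = 0.05)
  set.seed(17)
  noise_corpus <- lapply(1:4, function(i)
    raw_spectrum(mz, pmax(rnorm(length(mz), 0, 1), 0)))
  bins0 <- detect_peak_bins(noise_corpus, window = c(650, 850),
                            significance = 6)
  expect_equal(nrow(bins0), 0)
  centers <- c(700, 760, 820)
  corpus <- lapply(1:4, function(i)
    profile_with_peaks(mz, centers, c(400, 900, 250), sd = 0.5,
                       background = function(x)
                         abs(rnorm(length(x), 0, 0.5))))
  bins <- detect_peak_bins(corpus, window = c(650, 850), significance = 5)
  expect_equal(nrow(bins), 3)
  for (j in 1:3)
    expect_true(any(bins$low <= centers[j] & centers[j] < bins$high))
  expect_true(all(diff(bins$low) > 0))
  expect_true(all(bins$centroid >= bins$low & bins$centroid <= bins$high))
  expect_error(detect_peak_bins(list(), c(650, 850)), "at least one")
})

test_that("peak integration recovers analytic areas and scales with gain", {
  mz <- seq(640, 860, by = 0.05)
  centers <- c(700, 760, 820)
  areas <- c(400, 900, 250)
  sp <- profile_with_peaks(mz, centers, areas, sd = 0.5)
  bins <- peak_bin_set(centers - 4, centers + 4, centers, c(650, 850))
  h1 <- integrate_peaks(sp, bins, gain = 1)
  expect_equal(h1$counts, areas, tolerance = 0.01)
  h5 <- integrate_peaks(sp, bins, gain = 5)
  expect_equal(h5$counts, areas / 5, tolerance = 0.01)
  ## exact conservation of windowed signal
  inside <- rowSums(sapply(seq_len(nrow(bins)), function(j)
    sp$mz >= bins$low[j] & sp$mz < bins$high[j])) > 0
  expect_equal(sum(h1$counts) * 1, sum(sp$intensity[inside]))
  ## zero spectrum, and bins outside the axis
  z <- raw_spectrum(mz, rep(0, length(mz)))
  expect_equal(integrate_peaks(z, bins)$counts, c(0, 0, 0))
  far <- peak_bin_set(100, 110, 105, c(90, 120))
  expect_error(integrate_peaks(sp, far, 1), "outside")
})

test_that("spectrum filtering partitions by total signal", {
  hs <- lapply(c(50, 500, 20000), function(tot)
    peak_histogram(1:3, c(tot, 0, 0), sample_id = as.character(tot)))
  f <- filter_spectra(hs, 100, 10000)
  expect_equal(corpus_ids(f$kept), "500")
  expect_equal(corpus_ids(f$rejected_low), "50")
  expect_equal(corpus_ids(f$rejected_high), "20000")
  all_kept <- filter_spectra(hs, 0, Inf)
  expect_length(all_kept$kept, 3)
  ## 88-spectrum design with 6 pushed low and 2 pushed high keeps 80
  set.seed(4)
  totals <- c(runif(80, 200, 900), runif(6, 0, 40), runif(2, 5000, 9000))
  hs88 <- lapply(totals, function(tot) peak_histogram(1:2, c(tot, 0)))
  f88 <- filter_spectra(hs88, 50, 1000)
  expect_length(f88$kept, 80)
  expect_equal(length(f88$kept) + length(f88$rejected_low) +
                 length(f88$rejected_high), 88)
  expect_error(filter_spectra(hs, 10, 10), "low_total")
})

test_that("preprocessing commutes with a global axis shift", {
  pmfs <- tiny_pmfs()
  h <- peak_histogram(pmfs$centroids,
                      round(4000 * (0.5 * pmfs$pmf_A + 0.5 * pmfs$pmf_B)))
  ref <- add_profile_artifacts(h, seed = 3)
  shifted <- add_profile_artifacts(h, jitter_sd = 1.2, seed = 21)
  spacing <- diff(pmfs$centroids[1:2])
  bins <- peak_bin_set(pmfs$centroids - spacing / 2,
                       pmfs$centroids + spacing / 2, pmfs$centroids,
                       window = range(pmfs$centroids) + c(-1, 1) * spacing)
  aligned <- align_spectrum(shifted, ref, max_shift = 3)
  expect_lt(abs(aligned$shift + attr(shifted, "shift")), 0.25 * spacing)
  h_ref <- integrate_peaks(ref, bins)
  h_ali <- integrate_peaks(aligned$spectrum, bins)
  big <- h_ref$counts > 20
  expect_lt(max(abs(h_ali$counts[big] - h_ref$counts[big]) /
                  h_ref$counts[big]), 0.01)
})
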