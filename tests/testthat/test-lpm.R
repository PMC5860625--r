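test_that("expected histograms are exact weighted PMF sums", {
  P1 <- matrix(c(0.5, 0.5), ncol = 1)
  expect_equal(expected_histogram(0, P1), c(0, 0))
  expect_equal(expected_histogram(10, P1), c(5, 5))
  P2 <- cbind(c(1, 0), c(0.25, 0.75))
  expect_equal(expected_histogram(c(4, 8), P2), c(6, 6))
  expect_error(expected_histogram(c(-1, 2), P2), "non-negative")
  ## conservation and permutation invariance on random cases
  set.seed(2)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    P <- matrix(rgamma(6 * K, 1), 6, K)
    P <- sweep(P, 2, colSums(P), "/")
    w <- runif(K, 0, 50)
    m <- expected_histogram(w, P)
    expect_equal(sum(m), sum(w))
    perm <- sample(K)
    expect_equal(expected_histogram(w[perm], P[, perm]), m)
  }
})

test_that("the Poisson log-likelihood follows its defining formula", {
  expect_equal(poisson_loglik(c(2, 3), c(2, 3)),
               2 * log(2) + 3 * log(3) - 5)
  expect_equal(poisson_loglik(c(0, 0), c(0, 0)), 0)
  expect_identical(poisson_loglik(c(1, 0), c(0, 1)), -Inf)
  expect_error(poisson_loglik(c(1, 2), c(1, 2, 3)), "length")
  ## h = m maximises the likelihood over equal-total expectations
  set.seed(3)
  h <- c(4, 9, 2, 5)
  best <- poisson_loglik(h, h)
  for (i in 1:20) {
    m <- rgamma(4, 1)
    m <- m / sum(m) * sum(h)
    expect_lte(poisson_loglik(h, m), best)
  }
})

test_that("weight fitting solves exact and separable cases", {
  P1 <- matrix(c(0.3, 0.5, 0.2), ncol = 1)
  f <- fit_weights(100 * P1[, 1], P1)
  expect_equal(f$weights, 100, tolerance = 1e-6)
  ## disjoint supports are separable
  P2 <- cbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.25, 0.75))
  f2 <- fit_weights(c(30, 30, 10, 30), P2)
  expect_equal(f2$weights, c(60, 40), tolerance = 1e-6)
  ## all-zero histogram
  f0 <- fit_weights(c(0, 0, 0, 0), P2)
  expect_equal(f0$weights, c(0, 0))
  expect_error(fit_weights(c(1, 2), cbind(c(1, 0), c(0, 0))),
               "sum to 1|zero")
  ## conservation: sum(expected) == sum(weights)
  expect_equal(sum(f2$expected), sum(f2$weights), tolerance = 1e-9)
})

test_that("EM weight fits agree with the brute-force likelihood grid", {
  cases <- list(
    list(h = c(30, 50, 20), P = cbind(c(0.6, 0.4, 0), c(0, 0.5, 0.5))),
    list(h = c(12, 7, 3, 9), P = cbind(c(0.4, 0.3, 0.2, 0.1),
                                       c(0.1, 0.2, 0.3, 0.4))),
    list(h = c(5, 0, 11), P = cbind(c(0.8, 0.2, 0), c(0.2, 0.2, 0.6))))
  for (cs in cases) {
    oracle <- grid_fit_oracle(cs$h, cs$P, step = 0.1)
    fit <- fit_weights(cs$h, cs$P)
    expect_equal(fit$weights, oracle$weights, tolerance = 0.2)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
  }
})

test_that("EM log-likelihood is monotone non-decreasing", {
  sim <- tiny_sim()
  f <- fit_weights(sim$corpus[[5]], cbind(tiny_pmfs()$pmf_A,
                                          tiny_pmfs()$pmf_B),
                   trace = TRUE)
  expect_true(all(diff(f$loglik_trace) >= -1e-7))
  m <- train_components(sim$corpus[1:10], K = 2, seed = 3, trace = TRUE,
                        max_iter = 400)
  expect_true(all(diff(m$loglik_trace) >= -1e-6))
})

test_that("training recovers generating components", {
  pmfs <- tiny_pmfs()
  ## single-PMF corpus
  sim1 <- generate_corpus(pmfs, proportions = 1, replicates = 30,
                          total_events_range = c(3000, 6000),
                          contamination_level = 0, seed = 21)
  m1 <- train_components(sim1$corpus, K = 1, seed = 2)
  tot <- sum(corpus_counts(sim1$corpus))
  se <- sqrt(pmfs$pmf_A * (1 - pmfs$pmf_A) / tot)
  expect_true(all(abs(m1$components[, 1] - pmfs$pmf_A) <= 3 * se + 1e-9))
  ## two disjoint-support PMFs at varying proportions
  pm0 <- make_class_pmfs(n_bins = 24, n_peaks_per_class = 10,
                         overlap_fraction = 0, seed = 5)
  sim2 <- generate_corpus(pm0, proportions = seq(0, 1, 0.25),
                          replicates = 8, efficiency_B = 1,
                          contamination_level = 0,
                          total_events_range = c(3000, 6000), seed = 22)
  m2 <- train_components(sim2$corpus, K = 2, seed = 4)
  tvs <- sapply(list(c(1, 2), c(2, 1)), function(perm)
    max(tv_dist(m2$components[, perm[1]], pm0$pmf_A),
        tv_dist(m2$components[, perm[2]], pm0$pmf_B)))
  expect_lt(min(tvs), 0.05)
  ## determinism: same seed twice gives the identical model
  expect_identical(train_components(sim2$corpus, K = 2, seed = 4), m2)
  expect_error(train_components(sim2$corpus, K = 50), "K must")
})

test_that("weights scale with the histogram counts", {
  pmfs <- tiny_pmfs()
  P <- cbind(pmfs$pmf_A, pmfs$pmf_B)
  sim <- tiny_sim(seed = 31)
  h <- sim$corpus[[4]]$counts
  w1 <- fit_weights(h, P)$weights
  w4 <- fit_weights(4 * h, P)$weights
  expect_equal(w4, 4 * w1, tolerance = 1e-6)
})

test_that("goodness-of-fit matches its formula and calibrates near 1", {
  expect_equal(lpica:::chi2_stat(c(4, 1), c(2, 2)), 2.5)
  expect_equal(lpica:::chi2_stat(c(5, 5), c(5, 5)), 0)
  ## Poisson corpus fitted at the true order
  sim <- tiny_sim(seed = 41, replicates = 8)
  m <- train_components(sim$corpus, K = 3, seed = 6)
  fc <- fit_corpus(sim$corpus, m)
  expect_gt(fc$chi2_per_dof, 0.85)
  expect_lt(fc$chi2_per_dof, 1.15)
  expect_equal(chi2_per_dof(sim$corpus, m, fc$fits), fc$chi2_per_dof)
  ## over-parameterised dof guard
  expect_error(lpica:::lpm_dof(1, 2, 1), "over-parameterised")
})

test_that("model order is chosen by the plateau rule", {
  expect_equal(lpica:::plateau_select(1:5, c(10, 3, 1.05, 1.02, 1.01),
                                      0.05), 3)
  expect_equal(lpica:::plateau_select(1:3, c(1.0, 0.99, 0.98), 0.05), 1)
  ## a rise in the curve counts as a minimum reached
  expect_equal(lpica:::plateau_select(1:4, c(5, 1.0, 1.1, 1.2), 0.05), 2)
  expect_equal(lpica:::plateau_select(2, 1.3, 0.05), 2)
  ## the full selection returns the curve alongside the chosen order
  sim1 <- generate_corpus(tiny_pmfs(), proportions = 0.5, replicates = 12,
                          contamination_level = 0, efficiency_B = 1,
                          total_events_range = c(2000, 4000), seed = 51)
  sel <- select_model_order(sim1$corpus, 1:2, restarts = 2, seed = 3)
  expect_true(sel$K %in% 1:2)
  expect_named(sel$curve, c("K", "chi2_per_dof", "loglik"))
  expect_s3_class(sel$model, "lpm_model")
})
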