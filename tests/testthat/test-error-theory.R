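test_that("weight covariance reduces to closed forms", {
  ## one component: Var(Q) = N, the Poisson counting limit
  P1 <- matrix(c(0.4, 0.35, 0.25), ncol = 1)
  h <- c(40, 35, 25)
  C1 <- propagate_weight_errors(h, P1, sum(h))
  expect_equal(C1[1, 1], sum(h), tolerance = 1e-9)
  ## disjoint supports: independent counts, diagonal covariance
  P2 <- cbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.25, 0.75))
  h2 <- c(30, 30, 10, 30)
  C2 <- propagate_weight_errors(h2, P2, c(60, 40))
  expect_equal(C2[1, 1], 60, tolerance = 1e-9)
  expect_equal(C2[2, 2], 40, tolerance = 1e-9)
  expect_equal(C2[1, 2], 0, tolerance = 1e-9)
  ## chi2 scaling is one-sided: never deflates below the Poisson floor
  expect_equal(propagate_weight_errors(h, P1, sum(h), chi2_scale = 0.5),
               C1, ignore_attr = TRUE)
  expect_equal(propagate_weight_errors(h, P1, sum(h), chi2_scale = 3),
               3 * C1, ignore_attr = TRUE)
})

test_that("the information matrix matches a finite-difference Hessian", {
  P <- cbind(c(0.6, 0.3, 0.1), c(0.1, 0.4, 0.5))
  h <- c(55, 40, 30)
  fit <- fit_weights(h, P)
  negll <- function(q) -poisson_loglik(h, as.numeric(P %*% q))
  Hfd <- fd_hessian(negll, fit$weights, eps = 1e-3)
  C_an <- propagate_weight_errors(h, P, fit$weights)
  C_fd <- solve(Hfd)
  expect_lt(max(abs(C_an - C_fd)) / max(abs(C_fd)), 0.01)
})

test_that("duplicated components give a flagged pseudo-inverse", {
  P <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_warning(C <- propagate_weight_errors(c(10, 10), P, c(10, 10)),
                 "pseudo-inverse")
  expect_true(attr(C, "pseudo_inverse"))
  expect_equal(C, t(C), ignore_attr = TRUE)
})

test_that("propagated errors scale with the square root of counts", {
  pmfs <- tiny_pmfs()
  P <- cbind(pmfs$pmf_A, pmfs$pmf_B)
  h <- tiny_sim(seed = 91)$corpus[[6]]$counts
  se1 <- sqrt(diag(propagate_weight_errors(h, P, fit_weights(h, P)$weights)))
  h4 <- 4 * h
  se4 <- sqrt(diag(propagate_weight_errors(h4, P,
                                           fit_weights(h4, P)$weights)))
  expect_equal(se4, 2 * se1, tolerance = 0.02)
})

test_that("pull statistics follow their definition", {
  p <- c(0.2, 0.5, 0.8)
  expect_equal(pull_statistics(p, p, rep(0.1, 3))$mean, 0)
  ## alternating unit pulls: mean 0, sample std ~ 1
  res <- rep(c(1, -1), 25)
  ps <- pull_statistics(0.5 + 0.01 * res, rep(0.5, 50), rep(0.01, 50))
  expect_equal(ps$mean, 0)
  expect_equal(ps$std, sqrt(50 / 49), tolerance = 1e-9)
  expect_equal(ps$n, 50)
  ## residuals uniformly 1.6x their predicted errors give std 1.6
  ps2 <- pull_statistics(0.5 + 0.016 * res, rep(0.5, 50), rep(0.01, 50))
  expect_equal(ps2$std, 1.6 * ps$std, tolerance = 1e-9)
  expect_error(pull_statistics(p, p, c(0.1, 0, 0.1)), "positive")
})

test_that("Bland-Altman points expose residuals on the intensity scale", {
  pmfs <- tiny_pmfs()
  P <- cbind(pmfs$pmf_A, pmfs$pmf_B)
  sim <- tiny_sim(seed = 101, replicates = 4)
  fc <- fit_corpus(sim$corpus, P)
  fake_model <- list(components = P)
  pts <- bland_altman_points(sim$corpus, fake_model, fc$fits)
  expect_true(all(pts$expected > 0))
  ## a perfect model has zero residuals
  perfect <- lapply(sim$corpus, function(h) fit_stub(c(1, 1)))
  for (s in seq_along(perfect)) perfect[[s]]$expected <- sim$corpus[[s]]$counts
  pts0 <- bland_altman_points(sim$corpus, fake_model, perfect)
  expect_equal(max(abs(pts0$residual)), 0)
})

test_that("the power law recovers constructed noise models", {
  set.seed(12)
  x <- exp(runif(4000, log(5), log(500)))
  ## Var = x (Poisson-style)
  p1 <- data.frame(expected = x, residual = rnorm(4000, 0, sqrt(x)))
  f1 <- fit_power_law(p1)
  expect_lt(abs(f1$b - 1), 3 * f1$b_err)
  expect_lt(abs(f1$a - 1) / f1$a, 0.25)
  ## Var = 5x (scaled Poisson)
  p5 <- data.frame(expected = x, residual = rnorm(4000, 0, sqrt(5 * x)))
  f5 <- fit_power_law(p5)
  expect_lt(abs(f5$b - 1), 3 * f5$b_err)
  expect_equal(f5$a, 5, tolerance = 0.25)
  ## iid Gaussian: flat variance, b near 0
  pg <- data.frame(expected = x, residual = rnorm(4000, 0, 3))
  fg <- fit_power_law(pg)
  expect_lt(abs(fg$b), 3 * fg$b_err + 0.05)
  expect_equal(fg$a, 9, tolerance = 0.3)
  expect_error(fit_power_law(p1[1:50, ]), "at least")
})

test_that("the generator exponent is recovered across gains", {
  pmfs <- make_class_pmfs(seed = 2)
  for (g in c(1, 5, 25)) {
    sim <- generate_corpus(pmfs, proportions = seq(0, 1, 0.2),
                           replicates = 5, gain = g, seed = 110 + g)
    m <- train_components(sim$corpus, K = 3, seed = 7)
    fc <- fit_corpus(sim$corpus, m)
    pl <- fit_power_law(bland_altman_points(sim$corpus, m, fc$fits),
                        n_bands = 15)
    expect_lt(abs(pl$b - 1), 2 * pl$b_err + 0.05)
    ## the power-law scale tracks the gain
    expect_equal(pl$a, g, tolerance = 0.35)
  }
})
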