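test_that("R^2 is the squared correlation of response and prediction", {
  expect_equal(r_squared(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(r_squared(c(0, 0, 1, 1), c(0.2, 0.4, 0.6, 0.8)), 0.8)
  expect_warning(r0 <- r_squared(c(0, 1, 0, 1), rep(0.5, 4)), "zero variance")
  expect_equal(r0, 0)
  expect_error(r_squared(c(0, 1), c(0.5)), "length")
})

test_that("probit GLM recovers coefficients against the grid-search oracle", {
  set.seed(21)
  for (i in 1:6) {
    beta <- runif(2, -1, 1)
    d <- probit_rows(300, beta, intercept = runif(1, -0.3, 0.3), seed = 100 + i)
    fit <- fit_probit_glm(d, c("centrality", "saliency"))
    X <- as.matrix(d[c("centrality_z", "saliency_z")])
    want <- oracle_probit_grid(d$fixated, X)
    expect_true(fit$converged)
    expect_equal(unname(c(fit$intercept, unlist(fit$coefficients))), want,
                 tolerance = 1e-3)
  }
})

test_that("balanced null data give a zero intercept; separation is flagged", {
  d <- data.frame(centrality_z = rep(0, 40), fixated = rep(0:1, 20))
  fit <- fit_probit_glm(d, "centrality")
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_true("centrality_z" %in% fit$dropped)  # constant column dropped

  sep <- data.frame(centrality_z = c(-(20:1), 1:20) / 10,
                    fixated = rep(0:1, each = 20))
  expect_false(fit_probit_glm(sep, "centrality")$converged)
})

test_that("probit symmetry: negating predictors and swapping labels negates beta", {
  d <- probit_rows(400, c(0.6, -0.3), seed = 3)
  f1 <- fit_probit_glm(d, c("centrality", "saliency"))
  d2 <- d
  d2$centrality_z <- -d2$centrality_z
  d2$saliency_z <- -d2$saliency_z
  d2$fixated <- 1L - d2$fixated
  f2 <- fit_probit_glm(d2, c("centrality", "saliency"))
  expect_equal(unlist(f1$coefficients), unlist(f2$coefficients),
               tolerance = 1e-6)
  expect_equal(f1$intercept, -f2$intercept, tolerance = 1e-6)
})

test_that("GLMM with zero-variance grouping matches the plain GLM", {
  set.seed(4)
  n <- 50000
  d <- probit_rows(n, c(0.4, 0.25), seed = 17)
  d$participant <- factor(rep(1:8, length.out = n))
  d$video <- factor(rep(1:10, each = n / 10))
  g1 <- fit_probit_glm(d, c("centrality", "saliency"))
  g2 <- fit_probit_glmm(d, c("centrality", "saliency"))
  expect_true(all(unlist(g2$variances) <= 0.05))
  expect_equal(unlist(g1$coefficients), unlist(g2$coefficients),
               tolerance = 0.1)
  expect_true(max(abs(unlist(g1$coefficients) - unlist(g2$coefficients))) < 0.02)
  expect_error(fit_probit_glmm(d[d$participant == 1 & d$video == 1, ],
                               c("centrality")), "levels")
})

test_that("participant heterogeneity shows up in the variance components", {
  set.seed(6)
  n <- 20000
  P <- 10
  b <- rnorm(P, 0, 0.5)
  d <- probit_rows(n, c(0.3), seed = 23)
  d$participant <- factor(rep(1:P, length.out = n))
  d$video <- factor(rep(1:8, each = n / 8))
  d$fixated <- rbinom(n, 1, pnorm(0.3 * d$centrality_z + b[d$participant]))
  fit <- fit_probit_glmm(d, "centrality")
  expect_gt(fit$variances[["participant"]], 0.05)
  expect_lt(fit$variances[["participant"]], 0.6)
})

test_that("the incremental series is nested with non-decreasing log-likelihood", {
  obs <- tiny_obs()
  series <- incremental_series(obs, nAGQ = 0)
  expect_named(series, paste0("model", 1:5))
  expect_equal(names(series$model3$coefficients),
               c("centrality", "saliency", "roi"))
  expect_equal(names(series$model5$coefficients),
               c("centrality", "saliency", "roi", "saliency:roi",
                 "saliency:valence"))
  ll <- vapply(series, `[[`, numeric(1), "loglik")
  expect_true(all(diff(ll) > -1e-4 * abs(ll[-5])))
  r2 <- vapply(series, `[[`, numeric(1), "r_squared")
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("bootstrap summaries are seed-reproducible and order-invariant", {
  st <- tiny_study()
  labels <- tiny_prep()$labels
  cells <- lapply(st$videos, `[[`, "cells")
  b1 <- bootstrap_series(cells, labels, n_iter = 3, seed = 5, models = 1,
                         nAGQ = 0, grid = st$config$grid)
  b2 <- bootstrap_series(cells, labels, n_iter = 3, seed = 5, models = 1,
                         nAGQ = 0, grid = st$config$grid)
  expect_equal(b1$weights, b2$weights)
  expect_equal(b1$n_iterations, 3)
  expect_true(all(b1$weights$lower <= b1$weights$mean &
                    b1$weights$mean <= b1$weights$upper))
  expect_error(bootstrap_series(cells, labels, n_iter = 1, seed = 1,
                                grid = st$config$grid), ">= 2")
})
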