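make_weight_table <- function(w, terms = "saliency") {
  # w: participants x videos matrix (one term)
  data.frame(participant = rep(seq_len(nrow(w)), ncol(w)),
             video = rep(seq_len(ncol(w)), each = nrow(w)),
             term = terms, weight = as.vector(w),
             converged = !is.na(as.vector(w)))
}

test_that("Cronbach's alpha closed forms hold", {
  # two standardized items with correlation exactly 0.5 -> alpha = 2/3
  # (Spearman-Brown: alpha = k r / (1 + (k-1) r))
  set.seed(1)
  a <- rnorm(40)
  b <- rnorm(40)
  x1 <- as.numeric(scale(a))
  resid <- residuals(lm(b ~ a))          # exactly uncorrelated with x1
  z2 <- as.numeric(scale(resid))
  x2 <- 0.5 * x1 + sqrt(0.75) * z2
  expect_equal(cor(x1, x2), 0.5, tolerance = 1e-12)
  expect_equal(cronbach_alpha(cbind(x1, x2)), 2 / 3, tolerance = 1e-9)

  # additive participant x video structure without noise -> alpha = 1
  w <- outer(rnorm(8), rep(1, 10)) + outer(rep(1, 8), rnorm(10))
  a <- consistency_alpha(list(make_weight_table(w)))
  expect_equal(a$alpha, 1, tolerance = 1e-9)
})

test_that("independent random weights give alpha centred near zero", {
  set.seed(13)
  a <- replicate(20, {
    w <- matrix(rnorm(32 * 45), 32, 45)
    consistency_alpha(list(make_weight_table(w)))$alpha
  })
  # the null distribution of alpha is centred near 0 but has spread ~0.29
  # at 32 cases (driven by the chi-square noise of var(rowSums))
  expect_lt(abs(mean(a)), 0.2)
  expect_lt(median(abs(a)), 0.3)
  expect_true(all(a < 0.6))
})

test_that("alpha is exactly invariant to per-video shifts, robust to participant shifts", {
  set.seed(14)
  w <- outer(rnorm(8), rep(1, 12)) + matrix(rnorm(96, sd = 0.5), 8, 12)
  a1 <- consistency_alpha(list(make_weight_table(w)))$alpha
  # video-wise standardization removes per-video offsets exactly
  w_vid <- sweep(w, 2, rnorm(12, sd = 50), "+")
  expect_equal(consistency_alpha(list(make_weight_table(w_vid)))$alpha, a1,
               tolerance = 1e-9)
  # a constant added to one participant's profile perturbs the per-video
  # scale estimates, so invariance is approximate at realistic magnitudes
  w_par <- w; w_par[3, ] <- w_par[3, ] + 1
  expect_equal(consistency_alpha(list(make_weight_table(w_par)))$alpha, a1,
               tolerance = 0.05)
})

test_that("stable individual differences beat a shuffled-participant null", {
  set.seed(15)
  wins <- replicate(20, {
    w <- outer(rnorm(16), rep(1, 20)) + matrix(rnorm(320, sd = 0.4), 16, 20)
    a <- consistency_alpha(list(make_weight_table(w)))$alpha
    w_null <- apply(w, 2, sample)  # break profiles within each video
    a0 <- consistency_alpha(list(make_weight_table(w_null)))$alpha
    a > a0
  })
  expect_gte(sum(wins), 19)
})

test_that("PMM imputes from the nearest donor pool and preserves observed entries", {
  # donor-pool property on a constructed case
  set.seed(16)
  w <- matrix(rnorm(60), 6, 10)
  w[2, 3] <- NA
  tab <- make_weight_table(w)
  out <- pmm_impute(tab, m = 8, k_donors = 5, seed = 2)
  expect_length(out, 8)
  obs_pool <- tab$weight[!is.na(tab$weight)]
  for (t in out) {
    expect_false(anyNA(t$weight))
    expect_identical(t$weight[!is.na(tab$weight)], tab$weight[!is.na(tab$weight)])
    expect_true(t$weight[is.na(tab$weight)] %in% obs_pool)
  }
  # no missing entries: tables identical to the input
  full <- pmm_impute(make_weight_table(matrix(rnorm(20), 4, 5)), m = 3)
  expect_true(all(vapply(full, identical, logical(1), full[[1]])))
})

test_that("the nearest-donor rule picks among the k closest predicted values", {
  # internal donor draw: predicted 1.0, donors at 0.9/1.0/1.1/2.9/3.0, k = 3
  set.seed(17)
  draws <- replicate(200, gazescape:::pmm_draw(1.0, c(0.9, 1.0, 1.1, 2.9, 3.0),
                                               c(0.9, 1.0, 1.1, 2.9, 3.0), 3))
  expect_true(all(draws %in% c(0.9, 1.0, 1.1)))
  expect_equal(sort(unique(draws)), c(0.9, 1.0, 1.1))
})

test_that("ICC matches the ANOVA oracle and behaves at the extremes", {
  set.seed(18)
  x <- matrix(rnorm(24, sd = 0.3), 6, 4) + outer(rnorm(6, sd = 1), rep(1, 4))
  got <- icc(x)
  expect_equal(got$icc, oracle_icc_anova(x), tolerance = 1e-9)
  expect_true(got$lower <= got$icc && got$icc <= got$upper)

  # identical raters, differing videos -> ICC 1
  v <- rnorm(8)
  perfect <- icc(matrix(rep(v, 5), 8, 5))
  expect_equal(perfect$icc, 1, tolerance = 1e-9)

  # ratings independent of video -> ICC near 0 (32 raters x 90 videos)
  r <- simulate_ratings(32, 90, video_means = rep(5, 90),
                        rater_noise_sd = 2, seed = 3)
  names(r)[3] <- "valence"
  expect_lt(abs(icc(r)$icc), 0.1)
})

test_that("consistency analysis runs end to end on the tiny study", {
  st <- tiny_study()
  prep <- tiny_prep()
  social <- names(st$videos)[vapply(st$videos, `[[`, logical(1), "social")]
  labels <- prep$labels[prep$labels$video %in% as.integer(social), ]
  res <- consistency_analysis(lapply(st$videos, `[[`, "cells"), labels,
                              n_iter = 2, m = 2, k_donors = 3, seed = 9,
                              grid = st$config$grid)
  expect_equal(res$n_units, 3 * 2)   # 3 participants x 2 social videos
  expect_equal(nrow(res$alpha), 3)
  expect_equal(res$alpha$n_datasets, rep(4, 3))
})
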