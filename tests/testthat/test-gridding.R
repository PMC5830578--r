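test_that("grid aggregation averages cells and scales linearly", {
  g <- grid_spec(cell_px = 4, n_cols = 4, n_rows = 3)
  m <- array(2.5, c(12, 16, 2))
  agg <- aggregate_to_grid(m, g)
  expect_equal(dim(agg), c(2, 12))
  expect_true(all(agg == 2.5))
  # single hot pixel spreads over its cell only
  m2 <- array(0, c(12, 16, 1))
  m2[1, 1, 1] <- 16
  agg2 <- aggregate_to_grid(m2, g)
  expect_equal(agg2[1, 1], 1)
  expect_true(all(agg2[1, -1] == 0))
  # commutes with scaling
  set.seed(2)
  m3 <- array(runif(12 * 16), c(12, 16, 1))
  expect_equal(aggregate_to_grid(m3 * 3, g), 3 * aggregate_to_grid(m3, g))
  expect_error(aggregate_to_grid(array(0, c(10, 16, 1)), g), "divide")
})

test_that("the default grid is 32 x 18 cells of 40 px = 576 cells", {
  g <- grid_spec()
  expect_equal(g$n_cells, 576)
  expect_equal(c(g$width_px, g$height_px), c(1280, 720))
})

test_that("fixated-cell labelling uses half-open 40 px cells", {
  g <- grid_spec()
  expect_equal(label_fixated_cell(0, 0, g), 0L)
  expect_equal(label_fixated_cell(1279.9, 719.9, g), 575L)
  expect_equal(label_fixated_cell(40, 0, g), 1L)   # boundary goes right
  expect_equal(label_fixated_cell(0, 40, g), 32L)
  expect_true(is.na(label_fixated_cell(1280, 10, g)))
  expect_true(is.na(label_fixated_cell(-0.1, 10, g)))
})

test_that("observation matrix is balanced, standardized, and control cells differ", {
  st <- tiny_study()
  obs <- tiny_obs()
  labels <- tiny_prep()$labels
  expect_equal(nrow(obs), 2 * nrow(labels))
  expect_equal(sum(obs$fixated == 1), sum(obs$fixated == 0))
  # exactly one case and one control per labelled frame
  key <- paste(obs$participant, obs$video, obs$frame)
  expect_true(all(table(key) == 2))
  fx <- obs[obs$fixated == 1, ]
  ct <- obs[obs$fixated == 0, ]
  ord <- order(fx$participant, fx$video, fx$frame)
  ord2 <- order(ct$participant, ct$video, ct$frame)
  expect_true(all(fx$cell[ord] != ct$cell[ord2]))
  expect_true(all(obs$cell >= 0 & obs$cell < st$config$grid$n_cells))
  for (col in c("centrality_z", "saliency_z", "roi_z", "valence_z")) {
    expect_equal(mean(obs[[col]]), 0, tolerance = 1e-9)
    expect_equal(sd(obs[[col]]), 1, tolerance = 1e-9)
  }
})

test_that("redrawing controls changes only control rows", {
  st <- tiny_study()
  labels <- tiny_prep()$labels
  cells <- lapply(st$videos, `[[`, "cells")
  o1 <- build_observation_matrix(cells, labels, seed = 1, grid = st$config$grid)
  o2 <- build_observation_matrix(cells, labels, seed = 2, grid = st$config$grid)
  expect_identical(o1$cell[o1$fixated == 1], o2$cell[o2$fixated == 1])
  expect_false(identical(o1$cell[o1$fixated == 0], o2$cell[o2$fixated == 0]))
  # same seed reproduces bit-identically
  o3 <- build_observation_matrix(cells, labels, seed = 1, grid = st$config$grid)
  expect_identical(o1, o3)
})

test_that("degenerate predictors are flagged and zeroed", {
  st <- tiny_study()
  labels <- tiny_prep()$labels
  cells <- lapply(st$videos, `[[`, "cells")
  for (v in names(cells)) cells[[v]]$roi <- cells[[v]]$roi * 0
  obs <- build_observation_matrix(cells, labels, seed = 1,
                                  grid = st$config$grid)
  expect_true("roi_z" %in% attr(obs, "degenerate"))
  expect_true(all(obs$roi_z == 0))
})

test_that("looked-at saliency is 1 for uniform maps and approaches 1 under random gaze", {
  uni <- feature_stack(array(1, c(36, 64, 10)), "saliency")
  fg <- data.frame(frame = 0:9, x_px = runif(10, 0, 64),
                   y_px = runif(10, 0, 36), missing = FALSE)
  expect_equal(looked_at_saliency(fg, uni), 1)

  # law of large numbers over a mean-1 map
  set.seed(9)
  n <- 10000
  vals <- array(runif(36 * 64, 0.2, 1.8), c(36, 64, 1))
  vals <- vals / mean(vals)
  stack <- feature_stack(vals, "saliency")
  fg2 <- data.frame(frame = 0, x_px = runif(n, 0, 64),
                    y_px = runif(n, 0, 36), missing = FALSE)
  expect_equal(looked_at_saliency(fg2, stack), 1, tolerance = 0.05)

  # gaze pinned to the peak exceeds 1
  pk <- unname(which(vals[, , 1] == max(vals), arr.ind = TRUE))
  fg3 <- data.frame(frame = 0, x_px = pk[1, 2] - 0.5, y_px = pk[1, 1] - 0.5,
                    missing = FALSE)
  expect_gt(looked_at_saliency(fg3, stack), 1)

  expect_true(is.na(looked_at_saliency(
    data.frame(frame = 0, x_px = 1, y_px = 1, missing = TRUE), uni)))
})
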