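test_that("scenes are deterministic, bounded, and annotate one ROI row per frame per head", {
  spec <- scene_spec(width_px = 64, height_px = 36, n_frames = 10,
                     n_blobs = 2, n_heads = 1, head_radius_px = 5)
  s1 <- make_scene(spec, seed = 3)
  s2 <- make_scene(spec, seed = 3)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$roi, s2$roi)
  expect_false(identical(s1$frames, make_scene(spec, seed = 4)$frames))

  expect_equal(nrow(s1$roi), 10)
  expect_true(all(s1$roi$cx_px >= 0 & s1$roi$cx_px <= 63))
  expect_true(all(s1$roi$cy_px >= 0 & s1$roi$cy_px <= 35))
  expect_true(all(s1$frames >= 0 & s1$frames <= 1))

  empty <- make_scene(scene_spec(width_px = 64, height_px = 36, n_frames = 3,
                                 n_blobs = 0, n_heads = 0), seed = 1)
  expect_equal(nrow(empty$roi), 0)
  expect_equal(max(empty$frames) - min(empty$frames), 0)
})

test_that("reflecting trajectories stay inside bounds for fast motion", {
  spec <- scene_spec(width_px = 64, height_px = 36, n_frames = 200,
                     n_blobs = 0, n_heads = 1, head_radius_px = 4,
                     motion_speed_px_per_frame = 7)
  for (seed in 1:5) {
    roi <- make_scene(spec, seed = seed)$roi
    expect_true(all(roi$cx_px >= 4 - 1e-9 & roi$cx_px <= 59 + 1e-9))
    expect_true(all(roi$cy_px >= 4 - 1e-9 & roi$cy_px <= 31 + 1e-9))
  }
})

test_that("null gaze model selects cells uniformly; strong weights dominate", {
  draws <- draw_fixated_cells(rep(0, 576), 1e5, seed = 6)
  expect_true(all(draws >= 0 & draws < 576))
  p <- suppressWarnings(chisq.test(tabulate(draws + 1, 576))$p.value)
  expect_gt(p, 0.01)

  st <- tiny_study()
  cells <- st$videos[["1"]]$cells
  grid <- st$config$grid
  strong <- ground_truth(beta_centrality = 10, beta_saliency = 0,
                         beta_roi = 0, beta_interaction = 0,
                         participant_sd = 0, video_sd = 0)
  g <- suppressWarnings(simulate_gaze(cells, strong, 1, 1, grid,
                                      n_frames = 24, seed = 8,
                                      jitter_sd_px = 0, drift_sd_px = 0))
  fix <- attr(g, "fixated_cells")
  cen <- cells$centrality
  top <- which(cen == max(cen)) - 1L  # the argmax set (ties at an even grid)
  expect_gt(mean(fix %in% top), 0.99)
})

test_that("case-control refits recover the sign of a pure saliency effect", {
  st <- tiny_study()
  grid <- st$config$grid
  truth <- ground_truth(beta_centrality = 0, beta_saliency = 0.5,
                        beta_roi = 0, beta_interaction = 0,
                        participant_sd = 0, video_sd = 0)
  labels <- list()
  for (p in 1:4) for (v in 1:4) {
    g <- suppressWarnings(simulate_gaze(st$videos[[v]]$cells, truth, p, v,
                                        grid, n_frames = 24,
                                        seed = 100 * p + v))
    labels[[length(labels) + 1L]] <-
      data.frame(participant = p, video = v, frame = 0:23,
                 cell = attr(g, "fixated_cells"))
  }
  obs <- build_observation_matrix(lapply(st$videos, `[[`, "cells"),
                                  do.call(rbind, labels), seed = 2,
                                  grid = grid)
  fit <- fit_probit_glm(obs, c("centrality", "saliency", "roi"))
  expect_gt(fit$coefficients[["saliency"]], 0.1)
  expect_gt(fit$coefficients[["saliency"]],
            abs(fit$coefficients[["centrality"]]))
})

test_that("ratings generator hits exact means without noise and decays with noise", {
  exact <- simulate_ratings(5, 9, video_means = 1:9, rater_bias_sd = 0,
                            rater_noise_sd = 0, seed = 1)
  expect_true(all(exact$rating == exact$video))

  noisy <- simulate_ratings(32, 90, rater_bias_sd = 0, rater_noise_sd = 30,
                            seed = 2)
  names(noisy)[3] <- "valence"
  expect_lt(abs(icc(noisy)$icc), 0.1)

  # pilot-calibrated default: ICC near 0.65
  cal <- simulate_ratings(32, 90, seed = 3)
  names(cal)[3] <- "valence"
  expect_equal(icc(cal)$icc, 0.65, tolerance = 0.1)

  expect_error(simulate_ratings(2, 3, video_means = c(0, 5, 9)), "1, 9")
})

test_that("studies are deterministic in the master seed", {
  cfg <- study_config(n_participants = 2, n_videos = 2,
                      scene = scene_spec(width_px = 64, height_px = 36,
                                         n_frames = 6, n_blobs = 1,
                                         n_heads = 1))
  s1 <- make_study(cfg, seed = 5)
  s2 <- make_study(cfg, seed = 5)
  expect_identical(s1$gaze, s2$gaze)
  expect_identical(s1$ratings, s2$ratings)
  expect_identical(s1$videos[["1"]]$cells, s2$videos[["1"]]$cells)
  expect_false(identical(s1$gaze, make_study(cfg, seed = 6)$gaze))
})

test_that("a paper-layout study yields participants x videos x frames x 2 rows", {
  cfg <- study_config(n_participants = 6, n_videos = 9, n_social = 5,
                      scene = scene_spec(width_px = 64, height_px = 36,
                                         n_frames = 8, n_blobs = 1,
                                         n_heads = 1),
                      jitter_sd_px = 0, drift_sd_px = 0,
                      contam_outlier_prob = 0, contam_blink_prob = 0)
  st <- make_study(cfg, seed = 11)
  prep <- preprocess_study(st)
  # with zero jitter/drift and no contamination every frame is labelled,
  # except those removed entirely by the 150 ms onset exclusion
  excluded <- floor(0.150 * cfg$scene$fps)
  expect_equal(nrow(prep$labels),
               cfg$n_participants * cfg$n_videos * (8 - excluded))
  obs <- build_observation_matrix(lapply(st$videos, `[[`, "cells"),
                                  prep$labels, seed = 1, grid = cfg$grid)
  expect_equal(nrow(obs), 2 * nrow(prep$labels))
})
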