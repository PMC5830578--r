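# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

## Tiny complete study: 3 participants x 4 videos (2 social), 64 x 36 px,
## 24 frames. Shared by gridding / model / pipeline tests.
tiny_study <- function() {
  cached("tiny_study", function() {
    cfg <- study_config(
      n_participants = 3, n_videos = 4,
      scene = scene_spec(width_px = 64, height_px = 36, n_frames = 24,
                         n_blobs = 2, n_heads = 1),
      n_bootstrap = 2)
    make_study(cfg, seed = 42)
  })
}

tiny_prep <- function() {
  cached("tiny_prep", function() preprocess_study(tiny_study()))
}

tiny_obs <- function() {
  cached("tiny_obs", function() {
    st <- tiny_study()
    build_observation_matrix(lapply(st$videos, `[[`, "cells"),
                             tiny_prep()$labels,
                             data.frame(participant = st$ratings$participant,
                                        video = st$ratings$video,
                                        valence = st$ratings$valence),
                             seed = 11, grid = st$config$grid)
  })
}

## Recovery-study predictor maps: 10 videos (5 social) of 120 frames at
## 64 x 36 px (2 px grid cells keep the 32 x 18 grid exact). Built once.
recovery_cells <- function() {
  cached("recovery_cells", function() {
    grid <- grid_spec(cell_px = 2)
    cen <- aggregate_to_grid(centrality_map(64, 36), grid)
    cells <- lapply(1:10, function(v) {
      sp <- scene_spec(width_px = 64, height_px = 36, n_frames = 120,
                       n_blobs = 3, n_heads = if (v <= 5) 2 else 0)
      sc <- make_scene(sp, seed = 9000 + v)
      sal <- normalize_mean1(temporal_blur(compute_saliency_stack(sc$frames)))
      list(centrality = cen[1, ],
           saliency = aggregate_to_grid(sal, grid),
           roi = aggregate_to_grid(roi_mask_stack(sc$roi, 64, 36, 120), grid))
    })
    names(cells) <- as.character(1:10)
    cells
  })
}

## Draw fixated-cell labels for all participants directly from the softmax
## gaze model (participant/video intercepts cancel within a frame).
recovery_labels <- function(cells, truth, n_participants, seed) {
  labs <- list()
  for (v in names(cells)) {
    U <- suppressWarnings(
      gazescape:::cell_utilities(cells[[v]], truth, 120, 576))
    draws <- gazescape:::with_seed(gazescape:::derive_seed(seed, "lab", v), {
      vapply(seq_len(120), function(f) {
        p <- exp(U[f, ] - max(U[f, ]))
        sample.int(576, n_participants, replace = TRUE, prob = p) - 1L
      }, integer(n_participants))
    })
    # draws: n_participants x 120
    labs[[v]] <- data.frame(
      participant = rep(seq_len(n_participants), times = 120),
      video = as.integer(v),
      frame = rep(0:119, each = n_participants),
      cell = as.integer(draws))
  }
  do.call(rbind, labs)
}

## Balanced case-control rows with known probit structure (no grouping).
probit_rows <- function(n, beta, intercept = 0, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    X <- matrix(rnorm(n * length(beta)), n)
    eta <- intercept + X %*% beta
    y <- rbinom(n, 1, pnorm(eta))
    d <- data.frame(X, fixated = y)
    names(d) <- c(paste0(c("centrality", "saliency", "roi")[seq_along(beta)],
                         "_z"), "fixated")
    d
  })
}
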