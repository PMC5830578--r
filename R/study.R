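# Assembly of a complete synthetic study: scenes, predictor maps, gaze,
# ratings and physiology with a shared ground truth.

#' Study configuration
#'
#' Bundles every generator parameter. The default is a mini-study (4
#' participants x 6 videos, half social) at reduced resolution; pass
#' `n_participants = 32, n_videos = 90, n_social = 45` and a full-size
#' [scene_spec()] for the full-scale layout. Gaze jitter and drift default to
#' 5 px at the reference width of 1280 px and scale proportionally with the
#' frame width, keeping the angular noise constant across resolutions.
#'
#' @param n_participants,n_videos study dimensions.
#' @param n_social number of videos containing heads (the first `n_social`
#'   video ids).
#' @param scene a [scene_spec()]; its width/height must divide into the grid.
#' @param truth a [ground_truth()].
#' @param grid a [grid_spec()] (defaults to 32 x 18 cells sized to the
#'   scene).
#' @param sampling_rate gaze sampling rate (Hz).
#' @param jitter_sd_px,drift_sd_px gaze noise (defaults scale with width).
#' @param pre_ms pre-stimulus fixation segment length.
#' @param contam_outlier_prob,contam_blink_prob per-trial probabilities of
#'   baseline contamination (displaced samples / a blink run); defaults give
#'   a replaced-baseline rate near 9% of trials.
#' @param contam_frac fraction of baseline samples affected within a
#'   contaminated trial.
#' @param rating_noise named numeric, per-scale rater noise SDs (defaults
#'   produce high/medium/low inter-rater consistency for valence, arousal
#'   and relevance respectively).
#' @param rater_bias_sd per-participant rating shift SD.
#' @param physio named list of [simulate_physio()] overrides.
#' @param n_bootstrap,m_imputations pipeline defaults carried in the config.
#' @return A `study_config` object.
#' @export
study_config <- function(n_participants = 4, n_videos = 6,
                         n_social = ceiling(n_videos / 2),
                         scene = scene_spec(width_px = 160, height_px = 90,
                                            n_frames = 120, n_blobs = 3,
                                            n_heads = 2),
                         truth = ground_truth(),
                         grid = grid_spec(cell_px = scene$width_px %/% 32),
                         sampling_rate = 250,
                         jitter_sd_px = 5 * scene$width_px / 1280,
                         drift_sd_px = 5 * scene$width_px / 1280,
                         pre_ms = 1000,
                         contam_outlier_prob = 0.06,
                         contam_blink_prob = 0.03,
                         contam_frac = 0.1,
                         rating_noise = c(valence = 1.15, arousal = 1.75,
                                          relevance = 3.4),
                         rater_bias_sd = 0.5,
                         physio = list(),
                         n_bootstrap = 10, m_imputations = 5) {
  if (grid$width_px != scene$width_px || grid$height_px != scene$height_px)
    stop("grid does not tile the scene exactly")
  if (n_social > n_videos) stop("'n_social' cannot exceed 'n_videos'")
  structure(list(n_participants = as.integer(n_participants),
                 n_videos = as.integer(n_videos),
                 n_social = as.integer(n_social), scene = scene,
                 truth = truth, grid = grid, sampling_rate = sampling_rate,
                 jitter_sd_px = jitter_sd_px, drift_sd_px = drift_sd_px,
                 pre_ms = pre_ms, contam_outlier_prob = contam_outlier_prob,
                 contam_blink_prob = contam_blink_prob,
                 contam_frac = contam_frac, rating_noise = rating_noise,
                 rater_bias_sd = rater_bias_sd, physio = physio,
                 n_bootstrap = n_bootstrap, m_imputations = m_imputations),
            class = "study_config")
}

#' Generate a complete synthetic study
#'
#' Builds scenes and ROI tracks, computes the three predictor map stacks
#' (graph-based saliency -> temporal blur -> mean-1 normalization; central
#' bias; ROI masks), collapses them to the grid, draws participant and video
#' intercepts from the ground truth, simulates gaze for every participant x
#' video trial, and generates ratings (valence, arousal, relevance) and
#' trial physiology. Deterministic given `(config, seed)`.
#'
#' @param config a [study_config()].
#' @param seed integer master seed; every component uses a derived stream.
#' @param keep_frames keep rendered frames in the result (memory-hungry;
#'   default FALSE, the predictor maps are always kept).
#' @return A `gaze_study` object: list with `config`, `truth`, `videos`
#'   (per video: `social`, `roi`, `cells` (grid tables), `saliency`
#'   (normalized pixel stack)), `gaze` (raw sample data.frame), `ratings`,
#'   `physio`, `intercepts`, `seed`.
#' @export
make_study <- function(config = study_config(), seed = 1L,
                       keep_frames = FALSE) {
  stopifnot(inherits(config, "study_config"))
  sc <- config$scene
  grid <- config$grid
  cen_grid <- aggregate_to_grid(centrality_map(sc$width_px, sc$height_px), grid)
  videos <- vector("list", config$n_videos)
  for (v in seq_len(config$n_videos)) {
    social <- v <= config$n_social
    spec_v <- sc
    if (!social) spec_v$n_heads <- 0L
    scene <- make_scene(spec_v, derive_seed(seed, "scene", v))
    sal <- normalize_mean1(temporal_blur(compute_saliency_stack(scene$frames)))
    roi_stack <- roi_mask_stack(scene$roi, sc$width_px, sc$height_px,
                                sc$n_frames)
    videos[[v]] <- list(
      id = v, social = social, roi = scene$roi,
      cells = list(centrality = cen_grid[1, ],
                   saliency = aggregate_to_grid(sal, grid),
                   roi = aggregate_to_grid(roi_stack, grid)),
      saliency = sal,
      frames = if (keep_frames) scene$frames else NULL)
  }
  names(videos) <- as.character(seq_len(config$n_videos))
  b_p <- with_seed(derive_seed(seed, "b_participant"),
                   stats::rnorm(config$n_participants, 0,
                                config$truth$participant_sd))
  b_v <- with_seed(derive_seed(seed, "b_video"),
                   stats::rnorm(config$n_videos, 0, config$truth$video_sd))
  ## stable per-participant weight offsets: the source of the individual
  ## differences the consistency analysis quantifies
  beta_p <- with_seed(derive_seed(seed, "beta_participant"),
                      matrix(stats::rnorm(3 * config$n_participants, 0,
                                          config$truth$beta_participant_sd %||% 0),
                             nrow = 3,
                             dimnames = list(c("beta_centrality",
                                               "beta_saliency", "beta_roi"),
                                             NULL)))
  gaze <- vector("list", config$n_participants * config$n_videos)
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    for (v in seq_len(config$n_videos)) {
      k <- k + 1L
      tseed <- derive_seed(seed, "gaze", p, v)
      flags <- with_seed(derive_seed(seed, "contam", p, v),
                         stats::runif(2))
      truth_p <- config$truth
      for (nm in rownames(beta_p)) truth_p[[nm]] <- truth_p[[nm]] + beta_p[nm, p]
      gaze[[k]] <- suppressWarnings(simulate_gaze(
        videos[[v]]$cells, truth_p, p, v, grid,
        n_frames = sc$n_frames, fps = sc$fps,
        sampling_rate = config$sampling_rate,
        participant_intercept = b_p[p], video_intercept = b_v[v],
        jitter_sd_px = config$jitter_sd_px,
        drift_sd_px = config$drift_sd_px, pre_ms = config$pre_ms,
        contaminate_outliers = flags[1] < config$contam_outlier_prob,
        contaminate_blink = flags[2] < config$contam_blink_prob,
        contam_frac = config$contam_frac, seed = tseed))
    }
  }
  ratings <- NULL
  for (scale_nm in names(config$rating_noise)) {
    r <- simulate_ratings(config$n_participants, config$n_videos,
                          rater_bias_sd = config$rater_bias_sd,
                          rater_noise_sd = config$rating_noise[[scale_nm]],
                          seed = derive_seed(seed, "ratings", scale_nm))
    if (is.null(ratings)) {
      ratings <- r
      names(ratings)[names(ratings) == "rating"] <- scale_nm
    } else {
      ratings[[scale_nm]] <- r$rating
    }
  }
  physio_args <- utils::modifyList(
    list(n_trials = config$n_videos,
         trial_dur_s = sc$n_frames / sc$fps,
         seed = derive_seed(seed, "physio")),
    config$physio)
  physio <- lapply(seq_len(config$n_participants), function(p)
    do.call(simulate_physio, physio_args))
  names(physio) <- as.character(seq_len(config$n_participants))
  structure(list(config = config, truth = config$truth, videos = videos,
                 gaze = do.call(rbind, gaze), ratings = ratings,
                 physio = physio,
                 intercepts = list(participant = b_p, video = b_v),
                 participant_betas = beta_p,
                 seed = as.integer(seed)),
            class = "gaze_study")
}

#' @export
print.gaze_study <- function(x, ...) {
  cat(sprintf("gaze_study: %d participants x %d videos (%d social), %dx%d px, %d frames @ %g fps\n",
              x$config$n_participants, x$config$n_videos, x$config$n_social,
              x$config$scene$width_px, x$config$scene$height_px,
              x$config$scene$n_frames, x$config$scene$fps))
  cat(sprintf("  %d gaze samples, seed %d\n", nrow(x$gaze), x$seed))
  invisible(x)
}
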