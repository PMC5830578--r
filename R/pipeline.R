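# End-to-end orchestration: preprocessing -> labelling -> models ->
# consistency -> ratings -> physiology, with reproducible seeding and
# TSV/JSON outputs.

#' Preprocess a study's gaze and label fixated grid cells
#'
#' Runs drift correction (with recursive-outlier baseline estimation and
#' onset exclusion) per participant, aligns samples to frames, and labels
#' the fixated grid cell per non-missing frame.
#'
#' @param study a `gaze_study` (or any list with `gaze`, `config`).
#' @return List with `labels` (data.frame `participant`, `video`, `frame`,
#'   `cell`), `frame_gaze` (per-trial frame-aligned gaze, named
#'   `"participant.video"`), `baselines` (per participant) and
#'   `n_missing_frames`.
#' @export
preprocess_study <- function(study) {
  sc <- study$config$scene
  grid <- study$config$grid
  labels <- list()
  frame_gaze <- list()
  baselines <- list()
  for (p in unique(study$gaze$participant)) {
    gp <- study$gaze[study$gaze$participant == p, , drop = FALSE]
    corr <- correct_trials(gp, sc$width_px, sc$height_px)
    baselines[[as.character(p)]] <- attr(corr, "baselines")
    for (v in unique(corr$video)) {
      tr <- corr[corr$video == v, , drop = FALSE]
      fg <- align_gaze_to_frames(tr, sc$n_frames, sc$fps,
                                 sc$width_px, sc$height_px)
      frame_gaze[[paste(p, v, sep = ".")]] <- fg
      ok <- !fg$missing
      if (any(ok)) {
        labels[[length(labels) + 1L]] <- data.frame(
          participant = p, video = v, frame = fg$frame[ok],
          cell = label_fixated_cell(fg$x_px[ok], fg$y_px[ok], grid))
      }
    }
  }
  labels <- do.call(rbind, labels)
  labels <- labels[!is.na(labels$cell), , drop = FALSE]
  rownames(labels) <- NULL
  list(labels = labels, frame_gaze = frame_gaze, baselines = baselines,
       n_missing_frames = study$config$n_participants *
         study$config$n_videos * sc$n_frames - nrow(labels))
}

## grid cell tables of a study, keyed by video id
study_cells <- function(study) lapply(study$videos, `[[`, "cells")

## ratings in the two-column form build_observation_matrix() expects
valence_ratings <- function(study) {
  data.frame(participant = study$ratings$participant,
             video = study$ratings$video,
             valence = study$ratings$valence)
}

#' Run the full analysis pipeline on a study
#'
#' Executes preprocessing, looked-at-pixel saliency, the incremental probit
#' GLMM series with bootstrap percentile intervals over control-cell
#' redraws, the intra-individual consistency analysis (per-unit fits on
#' social videos, PMM imputation, video-wise z-standardization, Cronbach's
#' alpha), individualized valence reclassification, ratings ICCs and
#' trial-level autonomic summaries. Re-running with the same study and seed
#' reproduces all outputs.
#'
#' @param study a `gaze_study` from [make_study()].
#' @param seed master seed for control draws and imputation.
#' @param n_bootstrap bootstrap iterations (default from the study config).
#' @param models integer subset of 1:5 to fit.
#' @param nAGQ GLMM integration setting (see [fit_probit_glmm()]).
#' @param consistency_iter control redraws for the consistency analysis
#'   (default `n_bootstrap`).
#' @param out_dir optional directory; when given, results are written as
#'   TSV/CSV/JSON (see [write_pipeline_results()]).
#' @return A `pipeline_result` list: `labels`, `looked_at` (per-trial mean
#'   saliency at gaze), `series` (single-draw fits), `bootstrap`
#'   (`bootstrap_summary`), `consistency`, `valence_classes`, `icc`
#'   (per rating scale), `physio` (per-trial HR/EDA summaries), `manifest`.
#' @export
run_pipeline <- function(study, seed = study$seed %||% 1L,
                         n_bootstrap = study$config$n_bootstrap,
                         models = 1:5, nAGQ = 1,
                         consistency_iter = n_bootstrap, out_dir = NULL) {
  stopifnot(inherits(study, "gaze_study"))
  grid <- study$config$grid
  pre <- preprocess_study(study)

  looked <- list()
  for (key in names(pre$frame_gaze)) {
    pv <- strsplit(key, ".", fixed = TRUE)[[1]]
    sal <- study$videos[[pv[2]]]$saliency
    looked[[key]] <- data.frame(participant = pv[1], video = pv[2],
                                social = study$videos[[pv[2]]]$social,
                                mean_saliency =
                                  looked_at_saliency(pre$frame_gaze[[key]], sal))
  }
  looked <- do.call(rbind, looked)
  rownames(looked) <- NULL

  cells <- study_cells(study)
  obs <- build_observation_matrix(cells, pre$labels, valence_ratings(study),
                                  seed = derive_seed(seed, "obs"), grid = grid)
  series <- incremental_series(obs, models = models, nAGQ = nAGQ)
  boot <- bootstrap_series(cells, pre$labels, valence_ratings(study),
                           n_iter = n_bootstrap,
                           seed = derive_seed(seed, "boot"),
                           grid = grid, models = models, nAGQ = nAGQ)

  social_ids <- names(study$videos)[vapply(study$videos, `[[`, logical(1),
                                           "social")]
  soc_labels <- pre$labels[pre$labels$video %in% as.integer(social_ids), ,
                           drop = FALSE]
  n_soc_units <- length(social_ids) * study$config$n_participants
  consistency <- consistency_analysis(
    cells, soc_labels, valence_ratings(study),
    n_iter = consistency_iter, m = study$config$m_imputations,
    k_donors = max(2L, min(5L, n_soc_units - 1L)),
    seed = derive_seed(seed, "consistency"), grid = grid)

  valence_classes <- lapply(split(study$ratings, study$ratings$participant),
                            function(rp) reclassify_valence(rp$valence, rp$video))
  iccs <- lapply(intersect(c("valence", "arousal", "relevance"),
                           names(study$ratings)),
                 function(scale_nm) icc(study$ratings, value = scale_nm))
  names(iccs) <- intersect(c("valence", "arousal", "relevance"),
                           names(study$ratings))

  physio <- list()
  dur_s <- study$config$physio$trial_dur_s %||%
    (study$config$scene$n_frames / study$config$scene$fps)
  end_s <- max(1, floor(dur_s))
  for (p in names(study$physio)) {
    ph <- study$physio[[p]]
    for (tr in unique(ph$r_peaks$trial)) {
      hr <- hr_per_second(ph$r_peaks$t_s[ph$r_peaks$trial == tr],
                          start = -1, end = end_s)
      s <- trial_autonomic_summary(hr, ph$eda[ph$eda$trial == tr, ],
                                   trial_start = -1, trial_end = dur_s)
      physio[[length(physio) + 1L]] <-
        data.frame(participant = p, trial = tr,
                   hr_mean_delta = s$hr_mean_delta,
                   eda_mean_delta = s$eda_mean_delta)
    }
  }
  physio <- do.call(rbind, physio)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gazescape")),
    seed = seed, n_bootstrap = n_bootstrap,
    models_fitted = length(series), nAGQ = nAGQ,
    n_participants = study$config$n_participants,
    n_videos = study$config$n_videos,
    n_observation_rows = nrow(obs),
    n_missing_frames = pre$n_missing_frames,
    nonconverged_units = consistency$n_nonconverged)

  res <- structure(list(labels = pre$labels, baselines = pre$baselines,
                        looked_at = looked, observation = obs,
                        series = series, bootstrap = boot,
                        consistency = consistency,
                        valence_classes = valence_classes, icc = iccs,
                        physio = physio, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_results(res, study, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("pipeline_result: %d x %d study, %d observation rows, %d models, %d bootstrap iterations\n",
              m$n_participants, m$n_videos, m$n_observation_rows,
              m$models_fitted, x$bootstrap$n_iterations))
  cat(sprintf("  mean looked-at saliency: %.3f\n",
              mean(x$looked_at$mean_saliency, na.rm = TRUE)))
  r2 <- x$bootstrap$r2
  cat(sprintf("  R^2 by model: %s\n",
              paste(sprintf("%.3f", r2$mean), collapse = ", ")))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Emits the standard plain-text outputs: corrected labels and looked-at
#' saliency (CSV), the observation matrix with its standardization sidecar
#' (TSV + JSON), the model summary table (TSV), consistency and ICC results
#' (TSV/JSON), physiology summaries (TSV) and a run manifest (JSON).
#'
#' @param result a `pipeline_result`.
#' @param study the `gaze_study` it came from.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE)
  wtsv <- function(d, f) utils::write.table(d, file.path(dir, f),
                                            sep = "\t", row.names = FALSE,
                                            quote = FALSE)
  wcsv(result$labels, "labels.csv")
  wcsv(result$looked_at, "looked_at_saliency.csv")
  wtsv(result$observation, "observation_matrix.tsv")
  jsonlite::write_json(attr(result$observation, "standardization"),
                       file.path(dir, "observation_matrix.json"),
                       auto_unbox = TRUE, digits = NA)
  wtsv(summary_table(result$bootstrap), "model_table.tsv")
  wtsv(result$consistency$alpha, "consistency_alpha.tsv")
  jsonlite::write_json(result$icc, file.path(dir, "icc.json"),
                       auto_unbox = TRUE, digits = NA)
  classes <- do.call(rbind, lapply(names(result$valence_classes), function(p) {
    vc <- result$valence_classes[[p]]
    data.frame(participant = p, video = names(vc$category),
               category = as.character(vc$category), t1 = vc$t1, t2 = vc$t2)
  }))
  wcsv(classes, "valence_categories.csv")
  wtsv(result$physio, "physio_summary.tsv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a study's raw data in the pipeline's interchange formats
#'
#' Gaze streams (`participant,video,t_ms,x_px,y_px,valid`), ROI annotations
#' (`video,frame,cx_px,cy_px,r_px`), ratings
#' (`participant,video,valence,arousal,relevance`) as CSV and the ground
#' truth as JSON.
#'
#' @param study a `gaze_study`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$gaze, file.path(dir, "gaze.csv"), row.names = FALSE)
  roi <- do.call(rbind, lapply(study$videos, function(v)
    if (nrow(v$roi)) cbind(video = v$id, v$roi) else NULL))
  utils::write.csv(roi %||% data.frame(video = integer(0), frame = integer(0),
                                       cx_px = numeric(0), cy_px = numeric(0),
                                       r_px = numeric(0)),
                   file.path(dir, "roi.csv"), row.names = FALSE)
  utils::write.csv(study$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(study$truth),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a frame stack as a PNG directory
#'
#' One numbered PNG per frame (`frame_0000.png`, ...), 8-bit. Accepts RGB
#' (`h x w x 3 x n`) or grayscale (`h x w x n`) arrays in `[0, 1]`.
#'
#' @param frames numeric array.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames_png <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) stop("'frames' must be h x w x n or h x w x 3 x n")
  n <- dim(frames)[nd]
  for (t in seq_len(n)) {
    fr <- if (nd == 4L) frames[, , , t] else frames[, , t]
    png::writePNG(fr, file.path(dir, sprintf("frame_%04d.png", t - 1L)))
  }
  invisible(dir)
}

#' Read a PNG frame directory back into an array
#'
#' @param dir directory of numbered PNGs written by [write_frames_png()].
#' @return Array `h x w x 3 x n` (RGB) or `h x w x n` (grayscale).
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames found")
  first <- png::readPNG(files[1])
  rgb <- length(dim(first)) == 3L
  out <- if (rgb) array(0, c(dim(first), length(files)))
         else array(0, c(dim(first), length(files)))
  for (i in seq_along(files)) {
    fr <- png::readPNG(files[i])
    if (rgb) out[, , , i] <- fr else out[, , i] <- fr
  }
  out
}
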