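# Collapsing predictor maps to the fixation grid, labelling fixated cells,
# and building the balanced case-control observation matrix.

#' Fixation grid specification
#'
#' The analysis grid divides the video into `n_cols x n_rows` square cells of
#' `cell_px` pixels (defaults: 32 x 18 cells of 40 px for a 1280 x 720 video).
#' Cells are indexed row-major from the top-left, 0-based.
#'
#' @param cell_px cell edge length in pixels.
#' @param n_cols,n_rows grid dimensions.
#' @return A `grid_spec` object with fields `cell_px`, `n_cols`, `n_rows`,
#'   `n_cells`, `width_px`, `height_px`.
#' @export
grid_spec <- function(cell_px = 40, n_cols = 32, n_rows = 18) {
  stopifnot_scalar(cell_px, "cell_px", integer = TRUE)
  stopifnot_scalar(n_cols, "n_cols", integer = TRUE)
  stopifnot_scalar(n_rows, "n_rows", integer = TRUE)
  structure(list(cell_px = as.integer(cell_px), n_cols = as.integer(n_cols),
                 n_rows = as.integer(n_rows),
                 n_cells = as.integer(n_cols * n_rows),
                 width_px = as.integer(n_cols * cell_px),
                 height_px = as.integer(n_rows * cell_px)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %d px (%d cells, %d x %d px video)\n",
              x$n_cols, x$n_rows, x$cell_px, x$n_cells, x$width_px, x$height_px))
  invisible(x)
}

#' Collapse a map stack to grid-cell means
#'
#' Each grid cell's value is the arithmetic mean of its `cell_px^2` pixels.
#' Map dimensions must be exactly divisible into the grid (no partial cells).
#'
#' @param stack a [feature_stack()] or 3-D array `h x w x n`.
#' @param grid a [grid_spec()] whose pixel dimensions match the stack.
#' @return Numeric matrix `n_frames x n_cells` (cells row-major, 0-based
#'   column `j` holds cell index `j - 1`). Single-frame (static) stacks give
#'   a 1-row matrix.
#' @export
aggregate_to_grid <- function(stack, grid) {
  vals <- if (inherits(stack, "feature_stack")) stack$values else stack
  stopifnot(is.array(vals), length(dim(vals)) == 3L)
  h <- dim(vals)[1]; w <- dim(vals)[2]; n <- dim(vals)[3]
  if (w != grid$width_px || h != grid$height_px)
    stop(sprintf("map %dx%d px does not divide into the %dx%d grid of %d px cells",
                 w, h, grid$n_cols, grid$n_rows, grid$cell_px))
  row_f <- rep(seq_len(grid$n_rows), each = grid$cell_px)
  col_f <- rep(seq_len(grid$n_cols), each = grid$cell_px)
  out <- matrix(0, n, grid$n_cells)
  for (t in seq_len(n)) {
    cm <- rowsum(vals[, , t], row_f, reorder = TRUE)          # n_rows x w
    cm <- rowsum(t(cm), col_f, reorder = TRUE)                # n_cols x n_rows
    # cm[c, r] = sum over cell (r, c); row-major index = (r-1)*n_cols + c
    out[t, ] <- as.vector(cm) / grid$cell_px^2
  }
  out
}

#' Grid cell containing a gaze point
#'
#' Half-open cells: `col = floor(x / cell_px)`, `row = floor(y / cell_px)`,
#' `index = row * n_cols + col` (0-based, row-major).
#'
#' @param x_px,y_px gaze coordinates (vectors allowed), must lie in
#'   `[0, width) x [0, height)`; out-of-bounds points give `NA` (the frame is
#'   treated as missing).
#' @param grid a [grid_spec()].
#' @return Integer cell indices in `[0, n_cells)`, `NA` where out of bounds.
#' @export
label_fixated_cell <- function(x_px, y_px, grid) {
  col <- floor(x_px / grid$cell_px)
  row <- floor(y_px / grid$cell_px)
  idx <- row * grid$n_cols + col
  oob <- x_px < 0 | x_px >= grid$width_px | y_px < 0 | y_px >= grid$height_px
  idx[oob | is.na(x_px) | is.na(y_px)] <- NA
  as.integer(idx)
}

#' Balanced case-control observation matrix
#'
#' For every labelled (participant, video, frame) the fixated cell's predictor
#' row is emitted together with exactly one control row drawn uniformly from
#' the remaining `n_cells - 1` non-fixated cells, using an independent seeded
#' stream per participant x video. Predictors (centrality, saliency, ROI) and
#' the participant's valence rating are then z-standardized over all emitted
#' rows; the constants used are stored in the attributes for reuse.
#'
#' @param cells named list, one element per video id, each a list with
#'   elements `centrality` (length `n_cells` vector or 1-row matrix),
#'   `saliency` and `roi` (matrices `n_frames x n_cells` from
#'   [aggregate_to_grid()]).
#' @param labels data.frame with columns `participant`, `video`, `frame`
#'   (0-based), `cell` (0-based fixated cell index); rows with `NA` cells are
#'   dropped.
#' @param ratings data.frame with columns `participant`, `video`, `valence`
#'   (1-9); may be `NULL`, in which case the valence column is 0.
#' @param seed integer master seed for the control draws.
#' @param grid a [grid_spec()] (only `n_cells` is used).
#' @return data.frame with columns `participant`, `video`, `frame`, `cell`,
#'   `centrality_z`, `saliency_z`, `roi_z`, `valence_z`, `fixated`; attributes
#'   `standardization` (per-predictor center/scale), `degenerate` (names of
#'   zero-variance predictors, standardized to 0) and `seed`.
#' @export
build_observation_matrix <- function(cells, labels, ratings = NULL, seed = 1L,
                                     grid = grid_spec()) {
  labels <- labels[!is.na(labels$cell), , drop = FALSE]
  if (nrow(labels) == 0L) stop("no labelled frames")
  n_cells <- grid$n_cells
  if (any(labels$cell < 0 | labels$cell >= n_cells))
    stop("fixated cell index out of range")
  parts <- split(seq_len(nrow(labels)),
                 list(labels$participant, labels$video), drop = TRUE)
  control <- integer(nrow(labels))
  for (p in parts) {
    pv_seed <- derive_seed(seed, "control",
                           labels$participant[p[1]], labels$video[p[1]])
    draw <- with_seed(pv_seed,
                      sample.int(n_cells - 1L, length(p), replace = TRUE) - 1L)
    control[p] <- draw + (draw >= labels$cell[p])
  }
  pull <- function(cellidx) {
    cen <- sal <- roi <- numeric(nrow(labels))
    for (v in unique(labels$video)) {
      i <- which(labels$video == v)
      cv <- cells[[as.character(v)]]
      if (is.null(cv)) stop(sprintf("no cell table for video '%s'", v))
      cenv <- as.vector(cv$centrality)
      fr <- labels$frame[i] + 1L
      cl <- cellidx[i] + 1L
      cen[i] <- cenv[cl]
      sal[i] <- cv$saliency[cbind(fr, cl)]
      roi[i] <- cv$roi[cbind(fr, cl)]
    }
    list(cen = cen, sal = sal, roi = roi)
  }
  fx <- pull(labels$cell)
  ct <- pull(control)
  val <- if (is.null(ratings)) rep(0, nrow(labels)) else {
    key <- paste(labels$participant, labels$video)
    rkey <- paste(ratings$participant, ratings$video)
    ratings$valence[match(key, rkey)]
  }
  out <- data.frame(
    participant = rep(labels$participant, 2L),
    video = rep(labels$video, 2L),
    frame = rep(labels$frame, 2L),
    cell = c(labels$cell, control),
    centrality_z = c(fx$cen, ct$cen),
    saliency_z = c(fx$sal, ct$sal),
    roi_z = c(fx$roi, ct$roi),
    valence_z = rep(val, 2L),
    fixated = rep(c(1L, 0L), each = nrow(labels)))
  degenerate <- character(0)
  standardization <- list()
  for (col in c("centrality_z", "saliency_z", "roi_z", "valence_z")) {
    mu <- mean(out[[col]])
    sdv <- stats::sd(out[[col]])
    if (!is.finite(sdv) || sdv == 0) {
      degenerate <- c(degenerate, col)
      out[[col]] <- out[[col]] * 0
      standardization[[col]] <- c(center = mu, scale = NA_real_)
    } else {
      out[[col]] <- (out[[col]] - mu) / sdv
      standardization[[col]] <- c(center = mu, scale = sdv)
    }
  }
  attr(out, "standardization") <- standardization
  attr(out, "degenerate") <- degenerate
  attr(out, "seed") <- seed
  out
}

#' Mean low-level saliency at looked-at pixels
#'
#' For each trial, the mean over non-missing frames of the (mean-1
#' normalized) saliency value at the gaze position, via nearest-pixel lookup.
#' Under viewing behaviour not guided by low-level saliency the expected
#' value is 1.
#'
#' @param frame_gaze data.frame from [align_gaze_to_frames()] (columns
#'   `frame`, `x_px`, `y_px`, `missing`).
#' @param saliency a mean-1 normalized [feature_stack()] of kind `"saliency"`.
#' @return Scalar trial mean, or `NA` if every frame is missing.
#' @export
looked_at_saliency <- function(frame_gaze, saliency) {
  vals <- if (inherits(saliency, "feature_stack")) saliency$values else saliency
  g <- frame_gaze[!frame_gaze$missing, , drop = FALSE]
  if (nrow(g) == 0L) return(NA_real_)
  px <- pmin(pmax(floor(g$x_px), 0), dim(vals)[2] - 1L) + 1L
  py <- pmin(pmax(floor(g$y_px), 0), dim(vals)[1] - 1L) + 1L
  # a single-frame stack is static and shared by all frames
  fr <- if (dim(vals)[3] == 1L) rep(1L, nrow(g)) else g$frame + 1L
  mean(vals[cbind(py, px, fr)])
}
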