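# Predictor map construction: graph-based low-level saliency (intensity,
# colour-opponent, orientation, flicker channels), temporal blurring,
# mean-1 normalization, central-bias maps and circular social-ROI masks.

#' Per-frame scalar map stack
#'
#' Container for per-frame predictor maps aligned to video pixel space.
#' `values` is a `height x width x n_frames` array (`n_frames = 1` denotes a
#' static map such as centrality, implicitly shared by all frames).
#'
#' @param values numeric array `h x w x n` (a matrix is treated as one frame).
#' @param kind one of `"saliency"`, `"centrality"`, `"roi"`.
#' @return A `feature_stack` object.
#' @export
feature_stack <- function(values, kind = c("saliency", "centrality", "roi")) {
  kind <- match.arg(kind)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (any(!is.finite(values))) stop("non-finite map values")
  structure(list(values = values, kind = kind,
                 height_px = dim(values)[1], width_px = dim(values)[2],
                 n_frames = dim(values)[3]),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("feature_stack<%s>: %d x %d px, %d frame(s), range [%.4g, %.4g]\n",
              x$kind, x$width_px, x$height_px, x$n_frames,
              min(x$values), max(x$values)))
  invisible(x)
}

## ---- lattice kernels (cached per (nx, ny, sigma)) --------------------------

.gaze_cache <- new.env(parent = emptyenv())

lattice_kernels <- function(nx, ny, sigma) {
  key <- sprintf("k_%d_%d_%g", nx, ny, sigma)
  if (!is.null(.gaze_cache[[key]])) return(.gaze_cache[[key]])
  gx <- exp(-outer(0:(nx - 1), 0:(nx - 1), "-")^2 / (2 * sigma^2))
  gy <- exp(-outer(0:(ny - 1), 0:(ny - 1), "-")^2 / (2 * sigma^2))
  # dense falloff kernel over nodes in ny x nx column-major order:
  # F = gx %x% gy  (F[i,j] = exp(-d(i,j)^2 / 2 sigma^2))
  k <- list(gx = gx, gy = gy, dense = kronecker(gx, gy))
  .gaze_cache[[key]] <- k
  k
}

#' Graph-based activation of a feature map
#'
#' Defines a fully connected Markov chain over the lattice of map locations
#' with transition weight proportional to `|M(i) - M(j)| * exp(-d(i,j)^2 /
#' (2 sigma^2))` and takes its equilibrium distribution as the activation
#' (dissimilar, locally contrasting locations accumulate mass). A second
#' mass-concentration pass uses weights proportional to `A(j) * exp(-d^2 /
#' (2 sigma^2))`, sharpening the activation peaks. Because the first-pass
#' weight matrix is symmetric, its chain is reversible and the equilibrium is
#' the normalized degree vector; the second pass is solved by power iteration.
#' A constant map carries no contrast information and yields the uniform
#' distribution.
#'
#' @param m numeric matrix (lattice-resolution feature map, rows = y).
#' @param sigma falloff scale in lattice pixels (default 0.15 * ncol(m)).
#' @param tol power-iteration convergence tolerance (max absolute change).
#' @return Matrix of the same shape, non-negative, summing to 1.
#' @export
graph_activation <- function(m, sigma = 0.15 * ncol(m), tol = 1e-10) {
  ny <- nrow(m); nx <- ncol(m)
  n <- nx * ny
  if (any(!is.finite(m))) stop("non-finite map values")
  v <- as.vector(m)
  if (max(v) - min(v) <= 1e-12 * max(1, abs(mean(v)))) {
    return(matrix(1 / n, ny, nx))
  }
  k <- lattice_kernels(nx, ny, sigma)
  ## pass 1: stationary distribution = degree / total degree
  W <- abs(outer(v, v, "-")) * k$dense
  A <- rowSums(W)
  A <- A / sum(A)
  ## pass 2: transitions into i proportional to A(i) * F(d); iterate
  ## v <- A * (F (v / c)) with c_j = (F A)_j, using F = gx %x% gy so that
  ## F x = vec(gy X gx) for X = matrix(x, ny, nx).
  Fmul <- function(x) as.vector(k$gy %*% matrix(x, ny, nx) %*% k$gx)
  cc <- Fmul(A)
  p <- A
  for (it in seq_len(5000)) {
    p2 <- A * Fmul(p / cc)
    p2 <- p2 / sum(p2)
    if (max(abs(p2 - p)) < tol) { p <- p2; break }
    p <- p2
  }
  matrix(p, ny, nx)
}

## ---- channel extraction ----------------------------------------------------

## bilinear resize of a matrix [y, x] to out_h x out_w
resize_map <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)),
                                       w = out_w, h = out_h)))
}

## RGB (h x w x 3, linear 0..1) to LMS-based opponent channels
rgb_to_dkl <- function(rgb) {
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  L <- 0.3811 * r + 0.5783 * g + 0.0402 * b
  M <- 0.1967 * r + 0.7244 * g + 0.0782 * b
  S <- 0.0241 * r + 0.1288 * g + 0.8444 * b
  list(rg = L - M, by = S - (L + M) / 2)
}

gabor_bank <- function(radius = 4, sigma = 2, wavelength = 5,
                       orientations = c(0, 45, 90, 135)) {
  key <- sprintf("g_%d_%g_%g", radius, sigma, wavelength)
  if (!is.null(.gaze_cache[[key]])) return(.gaze_cache[[key]])
  g <- lapply(orientations * pi / 180, function(th) {
    xs <- outer(rep(1, 2 * radius + 1), -radius:radius)
    ys <- outer(-radius:radius, rep(1, 2 * radius + 1))
    xr <- xs * cos(th) + ys * sin(th)
    yr <- -xs * sin(th) + ys * cos(th)
    env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
    kc <- env * cos(2 * pi * xr / wavelength)
    ks <- env * sin(2 * pi * xr / wavelength)
    kc <- kc - mean(kc)  # remove DC so constant images give zero energy
    list(cos = kc, sin = ks)
  })
  .gaze_cache[[key]] <- g
  g
}

gabor_energy <- function(m, bank = NULL) {
  if (is.null(bank)) {
    # kernel must fit inside the lattice
    r <- min(4L, (min(dim(m)) - 1L) %/% 2L)
    bank <- gabor_bank(radius = r, sigma = max(1, r / 2),
                       wavelength = max(2, r + 1))
  }
  e <- matrix(0, nrow(m), ncol(m))
  img <- EBImage::Image(t(m))
  for (k in bank) {
    rc <- t(EBImage::imageData(EBImage::filter2(img, t(k$cos),
                                                boundary = "replicate")))
    rs <- t(EBImage::imageData(EBImage::filter2(img, t(k$sin),
                                                boundary = "replicate")))
    e <- e + rc^2 + rs^2
  }
  e
}

#' Graph-based low-level saliency for a video
#'
#' Computes, per frame, feature channels for intensity (luminance), a
#' colour-opponent pair derived from an LMS cone transform, orientation (Gabor
#' energy pooled over four orientations) and flicker (absolute intensity
#' difference to the previous frame; zero for the first frame). Each channel
#' map is down-sampled to a lattice, activated via [graph_activation()]
#' (activation plus one mass-concentration pass), the channels are combined
#' with equal weights, and the result is up-sampled back to video resolution.
#' The output is unnormalized; apply [temporal_blur()] and then
#' [normalize_mean1()] to obtain mean-1 saliency maps.
#'
#' @param frames numeric array: `h x w x n` (grayscale, colour channel then
#'   skipped) or `h x w x 3 x n` (RGB in `[0, 1]`).
#' @param lattice integer length-2, activation lattice size `(nx, ny)`
#'   (default `c(32, 24)`).
#' @param sigma_frac falloff scale as a fraction of lattice width
#'   (default 0.15).
#' @return A [feature_stack()] of kind `"saliency"`.
#' @export
compute_saliency_stack <- function(frames, lattice = c(32, 24),
                                   sigma_frac = 0.15) {
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) stop("'frames' must be h x w x n or h x w x 3 x n")
  if (any(!is.finite(frames))) stop("non-finite pixel values")
  n <- dim(frames)[nd]
  if (n < 2L) stop("at least 2 frames required (flicker needs a predecessor)")
  h <- dim(frames)[1]; w <- dim(frames)[2]
  nx <- lattice[1]; ny <- lattice[2]
  sigma <- sigma_frac * nx
  rgb <- nd == 4L
  out <- array(0, c(h, w, n))
  prev_int <- NULL
  for (t in seq_len(n)) {
    if (rgb) {
      fr <- frames[, , , t, drop = FALSE]
      dim(fr) <- c(h, w, 3L)
      intensity <- (fr[, , 1] + fr[, , 2] + fr[, , 3]) / 3
      dkl <- rgb_to_dkl(fr)
    } else {
      intensity <- frames[, , t]
      dkl <- NULL
    }
    ilat <- resize_map(intensity, ny, nx)
    acts <- list(graph_activation(ilat, sigma))                 # intensity
    if (!is.null(dkl)) {                                        # DKL colour
      a1 <- graph_activation(resize_map(dkl$rg, ny, nx), sigma)
      a2 <- graph_activation(resize_map(dkl$by, ny, nx), sigma)
      acts <- c(acts, list((a1 + a2) / 2))
    }
    acts <- c(acts, list(graph_activation(gabor_energy(ilat), sigma)))
    flick <- if (is.null(prev_int)) matrix(0, ny, nx) else abs(ilat - prev_int)
    acts <- c(acts, list(graph_activation(flick, sigma)))
    prev_int <- ilat
    comb <- Reduce(`+`, acts)
    out[, , t] <- resize_map(comb, h, w)
  }
  feature_stack(out, "saliency")
}

#' Gaussian blur along the temporal (frame) dimension
#'
#' Per-pixel 1-D Gaussian convolution across frames, kernel truncated at
#' `4 * sd_frames` and renormalized at the sequence edges (no padding mass is
#' invented). `sd_frames = 0` is the identity.
#'
#' @param stack a [feature_stack()] or 3-D array `h x w x n`.
#' @param sd_frames Gaussian standard deviation in frames (default 2).
#' @return Same type as the input.
#' @export
temporal_blur <- function(stack, sd_frames = 2) {
  is_fs <- inherits(stack, "feature_stack")
  vals <- if (is_fs) stack$values else stack
  stopifnot(is.array(vals), length(dim(vals)) == 3L)
  if (sd_frames < 0) stop("'sd_frames' must be >= 0")
  if (sd_frames == 0) return(stack)
  n <- dim(vals)[3]
  r <- ceiling(4 * sd_frames)
  wts <- stats::dnorm(-r:r, sd = sd_frames)
  wts <- wts / sum(wts)
  out <- array(0, dim(vals))
  for (t in seq_len(n)) {
    ks <- max(1L, t - r):min(n, t + r)
    wk <- wts[ks - t + r + 1L]
    wk <- wk / sum(wk)
    acc <- vals[, , ks[1]] * wk[1]
    for (j in seq_along(ks)[-1]) acc <- acc + vals[, , ks[j]] * wk[j]
    out[, , t] <- acc
  }
  if (is_fs) feature_stack(out, stack$kind) else out
}

#' Normalize each frame to mean 1
#'
#' Divides every frame by its own mean so that the average map value is
#' exactly 1 per frame (the chance reference for viewing behaviour not guided
#' by the map). Frames with non-positive mean are rejected.
#'
#' @param stack a [feature_stack()] or 3-D array.
#' @return Same type as the input.
#' @export
normalize_mean1 <- function(stack) {
  is_fs <- inherits(stack, "feature_stack")
  vals <- if (is_fs) stack$values else stack
  stopifnot(is.array(vals), length(dim(vals)) == 3L)
  mns <- apply(vals, 3, mean)
  if (any(mns <= 0)) stop("frame mean must be positive for mean-1 normalization")
  out <- sweep(vals, 3, mns, "/")
  if (is_fs) feature_stack(out, stack$kind) else out
}

#' Central-bias map
#'
#' `C(x, y) = 1 / (1 + d)` where `d` is the Euclidean distance (in pixels)
#' to the map centre `((w-1)/2, (h-1)/2)`; the `1 +` offset removes the
#' singularity of a pure inverse distance at the centre. Strictly decreasing
#' in `d`, identical for all frames.
#'
#' @param width_px,height_px map dimensions.
#' @return A single-frame [feature_stack()] of kind `"centrality"`.
#' @export
centrality_map <- function(width_px, height_px) {
  stopifnot_scalar(width_px, "width_px", integer = TRUE)
  stopifnot_scalar(height_px, "height_px", integer = TRUE)
  cx <- (width_px - 1) / 2
  cy <- (height_px - 1) / 2
  d <- sqrt(outer((0:(height_px - 1) - cy)^2, (0:(width_px - 1) - cx)^2, "+"))
  feature_stack(1 / (1 + d), "centrality")
}

#' Binary social-ROI mask stack from circular head annotations
#'
#' A pixel is 1 on a frame iff it lies within distance `r` of some annotated
#' head centre on that frame (union over heads), else 0.
#'
#' @param annotations data.frame with columns `frame` (0-based), `cx_px`,
#'   `cy_px`, `r_px`.
#' @param width_px,height_px,n_frames video dimensions.
#' @return A [feature_stack()] of kind `"roi"` with values in `{0, 1}`.
#' @export
roi_mask_stack <- function(annotations, width_px, height_px, n_frames) {
  out <- array(0, c(height_px, width_px, n_frames))
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(feature_stack(out, "roi"))
  if (any(annotations$r_px <= 0)) stop("ROI radii must be positive")
  if (any(annotations$frame < 0 | annotations$frame >= n_frames))
    stop("ROI annotation references a frame outside the video")
  xs <- 0:(width_px - 1)
  ys <- 0:(height_px - 1)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    d2 <- outer((ys - a$cy_px)^2, (xs - a$cx_px)^2, "+")
    f <- a$frame + 1L
    out[, , f] <- pmax(out[, , f], (d2 <= a$r_px^2) * 1)
  }
  feature_stack(out, "roi")
}
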