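#' Display geometry for visual-angle computations
#'
#' Bundles the physical screen size, screen resolution, viewing distance and
#' the pixel size of the centrally presented video. Defaults reproduce a
#' 24-inch 1920x1200 display (516.9 x 323.1 mm) viewed from 50 cm with a
#' 1280x720 video, under which the video subtends 38.03 x 21.94 degrees.
#'
#' @param screen_px integer length-2, screen resolution (width, height) in px.
#' @param screen_mm numeric length-2, physical screen size (width, height) mm.
#' @param viewing_distance_mm viewing distance in mm.
#' @param video_px integer length-2, video size (width, height) in pixels.
#' @return An object of class `display_geometry`.
#' @examples
#' geom <- display_geometry()
#' visual_angle(1280, geom, axis = "horizontal")
#' @export
display_geometry <- function(screen_px = c(1920, 1200),
                             screen_mm = c(516.9, 323.1),
                             viewing_distance_mm = 500,
                             video_px = c(1280, 720)) {
  if (any(screen_px <= 0) || any(screen_mm <= 0) || viewing_distance_mm <= 0 ||
      any(video_px <= 0))
    stop("all geometry quantities must be positive")
  if (video_px[1] > screen_px[1] || video_px[2] > screen_px[2])
    stop("video does not fit on the screen")
  structure(list(screen_px = as.numeric(screen_px),
                 screen_mm = as.numeric(screen_mm),
                 viewing_distance_mm = as.numeric(viewing_distance_mm),
                 video_px = as.numeric(video_px)),
            class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("display_geometry: %gx%g px (%.1f x %.1f mm) at %g mm; video %gx%g px\n",
              x$screen_px[1], x$screen_px[2], x$screen_mm[1], x$screen_mm[2],
              x$viewing_distance_mm, x$video_px[1], x$video_px[2]))
  cat(sprintf("  video subtends %.2f x %.2f degrees\n",
              visual_angle(x$video_px[1], x, "horizontal"),
              visual_angle(x$video_px[2], x, "vertical")))
  invisible(x)
}

#' Visual angle subtended by a pixel extent
#'
#' Converts a pixel extent on one display axis to degrees of visual angle:
#' the extent is mapped to millimetres through the physical pixel pitch and
#' the full angle is `2 * atan(extent_mm / (2 * distance))`.
#'
#' @param extent_px extent in pixels (>= 0).
#' @param geometry a [display_geometry()].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return Angle in degrees.
#' @export
visual_angle <- function(extent_px, geometry = display_geometry(),
                         axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (!is.numeric(extent_px) || any(extent_px < 0))
    stop("'extent_px' must be non-negative")
  i <- if (axis == "horizontal") 1L else 2L
  extent_mm <- extent_px * geometry$screen_mm[i] / geometry$screen_px[i]
  2 * atan(extent_mm / (2 * geometry$viewing_distance_mm)) * 180 / pi
}
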