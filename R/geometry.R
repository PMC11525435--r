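#' Screen geometry
#'
#' Physical measurements of the display used to convert pixels to
#' centimeters and centimeters to degrees of visual angle.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_cm,height_cm Physical screen size in centimeters.
#' @param viewing_distance_cm Eye-to-screen distance in centimeters.
#' @return An object of class `screen_geometry`.
#' @export
#' @examples
#' screen_geometry(1920, 1080, 53.33, 30, 57.3)
screen_geometry <- function(width_px, height_px, width_cm, height_cm,
                            viewing_distance_cm) {
  for (nm in c("width_px", "height_px", "width_cm", "height_cm",
               "viewing_distance_cm")) {
    assert_positive(get(nm), nm)
  }
  structure(
    list(
      width_px = width_px, height_px = height_px,
      width_cm = width_cm, height_cm = height_cm,
      viewing_distance_cm = viewing_distance_cm
    ),
    class = "screen_geometry"
  )
}

#' Pixel-to-centimeter conversion factor
#'
#' Computes the conversion factor c = size_cm / size_px from the height and
#' from the width independently. On a display with square pixels the two
#' must agree; a relative disagreement above `tol` (default 2%) triggers a
#' warning since it indicates a measurement problem (or a non-1:1 pixel
#' aspect ratio, which should then be declared).
#'
#' @param screen A [screen_geometry()].
#' @param tol Relative disagreement above which a warning is emitted.
#' @return A one-row tibble: `cm_per_px_height`, `cm_per_px_width`,
#'   `cm_per_px` (their mean), `rel_disagreement`, `consistent`.
#' @export
#' @examples
#' px_cm_conversion(screen_geometry(1920, 1080, 53.33, 30, 57.3))
px_cm_conversion <- function(screen, tol = 0.02) {
  stopifnot(inherits(screen, "screen_geometry"))
  c_h <- screen$height_cm / screen$height_px
  c_w <- screen$width_cm / screen$width_px
  rel <- abs(c_h - c_w) / mean(c(c_h, c_w))
  if (rel > tol) {
    warn(sprintf(
      paste0("height- and width-based conversion factors disagree by %.1f%%;",
             " this indicates measurement issues (or a non-square pixel",
             " aspect ratio)."),
      100 * rel
    ))
  }
  tibble(
    cm_per_px_height = c_h,
    cm_per_px_width = c_w,
    cm_per_px = mean(c(c_h, c_w)),
    rel_disagreement = rel,
    consistent = rel <= tol
  )
}

#' Visual angle of a stimulus
#'
#' Angular size at the eye from right-angle trigonometry:
#' theta = 2 * atan((size / 2) / distance), returned in degrees. At 57.3 cm
#' viewing distance, 1 cm subtends almost exactly 1 degree.
#'
#' @param size_cm Stimulus extent in centimeters (vectorized).
#' @param distance_cm Viewing distance in centimeters.
#' @return Visual angle(s) in degrees.
#' @export
#' @examples
#' visual_angle(1, 57.3)
visual_angle <- function(size_cm, distance_cm) {
  assert_positive(size_cm, "size_cm")
  assert_positive(distance_cm, "distance_cm")
  2 * atan((size_cm / 2) / distance_cm) * 180 / pi
}

#' Eccentricity in degrees of visual angle
#'
#' Same closed form as [visual_angle()] applied to the distance between the
#' screen center (assumed fixation) and the stimulus center. Horizontal and
#' vertical offsets should be converted separately so the pair fixes the
#' stimulus position uniquely. Zero offset is allowed and returns 0.
#'
#' Note: for stimuli far off-center the flat-screen small-tilt approximation
#' underlying this formula becomes coarse; results for such layouts should
#' be labelled as approximations.
#'
#' @param offset_cm Distance from screen center in centimeters (>= 0).
#' @param distance_cm Viewing distance in centimeters.
#' @return Eccentricity in degrees.
#' @export
#' @examples
#' eccentricity_angle(3, 4) # 2 * atan(0.375) in degrees
eccentricity_angle <- function(offset_cm, distance_cm) {
  if (any(offset_cm < 0)) abort("`offset_cm` must be >= 0.")
  assert_positive(distance_cm, "distance_cm")
  2 * atan((offset_cm / 2) / distance_cm) * 180 / pi
}

#' Convert pixel measurements to degrees via a screen geometry
#'
#' Convenience wrapper: pixels -> centimeters (via [px_cm_conversion()]) ->
#' degrees (via [visual_angle()]).
#'
#' @param size_px Extent in pixels.
#' @param screen A [screen_geometry()].
#' @return Visual angle in degrees.
#' @export
px_visual_angle <- function(size_px, screen) {
  conv <- px_cm_conversion(screen)
  visual_angle(size_px * conv$cm_per_px, screen$viewing_distance_cm)
}
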