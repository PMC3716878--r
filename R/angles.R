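#' Wrap angles into (-180, 180]
#'
#' All directions in this package live on a circle with 0 deg pointing
#' straight ahead (the start-position-to-first-target axis) and
#' counter-clockwise (CCW) positive. `wrap_angle()` maps arbitrary degree
#' values into the canonical half-open interval (-180, 180].
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped into (-180, 180].
#' @examples
#' wrap_angle(c(0, 190, -185, 360, 180))
#' @export
wrap_angle <- function(x) {
  stopifnot(is.numeric(x))
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Signed angular deviation of a judged from an actual direction
#'
#' The elementary error measure of the task: the judged direction minus the
#' actual direction, wrapped to (-180, 180]. A positive value is a
#' counter-clockwise deviation of the judgment from the physical direction,
#' a negative value a clockwise one.
#'
#' @param judged,actual Numeric vectors of directions in degrees (recycled
#'   to a common length).
#' @return Signed deviation in degrees, CCW positive, in (-180, 180].
#' @examples
#' wrap_deviation(30, 30)     # 0
#' wrap_deviation(-175, 180)  # +5: wrap-around
#' wrap_deviation(20, 35)     # -15
#' @export
wrap_deviation <- function(judged, actual) {
  if (!all(is.finite(judged)) || !all(is.finite(actual))) {
    stop("wrap_deviation(): non-finite direction; invalid trial", call. = FALSE)
  }
  wrap_angle(judged - actual)
}

#' Direction of the vector from one point to another
#'
#' Converts planar digitizer coordinates (x rightward, y away from the
#' participant) into the package's direction convention: 0 deg along +y,
#' CCW positive.
#'
#' @param origin_x,origin_y,target_x,target_y Numeric vectors of coordinates
#'   in cm.
#' @return Direction(s) in degrees in (-180, 180].
#' @examples
#' direction_from(0, 0, 0, 1)   # 0: straight ahead
#' direction_from(0, 0, -1, 0)  # +90: CCW quarter turn
#' direction_from(0, 0, 1, 1)   # -45
#' @export
direction_from <- function(origin_x, origin_y, target_x, target_y) {
  dx <- target_x - origin_x
  dy <- target_y - origin_y
  if (any(dx == 0 & dy == 0)) {
    stop("direction_from(): coincident points give no direction", call. = FALSE)
  }
  atan2(-dx, dy) * 180 / pi
}

#' Unit vector for a direction
#'
#' Inverse of [direction_from()] from the origin: the point at distance 1
#' in the given direction.
#'
#' @param angle Direction in degrees (0 = +y axis, CCW positive).
#' @return A list with numeric components `x` and `y`.
#' @keywords internal
unit_from_angle <- function(angle) {
  a <- angle * pi / 180
  list(x = -sin(a), y = cos(a))
}

#' Rotate points about the origin
#'
#' Rotation by `angle` degrees in the CCW-positive sense of the package's
#' direction convention (so rotating a point rotates its
#' [direction_from()] the origin by exactly `angle`).
#'
#' @param x,y Numeric coordinate vectors.
#' @param angle Rotation in degrees, CCW positive.
#' @return A list with rotated components `x` and `y`.
#' @export
rotate_point <- function(x, y, angle) {
  a <- angle * pi / 180
  list(
    x = cos(a) * x - sin(a) * y,
    y = sin(a) * x + cos(a) * y
  )
}

#' Implicit angular deviation from three-stroke endpoints
#'
#' The indirect (implicit) measure of the felt hand direction. In the
#' three-stroke task, the hand moves out from the first target T1 to the
#' stopper ring (end of stroke 2) and then returns, without visual feedback,
#' to the remembered T1 (end of stroke 3). If the felt hand position at the
#' end of stroke 2 is rotated relative to the actual one, the return stroke
#' inherits that rotation. The measure is computed in three steps: take
#' Line A from T1 to the stroke-2 endpoint and Line B from the stroke-2
#' endpoint to the stroke-3 endpoint; shift Line B in parallel so that the
#' stroke-3 endpoint coincides with T1 (Line B'); the implicit angular
#' deviation is the signed angle from Line A to Line B', CCW positive.
#' Equivalently, it is the angle from the direction of (end2 - t1) to the
#' direction of (end2 - end3).
#'
#' Trials with a zero-length outward or return stroke are degenerate: their
#' value is `NA` and a warning reports how many were skipped.
#'
#' @param t1_x,t1_y Coordinates of the first target T1 (cm).
#' @param end2_x,end2_y Stroke-2 endpoint, on the 15-cm stopper ring (cm).
#' @param end3_x,end3_y Stroke-3 (return) endpoint (cm).
#' @return Signed implicit angular deviation(s) in degrees, CCW positive,
#'   in (-180, 180]; `NA` for degenerate trials.
#' @examples
#' # perfect return: no deviation
#' implicit_angular_deviation(0, 0, 0, 15, 0, 0)
#' # undershoot along the same line: still no deviation
#' implicit_angular_deviation(0, 0, 0, 15, 0, 7.5)
#' @export
implicit_angular_deviation <- function(t1_x, t1_y, end2_x, end2_y,
                                       end3_x, end3_y) {
  ax <- end2_x - t1_x
  ay <- end2_y - t1_y
  bx <- end2_x - end3_x
  by <- end2_y - end3_y
  bad <- (ax == 0 & ay == 0) | (bx == 0 & by == 0)
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE),
            " degenerate trial(s) with a zero-length stroke set to NA",
            call. = FALSE)
  }
  out <- wrap_angle((atan2(-bx, by) - atan2(-ax, ay)) * 180 / pi)
  out[bad] <- NA_real_
  out
}

#' Construct a return-stroke endpoint from a felt-direction rotation
#'
#' Generative inverse of [implicit_angular_deviation()]: given the stroke-2
#' endpoint and an implicit deviation `alpha`, the felt hand position is the
#' stroke-2 endpoint rotated by `alpha` about T1, and the return stroke goes
#' from the actual endpoint toward the remembered T1 *as seen from the felt
#' position*, scaled by `length_factor` (1 = a complete return).
#'
#' @param t1_x,t1_y,end2_x,end2_y Coordinates as in
#'   [implicit_angular_deviation()].
#' @param alpha Implicit angular deviation in degrees, CCW positive.
#' @param length_factor Positive scale of the return stroke length.
#' @return A list with components `x` and `y`: the stroke-3 endpoint.
#' @export
make_return_endpoint <- function(t1_x, t1_y, end2_x, end2_y, alpha,
                                 length_factor = 1) {
  stopifnot(all(length_factor > 0))
  felt <- rotate_point(end2_x - t1_x, end2_y - t1_y, alpha)
  list(
    x = end2_x - length_factor * felt$x,
    y = end2_y - length_factor * felt$y
  )
}
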