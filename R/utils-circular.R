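# Circular helpers. All angles are in degrees unless noted; directions live on
# [0, 360) and angular differences on (-180, 180].

#' Wrap angles into [0, 360)
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to [0, 360).
#' @export
wrap360 <- function(x) x %% 360

#' Wrap angular differences into (-180, 180]
#' @param x numeric vector of angular differences in degrees.
#' @return differences wrapped to (-180, 180].
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  # map -180 to +180 so the interval is (-180, 180]
  y[y == -180] <- 180
  y
}

#' Circular mean of directions
#' @param x directions in degrees.
#' @return circular mean in [0, 360).
#' @export
circ_mean <- function(x) {
  r <- x * pi / 180
  wrap360(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

deg2rad <- function(x) x * pi / 180

#' Direction category relative to the vertical boundary
#'
#' Directions whose angular distance from the rightward horizontal (0 deg) is
#' less than 90 deg belong to the "right" category; the remainder to "left".
#' The vertical axis (90/270 deg) is the learned category boundary.
#'
#' @param direction directions in degrees.
#' @return character vector, "left" or "right".
#' @export
direction_category <- function(direction) {
  ifelse(abs(wrap180(direction)) < 90, "right", "left")
}

#' Signed horizontal distance from the vertical category boundary
#'
#' Maps a direction to its signed distance (degrees) from the vertical
#' boundary, positive toward the right category center (0 deg), negative
#' toward the left center (180 deg). The circle is folded onto [-90, 90].
#'
#' @param direction directions in degrees.
#' @return signed distances in [-90, 90].
#' @export
boundary_distance <- function(direction) {
  90 - abs(wrap180(direction))
}

#' Nearest horizontal category center
#' @param direction directions in degrees.
#' @return 0 for the right category, 180 for the left.
#' @export
category_center <- function(direction) {
  ifelse(direction_category(direction) == "right", 0, 180)
}

# Offset of each direction relative to a reference, on the canonical 8-point
# grid {-135,-90,-45,0,45,90,135,180}.
direction_offsets <- function(direction, reference) wrap180(direction - reference)
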