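#' Sensor mounting placement
#'
#' Coordinate frame: origin at seat centre on the seat plane, x toward the
#' stall door, y across the stall, z up; distances in metres inside the
#' geometry module (placement arguments are in the cm the field notes use).
#' The published mounting puts the sensor 85 cm horizontally from the front
#' of the chest (centre of seat), 85 cm above the seat, angled 30 degrees
#' down from horizontal, with the boresight yawed 45 degrees out from the
#' mounting wall toward the seat.
#'
#' @param forward_offset horizontal distance from the sensor to the
#'   seat-centre chest axis, cm (default 85).
#' @param height_above_seat sensor height above the seat plane, cm (85).
#' @param depression_angle boresight angle below horizontal, degrees (30).
#' @param yaw_angle boresight rotation out from the wall plane, degrees (45).
#' @export
device_placement <- function(forward_offset = 85, height_above_seat = 85,
                             depression_angle = 30, yaw_angle = 45) {
  if (!(forward_offset > 0)) stop_odr("invalid_spec", "forward_offset must be > 0")
  if (!(depression_angle >= 0 && depression_angle < 90)) {
    stop_odr("invalid_spec", "depression_angle must be in [0, 90)")
  }
  structure(list(forward_offset = forward_offset,
                 height_above_seat = height_above_seat,
                 depression_angle = depression_angle,
                 yaw_angle = yaw_angle),
            class = "device_placement")
}

#' Radar capture cone
#' @param horizontal,vertical full field-of-view angles in degrees
#'   (defaults 65 x 53, the sensor's bounded capture area).
#' @export
fov_spec <- function(horizontal = 65, vertical = 53) {
  if (!(horizontal > 0 && horizontal < 180 && vertical > 0 && vertical < 180)) {
    stop_odr("invalid_spec", "FOV angles must be in (0, 180)")
  }
  structure(list(horizontal = horizontal, vertical = vertical),
            class = "fov_spec")
}

#' Restroom stall dimensions
#' @param width stall width in mm (building code 890-940; default 915).
#' @param length stall length in mm (1500).
#' @param door_opening door opening in mm (860).
#' @param seat_height_reference seat height used as the z = 0 plane, cm.
#' @export
stall_geometry <- function(width = 915, length = 1500, door_opening = 860,
                           seat_height_reference = 43) {
  if (any(c(width, length, door_opening) <= 0)) {
    stop_odr("invalid_spec", "stall dimensions must be positive")
  }
  structure(list(width = width, length = length, door_opening = door_opening,
                 seat_height_reference = seat_height_reference),
            class = "stall_geometry")
}

deg2rad <- function(d) d * pi / 180

# Sensor position and orthonormal boresight frame in the stall coordinates.
sensor_frame <- function(placement) {
  f <- placement$forward_offset / 100
  h <- placement$height_above_seat / 100
  dep <- deg2rad(placement$depression_angle)
  yaw <- deg2rad(placement$yaw_angle)
  dh <- c(cos(yaw), sin(yaw), 0)          # horizontal boresight direction
  pos <- c(-f * dh[1], -f * dh[2], h)     # so the seat axis is f metres ahead
  fwd <- c(dh[1] * cos(dep), dh[2] * cos(dep), -sin(dep))
  right <- c(dh[2], -dh[1], 0)
  up <- cross3(right, fwd)
  list(pos = pos, fwd = fwd, right = right, up = up, f = f, h = h, dep = dep)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Boresight aim point and range
#'
#' Intersects the boresight ray with the vertical chest plane through the
#' seat axis (perpendicular to the horizontal boresight direction). At the
#' published defaults the ray lands ~36 cm above the seat — the "35 cm above
#' the toilet seat" chest/abdomen aim — at a range of about 1 m.
#'
#' @param placement a [device_placement()].
#' @return list with `sensor` (xyz, m), `aim_point` (xyz, m), `range` (m,
#'   sensor to aim point) and `aim_height_above_seat` (m).
#' @export
boresight <- function(placement = device_placement()) {
  fr <- sensor_frame(placement)
  s <- fr$f / cos(fr$dep)                 # ray length to the chest plane
  aim <- fr$pos + s * fr$fwd
  list(sensor = fr$pos, aim_point = aim, range = s,
       aim_height_above_seat = aim[3])
}

#' Distance from the sensor to an arbitrary target
#'
#' For the published mounting and the chest target 35 cm above the seat this
#' is sqrt(0.85^2 + 0.50^2) = 0.986 m, the paper's "approximately 1 m".
#'
#' @param placement a [device_placement()].
#' @param point xyz in metres (stall frame).
#' @return Euclidean range in metres.
#' @export
slant_range <- function(placement, point) {
  fr <- sensor_frame(placement)
  sqrt(sum((point - fr$pos)^2))
}

#' Depression angle from the sensor to a target
#'
#' Inverse of the mounting arithmetic: from 85 cm up to a point 35 cm up at
#' 85 cm horizontal distance the tilt is atan(50/85) = 30.5 degrees, i.e.
#' the published 30-degree setting.
#'
#' @inheritParams slant_range
#' @return angle below horizontal in degrees.
#' @export
depression_to <- function(placement, point) {
  fr <- sensor_frame(placement)
  d <- point - fr$pos
  horiz <- sqrt(d[1]^2 + d[2]^2)
  atan2(-d[3], horiz) * 180 / pi
}

#' Is a point inside the capture cone?
#'
#' True iff the point lies in front of the sensor and its horizontal and
#' vertical off-axis angles are within half the respective FOV angles.
#'
#' @param placement a [device_placement()].
#' @param point xyz in metres.
#' @param fov a [fov_spec()].
#' @return logical, with attributes `azimuth` and `elevation` (degrees).
#' @export
in_fov <- function(placement, point, fov = fov_spec()) {
  fr <- sensor_frame(placement)
  v <- point - fr$pos
  ahead <- sum(v * fr$fwd)
  az <- atan2(sum(v * fr$right), ahead) * 180 / pi
  el <- atan2(sum(v * fr$up), ahead) * 180 / pi
  ok <- ahead > 0 && abs(az) <= fov$horizontal / 2 && abs(el) <= fov$vertical / 2
  structure(ok, azimuth = az, elevation = el)
}

#' Default slumped-posture chest targets
#'
#' Modelled (not measured) chest positions for a person on the seat:
#' upright, and slumped forward / backward / left / right. Heights and
#' offsets are plausible for an adult torso pivoting at the hips; the
#' forward slump drops the chest toward the knees.
#'
#' @return data.frame with `label`, `x`, `y`, `z` (metres).
#' @export
default_posture_targets <- function() {
  data.frame(
    label = c("upright", "slump_forward", "slump_backward", "slump_left",
              "slump_right"),
    x = c(0.00, 0.30, -0.15, 0.00, 0.00),
    y = c(0.00, 0.00, 0.00, -0.20, 0.20),
    z = c(0.35, 0.25, 0.45, 0.40, 0.40),
    stringsAsFactors = FALSE
  )
}

#' Coverage of posture targets by the mounted sensor
#'
#' Systematizes the iterative placement check: for each labelled chest
#' position, is it inside the capture cone, at what range and off-axis
#' angles?
#'
#' @param stall a [stall_geometry()] (recorded in the report).
#' @param placement a [device_placement()].
#' @param targets data.frame like [default_posture_targets()].
#' @param fov a [fov_spec()].
#' @return a `coverage_report`: list with `targets` (per-target table:
#'   `label`, `in_fov`, `range_m`, `azimuth_deg`, `elevation_deg`) and
#'   `fraction_covered`.
#' @export
coverage_report <- function(stall = stall_geometry(),
                            placement = device_placement(),
                            targets = default_posture_targets(),
                            fov = fov_spec()) {
  if (!nrow(targets)) stop_odr("invalid_spec", "targets must be non-empty")
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    p <- c(targets$x[i], targets$y[i], targets$z[i])
    hit <- in_fov(placement, p, fov)
    data.frame(label = targets$label[i], in_fov = as.logical(hit),
               range_m = slant_range(placement, p),
               azimuth_deg = attr(hit, "azimuth"),
               elevation_deg = attr(hit, "elevation"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(targets = tab,
                 fraction_covered = mean(tab$in_fov),
                 stall = stall, placement = placement, fov = fov),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %.0f%% of %d targets covered\n",
              100 * x$fraction_covered, nrow(x$targets)))
  print(x$targets, row.names = FALSE)
  invisible(x)
}
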