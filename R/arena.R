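#' Arena geometry specification
#'
#' Describes the square object-enriched open field: a `side` x `side` cm box
#' with two fixed objects and checking zones at the four corners and the two
#' objects. Coordinates use the arena's south-west corner as origin, x east,
#' y north, in cm. Zone radii default to the empirically calibrated values of
#' the checking assay: 10 cm circular object zones and 15 cm quarter-disc
#' corner zones.
#'
#' @param side Arena side length in cm.
#' @param object_centers Two-row matrix (or list of two `c(x, y)` vectors) of
#'   object center coordinates in cm, strictly inside the arena.
#' @param object_zone_radius Radius of the circular object zones, cm.
#' @param corner_zone_radius Radius of the quarter-disc corner zones, cm,
#'   anchored at the corner vertices.
#' @param wall_height Wall height in cm; metadata only.
#'
#' @return An object of class `arena_spec`.
#' @export
#' @examples
#' arena <- arena_spec()
#' build_zones(arena)
arena_spec <- function(side = 95,
                       object_centers = rbind(c(30, 62), c(62, 30)),
                       object_zone_radius = 10,
                       corner_zone_radius = 15,
                       wall_height = 50) {
  stopifnot_scalar_number(side, "side", min = 1e-6)
  stopifnot_scalar_number(object_zone_radius, "object_zone_radius", min = 1e-9)
  stopifnot_scalar_number(corner_zone_radius, "corner_zone_radius", min = 1e-9)
  if (object_zone_radius >= side / 2 || corner_zone_radius >= side / 2) {
    abort("Zone radii must be smaller than side/2.",
          class = "checkfish_config_error")
  }
  if (is.list(object_centers)) object_centers <- do.call(rbind, object_centers)
  object_centers <- as.matrix(object_centers)
  if (!is.numeric(object_centers) || !identical(dim(object_centers), c(2L, 2L))) {
    abort("`object_centers` must give two (x, y) points.",
          class = "checkfish_config_error")
  }
  if (any(object_centers <= 0) || any(object_centers >= side)) {
    abort("Object centers must lie strictly inside the arena.",
          class = "checkfish_config_error")
  }
  spec <- structure(
    list(side = side,
         object_centers = unname(object_centers),
         object_zone_radius = object_zone_radius,
         corner_zone_radius = corner_zone_radius,
         wall_height = wall_height),
    class = "arena_spec")
  # zone disjointness is a construction-time invariant
  validate_zones(build_zones_impl(spec))
  spec
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g cm; objects at (%g, %g), (%g, %g); zone radii %g (object) / %g (corner) cm\n",
              x$side, x$side,
              x$object_centers[1, 1], x$object_centers[1, 2],
              x$object_centers[2, 1], x$object_centers[2, 2],
              x$object_zone_radius, x$corner_zone_radius))
  invisible(x)
}

# Canonical zone enumeration order; also the documented rank tie-break order.
zone_levels <- function() {
  c("corner_NW", "corner_NE", "corner_SW", "corner_SE", "object_1", "object_2")
}

build_zones_impl <- function(arena) {
  s <- arena$side
  anchors <- rbind(
    corner_NW = c(0, s),
    corner_NE = c(s, s),
    corner_SW = c(0, 0),
    corner_SE = c(s, 0),
    object_1  = arena$object_centers[1, ],
    object_2  = arena$object_centers[2, ])
  tibble(
    zone_id = zone_levels(),
    anchor_x = anchors[zone_levels(), 1],
    anchor_y = anchors[zone_levels(), 2],
    radius = c(rep(arena$corner_zone_radius, 4), rep(arena$object_zone_radius, 2)),
    kind = c(rep("corner", 4), rep("object", 2)))
}

validate_zones <- function(zones) {
  n <- nrow(zones)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sqrt((zones$anchor_x[i] - zones$anchor_x[j])^2 +
                (zones$anchor_y[i] - zones$anchor_y[j])^2)
      if (d <= zones$radius[i] + zones$radius[j]) {
        abort(sprintf("Zones %s and %s overlap (anchor distance %.2f <= %.2f).",
                      zones$zone_id[i], zones$zone_id[j], d,
                      zones$radius[i] + zones$radius[j]),
              class = "checkfish_config_error")
      }
    }
  }
  invisible(zones)
}

#' Build the six checking zones of an arena
#'
#' Returns the four quarter-disc corner zones (anchored at the corner
#' vertices) and the two circular object zones. A point belongs to a zone when
#' its Euclidean distance to the anchor is at most the zone radius; for corner
#' zones the quarter-disc clipping to the arena square is automatic for any
#' point inside the arena. Zones are validated to be pairwise disjoint.
#'
#' @param arena An [arena_spec()].
#' @return A tibble with one row per zone: `zone_id`, `anchor_x`, `anchor_y`,
#'   `radius`, `kind`.
#' @export
build_zones <- function(arena) {
  if (!inherits(arena, "arena_spec")) {
    abort("`arena` must be an arena_spec.", class = "checkfish_config_error")
  }
  validate_zones(build_zones_impl(arena))
}

#' Zone membership of points
#'
#' @param x,y Coordinate vectors, cm.
#' @param zones A zone table from [build_zones()].
#' @return A character vector: the containing `zone_id` or `NA` when the point
#'   is in no zone (zones are disjoint, so membership is unique).
#' @export
zone_membership <- function(x, y, zones) {
  out <- rep(NA_character_, length(x))
  for (k in seq_len(nrow(zones))) {
    inside <- (x - zones$anchor_x[k])^2 + (y - zones$anchor_y[k])^2 <=
      zones$radius[k]^2
    out[inside & is.na(out)] <- zones$zone_id[k]
  }
  out
}
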