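#' Marker-channel geometry of the impeller blades
#'
#' Each of the four main blades carries two straight fluorescent bores
#' (an inner and an outer channel) drilled at an angle through the
#' blade. In rotor-local coordinates a channel centerline is the line
#' `x(z) = x0 + a z`, `y(z) = y0 + b z` parametrised by the height `z`
#' above the blade-root reference plane. The counter-angled slopes make
#' the planar distance between the two laser-plane intersection dots a
#' monotone function of the local cut height -- the depth cue that a
#' single camera can read.
#'
#' Blades 2-4 are the first blade's channels rotated by successive 90
#' degree steps about the local z axis (base points and slope vectors
#' alike), reflecting the impeller's fourfold symmetry.
#'
#' @param inner_base,outer_base numeric length-2 base points `(x0, y0)`
#'   of the blade-1 inner/outer channel, mm in the reference plane.
#' @param inner_slope,outer_slope numeric length-2 slopes `(a, b)`, mm
#'   of lateral travel per mm of height (dimensionless).
#' @param height_range numeric length-2, physical `z` range of the bores
#'   in mm; intersections outside it are rejected as unphysical.
#' @return data.frame of class `channel_geometry` with one row per
#'   blade/channel: columns `blade, channel, x0, y0, a, b` and the
#'   height range stored as an attribute.
#' @examples
#' geom <- channel_geometry()
#' subset(geom, blade == 2)
#' @export
channel_geometry <- function(inner_base = c(11.5, 0),
                             inner_slope = c(0.20, 0.05),
                             outer_base = c(16.0, 0.8),
                             outer_slope = c(-0.15, 0.10),
                             height_range = c(0, 7)) {
  rot90 <- function(v, k) {
    th <- deg2rad(90 * k)
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }
  rows <- list()
  for (n in 1:4) {
    k <- n - 1
    bi <- rot90(inner_base, k); si <- rot90(inner_slope, k)
    bo <- rot90(outer_base, k); so <- rot90(outer_slope, k)
    rows[[length(rows) + 1]] <- data.frame(
      blade = n, channel = c("in", "out"),
      x0 = c(bi[1], bo[1]), y0 = c(bi[2], bo[2]),
      a = c(si[1], so[1]), b = c(si[2], so[2]))
  }
  geom <- do.call(rbind, rows)
  da <- geom$a[geom$channel == "out"] - geom$a[geom$channel == "in"]
  db <- geom$b[geom$channel == "out"] - geom$b[geom$channel == "in"]
  if (any(da^2 + db^2 == 0))
    stop("inner and outer channels of a blade must have different slopes")
  attr(geom, "height_range") <- height_range
  class(geom) <- c("channel_geometry", "data.frame")
  geom
}

# One blade's difference parameters for the height quadratic:
# Delta x0, Delta y0, Delta a, Delta b and the reference-plane dot
# distance d0.
channel_deltas <- function(geom, blade) {
  g <- geom[geom$blade == blade, ]
  gi <- g[g$channel == "in", ]; go <- g[g$channel == "out", ]
  dx0 <- go$x0 - gi$x0; dy0 <- go$y0 - gi$y0
  da <- go$a - gi$a; db <- go$b - gi$b
  list(dx0 = dx0, dy0 = dy0, da = da, db = db,
       d0 = sqrt(dx0^2 + dy0^2))
}

#' Laser light-sheet specification
#'
#' @param Z_mm global Z position of the sheet mid-plane in mm.
#' @param thickness_mm sheet thickness in mm.
#' @return list of class `laser_plane`.
#' @export
laser_plane <- function(Z_mm = -2.25, thickness_mm = 0.5) {
  stopifnot(thickness_mm > 0)
  structure(list(Z_mm = Z_mm, thickness_mm = thickness_mm),
            class = "laser_plane")
}
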