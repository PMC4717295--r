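# Retinotopic geometry: the modeled visual field is the left hemifield sector
# from 0.5 to 27 degrees eccentricity.  Visual-field positions are (x, y) in
# degrees with x <= 0; the polar angle phi = atan2(y, -x) is measured from the
# horizontal meridian, |phi| <= pi/2.
#
# The cortical sheet uses the conformal log-polar map
#   w = k * log(1 + z / a),   z = ecc * exp(i phi),
# in cortical millimetres, with local magnification |dw/dz| = k / (|z + a|)
# ~ k / (ecc + a) mm/deg, monotonically decreasing with eccentricity.

#' Log-polar cortical map
#'
#' @param a Foveal offset of the conformal map (degrees).
#' @param k Scale of the map (mm); `k / (ecc + a)` is the linear cortical
#'   magnification in mm/deg.
#' @param mm_retina_per_deg Retinal millimetres per degree of visual field
#'   (the retina covers 3.8 degrees per mm by default).
#' @return Object of class `cortical_map`.
#' @export
cortical_map <- function(a = 0.7, k = 17.3, mm_retina_per_deg = 1 / 3.8) {
  stopifnot(a > 0, k > 0, mm_retina_per_deg > 0)
  structure(list(a = a, k = k, mm_retina_per_deg = mm_retina_per_deg),
            class = "cortical_map")
}

# polar field coords -> complex z (left hemifield folded onto Re >= 0)
.polar_to_z <- function(ecc, phi) complex(real = ecc * cos(phi),
                                          imaginary = ecc * sin(phi))

#' Map visual-field positions to the cortical sheet
#'
#' @param map A [cortical_map()].
#' @param ecc,phi Eccentricity (degrees) and polar angle (radians, from the
#'   horizontal meridian) of visual-field positions.
#' @return Data frame with cortical coordinates `u`, `v` in mm.
#' @export
map_deg_to_cortex <- function(map, ecc, phi) {
  w <- map$k * log(1 + .polar_to_z(ecc, phi) / map$a)
  data.frame(u = Re(w), v = Im(w))
}

#' Inverse cortical map
#'
#' @param map A [cortical_map()].
#' @param u,v Cortical coordinates in mm.
#' @return Data frame with `ecc` (degrees) and `phi` (radians).
#' @export
map_cortex_to_deg <- function(map, u, v) {
  z <- map$a * (exp(complex(real = u, imaginary = v) / map$k) - 1)
  data.frame(ecc = Mod(z), phi = Arg(z))
}

#' Linear cortical magnification
#'
#' @param map A [cortical_map()].
#' @param ecc Eccentricity in degrees.
#' @return Magnification in mm of cortex per degree of visual field.
#' @export
cortical_magnification <- function(map, ecc) map$k / (ecc + map$a)

#' Field geometry of the pipeline
#'
#' Bundles the modeled sector, the pixel resolution at which images are
#' rendered and filtered, and the cortical map.
#'
#' @param ecc_range Eccentricity range of the modeled hemifield sector
#'   (degrees).
#' @param px_per_deg Image resolution.
#' @param map A [cortical_map()].
#' @return Object of class `field_geometry`.
#' @export
field_geometry <- function(ecc_range = c(0.5, 27), px_per_deg = 8.2,
                           map = cortical_map()) {
  stopifnot(length(ecc_range) == 2, ecc_range[1] >= 0,
            ecc_range[2] > ecc_range[1], px_per_deg > 0)
  structure(list(ecc_range = ecc_range, px_per_deg = px_per_deg, map = map),
            class = "field_geometry")
}

# distance (degrees) from a field point to the sector boundary
field_edge_distance <- function(geom, ecc, phi) {
  d_in <- ecc - geom$ecc_range[1]
  d_out <- geom$ecc_range[2] - ecc
  d_ang <- ecc * (pi / 2 - abs(phi))   # arc distance to the vertical meridian
  pmin(d_in, d_out, d_ang)
}

# blank canvas covering the sector (plus margin), mid-gray background
field_canvas <- function(geom, margin = 0.5, background = 0.5) {
  dpx <- 1 / geom$px_per_deg
  e2 <- geom$ecc_range[2] + margin
  xs <- seq(-e2, 0, by = dpx)
  ys <- seq(-e2, e2, by = dpx)
  vf_image(matrix(background, length(ys), length(xs)),
           dpx, c(xs[1], ys[1]))
}
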