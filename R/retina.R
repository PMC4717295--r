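# Midget on-cell retina model.
#
# The mosaic tiles the hemifield sector with arc-sector segments: rings of
# width matched to the local cell spacing, each split into angular sectors of
# roughly equal arc length, so every sampled field point belongs to exactly
# one on-cell center region.  Cell density falls with eccentricity following
# a configurable inverse-polynomial profile.  Images are integrated over each
# center segment, contrasted with a -1/8-weighted 8-neighborhood, passed
# through a logistic output nonlinearity, and mapped onto the cortical sheet.

#' Midget-cell density profile
#'
#' Inverse-polynomial on-cell density in cells per square degree,
#' `d(e) = d0 / (1 + e / e2)^2`.  The defaults are calibrated so that the
#' full-scale mosaic over the 0.5-27 degree hemifield sector holds on the
#' order of 8e4 cells (the full human-retina reference for this sector is
#' 83,934 on-cells; that number is a configuration reference, not a
#' construction target).
#'
#' @param d0 Density extrapolated to the fovea (cells/deg^2).
#' @param e2 Eccentricity at which density has fallen to a quarter (degrees).
#' @return A function of eccentricity (degrees) returning cells/deg^2.
#' @export
midget_density <- function(d0 = 3900, e2 = 2) {
  force(d0); force(e2)
  stopifnot(d0 > 0, e2 > 0)
  function(e) d0 / (1 + e / e2)^2
}

#' Build the midget on-cell mosaic
#'
#' @param density_profile Function of eccentricity returning on-cell density
#'   in cells/deg^2 (see [midget_density()]).
#' @param resolution_factor Fraction of the profile density to realise, in
#'   `(0, 1]`; cell count scales approximately linearly with it.
#' @param geom A [field_geometry()].
#' @param inner_segment_shift Maximum centrifugal receptive-field
#'   displacement (degrees) compensated near the fovea; the compensation
#'   decays linearly to zero at 3 mm of retinal eccentricity.
#' @param include_off Also construct the midget off-cell mosaic (center
#'   diameters about 30% smaller than on-cells, hence denser).  Off-cells
#'   carry no signal anywhere in the pipeline — the cortex model has no
#'   connection specificity, so an active off pathway would cancel the on
#'   pathway's net input — and are recorded for completeness only.
#' @return Object of class `retina_mosaic`: `cells` data frame (id, ring,
#'   sector, ecc, phi, x, y, rf_ecc, rf_x, rf_y, r_mm, area_deg2) and a
#'   `rings` table; with `include_off`, an `off_cells` mosaic of the same
#'   shape.
#' @export
build_mosaic <- function(density_profile = midget_density(),
                         resolution_factor = 1,
                         geom = field_geometry(),
                         inner_segment_shift = 0.3,
                         include_off = FALSE) {
  stopifnot(resolution_factor > 0, resolution_factor <= 1)
  if (include_off) {
    # off-cell centers are ~30% smaller in diameter, i.e. ~1/0.7^2 denser
    off <- build_mosaic(function(e) density_profile(e) / 0.7^2,
                        resolution_factor, geom, inner_segment_shift,
                        include_off = FALSE)
  }
  e_lo <- geom$ecc_range[1]; e_hi <- geom$ecc_range[2]
  edges <- e_lo
  repeat {
    e <- edges[length(edges)]
    h <- 1 / sqrt(density_profile(e) * resolution_factor)
    nxt <- e + h
    if (nxt >= e_hi) { edges <- c(edges, e_hi); break }
    edges <- c(edges, nxt)
  }
  n_ring <- length(edges) - 1L
  e_mid <- (edges[-1] + edges[-length(edges)]) / 2
  h_mid <- 1 / sqrt(density_profile(e_mid) * resolution_factor)
  n_sect <- pmax(1L, as.integer(round(pi * e_mid / h_mid)))
  rings <- data.frame(ring = seq_len(n_ring), e_lo = edges[-length(edges)],
                      e_hi = edges[-1], n_sect = n_sect)
  if (sum(n_sect) < 10)
    stop("density profile yields fewer than 10 cells; check configuration")
  ring_id <- rep(rings$ring, rings$n_sect)
  sect_id <- unlist(lapply(rings$n_sect, seq_len), use.names = FALSE)
  dphi <- pi / rings$n_sect[ring_id]
  phi <- -pi / 2 + (sect_id - 0.5) * dphi
  ecc <- e_mid[ring_id]
  # annular sector area: dphi/2 * (e_hi^2 - e_lo^2)
  area <- (dphi / 2) * (rings$e_hi[ring_id]^2 - rings$e_lo[ring_id]^2)
  # foveal inner-segment displacement compensation (identity beyond 3 mm)
  e_comp <- 3 / geom$map$mm_retina_per_deg
  shift <- inner_segment_shift * pmax(0, 1 - ecc / e_comp)
  rf_ecc <- ecc + shift
  cells <- data.frame(
    id = seq_along(ecc), ring = ring_id, sector = sect_id,
    ecc = ecc, phi = phi,
    x = -ecc * cos(phi), y = ecc * sin(phi),
    rf_ecc = rf_ecc, rf_x = -rf_ecc * cos(phi), rf_y = rf_ecc * sin(phi),
    r_mm = ecc * geom$map$mm_retina_per_deg,
    area_deg2 = area)
  out <- structure(list(cells = cells, rings = rings, geom = geom,
                        resolution_factor = resolution_factor),
                   class = "retina_mosaic")
  if (include_off) out$off_cells <- off
  out
}

#' @export
print.retina_mosaic <- function(x, ...) {
  cat(sprintf("retina mosaic: %d on-cells in %d rings, resolution factor %.3g\n",
              nrow(x$cells), nrow(x$rings), x$resolution_factor))
  invisible(x)
}

# cell id for field points (ecc, phi); NA outside the sector
mosaic_cell_at <- function(mosaic, ecc, phi) {
  rings <- mosaic$rings
  ring <- findInterval(ecc, c(rings$e_lo, rings$e_hi[nrow(rings)]),
                       rightmost.closed = TRUE)
  ok <- ring >= 1 & ring <= nrow(rings) & abs(phi) <= pi / 2 &
    ecc >= rings$e_lo[1] & ecc <= rings$e_hi[nrow(rings)]
  ring <- pmax(1L, pmin(ring, nrow(rings)))
  off <- c(0L, cumsum(rings$n_sect))
  ns <- rings$n_sect[ring]
  sect <- pmin(ns, pmax(1L, as.integer(floor((phi + pi / 2) / (pi / ns))) + 1L))
  out <- off[ring] + sect
  out[!ok] <- NA_integer_
  out
}

#' Project an image onto the retina mosaic
#'
#' Integrates image gray values over each on-cell center segment
#' (area-normalized, i.e. the mean intensity over the segment), and contrasts
#' the center with its 8-neighborhood (same-ring neighbors and the three
#' nearest cells in each adjacent ring), each weighted -1/8.  With equal-area
#' normalization a uniform image yields exactly zero net input.  Cells finer
#' than the pixel grid fall back to bilinear sampling at the cell center.
#'
#' The image's own pixel lattice serves as the resampling grid; the
#' full-scale reference grid is 161,900 units per retinal mm^2 (the peak
#' foveal photoreceptor density), which fixture-scale images subsample.
#'
#' @param img A [vf_image()] covering the mosaic's field.
#' @param mosaic A [build_mosaic()] mosaic.
#' @return Data frame: `id`, `center` (mean intensity), `surround`,
#'   `net` (= center + surround).
#' @export
resample_image_to_retina <- function(img, mosaic) {
  stopifnot(inherits(img, "vf_image"), inherits(mosaic, "retina_mosaic"))
  xs <- vf_x(img); ys <- vf_y(img)
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  py <- matrix(ys, length(ys), length(xs))
  ecc <- sqrt(px^2 + py^2)
  phi <- atan2(py, -px)
  cell <- mosaic_cell_at(mosaic, as.vector(ecc), as.vector(phi))
  inside <- !is.na(cell)
  n <- nrow(mosaic$cells)
  sums <- rowsum(as.vector(img$values)[inside], cell[inside])
  cnts <- rowsum(rep(1, sum(inside)), cell[inside])
  center <- rep(NA_real_, n)
  center[as.integer(rownames(sums))] <- sums / cnts
  # empty cells (mosaic finer than the image): bilinear sample at the center
  empty <- which(is.na(center))
  if (length(empty)) {
    center[empty] <- bilinear_sample(img, mosaic$cells$x[empty],
                                     mosaic$cells$y[empty])
  }
  nb <- mosaic_neighbors(mosaic)
  cmat <- matrix(center[nb], nrow = n)
  own <- is.na(nb)            # missing neighbors at the field edge
  cmat[own] <- center[row(cmat)[own]]
  surround <- -rowSums(cmat) / 8
  data.frame(id = mosaic$cells$id, center = center, surround = surround,
             net = center + surround)
}

# 8-neighborhood (n x 8 matrix of cell ids, NA where the field ends):
# same ring +-1 sector, and the nearest sector with its +-1 in each adjacent
# ring
mosaic_neighbors <- function(mosaic) {
  cells <- mosaic$cells; rings <- mosaic$rings
  off <- c(0L, cumsum(rings$n_sect))
  n <- nrow(cells)
  at <- function(ring, sect) {
    ok <- ring >= 1 & ring <= nrow(rings)
    ns <- rings$n_sect[pmax(1L, pmin(ring, nrow(rings)))]
    ok <- ok & sect >= 1 & sect <= ns
    out <- off[pmax(1L, pmin(ring, nrow(rings)))] + sect
    out[!ok] <- NA_integer_
    out
  }
  r <- cells$ring; s <- cells$sector; phi <- cells$phi
  nearest <- function(ring) {
    ns <- rings$n_sect[pmax(1L, pmin(ring, nrow(rings)))]
    pmin(ns, pmax(1L, as.integer(floor((phi + pi / 2) / (pi / ns))) + 1L))
  }
  s_up <- nearest(r + 1L); s_dn <- nearest(r - 1L)
  cbind(at(r, s - 1L), at(r, s + 1L),
        at(r - 1L, s_dn - 1L), at(r - 1L, s_dn), at(r - 1L, s_dn + 1L),
        at(r + 1L, s_up - 1L), at(r + 1L, s_up), at(r + 1L, s_up + 1L))
}

bilinear_sample <- function(img, x, y) {
  xs <- vf_x(img); ys <- vf_y(img)
  fx <- (x - xs[1]) / img$deg_per_px + 1
  fy <- (y - ys[1]) / img$deg_per_px + 1
  x0 <- pmax(1L, pmin(length(xs) - 1L, floor(fx)))
  y0 <- pmax(1L, pmin(length(ys) - 1L, floor(fy)))
  tx <- pmin(1, pmax(0, fx - x0)); ty <- pmin(1, pmax(0, fy - y0))
  v <- img$values
  v[cbind(y0, x0)] * (1 - tx) * (1 - ty) + v[cbind(y0, x0 + 1L)] * tx * (1 - ty) +
    v[cbind(y0 + 1L, x0)] * (1 - tx) * ty + v[cbind(y0 + 1L, x0 + 1L)] * tx * ty
}

#' Logistic retinal output nonlinearity
#'
#' Normalizes the center-surround inputs by the maximum absolute input over
#' the mosaic and applies a logistic squashing into (0, 1).  By default the
#' logistic is symmetric: zero input maps to 0.5 and the extreme inputs to
#' (0.05, 0.95).  A `midpoint` below 0.5 shifts the operating point toward
#' an ON-rectified regime (low spontaneous output, strong response to
#' luminance increments), which is how the pipeline drives the network: with
#' a symmetric operating point the spatial mean of the response to any
#' balanced pattern equals the gray-screen response and stimulus drive
#' cancels in downstream pooling.
#'
#' @param inputs Net center-surround inputs (numeric vector or the data frame
#'   from [resample_image_to_retina()]).
#' @param span Output value reached at the maximal input (default 0.95).
#' @param midpoint Output at zero input (spontaneous level).
#' @return Relative firing rates strictly inside (0, 1).
#' @export
retina_output <- function(inputs, span = 0.95, midpoint = 0.5) {
  if (is.data.frame(inputs)) inputs <- inputs$net
  stopifnot(span > midpoint, span < 1, midpoint > 0)
  m <- max(abs(inputs))
  # below round-off of unit-range intensities the field is flat
  x <- if (m > 1e-12) inputs / m else inputs * 0
  a <- stats::qlogis(midpoint)
  stats::plogis(a + (stats::qlogis(span) - a) * x)
}

#' Image-to-network drive
#'
#' Convenience wrapper running one image through the retina model of a
#' population: center-surround resampling, logistic output at the
#' configured operating point, and cortical mapping at the configured gain.
#'
#' @param pop A [build_population()] object.
#' @param img A [vf_image()].
#' @param config A [sim_config()] (uses `input_gain_hz` and
#'   `input_midpoint_rel`).
#' @return Vector of input firing rates (Hz), one per input neuron.
#' @export
image_drive <- function(pop, img, config = sim_config()) {
  rates <- retina_output(resample_image_to_retina(img, pop$mosaic),
                         midpoint = config$input_midpoint_rel)
  map_to_cortex(rates, pop$mosaic, pop$map,
                gain = config$input_gain_hz)$rate_hz
}

#' Map retinal rates onto the cortical sheet
#'
#' Places each on-cell at the cortical position of its (compensated)
#' receptive-field center under the log-polar map and scales relative rates
#' to model input firing rates.
#'
#' @param rates Relative rates in (0, 1), one per mosaic cell.
#' @param mosaic A [build_mosaic()] mosaic.
#' @param map A [cortical_map()]; defaults to the mosaic's geometry.
#' @param gain Peak input firing rate in Hz.
#' @return Data frame: `id`, `u`, `v` (cortical mm), `ecc`, `phi`,
#'   `rate_hz`.
#' @export
map_to_cortex <- function(rates, mosaic, map = mosaic$geom$map, gain = 250) {
  stopifnot(length(rates) == nrow(mosaic$cells), gain > 0)
  w <- map_deg_to_cortex(map, mosaic$cells$rf_ecc, mosaic$cells$phi)
  data.frame(id = mosaic$cells$id, u = w$u, v = w$v,
             ecc = mosaic$cells$rf_ecc, phi = mosaic$cells$phi,
             rate_hz = gain * rates)
}
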