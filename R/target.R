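# Area-summation target activation patterns: the per-neuron response
# predicted by integrating the ASF derivative weighting over the
# contrast-energy image around each V1 excitatory cell's receptive-field
# center, within a 7-degree-diameter disk (enough to reach the response
# asymptote).

#' Fit ASF parameters per eccentricity ring
#'
#' Parameters are fitted to the regression-mean characteristics at 1-degree
#' eccentricity rings (ring centers 1..27 degrees) rather than per neuron;
#' single-cell variability is deliberately averaged out.
#'
#' @param coeffs An [asf_regression()].
#' @param ring_centers Eccentricities (degrees) at which to fit.
#' @return Named list of [asf_params()], one per ring center.
#' @export
fit_ring_params <- function(coeffs = asf_regression(), ring_centers = 1:27) {
  out <- lapply(ring_centers, function(e)
    fit_asf_params(characteristics_at_eccentricity(coeffs, e)))
  names(out) <- as.character(ring_centers)
  out
}

# ring label (nearest ring center) for eccentricities
ring_of <- function(ecc, ring_centers = 1:27) {
  rc <- as.numeric(ring_centers)
  rc[pmax(1L, pmin(length(rc), round(ecc - rc[1] + 1)))]
}

#' Compute the target activation pattern
#'
#' For each V1 excitatory neuron, sums `f(u, v) * CE(u, v) * pixel_area` over
#' contrast-energy pixels within `disk_deg / 2` of its receptive-field
#' center, with `f` the derivative weighting of the neuron's
#' eccentricity-ring ASF.  The innermost pixel (containing the center, where
#' the density is singular but integrable) instead receives the exact disk
#' integral of the ASF over an equal-area disk, which preserves the
#' disk-integral identity at the center.
#'
#' @param ce Contrast-energy `vf_image` (from [contrast_energy_image()]).
#' @param pop A [build_population()] object.
#' @param ring_params Named list from [fit_ring_params()].
#' @param disk_deg Integration-disk diameter in degrees.
#' @return Object of class `target_pattern`: data frame `neurons` (cortical
#'   index `idx`, `ecc`, `x`, `y`, `target`, `border_affected`), aligned with
#'   the E_V1 rows of the cortical population; `normalized` flag.
#' @export
compute_target <- function(ce, pop, ring_params, disk_deg = 7) {
  stopifnot(inherits(ce, "vf_image"))
  cort <- cortical_neurons(pop)
  ev1 <- which(cort$group == "E_V1")
  ecc <- cort$ecc[ev1]; phi <- cort$phi[ev1]
  x <- -ecc * cos(phi); y <- ecc * sin(phi)
  dpx <- ce$deg_per_px
  half <- floor((disk_deg / 2) / dpx) + 1L
  offs <- seq(-half, half)
  off_x <- matrix(offs * dpx, length(offs), length(offs), byrow = TRUE)
  off_y <- matrix(offs * dpx, length(offs), length(offs))
  r <- sqrt(off_x^2 + off_y^2)
  rings <- ring_of(ecc, as.numeric(names(ring_params)))
  # one weight stencil per eccentricity ring in use
  # the density is averaged over a 3 x 3 sub-pixel grid per cell (it changes
  # quickly near the center), and boundary cells contribute the fraction of
  # their sub-points inside the disk; the singular center cell receives the
  # exact disk integral over an equal-area disk
  sub <- expand.grid(dx = (-1:1) / 3 * dpx, dy = (-1:1) / 3 * dpx)
  cover <- r <= disk_deg / 2 + dpx
  cover[half + 1L, half + 1L] <- FALSE
  kernels <- lapply(unique(rings), function(rc) {
    p <- ring_params[[as.character(rc)]]
    k <- matrix(0, length(offs), length(offs))
    acc <- numeric(sum(cover))
    for (s in seq_len(nrow(sub))) {
      sx <- off_x[cover] + sub$dx[s]; sy <- off_y[cover] + sub$dy[s]
      inside <- sx^2 + sy^2 <= (disk_deg / 2)^2
      acc <- acc + ifelse(inside, derivative_weight(p, sx, sy), 0)
    }
    k[cover] <- acc / nrow(sub) * dpx^2
    c0 <- half + 1L
    k[c0, c0] <- eval_asf(p, 2 * dpx / sqrt(pi))  # equal-area disk integral
    k
  })
  names(kernels) <- as.character(unique(rings))
  xs <- vf_x(ce); ys <- vf_y(ce)
  nr <- nrow(ce$values); ncl <- ncol(ce$values)
  target <- numeric(length(ev1))
  border <- logical(length(ev1))
  for (n in seq_along(ev1)) {
    j <- round((x[n] - xs[1]) / dpx) + 1L
    i <- round((y[n] - ys[1]) / dpx) + 1L
    i0 <- i - half; i1 <- i + half; j0 <- j - half; j1 <- j + half
    if (i1 < 1 || j1 < 1 || i0 > nr || j0 > ncl) {
      target[n] <- NA_real_; border[n] <- TRUE; next
    }
    ci0 <- max(i0, 1L); ci1 <- min(i1, nr)
    cj0 <- max(j0, 1L); cj1 <- min(j1, ncl)
    border[n] <- (ci0 != i0) || (ci1 != i1) || (cj0 != j0) || (cj1 != j1)
    k <- kernels[[as.character(rings[n])]]
    patch <- ce$values[ci0:ci1, cj0:cj1, drop = FALSE]
    ksub <- k[(ci0 - i0 + 1L):(ci1 - i0 + 1L),
              (cj0 - j0 + 1L):(cj1 - j0 + 1L), drop = FALSE]
    target[n] <- sum(patch * ksub)
  }
  structure(list(neurons = data.frame(idx = ev1, ecc = ecc, x = x, y = y,
                                      target = target,
                                      border_affected = border),
                 normalized = FALSE, disk_deg = disk_deg),
            class = "target_pattern")
}

#' Border-exclusion mask
#'
#' Boolean mask over the V1 excitatory population keeping neurons whose
#' receptive-field centers lie at least `margin` degrees inside the modeled
#' field; applied identically to simulated and target patterns.
#'
#' @param pop A [build_population()] object.
#' @param margin Margin in degrees (default 0.5).
#' @return Logical vector (TRUE = keep), one per E_V1 neuron.
#' @export
exclude_border <- function(pop, margin = 0.5) {
  stopifnot(margin >= 0)
  cort <- cortical_neurons(pop)
  ev1 <- which(cort$group == "E_V1")
  keep <- field_edge_distance(pop$geom, cort$ecc[ev1], cort$phi[ev1]) >= margin
  if (!any(keep))
    stop("border margin excludes every neuron; margin exceeds the field size")
  keep
}
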