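# Ratio-of-Gaussians area summation model.
#
# The response of a V1 neuron to a centred circular grating of diameter x is
# modelled as the ratio of the squared, scaled error-function integrals of a
# narrow excitatory (center) and a broad divisive (surround) Gaussian:
#
#   R(x) = k_c L_c(x) / (1 + k_s L_s(x)),
#   L(x; w) = ( (2/sqrt(pi)) * integral_0^x exp(-(y/w)^2) dy )^2
#           = w^2 * erf(x/w)^2.
#
# R rises with x while the center integral grows, then falls as the surround
# integral catches up (surround suppression), approaching the asymptote
# k_c w_c^2 / (1 + k_s w_s^2).

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Area summation function parameters
#'
#' Bundle of the center/surround gains and spatial extents of the
#' ratio-of-Gaussians area summation function (ASF) at one eccentricity.
#'
#' @param k_c Center gain (unitless, >= 0).
#' @param k_s Surround gain (unitless, >= 0).
#' @param w_c Center spatial extent (degrees, > 0).
#' @param w_s Surround spatial extent (degrees, > 0).
#' @param eccentricity Receptive-field eccentricity in degrees (>= 0).
#' @return An object of class `asf_params`.
#' @export
asf_params <- function(k_c, k_s, w_c, w_s, eccentricity = NA_real_) {
  stopifnot(is.finite(k_c), is.finite(k_s), is.finite(w_c), is.finite(w_s),
            k_c >= 0, k_s >= 0, w_c > 0, w_s > 0)
  structure(list(k_c = k_c, k_s = k_s, w_c = w_c, w_s = w_s,
                 eccentricity = eccentricity),
            class = "asf_params")
}

#' @export
print.asf_params <- function(x, ...) {
  cat(sprintf("ASF params (ecc %.2f deg): k_c=%.4g k_s=%.4g w_c=%.4g w_s=%.4g\n",
              x$eccentricity, x$k_c, x$k_s, x$w_c, x$w_s))
  invisible(x)
}

#' Evaluate the area summation function
#'
#' Neural response to a centred circular stimulus of diameter `x` under the
#' ratio-of-Gaussians model.
#'
#' @param params An [asf_params()] object.
#' @param x Stimulus diameter(s) in degrees, `x >= 0`.
#' @return Response in arbitrary rate units, same length as `x`.
#' @export
eval_asf <- function(params, x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("stimulus diameter `x` must be finite and non-negative")
  L_c <- params$w_c^2 * .erf(x / params$w_c)^2
  L_s <- params$w_s^2 * .erf(x / params$w_s)^2
  params$k_c * L_c / (1 + params$k_s * L_s)
}

# dR/dx in closed form.  With Lint(x,w) = integral_0^x exp(-(y/w)^2) dy
# = w sqrt(pi)/2 erf(x/w):
#   L'(x; w) = (8/pi) exp(-(x/w)^2) Lint(x, w)
#   R'(x) = [k_c Lc' (1 + k_s Ls) - k_s Ls' k_c Lc] / (1 + k_s Ls)^2
asf_deriv <- function(params, x) {
  w_c <- params$w_c; w_s <- params$w_s
  Lint_c <- w_c * sqrt(pi) / 2 * .erf(x / w_c)
  Lint_s <- w_s * sqrt(pi) / 2 * .erf(x / w_s)
  L_c <- (2 / sqrt(pi) * Lint_c)^2
  L_s <- (2 / sqrt(pi) * Lint_s)^2
  dL_c <- 8 / pi * exp(-(x / w_c)^2) * Lint_c
  dL_s <- 8 / pi * exp(-(x / w_s)^2) * Lint_s
  den <- 1 + params$k_s * L_s
  (params$k_c * dL_c * den - params$k_s * dL_s * params$k_c * L_c) / den^2
}

#' Distance-dependent derivative weighting of the ASF
#'
#' Converts the area summation function into a radial density over the visual
#' field: `f(u, v) = R'(2 r) / (pi r)` with `r^2 = u^2 + v^2`, so that the
#' integral of `f` over a disk of diameter `D` centred at the origin recovers
#' `R(D)` exactly.  Used to weight contrast energy around a receptive-field
#' center.
#'
#' @param params An [asf_params()] object.
#' @param u,v Offsets from the receptive-field center in degrees (recycled).
#' @param r_min Radii below `r_min` are evaluated at `r_min` (the density is
#'   integrable but unbounded at the origin; callers integrating over a grid
#'   should treat the innermost cell with [eval_asf()] directly — see
#'   [compute_target()]).
#' @return Weight per unit area (rate units / deg^2).
#' @export
derivative_weight <- function(params, u, v = 0, r_min = 1e-6) {
  r <- sqrt(u^2 + v^2)
  r <- pmax(r, r_min)
  asf_deriv(params, 2 * r) / (pi * r)
}

#' Linear eccentricity models of the ASF characteristics
#'
#' Slopes and intercepts describing the summation-field diameter, surround
#' diameter, and suppression level as linear functions of receptive-field
#' eccentricity.  The defaults are approximate values chosen so that the
#' 14-degree curve shows a summation peak near 1.5 degrees followed by visible
#' suppression toward an asymptote reached well inside a 7-degree stimulus;
#' they are calibration constants of this pipeline, not measured fits.
#' Summation field and surround diameter grow with eccentricity at a fixed
#' ratio of about 2.75, and suppression is eccentricity-flat, which keeps the
#' characteristic triple inside the region the ratio-of-Gaussians family can
#' actually realise (the suppression level and the surround/summation diameter
#' ratio are strongly coupled in that family).
#'
#' @param summation_field,surround_diameter,suppression Numeric `c(intercept,
#'   slope)` pairs (degrees and degrees/degree; suppression is a unitless
#'   fraction).
#' @return An object of class `asf_regression`.
#' @export
asf_regression <- function(summation_field = c(0.5, 0.07),
                           surround_diameter = c(1.4, 0.19),
                           suppression = c(0.35, 0)) {
  coef <- list(summation_field = summation_field,
               surround_diameter = surround_diameter,
               suppression = suppression)
  stopifnot(all(lengths(coef) == 2L))
  # predicted sizes must stay positive and ordered over the modeled range
  ecc <- c(0.5, 27)
  sf <- summation_field[1] + summation_field[2] * ecc
  sd_ <- surround_diameter[1] + surround_diameter[2] * ecc
  stopifnot(all(sf > 0), all(sd_ > sf))
  structure(coef, class = "asf_regression")
}

#' ASF characteristics at one eccentricity
#'
#' Evaluates the linear eccentricity regressions, clamping the suppression
#' level into `[0, 1)`.
#'
#' @param coeffs An [asf_regression()] object.
#' @param eccentricity Degrees, in `[0, 30]`.
#' @return List with `eccentricity`, `summation_field`, `surround_diameter`,
#'   `suppression` (class `asf_characteristics`).
#' @export
characteristics_at_eccentricity <- function(coeffs, eccentricity) {
  stopifnot(inherits(coeffs, "asf_regression"))
  if (!is.finite(eccentricity) || eccentricity < 0 || eccentricity > 30)
    stop("eccentricity must lie in [0, 30] degrees")
  ev <- function(cf) cf[1] + cf[2] * eccentricity
  structure(list(
    eccentricity = eccentricity,
    summation_field = ev(coeffs$summation_field),
    surround_diameter = ev(coeffs$surround_diameter),
    suppression = min(max(ev(coeffs$suppression), 0), 1 - 1e-9)
  ), class = "asf_characteristics")
}

#' Measure summation field, surround diameter and suppression from a curve
#'
#' Numerically characterises an ASF parameter set: the summation field is the
#' diameter at the response peak, the surround diameter is the first diameter
#' beyond the peak at which the response comes within 5% of its asymptote, and
#' the suppression level is `(peak - asymptote) / peak`.
#'
#' @param params An [asf_params()] object.
#' @param x_max Upper diameter bound for the peak search (degrees).
#' @param surround_tol Relative closeness to the asymptote defining the
#'   surround diameter.
#' @return An `asf_characteristics` list.
#' @export
measure_asf <- function(params, x_max = 20, surround_tol = 0.05) {
  # bracket the peak on a log grid first: the curve is flat near its
  # asymptote over most of any wide interval, which defeats golden search
  xg <- exp(seq(log(1e-3), log(x_max), length.out = 300))
  i <- which.max(eval_asf(params, xg))
  lo <- xg[max(1, i - 1)]; hi <- xg[min(length(xg), i + 1)]
  opt <- stats::optimize(function(x) eval_asf(params, x),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
  peak_x <- opt$maximum
  peak <- opt$objective
  asym <- params$k_c * params$w_c^2 / (1 + params$k_s * params$w_s^2)
  supp <- max(0, (peak - asym) / peak)
  # first diameter beyond the peak where |R - asym| <= tol * asym; bracket on
  # a coarse grid, then refine by root-finding so the measure is smooth in the
  # parameters (the fit optimises through it)
  g <- function(x) abs(eval_asf(params, x) - asym) - surround_tol * asym
  xs <- seq(peak_x, x_max, length.out = 400)
  gv <- g(xs)
  i <- which(gv <= 0)[1]
  sdiam <- if (is.na(i)) x_max
  else if (i == 1L) peak_x
  else stats::uniroot(g, c(xs[i - 1L], xs[i]), tol = 1e-10)$root
  structure(list(eccentricity = params$eccentricity,
                 summation_field = peak_x,
                 surround_diameter = sdiam,
                 suppression = supp),
            class = "asf_characteristics")
}

#' Fit ratio-of-Gaussians parameters to target ASF characteristics
#'
#' Nelder-Mead search (on log-parameters, keeping gains and extents positive)
#' for `k_s`, `w_c`, `w_s` such that the measured summation field, surround
#' diameter and suppression of the resulting curve match the target; the
#' overall gain `k_c` is fixed at 1 because the three characteristics are
#' invariant to it.
#'
#' @param target An `asf_characteristics` list (e.g. from
#'   [characteristics_at_eccentricity()]).
#' @param max_iter Maximum Nelder-Mead iterations.
#' @param tol Convergence tolerance on the loss.
#' @return An [asf_params()] object with attributes `loss` (sum of squared
#'   relative characteristic errors) and `converged`.
#' @export
fit_asf_params <- function(target, max_iter = 2000, tol = 1e-8) {
  stopifnot(target$summation_field > 0,
            target$surround_diameter > target$summation_field,
            target$suppression >= 0, target$suppression < 1)
  tg <- c(target$summation_field, target$surround_diameter,
          max(target$suppression, 1e-4))
  loss_fn <- function(theta) {
    p <- asf_params(1, exp(theta[1]), exp(theta[2]), exp(theta[3]),
                    eccentricity = target$eccentricity)
    if (p$w_s <= p$w_c) return(1e6 + (p$w_c - p$w_s)^2)
    m <- measure_asf(p)
    got <- c(m$summation_field, m$surround_diameter, max(m$suppression, 1e-4))
    sum(((got - tg) / tg)^2)
  }
  # surround gain init from the asymptote/peak ratio at erf saturation
  ss <- max(target$suppression, 0.02)
  ws0 <- target$surround_diameter / 2
  ks0 <- (1 / (1 - ss) - 1) / ws0^2
  starts <- list(log(c(ks0, target$summation_field / 2, ws0)),
                 log(c(2 * ks0, target$summation_field, 0.7 * ws0)),
                 log(c(0.5 * ks0, 0.7 * target$summation_field, 1.3 * ws0)))
  fit <- NULL
  for (theta0 in starts) {
    f <- stats::optim(theta0, loss_fn, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = tol))
    # restart from the solution: shrunk simplexes often stall short
    f <- stats::optim(f$par, loss_fn, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = tol))
    if (is.null(fit) || f$value < fit$value) fit <- f
    if (fit$value < 1e-6) break
  }
  out <- asf_params(1, exp(fit$par[1]), exp(fit$par[2]), exp(fit$par[3]),
                    eccentricity = target$eccentricity)
  attr(out, "loss") <- fit$value
  attr(out, "converged") <- fit$value < 1e-3
  if (!attr(out, "converged"))
    warning(sprintf("ASF fit did not converge (loss %.3g); returning best-so-far",
                    fit$value))
  out
}

#' Artificial ASF variants
#'
#' Rescales the center and surround gains, leaving the spatial extents
#' untouched.  Factors (4, 0.25) give a larger summation field with no
#' suppression; (0.25, 4) a smaller summation field with stronger suppression.
#'
#' @param params An [asf_params()] object.
#' @param factor_c,factor_s Positive multipliers for `k_c` and `k_s`.
#' @return An [asf_params()] object.
#' @export
make_variant_asf <- function(params, factor_c, factor_s) {
  stopifnot(factor_c > 0, factor_s > 0)
  asf_params(params$k_c * factor_c, params$k_s * factor_s,
             params$w_c, params$w_s, params$eccentricity)
}
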