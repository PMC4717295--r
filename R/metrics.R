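# Efficiency metrics of a simulated population response: distance to the
# area summation target (DAS), total spike count (the linear energy proxy),
# entropy per spike of the spatial rate pattern, and population sparseness.

#' Normalize a response pattern to [0, 1]
#'
#' Subtracts the minimum and divides by the spread, mapping the pattern onto
#' `[0, 1]`.  A constant pattern maps to all zeros with a degeneracy flag
#' (never NaN).  The `"max"` variant divides the min-subtracted pattern by
#' the raw maximum instead.
#'
#' @param values Numeric vector.
#' @param denominator `"range"` (default, guarantees max 1) or `"max"`.
#' @return Normalized vector with `attr(, "degenerate")`.
#' @export
normalize_pattern <- function(values, denominator = c("range", "max")) {
  denominator <- match.arg(denominator)
  stopifnot(all(is.finite(values)))
  lo <- min(values); hi <- max(values)
  den <- if (denominator == "range") hi - lo else hi
  if (den <= 0) {
    out <- values * 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (values - lo) / den
  attr(out, "degenerate") <- FALSE
  out
}

#' Distance to Area Summation (DAS)
#'
#' Sum of per-neuron absolute differences between the normalized simulated
#' and target patterns over unmasked neurons.
#'
#' @param sim,target Normalized patterns of equal length.
#' @param mask Logical keep-mask (e.g. [exclude_border()]); default all.
#' @return Non-negative scalar (at most the number of unmasked neurons).
#' @export
das <- function(sim, target, mask = NULL) {
  stopifnot(length(sim) == length(target))
  if (is.null(mask)) mask <- rep(TRUE, length(sim))
  stopifnot(length(mask) == length(sim))
  sum(abs(sim[mask] - target[mask]))
}

#' Entropy and entropy per spike of a spike-count pattern
#'
#' Spike counts are normalized by the maximum count, binned into 256
#' equal-width bins on `[0, 1]`, and the Shannon entropy of the bin
#' distribution is divided by the total spike count.
#'
#' @param spike_counts Non-negative per-neuron spike counts with a positive
#'   total.
#' @param n_bins Histogram bins (256 gives a ceiling of 8 bits).
#' @return List with `entropy` (bits), `entropy_per_spike` (bits/spike), and
#'   `total_spikes`.
#' @export
entropy_per_spike <- function(spike_counts, n_bins = 256) {
  stopifnot(all(spike_counts >= 0))
  n_s <- sum(spike_counts)
  if (n_s <= 0)
    stop("entropy per spike is undefined for an all-zero spike pattern")
  rel <- spike_counts / max(spike_counts)
  # right-closed bins ( (i-1)/n, i/n ]; zero falls in the first bin
  bin <- pmin(n_bins, ceiling(rel * n_bins))
  bin[bin < 1L] <- 1L
  q <- tabulate(bin, nbins = n_bins) / length(rel)
  q <- q[q > 0]
  e <- -sum(q * log2(q))
  list(entropy = e, entropy_per_spike = e / n_s, total_spikes = n_s)
}

#' Population sparseness
#'
#' `S_p = (1 - (sum(y)/N)^2 / (sum(y^2)/N)) / (1 - 1/N)`: 0 for a uniform
#' pattern, 1 when a single neuron carries all activity.
#'
#' @param rates Non-negative rates or counts, `N >= 2`, not all zero.
#' @return Scalar in `[0, 1]`.
#' @export
population_sparseness <- function(rates) {
  n <- length(rates)
  stopifnot(n >= 2, all(rates >= 0))
  if (all(rates == 0)) stop("sparseness is undefined for an all-zero pattern")
  (1 - (sum(rates) / n)^2 / (sum(rates^2) / n)) / (1 - 1 / n)
}

#' ATP energy estimate of a response
#'
#' Optional linear conversion of spike counts to ATP molecule usage:
#' maintaining the resting potential costs 3.4e8 ATP/s per neuron plus 1e8
#' ATP/s for associated glia, and each spike costs 1e9 ATP.
#'
#' @param total_spikes Total spikes in the pattern.
#' @param n_neurons Number of neurons.
#' @param duration_s Duration in seconds.
#' @param rest_atp_s,glia_atp_s,spike_atp Conversion constants.
#' @return ATP count (reporting only).
#' @export
atp_estimate <- function(total_spikes, n_neurons, duration_s,
                         rest_atp_s = 3.4e8, glia_atp_s = 1e8,
                         spike_atp = 1e9) {
  stopifnot(total_spikes >= 0, n_neurons >= 0, duration_s >= 0)
  n_neurons * duration_s * (rest_atp_s + glia_atp_s) + total_spikes * spike_atp
}

#' Efficiency report for one (image, parameter point) run
#'
#' Normalizes the simulated E_V1 spike pattern and the target pattern
#' (each over the unmasked neurons), and assembles DAS with the three
#' efficiency measures into one tidy row.
#'
#' @param resp A [simulate_network()] spike response.
#' @param target A [compute_target()] pattern.
#' @param mask Border mask from [exclude_border()].
#' @param image_id,beta_lat,beta_ffb,seed Provenance columns.
#' @return One-row data frame.
#' @export
efficiency_report <- function(resp, target, mask, image_id = NA,
                              beta_lat = NA, beta_ffb = NA, seed = NA) {
  counts <- resp$neurons$count[resp$neurons$group == "E_V1"]
  tg <- target$neurons$target
  stopifnot(length(counts) == length(tg))
  keep <- mask & !is.na(tg)
  s_norm <- normalize_pattern(counts[keep])
  t_norm <- normalize_pattern(tg[keep])
  total <- sum(counts[keep])
  es <- if (total > 0) entropy_per_spike(counts[keep])
        else list(entropy = NA_real_, entropy_per_spike = NA_real_)
  sp <- if (total > 0) population_sparseness(counts[keep]) else NA_real_
  data.frame(image_id = image_id, beta_lat = beta_lat, beta_ffb = beta_ffb,
             seed = seed, n_neurons = sum(keep),
             das = das(s_norm, t_norm),
             total_spikes = total,
             entropy = es$entropy,
             entropy_per_spike = es$entropy_per_spike,
             sparseness = sp,
             input_spikes = resp$input_spikes_recorded,
             degenerate = attr(s_norm, "degenerate"))
}
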