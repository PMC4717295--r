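# Sweep orchestration and statistics: the images x beta-grid manifest,
# pooled and per-image Pearson correlations of each efficiency metric
# against DAS, the spatial-frequency image grouping, range-based extreme
# exclusion, and the group-comparison tests.

#' Build the sweep manifest
#'
#' Full cross product of images and beta-grid points with deterministic
#' per-run seeds derived from the master seed.
#'
#' @param image_ids Character or integer image identifiers.
#' @param grid Data frame with `beta_lat`, `beta_ffb` (see [beta_grid()]).
#' @param master_seed Integer master seed.
#' @return Data frame of class `sweep_manifest`: `run`, `image_id`,
#'   `beta_lat`, `beta_ffb`, `seed`.
#' @export
build_manifest <- function(image_ids, grid, master_seed = 1L) {
  stopifnot(nrow(grid) >= 1, all(c("beta_lat", "beta_ffb") %in% names(grid)))
  man <- expand.grid(image_id = image_ids, point = seq_len(nrow(grid)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  man$beta_lat <- grid$beta_lat[man$point]
  man$beta_ffb <- grid$beta_ffb[man$point]
  man$point <- NULL
  man$run <- seq_len(nrow(man))
  # deterministic per-run seeds, kept inside 32-bit integer range
  man$seed <- as.integer((as.numeric(master_seed) * 7919 + man$run * 104729) %%
                           2147483647)
  class(man) <- c("sweep_manifest", "data.frame")
  man[, c("run", "image_id", "beta_lat", "beta_ffb", "seed")]
}

#' Run the sweep over one population
#'
#' Executes every manifest row: samples the network at the row's beta point,
#' simulates the response to the row's image, and assembles the per-run
#' efficiency report.  Connection candidates and per-image input rates and
#' targets are computed once and reused.
#'
#' @param pop A [build_population()] object.
#' @param cand [connection_candidates()] for `pop`.
#' @param drive_by_image Named list: per image, input rates (Hz) per input
#'   neuron.
#' @param target_by_image Named list of [compute_target()] patterns.
#' @param manifest A [build_manifest()] data frame.
#' @param config A [sim_config()].
#' @param mask Border mask; default [exclude_border()] at 0.5 degrees.
#' @param progress Print a line per run.
#' @return Data frame of efficiency reports, one row per run.
#' @export
run_sweep <- function(pop, cand, drive_by_image, target_by_image, manifest,
                      config = sim_config(), mask = NULL, progress = FALSE) {
  if (is.null(mask)) mask <- exclude_border(pop)
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- as.character(row$image_id)
    syn <- sample_connections(cand, row$beta_lat, row$beta_ffb,
                              seed = row$seed)
    resp <- simulate_network(pop, syn, drive_by_image[[img]], config,
                             seed = row$seed + 1L)
    out[[i]] <- efficiency_report(resp, target_by_image[[img]], mask,
                                  image_id = img, beta_lat = row$beta_lat,
                                  beta_ffb = row$beta_ffb, seed = row$seed)
    attr(out[[i]], "ev1_counts") <-
      resp$neurons$count[resp$neurons$group == "E_V1"]
    if (progress)
      message(sprintf("run %d/%d: image %s beta_lat %.3g beta_ffb %.3g das %.1f spikes %d",
                      i, nrow(manifest), img, row$beta_lat, row$beta_ffb,
                      out[[i]]$das, out[[i]]$total_spikes))
  }
  reports <- do.call(rbind, out)
  attr(reports, "ev1_counts") <-
    do.call(rbind, lapply(out, attr, "ev1_counts"))
  attr(reports, "mask") <- mask
  reports
}

#' Re-score DAS against alternative target patterns
#'
#' Recomputes the DAS column of a sweep's reports against a different set of
#' target patterns (e.g. an artificial-ASF variant), reusing the stored
#' simulated spike patterns instead of re-running any simulation.
#'
#' @param reports Output of [run_sweep()] (carries the per-run E_V1 spike
#'   patterns).
#' @param target_by_image Named list of [compute_target()] patterns.
#' @param mask Border mask; defaults to the mask stored with the reports.
#' @return The reports data frame with `das` recomputed.
#' @export
rescore_das <- function(reports, target_by_image, mask = NULL) {
  counts <- attr(reports, "ev1_counts")
  if (is.null(counts)) stop("reports carry no stored spike patterns")
  if (is.null(mask)) mask <- attr(reports, "mask")
  for (i in seq_len(nrow(reports))) {
    tg <- target_by_image[[as.character(reports$image_id[i])]]$neurons$target
    keep <- mask & !is.na(tg)
    reports$das[i] <- das(normalize_pattern(counts[i, keep]),
                          normalize_pattern(tg[keep]))
  }
  reports
}

#' Correlate efficiency metrics against DAS
#'
#' Pooled (raw data points across images) and per-image Pearson correlation
#' coefficients of total spikes, entropy per spike and population sparseness
#' against DAS.
#'
#' @param reports Data frame from [run_sweep()] / [efficiency_report()].
#' @param metrics Metric columns to correlate.
#' @return List with `pooled` (data frame metric, r, p, n) and `per_image`
#'   (data frame image_id, metric, r, n).
#' @export
correlate_metrics <- function(reports,
                              metrics = c("total_spikes", "entropy_per_spike",
                                          "sparseness")) {
  stopifnot("das" %in% names(reports), all(metrics %in% names(reports)))
  one <- function(df, m) {
    ok <- is.finite(df$das) & is.finite(df[[m]])
    if (sum(ok) < 3 || stats::sd(df$das[ok]) == 0 || stats::sd(df[[m]][ok]) == 0)
      return(data.frame(metric = m, r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- stats::cor.test(df$das[ok], df[[m]][ok])
    data.frame(metric = m, r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  pooled <- do.call(rbind, lapply(metrics, function(m) one(reports, m)))
  per_image <- do.call(rbind, lapply(split(reports, reports$image_id),
    function(df) {
      cbind(image_id = df$image_id[1],
            do.call(rbind, lapply(metrics, function(m) one(df, m)[, c("metric", "r", "n")])))
    }))
  rownames(per_image) <- NULL
  list(pooled = pooled, per_image = per_image)
}

#' Split images into frequency groups
#'
#' k-means clustering (fixed seed, multiple restarts) of the 5-bin Gabor
#' frequency signatures into `k = 2` groups, labeled `"low"` (the cluster
#' with more mass in the two lowest-frequency bins) and `"mixed"`.
#'
#' @param signatures Matrix (images x bins) or list of
#'   [frequency_signature()] vectors.
#' @param k Number of clusters.
#' @param seed RNG seed for the restarts.
#' @param nstart k-means restarts.
#' @return Factor of group labels with the k-means fit as `attr(, "fit")`;
#'   all-identical signatures return all-`"degenerate"` labels.
#' @export
split_frequency_groups <- function(signatures, k = 2, seed = 1L, nstart = 50) {
  m <- if (is.data.frame(signatures)) as.matrix(signatures)
       else if (is.list(signatures)) do.call(rbind, signatures)
       else as.matrix(signatures)
  if (nrow(unique(m)) < k) {
    out <- factor(rep("degenerate", nrow(m)))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nstart)
  low_mass <- rowSums(km$centers[, 1:2, drop = FALSE])
  labels <- rep("mixed", k)
  labels[which.max(low_mass)] <- "low"
  out <- factor(labels[km$cluster], levels = c("low", "mixed"))
  attr(out, "fit") <- km
  attr(out, "degenerate") <- FALSE
  out
}

#' Exclude extreme-responding runs
#'
#' Masks runs whose total spike count lies in the top or bottom `fraction`
#' of the dynamic range (range-based: `min + fraction * (max - min)` and the
#' mirrored upper cut), aiming past saturated and silent activation
#' patterns.
#'
#' @param totals Total spike counts per run (or a reports data frame).
#' @param fraction Fraction of the range cut from each end.
#' @return Logical keep-mask with attr `cuts = c(lower, upper)`.
#' @export
exclude_extremes <- function(totals, fraction = 0.15) {
  if (is.data.frame(totals)) totals <- totals$total_spikes
  stopifnot(fraction >= 0, fraction < 0.5 + 1e-12)
  lo <- min(totals); hi <- max(totals)
  cuts <- c(lo + fraction * (hi - lo), hi - fraction * (hi - lo))
  keep <- totals >= cuts[1] & totals <= cuts[2]
  attr(keep, "cuts") <- cuts
  keep
}

#' Compare per-image correlations between two image groups
#'
#' Two-sided Wilcoxon rank-sum test with the images as samples; exact
#' distribution for groups of at most 12 without ties, normal approximation
#' with continuity and tie correction otherwise.
#'
#' @param r_a,r_b Per-image correlation coefficients of the two groups.
#' @return `htest` object from [stats::wilcox.test()].
#' @export
compare_groups <- function(r_a, r_b) {
  stopifnot(is.numeric(r_a), is.numeric(r_b), length(r_a) >= 1,
            length(r_b) >= 1)
  no_ties <- !anyDuplicated(c(r_a, r_b))
  use_exact <- length(r_a) <= 12 && length(r_b) <= 12 && no_ties
  stats::wilcox.test(r_a, r_b, exact = use_exact, correct = TRUE)
}

#' Friedman check on the input drive
#'
#' Tests whether the summed input spike rate differs between matched
#' conditions (e.g. image groups, blocked by parameter point); reporting
#' only.
#'
#' @param drive Numeric matrix: blocks in rows, groups/treatments in
#'   columns.
#' @return `htest` object from [stats::friedman.test()].
#' @export
input_drive_check <- function(drive) {
  if (!is.matrix(drive) || !is.numeric(drive))
    stop("`drive` must be a numeric matrix (blocks x groups)")
  stopifnot(nrow(drive) >= 2, ncol(drive) >= 2)
  ranks <- t(apply(drive, 1, rank))
  if (stats::var(colSums(ranks)) == 0) {
    # fully tied design (e.g. identical columns): no treatment effect
    return(structure(list(statistic = c("Friedman chi-squared" = 0),
                          parameter = c(df = ncol(drive) - 1),
                          p.value = 1,
                          method = "Friedman rank sum test (degenerate ties)",
                          data.name = deparse(substitute(drive))),
                     class = "htest"))
  }
  stats::friedman.test(drive)
}
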