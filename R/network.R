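# Recurrent spiking network of the model visual cortex: five neuron groups in
# three hierarchical levels (Poisson input layer; V1 excitatory pyramidal and
# inhibitory basket cells; extrastriate excitatory and inhibitory cells),
# distance-dependent stochastic connectivity on the cortical sheet, and a
# 500 ms simulation protocol (200 ms baseline, 300 ms stationary image
# input; spike counts reported over 200-500 ms).

#' Full-scale reference neuron counts
#'
#' Group sizes of the full-scale model (`low_res_input` is the input-layer
#' size of the reduced-retina control).  Scaled geometries preserve these
#' ratios.
#'
#' @return Named numeric vector.
#' @export
reference_counts <- function() {
  c(input = 226206, E_V1 = 42849, I_V1 = 10713, E_X = 10713, I_X = 10713,
    low_res_input = 9014)
}

#' Build the model neuron populations
#'
#' Lays the five groups out on the cortical sheet.  The input layer sits at
#' the cortical positions of the retina mosaic's receptive-field centers;
#' the cortical groups are placed uniformly over the mapped hemifield sector
#' (uniform density per mm^2 of cortex, i.e. retinotopic neuron density in
#' the visual field follows the cortical magnification).  When
#' `scale_factor < 1` the cortical-map constant `k` is shrunk by
#' `sqrt(scale_factor)`, so neuron densities per mm^2, expected in-degrees,
#' and the mm-scale connectivity kernels all retain their full-scale values
#' on a proportionally smaller sheet.
#'
#' @param scale_factor Overall neuron-count scale in `(0, 1]`.
#' @param seed Integer seed for the stochastic cortical placement.
#' @param geom A [field_geometry()].
#' @param pointwise If `TRUE`, V1 excitatory cells are single-compartment
#'   (the compartmental-control experiment).
#' @param density_profile Retinal density profile for the input mosaic.
#' @return Object of class `neuron_population`: `neurons` data frame (id,
#'   group, u, v in mm, ecc, phi, n_comp; input neurons first), the scaled
#'   `map`, the `mosaic`, and count bookkeeping.
#' @export
build_population <- function(scale_factor, seed = 1L, geom = field_geometry(),
                             pointwise = FALSE,
                             density_profile = midget_density()) {
  stopifnot(scale_factor > 0, scale_factor <= 1)
  refs <- reference_counts()[1:5]
  target <- round(scale_factor * refs)
  # input mosaic: two-pass linear calibration of the resolution factor
  f0 <- min(1, scale_factor * refs[["input"]] / 8.5e4)
  trial <- build_mosaic(density_profile, f0, geom)
  f1 <- min(1, f0 * target[["input"]] / nrow(trial$cells))
  mosaic <- if (abs(f1 - f0) / f0 > 0.02) build_mosaic(density_profile, f1, geom)
            else trial
  map_s <- geom$map
  map_s$k <- geom$map$k * sqrt(scale_factor)
  w_in <- map_deg_to_cortex(map_s, mosaic$cells$rf_ecc, mosaic$cells$phi)
  input_df <- data.frame(group = "input", u = w_in$u, v = w_in$v,
                         ecc = mosaic$cells$rf_ecc, phi = mosaic$cells$phi,
                         n_comp = 1L)
  set.seed(seed)
  sample_sheet <- function(n) {
    e_lo <- geom$ecc_range[1]; e_hi <- geom$ecc_range[2]
    u_rng <- map_s$k * log(1 + c(e_lo, e_hi) / map_s$a)
    out_u <- numeric(0); out_v <- numeric(0)
    while (length(out_u) < n) {
      m <- 2 * (n - length(out_u)) + 32
      u <- stats::runif(m, u_rng[1], u_rng[2])
      v <- stats::runif(m, -map_s$k * pi / 2, map_s$k * pi / 2)
      zp <- map_cortex_to_deg(map_s, u, v)
      ok <- zp$ecc >= e_lo & zp$ecc <= e_hi & abs(zp$phi) <= pi / 2
      out_u <- c(out_u, u[ok]); out_v <- c(out_v, v[ok])
    }
    cbind(out_u[seq_len(n)], out_v[seq_len(n)])
  }
  groups <- c("E_V1", "I_V1", "E_X", "I_X")
  cort <- do.call(rbind, lapply(groups, function(g) {
    uv <- sample_sheet(target[[g]])
    zp <- map_cortex_to_deg(map_s, uv[, 1], uv[, 2])
    data.frame(group = g, u = uv[, 1], v = uv[, 2],
               ecc = zp$ecc, phi = zp$phi,
               n_comp = if (g == "E_V1" && !pointwise) 6L else 1L)
  }))
  neurons <- rbind(input_df, cort)
  neurons$id <- seq_len(nrow(neurons))
  structure(list(neurons = neurons, map = map_s, mosaic = mosaic, geom = geom,
                 scale_factor = scale_factor, pointwise = pointwise,
                 counts = c(input = nrow(input_df),
                            table(factor(cort$group, levels = groups))),
                 reference_counts = refs, seed = seed),
            class = "neuron_population")
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("neuron population, scale %.4g (%s E_V1 cells):\n",
              x$scale_factor,
              if (x$pointwise) "pointwise" else "6-compartment"))
  print(x$counts)
  invisible(x)
}

# cortical neurons (all but the input layer), indexed 1..n_cortical
cortical_neurons <- function(pop) {
  pop$neurons[pop$neurons$group != "input", , drop = FALSE]
}

#' Connectivity specification
#'
#' One row per projection: decay profile and scale on the cortical sheet,
#' base connection probability `p0` (the "sparseness" parameter: probability
#' at zero distance when the family's beta is 1), synaptic weight, target
#' compartment (0 soma, 1..5 dendrite proximal to distal; feedback lands
#' distally, feedforward proximally, basket inhibition on the soma), and the
#' beta family that scales it (`lateral_EI` for V1 excitatory-inhibitory
#' loops, `ffb_X` for the V1-extrastriate feedforward/feedback loop,
#' `fixed` otherwise).  `p0 = NA` for EX -> I_V1 marks the tied projection:
#' its probability is set from EX -> E_V1 so that 10% of feedback synapses
#' target inhibitory neurons.
#'
#' Profiles and spatial constants follow the model architecture (Gaussian
#' sigma 0.23 mm for the geniculate feedforward kernel; exponential lambda
#' 1 mm for lateral V1, lambda 3.3 mm for the V1-extrastriate loop).  `p0`
#' and weights are calibration constants of this implementation, chosen so
#' the network sits in a fluctuation-driven regime with evoked V1 rates of
#' order 10-100 Hz at mid-grid beta.
#'
#' @return Data frame of class `connectivity_spec`.
#' @export
connectivity_spec <- function() {
  s <- rbind(
    data.frame(name = "LGN_EV1",  pre = "input", post = "E_V1", profile = "gaussian",
               scale_mm = 0.23, p0 = 0.9,  weight_nS = 4.5, inhibitory = FALSE,
               family = "fixed",      comp = 1L),
    data.frame(name = "EV1_EV1",  pre = "E_V1", post = "E_V1", profile = "exponential",
               scale_mm = 1.0,  p0 = 0.12, weight_nS = 0.25, inhibitory = FALSE,
               family = "fixed",      comp = 2L),
    data.frame(name = "EV1_IV1",  pre = "E_V1", post = "I_V1", profile = "exponential",
               scale_mm = 1.0,  p0 = 0.5,  weight_nS = 0.9, inhibitory = FALSE,
               family = "lateral_EI", comp = 0L),
    data.frame(name = "IV1_EV1",  pre = "I_V1", post = "E_V1", profile = "exponential",
               scale_mm = 1.0,  p0 = 0.5,  weight_nS = 3.0, inhibitory = TRUE,
               family = "lateral_EI", comp = 0L),
    data.frame(name = "EV1_EX",   pre = "E_V1", post = "E_X", profile = "exponential",
               scale_mm = 3.3,  p0 = 0.11, weight_nS = 2.0, inhibitory = FALSE,
               family = "ffb_X",      comp = 0L),
    data.frame(name = "EX_IX",    pre = "E_X",  post = "I_X", profile = "exponential",
               scale_mm = 3.3,  p0 = 0.10, weight_nS = 1.0, inhibitory = FALSE,
               family = "ffb_X",      comp = 0L),
    data.frame(name = "IX_EX",    pre = "I_X",  post = "E_X", profile = "exponential",
               scale_mm = 3.3,  p0 = 0.10, weight_nS = 3.0, inhibitory = TRUE,
               family = "ffb_X",      comp = 0L),
    data.frame(name = "EX_EV1",   pre = "E_X",  post = "E_V1", profile = "exponential",
               scale_mm = 3.3,  p0 = 0.10, weight_nS = 0.35, inhibitory = FALSE,
               family = "ffb_X",      comp = 5L),
    data.frame(name = "EX_IV1",   pre = "E_X",  post = "I_V1", profile = "exponential",
               scale_mm = 3.3,  p0 = NA,   weight_nS = 0.35, inhibitory = FALSE,
               family = "ffb_X",      comp = 0L))
  class(s) <- c("connectivity_spec", "data.frame")
  s
}

#' Beta ranges of the two scaled connection families
#'
#' @return List with the `lateral_EI` and `ffb_X` log-spaced sweep ranges.
#' @export
beta_ranges <- function() list(lateral_EI = c(0.1, 2.45), ffb_X = c(0.17, 4.20))

#' Log-spaced beta grid
#'
#' @param n Points per axis (25 for the full-scale sweep).
#' @return Data frame with columns `beta_lat`, `beta_ffb` (n^2 rows).
#' @export
beta_grid <- function(n = 25) {
  r <- beta_ranges()
  lat <- exp(seq(log(r$lateral_EI[1]), log(r$lateral_EI[2]), length.out = n))
  ffb <- exp(seq(log(r$ffb_X[1]), log(r$ffb_X[2]), length.out = n))
  expand.grid(beta_lat = lat, beta_ffb = ffb, KEEP.OUT.ATTRS = FALSE)
}

# resolve the tied EX -> I_V1 probability: 10% of feedback synapses target
# inhibitory neurons, so N_I * p0_EXI = (1/9) * N_E * p0_EXE
resolve_spec <- function(spec, pop) {
  i <- which(is.na(spec$p0))
  if (length(i)) {
    p0_exe <- spec$p0[spec$name == "EX_EV1"]
    nE <- pop$counts[["E_V1"]]; nI <- pop$counts[["I_V1"]]
    spec$p0[i] <- p0_exe * (nE / nI) / 9
  }
  spec
}

#' Precompute connection candidates
#'
#' For every projection, computes the distance-decayed connection probability
#' `q = p0 * decay(d)` for all candidate (pre, post) pairs on the cortical
#' sheet, dropping pairs with negligible probability.  The result is reused
#' across the whole beta sweep: sampling a network then only requires one
#' uniform draw per candidate.
#'
#' @param pop A [build_population()] object.
#' @param spec A [connectivity_spec()].
#' @param q_min Candidates with `q` below this are dropped (well below any
#'   beta-scaled probability of consequence).
#' @return Object of class `connection_candidates`.
#' @export
connection_candidates <- function(pop, spec = connectivity_spec(),
                                  q_min = 1e-4) {
  spec <- resolve_spec(spec, pop)
  nrn <- pop$neurons
  cort <- cortical_neurons(pop)
  cort_index <- seq_len(nrow(cort))   # 1..n_cortical in pop order
  projections <- lapply(seq_len(nrow(spec)), function(k) {
    pr <- spec[k, ]
    pre_rows <- which(nrn$group == pr$pre)
    post_rows <- which(cort$group == pr$post)
    is_input <- pr$pre == "input"
    pre_u <- nrn$u[pre_rows]; pre_v <- nrn$v[pre_rows]
    post_u <- cort$u[post_rows]; post_v <- cort$v[post_rows]
    d <- sqrt(outer(pre_u, post_u, "-")^2 + outer(pre_v, post_v, "-")^2)
    q <- if (pr$profile == "gaussian") pr$p0 * exp(-d^2 / (2 * pr$scale_mm^2))
         else pr$p0 * exp(-d / pr$scale_mm)
    if (pr$pre == pr$post)   # same cells in the same order: no self-connections
      q[cbind(seq_along(pre_rows), seq_along(post_rows))] <- 0
    keep <- which(q >= q_min)
    pre_idx <- if (is_input) match(pre_rows, which(nrn$group == "input"))
               else match(pre_rows, which(nrn$group != "input"))
    list(name = pr$name, family = pr$family, is_input = is_input,
         pre = pre_idx[(keep - 1L) %% length(pre_rows) + 1L],
         post = post_rows[(keep - 1L) %/% length(pre_rows) + 1L],
         q = q[keep], d = d[keep],
         weight = pr$weight_nS, inhibitory = pr$inhibitory, comp = pr$comp)
  })
  structure(list(projections = projections, spec = spec,
                 n_cortical = nrow(cort), n_input = pop$counts[["input"]],
                 cort_groups = cort$group),
            class = "connection_candidates")
}

#' Sample a synapse list
#'
#' Realises the stochastic connectivity: every candidate pair connects with
#' probability `beta * q` (clipped at 1, with the clip count reported), where
#' `beta` is the family's scale factor (1 for the fixed family).
#'
#' @param cand A [connection_candidates()] object.
#' @param beta_lat,beta_ffb Scale factors for the lateral E-I family and the
#'   V1-extrastriate feedforward/feedback family.
#' @param seed Integer seed; the draw is reproducible.
#' @return Object of class `synapse_list`: per-projection synapse tables and
#'   totals.
#' @export
sample_connections <- function(cand, beta_lat = 1, beta_ffb = 1, seed = 1L) {
  stopifnot(beta_lat >= 0, beta_ffb >= 0)
  set.seed(seed)
  n_clipped <- 0L
  syn <- lapply(cand$projections, function(pr) {
    beta <- switch(pr$family, fixed = 1, lateral_EI = beta_lat, ffb_X = beta_ffb)
    p <- beta * pr$q
    over <- p > 1
    if (any(over)) {
      n_clipped <<- n_clipped + sum(over)
      p[over] <- 1
    }
    keep <- stats::runif(length(p)) < p
    list(name = pr$name, is_input = pr$is_input,
         pre = pr$pre[keep], post = pr$post[keep],
         weight = pr$weight, inhibitory = pr$inhibitory, comp = pr$comp)
  })
  if (n_clipped > 0)
    warning(sprintf("%d candidate probabilities clipped at 1", n_clipped))
  structure(list(synapses = syn, n_cortical = cand$n_cortical,
                 n_input = cand$n_input, beta_lat = beta_lat,
                 beta_ffb = beta_ffb, seed = seed, n_clipped = n_clipped),
            class = "synapse_list")
}

#' @export
print.synapse_list <- function(x, ...) {
  n <- vapply(x$synapses, function(s) length(s$pre), numeric(1))
  cat(sprintf("synapse list (beta_lat %.3g, beta_ffb %.3g):\n",
              x$beta_lat, x$beta_ffb))
  print(stats::setNames(n, vapply(x$synapses, `[[`, "", "name")))
  invisible(x)
}

#' Simulation protocol and neuron parameters
#'
#' Defaults: 500 ms runs (200 ms baseline then 300 ms of stationary image
#' input), 0.1 ms forward-Euler timestep, spike counts over 200-500 ms.
#' EIF and synaptic constants are standard cortical values (they are not
#' constrained by the analyses here beyond producing a fluctuation-driven
#' regime): 200 pF / 10 nS leak (20 ms membrane), spike slope 2 mV,
#' threshold -50 mV, reset -60 mV, 2 ms refractoriness; AMPA-like 5 ms / 0 mV
#' and GABA-A-like 10 ms / -75 mV conductances; passive dendritic chain with
#' 20 nS axial coupling.
#'
#' @param ... Overrides for any listed parameter.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(dt_ms = 0.1, t_total_ms = 500, t_stim_on_ms = 200,
              t_record_from_ms = 200,
              C_pF = 200, gL_nS = 10, EL_mV = -70, DeltaT_mV = 2,
              VT_mV = -50, Vreset_mV = -60, Vpeak_mV = -30, t_ref_ms = 2,
              tau_e_ms = 5, tau_i_ms = 10, Ee_mV = 0, Ei_mV = -75,
              g_ax_nS = 20, C_d_pF = 100, gL_d_nS = 5, I_const_pA = 0,
              input_gain_hz = 250, input_midpoint_rel = 0.15)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

# synapse tables -> CSR arrays (0-based) for the C++ core
syn_to_csr <- function(syn_list, n_pre, input = TRUE) {
  sel <- Filter(function(s) s$is_input == input, syn_list$synapses)
  pre <- unlist(lapply(sel, `[[`, "pre"), use.names = FALSE)
  post <- unlist(lapply(sel, `[[`, "post"), use.names = FALSE)
  w <- unlist(lapply(sel, function(s) rep(s$weight, length(s$pre))), use.names = FALSE)
  inh <- unlist(lapply(sel, function(s) rep(s$inhibitory, length(s$pre))), use.names = FALSE)
  comp <- unlist(lapply(sel, function(s) rep(s$comp, length(s$pre))), use.names = FALSE)
  o <- order(pre)
  ptr <- c(0L, cumsum(tabulate(pre, nbins = n_pre)))
  list(ptr = as.integer(ptr), post = as.integer(post[o] - 1L),
       w = as.numeric(w[o]), inh = as.integer(inh[o]),
       comp = as.integer(comp[o]))
}

#' Run one network simulation
#'
#' Integrates the EIF network for the full protocol and returns per-neuron
#' spike counts over the analysis window.  Input-layer neurons fire as
#' inhomogeneous Poisson sources: `baseline_rates_hz` before stimulus onset
#' and `stim_rates_hz` afterwards.
#'
#' @param pop A [build_population()] object.
#' @param syn A [sample_connections()] synapse list.
#' @param stim_rates_hz Stimulus-period rate (Hz) per input neuron (e.g.
#'   `map_to_cortex(...)$rate_hz`).
#' @param config A [sim_config()].
#' @param seed Integer seed (Poisson input and nothing else is stochastic
#'   here); identical seeds give bit-identical spike counts.
#' @param baseline_rates_hz Baseline-period rates; default is the gray-field
#'   response, `input_gain_hz * input_midpoint_rel`.
#' @return Object of class `spike_response`: data frame `neurons` (id, group,
#'   count) plus input-drive totals.
#' @export
simulate_network <- function(pop, syn, stim_rates_hz, config = sim_config(),
                             seed = 1L, baseline_rates_hz = NULL) {
  n_input <- pop$counts[["input"]]
  stopifnot(length(stim_rates_hz) == n_input, all(stim_rates_hz >= 0))
  if (is.null(baseline_rates_hz))
    baseline_rates_hz <- rep(config$input_gain_hz * config$input_midpoint_rel,
                             n_input)
  cort <- cortical_neurons(pop)
  csr_in <- syn_to_csr(syn, n_input, input = TRUE)
  csr_c <- syn_to_csr(syn, nrow(cort), input = FALSE)
  set.seed(seed)
  res <- eif_simulate_cpp(nrow(cort), as.integer(cort$n_comp),
                          csr_in$ptr, csr_in$post, csr_in$w, csr_in$comp,
                          csr_c$ptr, csr_c$post, csr_c$w, csr_c$inh,
                          csr_c$comp,
                          as.numeric(baseline_rates_hz),
                          as.numeric(stim_rates_hz),
                          unclass(config))
  structure(list(neurons = data.frame(id = seq_len(nrow(cort)),
                                      group = cort$group,
                                      count = res$counts),
                 input_spikes_recorded = res$input_spikes_recorded,
                 input_spikes_total = res$input_spikes_total,
                 beta_lat = syn$beta_lat, beta_ffb = syn$beta_ffb,
                 seed = seed),
            class = "spike_response")
}

#' @export
print.spike_response <- function(x, ...) {
  agg <- tapply(x$neurons$count, x$neurons$group, mean)
  cat("mean spike counts over the analysis window by group:\n")
  print(round(agg, 2))
  invisible(x)
}

# mean evoked rate (Hz) of one group over the analysis window
group_rate_hz <- function(resp, config, group = "E_V1") {
  win_s <- (config$t_total_ms - config$t_record_from_ms) / 1000
  mean(resp$neurons$count[resp$neurons$group == group]) / win_s
}

#' Area summation probe of the network
#'
#' Presents circular grating patches of increasing diameter centred on a
#' probe field location, runs the full retina + network pipeline for each
#' diameter on a fixed sampled network, and reports the spike count averaged
#' over the `n_neighbors` V1 excitatory cells whose receptive fields lie
#' closest to the probe center.
#'
#' @param pop,syn Population and sampled synapse list.
#' @param diameters Patch diameters in degrees (0 = blank background).
#' @param config A [sim_config()].
#' @param seed Base seed; run `i` uses `seed + i`.
#' @param center Probe center `c(x, y)` in degrees (default on the
#'   horizontal meridian at 14 degrees eccentricity).
#' @param sf_cpd,phase_deg,contrast Grating spatial frequency
#'   (cycles/degree), carrier phase at the center, and Michelson contrast.
#'   The default probe grating is low-frequency and peak-centered: at the
#'   scaled geometry the feedforward pooling footprint spans several degrees,
#'   so the cell-optimal grating is correspondingly coarse.
#' @param n_neighbors Cells averaged around the probe center.
#' @return Data frame `diameter`, `mean_count`.
#' @export
area_summation_probe <- function(pop, syn,
                                 diameters = c(0, 2, 4, 7, 10, 14, 18, 24),
                                 config = sim_config(), seed = 1L,
                                 center = c(-14, 0), sf_cpd = 0.5,
                                 phase_deg = 90, contrast = 0.9,
                                 n_neighbors = 15) {
  cort <- cortical_neurons(pop)
  ev1 <- which(cort$group == "E_V1")
  rf_x <- -cort$ecc[ev1] * cos(cort$phi[ev1])
  rf_y <- cort$ecc[ev1] * sin(cort$phi[ev1])
  d2 <- (rf_x - center[1])^2 + (rf_y - center[2])^2
  probe_cells <- ev1[order(d2)[seq_len(n_neighbors)]]
  vapply(seq_along(diameters), function(i) {
    img <- generate_grating_patch(grating_patch_spec(
      diameter = diameters[i], sf_cpd = sf_cpd, contrast = contrast,
      phase_deg = phase_deg, center = center), geom = pop$geom)
    drive <- image_drive(pop, img, config)
    resp <- simulate_network(pop, syn, drive, config, seed = seed + i)
    mean(resp$neurons$count[probe_cells])
  }, numeric(1)) -> mc
  data.frame(diameter = diameters, mean_count = mc)
}
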