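# Spiking network: population geometry, the stochastic connectivity sampler
# against its analytic law, EIF integration against an independent
# fine-timestep reference, determinism, and protocol behavior.

test_that("population reports reference counts and scaled groups preserve ratios", {
  refs <- reference_counts()
  expect_equal(unname(refs[c("input", "E_V1", "I_V1", "E_X", "I_X")]),
               c(226206, 42849, 10713, 10713, 10713))
  expect_equal(refs[["low_res_input"]], 9014)
  pop <- fx_pop()
  expect_identical(unname(pop$reference_counts["E_V1"]), 42849)
  for (g in c("input", "E_V1", "I_V1", "E_X", "I_X")) {
    got <- pop$counts[[g]]
    expect_lt(abs(got / (0.0129 * refs[[g]]) - 1), 0.1)
  }
  # every E_V1 receptive field lies inside the modeled sector
  cort <- asfnet:::cortical_neurons(pop)
  ev1 <- cort[cort$group == "E_V1", ]
  expect_true(all(ev1$ecc >= 0.5 & ev1$ecc <= 27 & abs(ev1$phi) <= pi / 2))
})

test_that("empirical connection probability follows the analytic decay laws", {
  cand <- fx_cand()
  syn <- suppressWarnings(sample_connections(cand, beta_lat = 1, beta_ffb = 1,
                                             seed = 41))
  for (k in seq_along(cand$projections)) {
    pr <- cand$projections[[k]]
    if (length(pr$q) < 1e5) next
    realized <- logical(length(pr$q))
    sy <- syn$synapses[[k]]
    realized[match(paste(sy$pre, sy$post), paste(pr$pre, pr$post))] <- TRUE
    bins <- cut(pr$d, breaks = 10)
    emp <- tapply(realized, bins, mean)
    expected <- tapply(pmin(1, pr$q), bins, mean)
    n <- tapply(pr$q, bins, length)
    z <- (emp - expected) / sqrt(pmax(expected * (1 - expected), 1e-12) / n)
    expect_true(all(abs(z[n > 50]) < 3.5),
                info = paste("projection", pr$name))
  }
})

test_that("beta = 0 silences a family and doubling beta doubles expected counts", {
  cand <- fx_cand()
  syn0 <- sample_connections(cand, beta_lat = 0, beta_ffb = 1, seed = 2)
  lat_names <- c("EV1_IV1", "IV1_EV1")
  for (s in syn0$synapses)
    if (s$name %in% lat_names) expect_length(s$pre, 0)
  count_lat <- function(syn) sum(vapply(syn$synapses, function(s)
    if (s$name %in% lat_names) length(s$pre) else 0L, numeric(1)))
  n1 <- mean(vapply(1:2, function(i)
    count_lat(sample_connections(cand, 0.25, 1, seed = i)), numeric(1)))
  n2 <- mean(vapply(3:4, function(i)
    count_lat(sample_connections(cand, 0.5, 1, seed = i)), numeric(1)))
  expect_lt(abs(n2 / n1 - 2), 0.05 * 2)
})

test_that("sampling is reproducible and simulation is bit-identical under a fixed seed", {
  cand <- fx_cand()
  s1 <- sample_connections(cand, 0.7, 1, seed = 9)
  s2 <- sample_connections(cand, 0.7, 1, seed = 9)
  expect_identical(s1$synapses, s2$synapses)
  pop <- fx_pop()
  drv <- rep(40, pop$counts[["input"]])
  r1 <- simulate_network(pop, s1, drv, seed = 5)
  r2 <- simulate_network(pop, s1, drv, seed = 5)
  expect_identical(r1$neurons$count, r2$neurons$count)
  expect_identical(r1$input_spikes_total, r2$input_spikes_total)
})

test_that("zero input drive leaves the cortex silent", {
  pop <- fx_pop()
  syn <- sample_connections(fx_cand(), 1, 1, seed = 3)
  resp <- simulate_network(pop, syn, rep(0, pop$counts[["input"]]),
                           baseline_rates_hz = rep(0, pop$counts[["input"]]),
                           seed = 4)
  expect_true(all(resp$neurons$count == 0))
})

test_that("a single EIF neuron matches an independent fine-timestep reference within 2%", {
  cfg <- sim_config(I_const_pA = 450, t_total_ms = 2000, t_stim_on_ms = 0,
                    t_record_from_ms = 200)
  empty_ptr <- integer(1)
  res <- asfnet:::eif_simulate_cpp(1L, 1L,
                                   integer(1), integer(0), numeric(0), integer(0),
                                   c(0L, 0L), integer(0), numeric(0),
                                   integer(0), integer(0),
                                   numeric(0), numeric(0), unclass(cfg))
  rate_cpp <- res$counts[1] / 1.8
  # independent reference: plain R Euler integration at a 100x finer step
  ref_rate <- local({
    dt <- 0.001; v <- cfg$EL_mV; t_ref_until <- -1; spikes <- 0; t <- 0
    while (t < 2000) {
      if (t >= t_ref_until) {
        dv <- (-cfg$gL_nS * (v - cfg$EL_mV) +
               cfg$gL_nS * cfg$DeltaT_mV * exp(min((v - cfg$VT_mV) / cfg$DeltaT_mV, 20)) +
               cfg$I_const_pA) / cfg$C_pF
        v <- v + dt * dv
        if (v >= cfg$Vpeak_mV) {
          v <- cfg$Vreset_mV
          t_ref_until <- t + cfg$t_ref_ms
          if (t >= 200) spikes <- spikes + 1
        }
      } else v <- cfg$Vreset_mV
      t <- t + dt
    }
    spikes / 1.8
  })
  expect_gt(ref_rate, 5)
  expect_lt(abs(rate_cpp / ref_rate - 1), 0.02)
})

test_that("input-rate scaling does not decrease V1 output below saturation", {
  pop <- fx_pop()
  syn <- sample_connections(fx_cand(), 0.7, 1, seed = 6)
  drv <- image_drive(pop, fx_image_low())
  lo <- simulate_network(pop, syn, drv * 0.8, seed = 11)
  hi <- simulate_network(pop, syn, drv * 1.2, seed = 11)
  total <- function(r) sum(r$neurons$count[r$neurons$group == "E_V1"])
  expect_gte(total(hi), total(lo))
})

test_that("pointwise-control populations spike differently from compartmental ones", {
  geom <- fx_geom()
  pop_c <- fx_pop()
  pop_p <- build_population(0.0129, seed = 7, geom = geom, pointwise = TRUE)
  expect_true(all(asfnet:::cortical_neurons(pop_p)$n_comp == 1L))
  cand_p <- connection_candidates(pop_p)
  drv <- image_drive(pop_c, fx_image_low())
  syn_c <- sample_connections(fx_cand(), 0.7, 1, seed = 8)
  syn_p <- sample_connections(cand_p, 0.7, 1, seed = 8)
  r_c <- simulate_network(pop_c, syn_c, drv, seed = 9)
  r_p <- simulate_network(pop_p, syn_p, drv, seed = 9)
  expect_false(identical(r_c$neurons$count, r_p$neurons$count))
})

test_that("probability clipping warns with a count", {
  cand <- fx_cand()
  expect_warning(sample_connections(cand, 2.45, 4.2, seed = 10), "clipped")
})
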