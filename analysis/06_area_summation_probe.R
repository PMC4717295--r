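#!/usr/bin/env Rscript
# Probe the network's emergent area summation: grating patches of growing
# diameter centred at 14 degrees eccentricity, response averaged over the 15
# nearest V1 excitatory cells, at a strongly laterally-inhibited and an
# almost lateral-free parameter point.
#
# Writes: results/probe_curves.csv

library(asfnet)

seed <- 1L
bundle <- suppressWarnings(fixture_bundle(seed = seed))
pop <- build_population(bundle$scale_factor, seed = seed + 100L,
                        geom = bundle$geom)
cand <- connection_candidates(pop, bundle$connectivity)

curves <- list()
for (beta_lat in c(2.45, 0.1)) {
  per_seed <- lapply(c(seed + 301L, seed + 302L), function(s) {
    syn <- suppressWarnings(sample_connections(cand, beta_lat, 1, seed = s))
    area_summation_probe(pop, syn, config = bundle$config, seed = s)
  })
  cv <- per_seed[[1]]
  cv$mean_count <- rowMeans(vapply(per_seed, `[[`, numeric(8), "mean_count"))
  cv$beta_lat <- beta_lat
  si <- 1 - cv$mean_count[nrow(cv)] / max(cv$mean_count)
  message(sprintf("beta_lat %.2f: counts %s | suppression index %.2f",
                  beta_lat, paste(sprintf("%.1f", cv$mean_count),
                                  collapse = " "), si))
  curves[[as.character(beta_lat)]] <- cv
}
write.csv(do.call(rbind, curves), "results/probe_curves.csv",
          row.names = FALSE)
message("wrote results/probe_curves.csv")
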