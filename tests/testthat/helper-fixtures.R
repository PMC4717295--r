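# Shared fixtures, built once per test session and memoized.  Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fx_geom <- function() fixture("geom", function() field_geometry(px_per_deg = 8.2))

fx_pop <- function() fixture("pop", function()
  build_population(0.0129, seed = 7, geom = fx_geom()))

fx_cand <- function() fixture("cand", function()
  connection_candidates(fx_pop()))

fx_bank <- function() fixture("bank", function()
  build_gabor_bank(gabor_bank_config(pixels_per_5deg = 41)))

fx_ring_params <- function() fixture("ring_params", function()
  suppressWarnings(fit_ring_params()))

fx_params14 <- function() fixture("params14", function()
  fit_asf_params(characteristics_at_eccentricity(asf_regression(), 14)))

# a small image that most contrast-energy unit tests can share
fx_image_low <- function() fixture("image_low", function()
  generate_surrogate(surrogate_image_spec(1.4), seed = 424, geom = fx_geom()))

# reference (brute-force) implementations used as independent oracles
ref_das <- function(s, t) {
  total <- 0
  for (i in seq_along(s)) total <- total + abs(s[i] - t[i])
  total
}

ref_entropy <- function(counts, n_bins = 256) {
  rel <- counts / max(counts)
  e <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins; hi <- b / n_bins
    q <- sum(if (b == 1) rel >= 0 & rel <= hi else rel > lo & rel <= hi) /
      length(rel)
    if (q > 0) e <- e - q * log2(q)
  }
  e
}

ref_sparseness <- function(y) {
  n <- length(y)
  num <- (sum(y) / n)^2
  den <- sum(y^2) / n
  (1 - num / den) / (1 - 1 / n)
}

ref_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exact two-sided rank-sum p-value by enumerating all group-A assignments
ref_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combs <- utils::combn(length(pooled), length(a))
  w_all <- apply(combs, 2, function(ix) sum(r[ix])) -
    length(a) * (length(a) + 1) / 2
  mu <- length(a) * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
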