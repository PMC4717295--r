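# Sweep bookkeeping and statistics: manifest construction, correlation
# summaries, frequency-group clustering, extreme exclusion, and the
# rank-sum / Friedman wrappers.

test_that("manifest is the full cross product with deterministic seeds", {
  g <- expand.grid(beta_lat = c(0.1, 0.5, 2), beta_ffb = c(0.2, 1, 4))
  man <- build_manifest(c("a", "b"), g, master_seed = 3)
  expect_equal(nrow(man), 18)
  expect_equal(sort(unique(as.character(man$image_id))), c("a", "b"))
  man2 <- build_manifest(c("a", "b"), g, master_seed = 3)
  expect_identical(man, man2)
  man3 <- build_manifest(c("a", "b"), g, master_seed = 4)
  expect_false(identical(man$seed, man3$seed))
  expect_true(all(man$seed >= 0 & man$seed < 2^31))
})

test_that("full-scale manifest cardinality is image count times grid size", {
  man <- build_manifest(sprintf("img%02d", 1:20), beta_grid(25), 1)
  expect_equal(nrow(man), 12500)
  expect_equal(nrow(beta_grid(25)), 625)
  r <- beta_ranges()
  expect_equal(range(beta_grid(25)$beta_lat), r$lateral_EI)
  expect_equal(range(beta_grid(25)$beta_ffb), r$ffb_X)
  # log spacing: constant ratio between consecutive grid values
  lat <- sort(unique(beta_grid(25)$beta_lat))
  expect_equal(sd(diff(log(lat))), 0, tolerance = 1e-12)
})

test_that("correlate_metrics recovers exact and brute-force correlations", {
  df <- data.frame(image_id = rep("x", 20), das = seq(1, 20),
                   total_spikes = seq(1, 20) * 2 + 3,
                   entropy_per_spike = -seq(1, 20) + 100,
                   sparseness = NA_real_)
  set.seed(17)
  df$sparseness <- runif(20)
  cc <- correlate_metrics(df)
  expect_equal(cc$pooled$r[cc$pooled$metric == "total_spikes"], 1)
  expect_equal(cc$pooled$r[cc$pooled$metric == "entropy_per_spike"], -1)
  expect_equal(cc$pooled$r[cc$pooled$metric == "sparseness"],
               ref_pearson(df$das, df$sparseness), tolerance = 1e-12)
})

test_that("well-separated signatures cluster perfectly with deterministic labels", {
  set.seed(2)
  lows <- t(replicate(8, {
    s <- c(10, 5, 1, 0.3, 0.1) + runif(5, 0, 0.2); s / sum(s)
  }))
  mixes <- t(replicate(8, {
    s <- c(3, 3, 3, 3, 3) + runif(5, 0, 0.2); s / sum(s)
  }))
  gr <- split_frequency_groups(rbind(lows, mixes), seed = 5)
  expect_equal(as.character(gr), rep(c("low", "mixed"), each = 8))
  gr2 <- split_frequency_groups(rbind(lows, mixes), seed = 5)
  expect_identical(as.character(gr), as.character(gr2))
  dg <- split_frequency_groups(matrix(0.2, 6, 5), seed = 5)
  expect_true(attr(dg, "degenerate"))
})

test_that("range-based extreme exclusion keeps the interior of the dynamic range", {
  totals <- seq(0, 100, by = 1)
  keep <- exclude_extremes(totals, 0.15)
  expect_equal(range(totals[keep]), c(15, 85))
  expect_true(all(exclude_extremes(totals, 0)))
  k5 <- exclude_extremes(totals, 0.5)
  expect_equal(totals[k5], 50)
})

test_that("rank-sum comparison matches exact enumeration on small samples", {
  same <- compare_groups(c(0.1, 0.2, 0.3), c(0.3, 0.1, 0.2))
  expect_equal(same$p.value, 1)
  sep <- compare_groups(1:10 / 100, 5 + 1:10 / 100)
  expect_equal(sep$p.value, 2 * prod(1:10) * prod(1:10) / prod(1:20),
               tolerance = 1e-12)
  set.seed(55)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5, 0.5)
    expect_equal(compare_groups(a, b)$p.value, ref_wilcox_p(a, b),
                 tolerance = 1e-10)
  }
})

test_that("input drive check reproduces a hand-ranked Friedman statistic", {
  expect_error(input_drive_check(data.frame(a = 1:3)), "matrix")
  m <- matrix(c(1, 2, 3,
                2, 3, 1,
                1, 3, 2,
                3, 2, 1), nrow = 4, byrow = TRUE)
  out <- input_drive_check(m)
  # hand ranking: row ranks as given; column rank sums 7, 10, 7
  # chi2 = 12/(n k (k+1)) * sum Rj^2 - 3 n (k+1) = (12/(4*3*4))*198 - 48 = 1.5
  expect_equal(unname(out$statistic), 1.5)
  ident <- matrix(rep(c(1, 1, 1), 4), nrow = 4, byrow = TRUE)
  # identical columns: every block is a full tie, statistic 0
  out0 <- input_drive_check(ident)
  expect_equal(unname(out0$statistic), 0)
  expect_equal(out0$p.value, 1)
})
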