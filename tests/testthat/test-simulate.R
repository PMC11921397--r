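test_that("Gaussian banding mass fractions behave at anchors", {
  sch <- density_group_scheme()
  # proportions sum to one for random band positions
  set.seed(17)
  for (i in 1:50) {
    p <- group_mass_fractions(runif(1, 1.66, 1.79), runif(1, 0.002, 0.02), sch)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  # tiny SD concentrates the band in its bin
  expect_gt(group_mass_fractions(1.72, 1e-5, sch)[["medium"]], 1 - 1e-12)
  # a band at a shared boundary splits evenly
  p <- group_mass_fractions(1.69, 0.004, sch)
  expect_equal(p[["light"]], p[["medium"]], tolerance = 1e-6)
  expect_error(group_mass_fractions(1.7, 0), class = "qsip_config_error")
})

test_that("simulations are reproducible and carry coherent truth", {
  cfg <- simulation_config(n_taxa = 25, depth = 2000)
  s1 <- simulate_qsip_experiment(cfg, seed = 14)
  s2 <- simulate_qsip_experiment(cfg, seed = 14)
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$qpcr, s2$qpcr)
  expect_identical(s1$truth, s2$truth)
  tr <- s1$truth
  # truth invariants: W_LIGHT inverts the GC relation; labeled WAD follows
  # the forward model; activity flags excess
  expect_equal(gc_from_wad(tr$w_light), tr$gc, tolerance = 1e-12)
  expect_equal(tr$w_lab, forward_density_shift(tr$w_light, 0.01111233 + tr$excess),
               tolerance = 1e-12)
  expect_identical(tr$active, tr$excess > 0)
  expect_equal(sum(tr$rel_abundance), 1)
})

test_that("point banding puts all unlabeled mass in the home density group", {
  cfg <- simulation_config(n_taxa = 8, active_fraction = 0, banding_sd = 1e-5,
                           sequencing = "exact", qpcr_cv = 0, dropout_prob = 0,
                           depth = 1000)
  sim <- simulate_qsip_experiment(cfg, seed = 15)
  sch <- density_group_scheme()
  home <- as.character(assign_density_group(sim$truth$w_light, sch))
  m <- sim$metadata
  for (t in seq_len(8)) {
    y <- sim$counts$values[t, ]
    grp <- m$density_group[match(names(y), m$sample_id)]
    expect_equal(sum(y[grp != home[t]]), 0, tolerance = 1e-9)
  }
})

test_that("fully labeled DNA bands where the forward model predicts", {
  # a taxon at W_LIGHT = 1.70 labeled at 99 atom % centers near 1.7525
  w_lab <- forward_density_shift(1.70, 0.99)
  p <- group_mass_fractions(w_lab, 0.005)
  expect_gt(p[["heavy"]], 0.5)
  cfg <- simulation_config(n_taxa = 5, ape_range = c(0.97889, 0.97889),
                           active_fraction = 1)
  sim <- simulate_qsip_experiment(cfg, seed = 16)
  expect_equal(sim$truth$w_lab, forward_density_shift(sim$truth$w_light, 0.99),
               tolerance = 1e-6)
})

test_that("dropout removes density-group samples but never a whole core", {
  cfg <- simulation_config(n_taxa = 10, depth = 500, dropout_prob = 0.6)
  sim <- simulate_qsip_experiment(cfg, seed = 18)
  m <- sim$metadata
  per_core <- table(m$core_id)
  expect_true(all(per_core >= 1))
  expect_lt(nrow(m), 6 * 3)  # at this rate some samples must be gone
})

test_that("zero-noise simulation recovers true APE through the whole pipeline", {
  cfg <- simulation_config(n_taxa = 40, ape_range = c(0.01, 0.5),
                           resolution = "fractions", n_fractions = 120,
                           density_range = c(1.60, 1.85),
                           sequencing = "exact", qpcr_cv = 0, dropout_prob = 0)
  sim <- simulate_qsip_experiment(cfg, seed = 19)
  nt <- qseq_normalize(to_relative_abundance(sim$counts), sim$qpcr)
  fit <- qsip(nt$table, sim$metadata, n_draws = 20, seed = 20)
  res <- fit$results
  tr <- sim$truth[match(res$taxon_id, sim$truth$taxon_id), ]
  expect_equal(nrow(res), 40)
  expect_lt(max(abs(res$ape_mean / 100 - tr$excess)), 1e-6)
  # identical replicates: intervals are degenerate and every enriched
  # taxon is called; truly-zero taxa sit at APE 0 up to cancellation
  # error, where the strict > 0 rule is a sign lottery by design
  expect_equal(max(res$ape_ci_high - res$ape_ci_low), 0)
  expect_true(all(res$active[tr$excess > 0]))
  expect_lt(max(abs(res$ape_mean[tr$excess == 0])), 1e-10)
})

test_that("invalid simulation configurations fail early", {
  expect_error(simulation_config(banding_sd = 0), class = "qsip_config_error")
  expect_error(simulation_config(dropout_prob = 1.2), class = "qsip_config_error")
  expect_error(simulation_config(density_range = c(1.8, 1.6)),
               class = "qsip_config_error")
  expect_error(simulation_config(ape_range = c(0.2, 0.1)),
               class = "qsip_config_error")
})
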