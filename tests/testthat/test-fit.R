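test_that("qsip recovers exact enrichment on a hand-built experiment", {
  hx <- hand_experiment()
  fit <- qsip(hx$table, hx$metadata, n_draws = 200, seed = 1)
  res <- fit$results
  expect_equal(nrow(res), 2)
  t1 <- res[res$taxon_id == "t1", ]
  t2 <- res[res$taxon_id == "t2", ]
  # degenerate replicates: point estimates are exact
  expect_equal(t1$w_light, 1.70)
  expect_equal(t1$w_lab, 1.75)
  expect_equal(t1$z, 0.05)
  expect_equal(t1$gc, gc_from_wad(1.70))
  ape_oracle <- 100 * (atom_fraction_from_shift(1.70, 1.75) - 0.01111233)
  expect_equal(t1$ape_mean, ape_oracle, tolerance = 1e-10)
  expect_equal(t1$ape_ci_low, ape_oracle, tolerance = 1e-10)
  expect_true(t1$active)
  expect_identical(t1$call_route, "ci_rule")
  # unshifted taxon: zero excess, not active
  expect_equal(t2$z, 0)
  expect_equal(t2$ape_mean, 0, tolerance = 1e-12)
  expect_false(t2$active)
  expect_identical(t2$call_route, "not_active")
  expect_equal(unique(res$n_draws), 200)
})

test_that("fits are reproducible under a fixed seed", {
  cfg <- simulation_config(n_taxa = 30, depth = 5000, dropout_prob = 0)
  sim <- simulate_qsip_experiment(cfg, seed = 21)
  nt <- qseq_normalize(to_relative_abundance(sim$counts), sim$qpcr)
  f1 <- qsip(nt$table, sim$metadata, n_draws = 300, seed = 5)
  f2 <- qsip(nt$table, sim$metadata, n_draws = 300, seed = 5)
  expect_identical(f1$results, f2$results)
})

test_that("taxa absent from unlabeled cores go through the label-only route", {
  hx <- hand_experiment()
  v <- hx$table$values
  v["t2", grep("^12C", colnames(v))] <- 0           # t2 only in labeled cores
  t3 <- ifelse(grepl("^13C.*heavy", colnames(v)), 2, 0)
  v <- rbind(v, t3 = t3)                            # heavy label-only taxon
  tab <- feature_table(v, "copies_per_ng_dna")
  fit <- qsip(tab, hx$metadata, n_draws = 200, seed = 2)
  res <- fit$results
  t2 <- res[res$taxon_id == "t2", ]
  t3r <- res[res$taxon_id == "t3", ]
  expect_equal(t2$n_unlabeled, 0L)
  expect_true(is.na(t2$ape_mean) && is.na(t2$w_light))
  # treatment community WAD: (10*1.75 + 8*1.70 + 2*1.75) / 20 = 1.73
  expect_equal(fit$treatment_wad$wad_mean, 1.73)
  # t2 bands at 1.70 < 1.73: not active; t3 at 1.75 > 1.73: active
  expect_false(t2$active)
  expect_identical(t2$call_route, "not_active")
  expect_true(t3r$active)
  expect_identical(t3r$call_route, "label_only_rule")
})

test_that("missing density groups are tolerated and bias is visible", {
  hx <- hand_experiment()
  v <- hx$table$values
  # t2 bands across light+medium in unlabeled cores: WAD (1.67+1.70)/2
  v["t2", grep("^12C.*(light|medium)", colnames(v))] <- 8
  v["t2", grep("^12C.*heavy", colnames(v))] <- 0
  drop <- "12C_c2_light"
  keep <- setdiff(colnames(v), drop)
  tab <- feature_table(v[, keep], "copies_per_ng_dna")
  meta <- hx$metadata[hx$metadata$sample_id %in% keep, ]
  fit <- qsip(tab, meta, n_draws = 1000, seed = 3)
  t2 <- fit$results[fit$results$taxon_id == "t2", ]
  # core c1 WAD 1.685; core c2 lost its light group -> WAD 1.70 (biased up)
  expect_equal(t2$w_light, mean(c(1.685, 1.70)), tolerance = 1e-3)
  expect_gt(t2$w_light, 1.685)
  cores <- fit$cores
  c2 <- cores[cores$core_id == "12C_c2", ]
  expect_false(grepl("light", c2$groups_used))
  expect_equal(c2$n_samples, 2L)
})

test_that("fit accessors and methods behave", {
  hx <- hand_experiment()
  fit <- qsip(hx$table, hx$metadata, n_draws = 100, seed = 4)
  expect_output(print(fit), "qSIP enrichment fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.qsip_fit")
  expect_equal(s$n_taxa, 2)
  expect_equal(s$n_active, 1)
  cf <- coef(fit)
  expect_named(cf, c("t1", "t2"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(2, 2))
  expect_true(all(ci["t1", 1] <= cf["t1"], cf["t1"] <= ci["t1", 2]))
  expect_error(confint(fit, level = 0.9), class = "qsip_config_error")
  expect_s3_class(as.data.frame(fit), "data.frame")
  expect_equal(active_taxa(fit, "restored / anoxic"), "t1")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("fraction-resolved gradients detect weak enrichment that pooled groups miss", {
  base <- list(n_taxa = 120, depth = 20000, dropout_prob = 0)
  sens <- sapply(c("fractions", "groups"), function(rmode) {
    cfg <- do.call(simulation_config, c(base, list(resolution = rmode)))
    sim <- simulate_qsip_experiment(cfg, seed = 31)
    fit <- suppressWarnings(fit_simulation(sim, n_draws = 500, seed = 32))
    called <- calls_vs_truth(fit, sim$truth)
    mean(called[sim$truth$ape_percent >= 3])
  })
  # pooling 12 fractions into 3 groups quantizes WADs to the group mean
  # densities: shifts much smaller than a group width become undetectable
  expect_gt(sens[["fractions"]], sens[["groups"]])
  expect_gt(sens[["fractions"]], 0.8)
})

test_that("metadata problems are reported by name", {
  hx <- hand_experiment()
  expect_error(qsip(hx$table, hx$metadata[, setdiff(names(hx$metadata), "isotope")]),
               "isotope", class = "qsip_data_error")
  expect_error(qsip(hx$table, hx$metadata[-1, ]), class = "qsip_data_error")
})
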