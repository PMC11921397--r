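# Small programmatic fixtures shared across test files.

# taxa x samples count matrix with ids
count_matrix <- function(values, n_taxa, n_samples,
                         taxa = sprintf("t%02d", seq_len(n_taxa)),
                         samples = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, n_taxa, n_samples, dimnames = list(taxa, samples))
}

# A hand-built two-taxon experiment with degenerate replicates: every core
# of an isotope is identical, so bootstrap intervals collapse and the fit
# is exactly hand-checkable. Taxon t1 shifts from WAD 1.70 (12C) to 1.75
# (13C); taxon t2 stays at 1.70.
hand_experiment <- function(n_cores = 2) {
  densities <- c(light = 1.67, medium = 1.70, heavy = 1.75)
  # abundance profiles per isotope: taxa x group
  prof <- list(
    `12C` = rbind(t1 = c(0, 10, 0), t2 = c(0, 8, 0)),     # both at 1.70
    `13C` = rbind(t1 = c(0, 0, 10), t2 = c(0, 8, 0)))     # t1 at 1.75
  cols <- list(); meta <- list(); qpcr <- list()
  for (iso in c("12C", "13C")) {
    for (k in seq_len(n_cores)) {
      for (g in names(densities)) {
        sid <- sprintf("%s_c%d_%s", iso, k, g)
        cols[[sid]] <- prof[[iso]][, match(g, names(densities))]
        meta[[sid]] <- data.frame(
          sample_id = sid, core_id = sprintf("%s_c%d", iso, k),
          wetland = "restored", redox = "anoxic", isotope = iso,
          density = unname(densities[g]), density_group = g,
          stringsAsFactors = FALSE)
        qpcr[[sid]] <- data.frame(sample_id = sid, copies_per_ng_dna = 1000,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- c("t1", "t2")
  list(table = feature_table(values, "copies_per_ng_dna"),
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       qpcr = do.call(rbind, c(qpcr, list(make.row.names = FALSE))),
       densities = densities)
}

# Run the standard preprocessing chain and fit on a simulated experiment.
fit_simulation <- function(sim, n_draws = 1000, seed = NULL, ...) {
  f1 <- filter_samples_by_depth(sim$counts)
  f2 <- filter_rare_taxa(f1$table)
  rel <- to_relative_abundance(f2$table)
  nt <- qseq_normalize(rel, sim$qpcr)
  qsip(nt$table, sim$metadata, n_draws = n_draws, seed = seed, ...)
}

# Active-call vector over all truth taxa (unfitted taxa count as inactive).
calls_vs_truth <- function(fit, truth) {
  called <- stats::setNames(rep(FALSE, nrow(truth)), truth$taxon_id)
  called[fit$results$taxon_id] <- fit$results$active
  called
}
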