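#' Configuration for the qSIP forward simulator
#'
#' Describes a simulated SIP experiment emulating the study design the
#' package targets: replicate soil cores amended with unlabeled
#' (\eqn{^{12}}C) or labeled (\eqn{^{13}}C) substrate, CsCl gradients
#' read out either as 12 pooled density fractions or collapsed into the
#' three canonical density groups, multinomial amplicon sequencing, noisy
#' qPCR totals, and occasional missing density-group samples.
#'
#' Defaults describe the reference simulation used throughout the test
#' suite: 200 taxa of which half are inactive (zero excess) and half are
#' enriched at 1-10 atom percent excess; GC content normal with mean 0.55
#' and SD 0.08 (truncated), giving unlabeled WADs around 1.69 g/mL;
#' mean-1 lognormal relative abundances (`abundance_sdlog = 1`); three
#' replicate cores per isotope; 50,000 reads per sample; Gaussian density
#' banding with SD 0.005 g/mL; qPCR totals proportional to each sample's
#' share of the gradient's DNA with 20% lognormal CV; and a 5% chance of
#' losing any density-group sample.
#'
#' @param n_taxa Number of taxa.
#' @param active_fraction Fraction of taxa with positive excess.
#' @param ape_range Range (atom fraction excess) of the true enrichment
#'   of active taxa, drawn uniformly.
#' @param gc_mean,gc_sd,gc_range Truncated-normal GC distribution.
#' @param abundance_sdlog Lognormal sdlog of mean relative abundances.
#' @param cores_per_isotope Replicate cores per isotope treatment.
#' @param depth Reads per sequenced sample.
#' @param banding_sd Gaussian banding SD in g/mL (> 0).
#' @param qpcr_copies_per_ng Total 16S copies per ng of gradient-loaded
#'   DNA (summed over a core's samples, before noise).
#' @param qpcr_cv Lognormal coefficient of variation of qPCR totals.
#' @param dropout_prob Probability that any one density-group (or
#'   fraction) sample is lost.
#' @param resolution `"groups"`: one pooled sample per density group
#'   (the study design); `"fractions"`: one sample per gradient fraction.
#' @param n_fractions Number of fractions when `resolution = "fractions"`.
#' @param density_range Gradient span (g/mL) covered by the fractions.
#' @param scheme [density_group_scheme()] used for grouping.
#' @param sequencing `"multinomial"` (sampled counts) or `"exact"`
#'   (expected counts; zero sequencing noise).
#' @param wetland,redox Treatment labels stamped into the metadata.
#' @param constants [enrichment_constants()] governing the banding
#'   physics.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 200,
                              active_fraction = 0.5,
                              ape_range = c(0.01, 0.10),
                              gc_mean = 0.55, gc_sd = 0.08,
                              gc_range = c(0.25, 0.80),
                              abundance_sdlog = 1,
                              cores_per_isotope = 3,
                              depth = 50000,
                              banding_sd = 0.005,
                              qpcr_copies_per_ng = 3e5,
                              qpcr_cv = 0.20,
                              dropout_prob = 0.05,
                              resolution = c("groups", "fractions"),
                              n_fractions = 12,
                              density_range = c(1.65, 1.80),
                              scheme = density_group_scheme(),
                              sequencing = c("multinomial", "exact"),
                              wetland = "restored", redox = "anoxic",
                              constants = enrichment_constants()) {
  resolution <- match.arg(resolution)
  sequencing <- match.arg(sequencing)
  cfg <- list(n_taxa = n_taxa, active_fraction = active_fraction,
              ape_range = ape_range, gc_mean = gc_mean, gc_sd = gc_sd,
              gc_range = gc_range, abundance_sdlog = abundance_sdlog,
              cores_per_isotope = cores_per_isotope, depth = depth,
              banding_sd = banding_sd,
              qpcr_copies_per_ng = qpcr_copies_per_ng, qpcr_cv = qpcr_cv,
              dropout_prob = dropout_prob, resolution = resolution,
              n_fractions = n_fractions, density_range = density_range,
              scheme = scheme, sequencing = sequencing,
              wetland = wetland, redox = redox, constants = constants)
  validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_taxa < 1) config_error("`n_taxa` must be >= 1")
    if (active_fraction < 0 || active_fraction > 1) {
      config_error("`active_fraction` must be in [0, 1]")
    }
    if (length(ape_range) != 2L || any(ape_range < 0) || diff(ape_range) < 0) {
      config_error("`ape_range` must be an increasing non-negative pair")
    }
    if (banding_sd <= 0) config_error("`banding_sd` must be > 0")
    if (depth <= 0) config_error("`depth` must be > 0")
    if (dropout_prob < 0 || dropout_prob > 1) {
      config_error("`dropout_prob` must be in [0, 1]")
    }
    if (qpcr_cv < 0) config_error("`qpcr_cv` must be >= 0")
    if (length(density_range) != 2L || diff(density_range) <= 0) {
      config_error("`density_range` must be an increasing pair")
    }
    if (resolution == "fractions" && n_fractions < 2) {
      config_error("`n_fractions` must be >= 2")
    }
    if (!inherits(scheme, "density_scheme")) {
      config_error("`scheme` must be a `density_scheme`")
    }
  })
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("qSIP simulation: %d taxa (%.0f%% active, APE %.3g-%.3g), %d+%d cores, depth %g\n",
              x$n_taxa, 100 * x$active_fraction, 100 * x$ape_range[1L],
              100 * x$ape_range[2L], x$cores_per_isotope, x$cores_per_isotope,
              x$depth))
  cat(sprintf("  resolution: %s; banding SD %.4g g/mL; qPCR CV %.2g; dropout %.2g; sequencing %s\n",
              x$resolution, x$banding_sd, x$qpcr_cv, x$dropout_prob, x$sequencing))
  invisible(x)
}

#' Gaussian banding mass split over density bins
#'
#' Fraction of a taxon's DNA mass landing in each bin of a density
#' scheme, from integrating a Gaussian band (mean `wad`, SD `sd`) over
#' the bin bounds and renormalizing over the scheme's covered range.
#'
#' @param wad Band center, the taxon's WAD (g/mL).
#' @param sd Banding SD (g/mL), > 0.
#' @param scheme A [density_group_scheme()] (bins may also be fractions).
#' @return Named numeric vector of proportions summing to 1.
#' @export
#' @examples
#' group_mass_fractions(1.72, 0.005)  # essentially all mass in "medium"
group_mass_fractions <- function(wad, sd, scheme = density_group_scheme()) {
  if (sd <= 0) config_error("`sd` must be > 0")
  stopifnot(inherits(scheme, "density_scheme"))
  p <- diff(stats::pnorm(scheme$breaks, mean = wad, sd = sd))
  total <- sum(p)
  if (total <= 0) {  # band entirely outside the scheme: nearest bin gets all
    p <- rep(0, length(scheme$labels))
    p[which.min(abs((scheme$breaks[-1L] + scheme$breaks[-length(scheme$breaks)]) / 2 - wad))] <- 1
    return(stats::setNames(p, scheme$labels))
  }
  stats::setNames(p / total, scheme$labels)
}

#' Simulate a qSIP experiment with known truth
#'
#' Forward-simulates the full observation chain: taxon GC contents set
#' unlabeled WADs through the density-GC relation; true atom fraction
#' excess shifts the labeled WADs through [forward_density_shift()];
#' per core, each taxon's DNA mass is split over density bins by Gaussian
#' banding ([group_mass_fractions()]); reads are drawn multinomially at
#' the configured depth per retained sample; qPCR totals are each
#' sample's share of the core's DNA times the per-ng copy total, with
#' lognormal noise; and density-group (or fraction) samples drop out at
#' the configured rate (at least one sample per core is always
#' retained). Fully reproducible under `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional RNG seed.
#' @return A list with components `counts` (a read-count
#'   [feature_table()] with synthetic taxonomy), `metadata` (per-sample
#'   data.frame as [read_sample_metadata()] returns), `qpcr`
#'   (per-sample totals), `truth` (per-taxon generative parameters:
#'   `gc`, `w_light`, `w_lab`, `excess`, `ape_percent`, `active`,
#'   `rel_abundance`) and `config`.
#' @export
simulate_qsip_experiment <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  validate_sim_config(config)
  with_seed(seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  n <- cfg$n_taxa
  cst <- cfg$constants
  taxon_id <- sprintf("ASV_%04d", seq_len(n))

  gc <- rtrunc_norm(n, cfg$gc_mean, cfg$gc_sd, cfg$gc_range)
  w_light <- cst$gc_intercept + cst$gc_slope * gc
  n_active <- round(cfg$active_fraction * n)
  excess <- rep(0, n)
  if (n_active > 0) {
    excess[seq_len(n_active)] <- stats::runif(n_active, cfg$ape_range[1L],
                                              cfg$ape_range[2L])
  }
  w_lab <- forward_density_shift(w_light, cst$background + excess, cst)
  p <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$abundance_sdlog)
  p <- p / sum(p)

  # density bins
  if (cfg$resolution == "groups") {
    bins <- cfg$scheme
    bin_names <- bins$labels
    fraction_index <- rep(NA_integer_, length(bin_names))
  } else {
    edges <- seq(cfg$density_range[1L], cfg$density_range[2L],
                 length.out = cfg$n_fractions + 1L)
    bins <- density_group_scheme(edges, sprintf("f%02d", seq_len(cfg$n_fractions)))
    bin_names <- bins$labels
    fraction_index <- seq_len(cfg$n_fractions)
  }
  mids <- (bins$breaks[-1L] + bins$breaks[-length(bins$breaks)]) / 2
  nb <- length(bin_names)

  # taxa x bins banding profiles per isotope
  prof <- function(wads) t(vapply(wads, group_mass_fractions, numeric(nb),
                                  sd = cfg$banding_sd, scheme = bins))
  profiles <- list(`12C` = prof(w_light), `13C` = prof(w_lab))

  counts <- list(); meta <- list(); qpcr <- list()
  sdlog_q <- sqrt(log(1 + cfg$qpcr_cv^2))
  for (iso in c("12C", "13C")) {
    for (k in seq_len(cfg$cores_per_isotope)) {
      core_id <- sprintf("%s_c%d", iso, k)
      mass <- p * profiles[[iso]]          # taxa x bins, sums to 1 overall
      bin_mass <- colSums(mass)
      keep <- stats::runif(nb) >= cfg$dropout_prob
      if (!any(keep)) keep[which.max(bin_mass)] <- TRUE
      for (b in which(keep)) {
        sid <- sprintf("%s_%s", core_id, bin_names[b])
        q <- mass[, b]
        if (sum(q) <= 0) next               # empty bin: nothing to sequence
        q <- q / sum(q)
        cts <- if (cfg$sequencing == "multinomial") {
          as.vector(stats::rmultinom(1L, cfg$depth, q))
        } else cfg$depth * q
        noise <- if (cfg$qpcr_cv > 0) {
          stats::rlnorm(1L, -sdlog_q^2 / 2, sdlog_q)
        } else 1
        counts[[sid]] <- cts
        meta[[sid]] <- data.frame(
          sample_id = sid, core_id = core_id,
          wetland = cfg$wetland, redox = cfg$redox, isotope = iso,
          fraction_index = fraction_index[b], density = mids[b],
          density_group = group_or_na(mids[b], cfg$scheme),
          dna_mass = 1000 * bin_mass[b], stringsAsFactors = FALSE)
        qpcr[[sid]] <- data.frame(
          sample_id = sid,
          copies_per_ng_dna = cfg$qpcr_copies_per_ng * bin_mass[b] * noise,
          stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(cbind, counts)
  dimnames(values) <- list(taxon_id, names(counts))
  genus <- sprintf("Genus_%02d", 1L + (seq_len(n) - 1L) %% 40L)
  taxonomy <- data.frame(
    taxon_id = taxon_id,
    phylum = sprintf("Phylum_%s", LETTERS[1L + (match(genus, sort(unique(genus))) - 1L) %% 6L]),
    genus = genus, stringsAsFactors = FALSE)
  truth <- data.frame(
    taxon_id = taxon_id, gc = gc, w_light = w_light, w_lab = w_lab,
    excess = excess, ape_percent = 100 * excess, active = excess > 0,
    rel_abundance = p, stringsAsFactors = FALSE)
  list(counts = feature_table(values, unit = "read_count", taxonomy = taxonomy),
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       qpcr = do.call(rbind, c(qpcr, list(make.row.names = FALSE))),
       truth = truth, config = cfg)
}

# Density-group label, or NA for densities beyond the pooling scheme
# (possible for fine fraction grids wider than the scheme).
group_or_na <- function(density, scheme) {
  idx <- findInterval(density, scheme$breaks, rightmost.closed = TRUE)
  if (idx == 0L || idx > length(scheme$labels)) NA_character_ else scheme$labels[idx]
}

# Truncated-normal sampler by rejection (bounds are mild here).
rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(0L)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= range[1L] & x <= range[2L]])
  }
  out[seq_len(n)]
}
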