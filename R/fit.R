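#' Fit the qSIP enrichment model
#'
#' The central estimator. For every taxon in every treatment group
#' (combination of the `group_by` metadata columns), `qsip()`:
#'
#' 1. computes a per-replicate-core weighted average density (WAD) over
#'    the core's sequenced density groups or fractions, using absolute
#'    abundances and the per-sample densities in `metadata`;
#' 2. bootstraps replicate cores (with replacement, `n_draws` draws,
#'    paired labeled/unlabeled resamples per draw) to obtain the density
#'    shift \eqn{Z = W_{lab} - W_{light}};
#' 3. converts each draw through the GC / molecular-weight chain
#'    ([gc_from_wad()], [molecular_weight_light()], [heavy_max_mass()],
#'    [labeled_mass()], [atom_fraction_excess()]) to atom percent excess
#'    (APE, %), summarized by its bootstrap mean and percentile CI;
#' 4. calls the taxon active when mean APE > 0 and the lower CI bound is
#'    above zero ([call_active()]). Taxa present only in labeled cores are
#'    instead assessed by the label-only WAD rule
#'    ([call_active_label_only()]) against the labeled treatment's
#'    community-average WAD.
#'
#' Cores missing density groups are tolerated: the WAD is computed over
#' the groups actually sequenced, and the per-core groups used are
#' recorded in the fit's `cores` table. GC values falling outside
#' \[-0.05, 1.05\] draw one aggregate warning; raw values are reported
#' while mass formulas use GC clamped to \[0, 1\].
#'
#' @param table A [feature_table()], normally QSEQ-normalized
#'   (`copies_per_ng_dna`); counts are accepted.
#' @param metadata Data.frame with one row per sample: `sample_id`,
#'   `core_id`, the `group_by` columns, `isotope`, `density` (see
#'   [read_sample_metadata()]).
#' @param group_by Metadata columns defining treatment groups (default
#'   `c("wetland", "redox")`).
#' @param labeled,unlabeled Isotope codes of the labeled and control
#'   treatments (defaults `"13C"`, `"12C"`).
#' @param n_draws Bootstrap draws (default 1000).
#' @param seed Optional RNG seed; recorded in every result row.
#' @param conf_level Confidence level for all intervals (default 0.95).
#' @param ci_method `"expanded"` (default) applies the small-sample
#'   \eqn{\sqrt{n/(n-1)}} expansion to the bootstrap percentile interval;
#'   `"percentile"` is the plain percentile interval.
#' @param constants [enrichment_constants()] governing the chain.
#' @return An object of class `qsip_fit` with components `results` (one
#'   row per taxon x treatment group), `cores` (per-core WAD accounting
#'   including density groups used), `treatment_wad` (community-average
#'   WAD estimates used by the label-only rule), and the fit settings.
#' @seealso [summary.qsip_fit()], [coef.qsip_fit()], [confint.qsip_fit()],
#'   [plot.qsip_fit()], [active_taxa()]
#' @export
qsip <- function(table, metadata,
                 group_by = c("wetland", "redox"),
                 labeled = "13C", unlabeled = "12C",
                 n_draws = 1000, seed = NULL, conf_level = 0.95,
                 ci_method = c("expanded", "percentile"),
                 constants = enrichment_constants()) {
  stopifnot(inherits(table, "feature_table"))
  ci_method <- match.arg(ci_method)
  expand <- ci_method == "expanded"
  if (table$unit == "relative_abundance") {
    warning("fitting on relative abundances; QSEQ-normalized absolute abundances are recommended")
  }
  need <- c("sample_id", "core_id", "isotope", "density", group_by)
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols)) {
    data_error(sprintf("metadata is missing column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  samples <- colnames(table$values)
  idx <- match(samples, metadata$sample_id)
  if (anyNA(idx)) {
    data_error(sprintf("no metadata for sample(s): %s",
                       paste(utils::head(samples[is.na(idx)], 5L), collapse = ", ")))
  }
  meta <- metadata[idx, , drop = FALSE]
  grp <- interaction(meta[group_by], drop = TRUE, sep = " / ")

  out <- with_seed(seed, {
    res <- list(); cores_acc <- list(); treat <- list(); gc_oob <- 0L
    for (g in levels(grp)) {
      sel <- grp == g
      fit_g <- fit_group(table$values[, sel, drop = FALSE],
                         meta[sel, , drop = FALSE], group_by,
                         labeled, unlabeled, n_draws, conf_level, expand,
                         constants)
      res[[g]] <- fit_g$results
      cores_acc[[g]] <- fit_g$cores
      treat[[g]] <- fit_g$treatment_wad
      gc_oob <- gc_oob + fit_g$gc_oob
    }
    list(results = do.call(rbind, res), cores = do.call(rbind, cores_acc),
         treatment_wad = do.call(rbind, treat), gc_oob = gc_oob)
  })
  if (out$gc_oob > 0L) {
    warning(sprintf("%d bootstrap GC value(s) outside [-0.05, 1.05]; clamped to [0, 1] for mass formulas",
                    out$gc_oob))
  }
  rownames(out$results) <- NULL
  out$results$n_draws <- n_draws
  out$results$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  structure(list(results = out$results, cores = out$cores,
                 treatment_wad = out$treatment_wad,
                 group_by = group_by, labeled = labeled, unlabeled = unlabeled,
                 n_draws = n_draws, seed = seed, conf_level = conf_level,
                 ci_method = ci_method, constants = constants,
                 call = match.call()),
            class = "qsip_fit")
}

# Fit one treatment group. values: taxa x samples; meta aligned to columns.
fit_group <- function(values, meta, group_by, labeled, unlabeled,
                      n_draws, conf_level, expand, constants) {
  core_ids <- unique(meta$core_id)
  n_taxa <- nrow(values)
  W <- matrix(NA_real_, n_taxa, length(core_ids),
              dimnames = list(rownames(values), core_ids))
  w_comm <- stats::setNames(rep(NA_real_, length(core_ids)), core_ids)
  iso <- character(length(core_ids)); nsamp <- integer(length(core_ids))
  groups_used <- character(length(core_ids))
  for (j in seq_along(core_ids)) {
    cols <- which(meta$core_id == core_ids[j])
    y <- values[, cols, drop = FALSE]
    rho <- meta$density[cols]
    tot <- rowSums(y)
    W[, j] <- ifelse(tot > 0, as.vector(y %*% rho) / tot, NA_real_)
    samp_tot <- colSums(y)
    w_comm[j] <- if (sum(samp_tot) > 0) sum(samp_tot * rho) / sum(samp_tot) else NA_real_
    iso[j] <- as.character(meta$isotope[cols[1L]])
    nsamp[j] <- length(cols)
    groups_used[j] <- if ("density_group" %in% names(meta)) {
      paste(unique(as.character(meta$density_group[cols])), collapse = ",")
    } else sprintf("%d fractions", length(cols))
  }
  lab_cores <- which(iso == labeled)
  unl_cores <- which(iso == unlabeled)
  if (!length(lab_cores)) {
    data_error(sprintf("treatment group has no '%s' cores", labeled))
  }

  # community-average WAD of the labeled treatment (label-only reference)
  treat_boot <- bootstrap_mean(w_comm[lab_cores], n_draws = n_draws,
                               conf_level = conf_level, expand = expand)

  grp_label <- paste(vapply(group_by, function(cc) as.character(meta[[cc]][1L]), ""),
                     collapse = " / ")
  rows <- vector("list", n_taxa)
  gc_oob <- 0L
  for (t in seq_len(n_taxa)) {
    wl <- W[t, lab_cores]; wl <- wl[!is.na(wl)]
    wu <- W[t, unl_cores]; wu <- wu[!is.na(wu)]
    if (!length(wl)) next  # taxon absent from the labeled treatment
    taxon <- rownames(values)[t]
    if (length(wu)) {
      est <- boot_chain(wl, wu, n_draws, conf_level, expand, constants)
      gc_oob <- gc_oob + est$gc_oob
      active <- call_active(list(mean = est$ape_mean, ci_low = est$ape_ci_low))
      rows[[t]] <- data.frame(
        taxon_id = taxon, group = grp_label,
        n_labeled = length(wl), n_unlabeled = length(wu),
        w_light = est$w_light, w_lab = est$w_lab, z = est$z,
        gc = est$gc, m_light = est$m_light, m_lab = est$m_lab,
        m_heavymax = est$m_heavymax,
        ape_mean = est$ape_mean, ape_ci_low = est$ape_ci_low,
        ape_ci_high = est$ape_ci_high,
        active = active,
        call_route = if (active) "ci_rule" else "not_active",
        stringsAsFactors = FALSE)
    } else {
      tw <- bootstrap_mean(wl, n_draws = n_draws, conf_level = conf_level,
                           expand = expand)
      active <- call_active_label_only(tw, treat_boot, n_unlabeled = 0)
      rows[[t]] <- data.frame(
        taxon_id = taxon, group = grp_label,
        n_labeled = length(wl), n_unlabeled = 0L,
        w_light = NA_real_, w_lab = tw$mean, z = NA_real_,
        gc = NA_real_, m_light = NA_real_, m_lab = NA_real_,
        m_heavymax = NA_real_,
        ape_mean = NA_real_, ape_ci_low = NA_real_, ape_ci_high = NA_real_,
        active = active,
        call_route = if (active) "label_only_rule" else "not_active",
        stringsAsFactors = FALSE)
    }
  }
  grp_meta <- meta[match(core_ids, meta$core_id), group_by, drop = FALSE]
  cores <- data.frame(grp_meta, core_id = core_ids, isotope = iso,
                      n_samples = nsamp, groups_used = groups_used,
                      community_wad = w_comm,
                      stringsAsFactors = FALSE, row.names = NULL)
  treatment_wad <- data.frame(
    group = grp_label, n_cores = length(lab_cores),
    wad_mean = treat_boot$mean, wad_ci_low = treat_boot$ci_low,
    wad_ci_high = treat_boot$ci_high, stringsAsFactors = FALSE)
  list(results = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
       cores = cores, treatment_wad = treatment_wad, gc_oob = gc_oob)
}

# Bootstrap one taxon's enrichment chain. wl/wu: per-core WADs (no NAs).
boot_chain <- function(wl, wu, n_draws, conf_level, expand, constants) {
  dl <- boot_draw_means(wl, n_draws, "resample")
  du <- boot_draw_means(wu, n_draws, "resample")
  if (expand) {
    dl <- expand_draws(dl, mean(wl), length(wl))
    du <- expand_draws(du, mean(wu), length(wu))
  }
  z <- dl - du
  g_raw <- (du - constants$gc_intercept) / constants$gc_slope
  gc_oob <- sum(g_raw < -0.05 | g_raw > 1.05)
  g <- clamp_gc(g_raw)
  ml <- molecular_weight_light(g, constants)
  mh <- heavy_max_mass(g, ml, constants)
  mlab <- (z / du + 1) * ml
  ape <- 100 * (mlab - ml) / (mh - ml) * (1 - constants$background)
  alpha <- (1 - conf_level) / 2
  qs <- stats::quantile(ape, c(alpha, 1 - alpha), names = FALSE)
  # point chain evaluated at the bootstrap WAD means
  w_light <- mean(du); w_lab <- mean(dl); z_pt <- mean(z)
  g_pt_raw <- (w_light - constants$gc_intercept) / constants$gc_slope
  g_pt <- clamp_gc(g_pt_raw)
  ml_pt <- molecular_weight_light(g_pt, constants)
  mh_pt <- heavy_max_mass(g_pt, ml_pt, constants)
  mlab_pt <- (z_pt / w_light + 1) * ml_pt
  list(w_light = w_light, w_lab = w_lab, z = z_pt,
       gc = g_pt_raw, m_light = ml_pt, m_heavymax = mh_pt, m_lab = mlab_pt,
       ape_mean = mean(ape), ape_ci_low = qs[1L], ape_ci_high = qs[2L],
       gc_oob = gc_oob)
}

#' Extract the active taxa from a qSIP fit
#'
#' @param fit A [qsip()] fit.
#' @param group Optional treatment-group label (as in
#'   `fit$results$group`); default all groups.
#' @return If `group` is given, a character vector of active taxon ids;
#'   otherwise a named list of such vectors, one per treatment group.
#' @export
active_taxa <- function(fit, group = NULL) {
  stopifnot(inherits(fit, "qsip_fit"))
  res <- fit$results
  if (!is.null(group)) {
    if (!group %in% res$group) data_error(sprintf("unknown treatment group '%s'", group))
    return(res$taxon_id[res$group == group & res$active])
  }
  lapply(split(res, res$group), function(d) d$taxon_id[d$active])
}

#' @export
print.qsip_fit <- function(x, ...) {
  res <- x$results
  cat("qSIP enrichment fit\n")
  cat(sprintf("  %d taxon-group estimates in %d treatment group(s); %d bootstrap draws (%s CI, %s)\n",
              nrow(res), length(unique(res$group)), x$n_draws,
              paste0(round(100 * x$conf_level), "%"), x$ci_method))
  act <- table(res$group, res$active)
  for (g in rownames(act)) {
    cat(sprintf("  %-28s %4d taxa, %4d active\n", g,
                sum(res$group == g), sum(res$active[res$group == g])))
  }
  invisible(x)
}

#' Summarize a qSIP fit
#'
#' Per-treatment-group counts of assessed and active taxa (split by call
#' route) and the median APE of the active taxa.
#'
#' @param object A [qsip()] fit.
#' @param ... Unused.
#' @return A data.frame of class `summary.qsip_fit`.
#' @export
summary.qsip_fit <- function(object, ...) {
  res <- object$results
  out <- do.call(rbind, lapply(split(res, res$group), function(d) {
    data.frame(group = d$group[1L],
               n_taxa = nrow(d),
               n_active = sum(d$active),
               n_active_ci_rule = sum(d$call_route == "ci_rule"),
               n_active_label_only = sum(d$call_route == "label_only_rule"),
               median_ape_active = stats::median(d$ape_mean[d$active], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("summary.qsip_fit", "data.frame"),
            n_draws = object$n_draws, ci_method = object$ci_method)
}

#' @export
print.summary.qsip_fit <- function(x, ...) {
  cat(sprintf("qSIP fit summary (%d draws, %s CI); median APE in %%\n",
              attr(x, "n_draws"), attr(x, "ci_method")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Atom-percent-excess estimates from a qSIP fit
#'
#' @param object A [qsip()] fit.
#' @param ... Unused.
#' @return Named numeric vector of mean APE (%) per taxon (names
#'   `taxon_id`, or `taxon_id|group` when several treatment groups were
#'   fit); label-only taxa are `NA`.
#' @export
coef.qsip_fit <- function(object, ...) {
  res <- object$results
  nm <- if (length(unique(res$group)) > 1L) {
    paste(res$taxon_id, res$group, sep = "|")
  } else res$taxon_id
  stats::setNames(res$ape_mean, nm)
}

#' Bootstrap confidence intervals for APE
#'
#' @param object A [qsip()] fit.
#' @param parm Optional taxon ids to extract.
#' @param level Must match the level the fit was run at.
#' @param ... Unused.
#' @return Two-column matrix of lower/upper APE (%) bounds.
#' @export
confint.qsip_fit <- function(object, parm = NULL, level = object$conf_level, ...) {
  if (!isTRUE(all.equal(level, object$conf_level))) {
    config_error(sprintf("intervals were computed at level %g; refit to change it",
                         object$conf_level))
  }
  res <- object$results
  if (!is.null(parm)) res <- res[res$taxon_id %in% parm, , drop = FALSE]
  alpha <- (1 - level) / 2
  out <- cbind(res$ape_ci_low, res$ape_ci_high)
  dimnames(out) <- list(res$taxon_id,
                        sprintf("%.1f %%", 100 * c(alpha, 1 - alpha)))
  out
}

#' @export
as.data.frame.qsip_fit <- function(x, ...) x$results

#' Plot a qSIP fit
#'
#' Caterpillar plot of per-taxon atom percent excess with bootstrap
#' intervals, ordered by the point estimate; active taxa are filled.
#'
#' @param x A [qsip()] fit.
#' @param group Treatment group to plot (default: the first).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.qsip_fit <- function(x, group = NULL, ...) {
  res <- x$results
  if (is.null(group)) group <- res$group[1L]
  d <- res[res$group == group & !is.na(res$ape_mean), , drop = FALSE]
  if (!nrow(d)) data_error(sprintf("no enrichment estimates in group '%s'", group))
  d <- d[order(d$ape_mean), , drop = FALSE]
  i <- seq_len(nrow(d))
  graphics::plot(i, d$ape_mean, ylim = range(d$ape_ci_low, d$ape_ci_high),
                 xlab = "taxa (ranked)", ylab = "atom percent excess (%)",
                 pch = ifelse(d$active, 19, 1),
                 col = ifelse(d$active, "firebrick", "grey40"),
                 main = sprintf("13C enrichment: %s", group), ...)
  graphics::segments(i, d$ape_ci_low, i, d$ape_ci_high,
                     col = ifelse(d$active, "firebrick", "grey70"))
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
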