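#' Weighted average density (WAD) of a taxon
#'
#' The taxon's buoyant density summarized over gradient fractions or
#' density groups: \eqn{W = \sum_i x_i \rho_i}, where \eqn{x_i} is the
#' taxon's abundance in fraction \eqn{i} normalized over the supplied
#' fractions and \eqn{\rho_i} the fraction's (mean) density. Zero
#' abundances contribute nothing; an all-zero profile has no defined WAD
#' and returns `NA`.
#'
#' @param abundances Non-negative abundances per fraction/density group
#'   (counts or copies per ng DNA).
#' @param densities Densities (g/mL) of the same fractions/groups.
#' @return The WAD in g/mL, or `NA_real_` if all abundances are zero.
#' @export
#' @examples
#' compute_wad(c(0.2, 0.5, 0.3), c(1.67, 1.72, 1.77))  # 1.725
compute_wad <- function(abundances, densities) {
  if (length(abundances) != length(densities)) {
    data_error("`abundances` and `densities` must have equal length")
  }
  if (anyNA(abundances) || anyNA(densities)) data_error("missing values in WAD input")
  if (any(abundances < 0)) data_error("negative abundances in WAD input")
  total <- sum(abundances)
  if (total == 0) return(NA_real_)
  sum(abundances * densities) / total
}

#' GC content from unlabeled buoyant density
#'
#' Inverts the linear relation between genomic GC content and buoyant
#' density: \eqn{G = (W_{light} - gc\_intercept)/gc\_slope}. The raw value
#' is returned unclamped; values outside \[-0.05, 1.05\] draw a warning
#' (downstream mass formulas clamp to \[0, 1\] while retaining the raw
#' value in results).
#'
#' @param w_light Unlabeled weighted average density (g/mL); a plausible
#'   DNA range is roughly 1.64-1.75.
#' @param constants An [enrichment_constants()] object.
#' @return GC content as a fraction (may fall outside \[0, 1\]).
#' @export
#' @examples
#' gc_from_wad(1.700)  # 0.64598
gc_from_wad <- function(w_light, constants = enrichment_constants()) {
  g <- (w_light - constants$gc_intercept) / constants$gc_slope
  out_of_band <- !is.na(g) & (g < -0.05 | g > 1.05)
  if (any(out_of_band)) {
    warning(sprintf("%d GC value(s) outside [-0.05, 1.05]; raw values kept, masses use clamped GC",
                    sum(out_of_band)))
  }
  g
}

# Clamp GC into [0, 1] for the mass formulas.
clamp_gc <- function(g) pmin(pmax(g, 0), 1)

#' Molecular weight of an unlabeled nucleotide
#'
#' Mean per-nucleotide molecular weight of a taxon's natural-abundance
#' DNA as a linear function of GC content:
#' \eqn{M_{light} = mw\_gc\_slope \cdot G + mw\_intercept} (g/mol).
#'
#' @param gc GC content in \[0, 1\].
#' @inheritParams gc_from_wad
#' @return Molecular weight in g/mol.
#' @export
molecular_weight_light <- function(gc, constants = enrichment_constants()) {
  constants$mw_gc_slope * gc + constants$mw_intercept
}

#' Molecular weight at full heavy-isotope substitution
#'
#' The ceiling mass reached when every assimilable carbon is the heavy
#' isotope: \eqn{M_{heavymax} = M_{light} + N_C(G)\,(1 - b)\,\Delta m},
#' with \eqn{N_C(G) = 10 - 0.5G} carbon atoms per average nucleotide
#' (A, T, G carry 10 carbons; C carries 9), \eqn{b} the natural background
#' atom fraction already present in `m_light`, and \eqn{\Delta m} the
#' isotope mass difference.
#'
#' @param gc GC content in \[0, 1\].
#' @param m_light Unlabeled molecular weight (g/mol), from
#'   [molecular_weight_light()].
#' @inheritParams gc_from_wad
#' @return Molecular weight in g/mol.
#' @export
heavy_max_mass <- function(gc, m_light, constants = enrichment_constants()) {
  n_c <- 10 - 0.5 * gc
  m_light + n_c * (1 - constants$background) * constants$isotope_mass_shift
}

#' Molecular weight of a taxon in the labeled treatment
#'
#' Converts the measured density shift into a labeled molecular weight via
#' the proportionality of relative mass and relative density change:
#' \eqn{M_{lab} = (Z / W_{light} + 1)\, M_{light}}.
#'
#' @param z Density shift \eqn{Z = W_{lab} - W_{light}} (g/mL); may be
#'   negative.
#' @param w_light Unlabeled WAD (g/mL), > 0.
#' @param m_light Unlabeled molecular weight (g/mol).
#' @return Labeled molecular weight in g/mol.
#' @export
#' @examples
#' labeled_mass(0.05, 1.7, 308.011)  # 317.070
labeled_mass <- function(z, w_light, m_light) {
  if (any(w_light <= 0, na.rm = TRUE)) data_error("`w_light` must be positive")
  (z / w_light + 1) * m_light
}

#' Atom fraction excess from molecular weights
#'
#' The fraction of a taxon's carbon that is heavy isotope above natural
#' abundance:
#' \deqn{A = \frac{M_{lab} - M_{light}}{M_{heavymax} - M_{light}} (1 - b)}
#' with \eqn{b} the background atom fraction. Negative values (labeled
#' WAD below unlabeled) are reported as-is, never clipped; atom percent
#' excess (APE) is \eqn{100 A}.
#'
#' @param m_lab Labeled molecular weight (g/mol).
#' @param m_light Unlabeled molecular weight (g/mol).
#' @param m_heavymax Fully-substituted molecular weight (g/mol), >
#'   `m_light`.
#' @inheritParams gc_from_wad
#' @return Atom fraction excess (dimensionless; at most \eqn{1 - b}).
#' @export
atom_fraction_excess <- function(m_lab, m_light, m_heavymax,
                                 constants = enrichment_constants()) {
  if (any(m_heavymax <= m_light, na.rm = TRUE)) {
    data_error("`m_heavymax` must exceed `m_light`")
  }
  (m_lab - m_light) / (m_heavymax - m_light) * (1 - constants$background)
}

#' Predicted labeled density from an atom fraction (forward model)
#'
#' Runs the enrichment chain in reverse: given an unlabeled WAD and the
#' total atom fraction of heavy isotope in the taxon's carbon (background
#' plus excess), predicts the labeled WAD. At `atom_fraction` equal to
#' the natural background the density is unchanged; the chain is the
#' exact inverse of [atom_fraction_from_shift()].
#'
#' @param w_light Unlabeled WAD (g/mL).
#' @param atom_fraction Total atom fraction of the heavy isotope in
#'   \[background, 1\].
#' @inheritParams gc_from_wad
#' @return Predicted labeled WAD (g/mL).
#' @export
#' @examples
#' forward_density_shift(1.700, 0.99)  # ~1.7525, i.e. 1.75 g/mL
forward_density_shift <- function(w_light, atom_fraction,
                                  constants = enrichment_constants()) {
  b <- constants$background
  if (any(atom_fraction < b * 0.99 | atom_fraction > 1, na.rm = TRUE)) {
    data_error("`atom_fraction` must lie between the natural background and 1")
  }
  g <- clamp_gc((w_light - constants$gc_intercept) / constants$gc_slope)
  m_light <- molecular_weight_light(g, constants)
  m_hmax <- heavy_max_mass(g, m_light, constants)
  excess <- atom_fraction - b
  m_lab <- m_light + excess / (1 - b) * (m_hmax - m_light)
  w_light * m_lab / m_light
}

#' Atom fraction implied by a density shift (inverse model)
#'
#' Chains [gc_from_wad()], [molecular_weight_light()], [heavy_max_mass()],
#' [labeled_mass()] and [atom_fraction_excess()] to recover the total atom
#' fraction of heavy isotope from a labeled/unlabeled WAD pair. Exact
#' inverse of [forward_density_shift()].
#'
#' @param w_light Unlabeled WAD (g/mL).
#' @param w_lab Labeled WAD (g/mL).
#' @inheritParams gc_from_wad
#' @return Total atom fraction (background + excess).
#' @export
atom_fraction_from_shift <- function(w_light, w_lab,
                                     constants = enrichment_constants()) {
  g <- clamp_gc((w_light - constants$gc_intercept) / constants$gc_slope)
  m_light <- molecular_weight_light(g, constants)
  m_hmax <- heavy_max_mass(g, m_light, constants)
  m_lab <- labeled_mass(w_lab - w_light, w_light, m_light)
  constants$background + atom_fraction_excess(m_lab, m_light, m_hmax, constants)
}

#' Call a taxon active from its bootstrapped enrichment
#'
#' A taxon is active when its mean atom (percent) excess is positive and
#' the lower bound of its 95% bootstrap confidence interval is above
#' zero.
#'
#' @param ape A [bootstrap_mean()] estimate of atom (percent) excess, or a
#'   list with elements `mean` and `ci_low`.
#' @return Logical.
#' @export
#' @examples
#' call_active(list(mean = 0.05, ci_low = 0.02, ci_high = 0.08))  # TRUE
call_active <- function(ape) {
  if (!all(c("mean", "ci_low") %in% names(ape))) {
    data_error("`ape` must carry elements `mean` and `ci_low`")
  }
  isTRUE(ape$mean > 0) && isTRUE(ape$ci_low > 0)
}

#' Call a label-only taxon active from WAD separation
#'
#' Taxa detected only in labeled (\eqn{^{13}}C) cores have no unlabeled
#' WAD and thus no enrichment estimate. They are called active when the
#' lower 95% CI of their bootstrapped WAD exceeds the upper 95% CI of the
#' labeled treatment's community-average WAD, i.e. they band credibly
#' heavier than the treatment as a whole. Applying this rule to a taxon
#' that does have unlabeled observations is an error (the CI rule
#' applies).
#'
#' @param taxon_wad [bootstrap_mean()] estimate of the taxon's WAD across
#'   labeled cores.
#' @param treatment_wad [bootstrap_mean()] estimate of the labeled
#'   treatment's community-average WAD.
#' @param n_unlabeled Number of unlabeled replicate cores in which the
#'   taxon was observed; must be 0.
#' @return Logical.
#' @export
call_active_label_only <- function(taxon_wad, treatment_wad, n_unlabeled = 0) {
  if (n_unlabeled > 0) {
    data_error("taxon has unlabeled observations; use the enrichment CI rule")
  }
  if (!"ci_low" %in% names(taxon_wad) || !"ci_high" %in% names(treatment_wad)) {
    data_error("WAD estimates must carry bootstrap confidence bounds")
  }
  isTRUE(taxon_wad$ci_low > treatment_wad$ci_high)
}
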