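#' Reference constants for the density-to-enrichment chain
#'
#' The qSIP chain converts buoyant densities to GC content, nucleotide
#' molecular weights and finally atom fraction excess through a set of
#' empirical and physical constants. The defaults reproduce the standard
#' relations used in \eqn{^{13}}C qSIP:
#'
#' * `gc_intercept`, `gc_slope` — linear map between unlabeled weighted
#'   average density (g/mL) and genomic GC content:
#'   \eqn{G = (W_{light} - gc\_intercept) / gc\_slope}.
#' * `mw_gc_slope`, `mw_intercept` — mean molecular weight (g/mol) of an
#'   unlabeled nucleotide as a function of GC content:
#'   \eqn{M_{light} = mw\_gc\_slope \cdot G + mw\_intercept}.
#' * `background` — natural atom fraction of \eqn{^{13}}C in carbon
#'   (0.01111233), the baseline above which excess is measured.
#' * `isotope_mass_shift` — mass difference between \eqn{^{13}}C and
#'   \eqn{^{12}}C in Da (1.003355).
#'
#' Carbon atoms per average nucleotide are derived from composition
#' (A, T, G nucleotides carry 10 carbons, C carries 9):
#' \eqn{N_C(G) = 10 - 0.5 G}.
#'
#' @param gc_intercept Density (g/mL) of hypothetical 0%-GC unlabeled DNA.
#' @param gc_slope Density increase (g/mL) per unit GC fraction.
#' @param mw_gc_slope Molecular-weight increase (g/mol) per unit GC fraction.
#' @param mw_intercept Molecular weight (g/mol) of a 0%-GC nucleotide.
#' @param background Natural atom fraction of the heavy isotope.
#' @param isotope_mass_shift Heavy-minus-light isotope mass difference (Da).
#'
#' @return An object of class `enrichment_constants` (a named list).
#' @seealso [gc_from_wad()], [atom_fraction_excess()], [forward_density_shift()]
#' @export
#' @examples
#' enrichment_constants()
enrichment_constants <- function(gc_intercept = 1.646057,
                                 gc_slope = 0.083506,
                                 mw_gc_slope = 0.496,
                                 mw_intercept = 307.691,
                                 background = 0.01111233,
                                 isotope_mass_shift = 1.003355) {
  stopifnot(gc_slope > 0, mw_intercept > 0,
            background > 0, background < 1, isotope_mass_shift > 0)
  structure(
    list(gc_intercept = gc_intercept, gc_slope = gc_slope,
         mw_gc_slope = mw_gc_slope, mw_intercept = mw_intercept,
         background = background, isotope_mass_shift = isotope_mass_shift),
    class = "enrichment_constants"
  )
}

#' @export
print.enrichment_constants <- function(x, ...) {
  cat("qSIP enrichment constants:\n")
  cat(sprintf("  GC from density:    G = (W - %.6f) / %.6f\n",
              x$gc_intercept, x$gc_slope))
  cat(sprintf("  nucleotide weight:  M_light = %.3f G + %.3f g/mol\n",
              x$mw_gc_slope, x$mw_intercept))
  cat(sprintf("  background %s atom fraction: %.8f\n", "13C", x$background))
  cat(sprintf("  isotope mass shift: %.6f Da\n", x$isotope_mass_shift))
  invisible(x)
}
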