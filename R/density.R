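#' Refractive-index to buoyant-density calibration
#'
#' CsCl gradient fraction densities are measured by refractometry and
#' converted to g/mL through an affine calibration,
#' `density = slope * ri + intercept`. The default constants are the
#' conventional 20 degree C CsCl relation; laboratories correct for
#' temperature and gradient-buffer addition, so both constants are
#' user-settable.
#'
#' @param slope Density change (g/mL) per refractive-index unit; must be > 0.
#' @param intercept Offset in g/mL.
#' @param temperature_reference Reference temperature (degrees C) of the
#'   calibration, recorded for provenance.
#' @return An object of class `ri_calibration`.
#' @export
#' @examples
#' ri_calibration()
ri_calibration <- function(slope = 10.9276, intercept = -13.593,
                           temperature_reference = 20) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0) {
    config_error("`slope` of an RI calibration must be a single positive number")
  }
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    config_error("`intercept` of an RI calibration must be a single finite number")
  }
  structure(list(slope = slope, intercept = intercept,
                 temperature_reference = temperature_reference),
            class = "ri_calibration")
}

#' @export
print.ri_calibration <- function(x, ...) {
  cat(sprintf("RI calibration: density = %.4f * ri %+0.4f g/mL (ref. %s C)\n",
              x$slope, x$intercept, format(x$temperature_reference)))
  invisible(x)
}

#' Convert refractive index to buoyant density
#'
#' Applies the affine calibration `cal` to refractive-index readings.
#' Readings outside the physically plausible window (1.3, 1.5) are still
#' converted but flagged: a warning is raised and the returned vector
#' carries a logical `flagged` attribute marking the offending entries.
#'
#' @param ri Numeric vector of refractive-index readings.
#' @param cal An [ri_calibration()] object; converting without a
#'   calibration is an error.
#' @return Numeric vector of densities (g/mL), with attribute `flagged`.
#' @export
#' @examples
#' ri_to_density(1.4000)  # 1.70564 g/mL under the default calibration
ri_to_density <- function(ri, cal = ri_calibration()) {
  if (is.null(cal)) config_error("an `ri_calibration` is required to convert refractive index")
  if (!inherits(cal, "ri_calibration")) config_error("`cal` must be an `ri_calibration` object")
  if (!is.numeric(ri)) data_error("`ri` must be numeric")
  flagged <- !is.na(ri) & (ri <= 1.3 | ri >= 1.5)
  if (any(flagged)) {
    warning(sprintf("%d refractive-index value(s) outside (1.3, 1.5); converted but flagged",
                    sum(flagged)))
  }
  out <- cal$slope * ri + cal$intercept
  attr(out, "flagged") <- flagged
  out
}

#' Density-group binning scheme for gradient fractions
#'
#' Gradient fractions are pooled into ordered buoyant-density groups
#' (canonically light / medium / heavy) before sequencing. Bins are
#' half-open `[low, high)` except the last, which also includes its upper
#' bound, so that every density in the covered range is assigned to
#' exactly one group. The default scheme pools at 1.65, 1.69, 1.75 and
#' 1.80 g/mL; the nominal published bounds (light up to 1.689, medium
#' from 1.69, heavy from 1.75) leave small gaps which the half-open bin
#' edges close, since no fraction may be unassignable.
#'
#' @param breaks Increasing numeric vector of bin edges (g/mL), length
#'   `length(labels) + 1`.
#' @param labels Character vector of group names, ordered light to heavy.
#' @return An object of class `density_scheme`.
#' @export
#' @examples
#' sch <- density_group_scheme()
#' assign_density_group(c(1.66, 1.69, 1.76), sch)
density_group_scheme <- function(breaks = c(1.65, 1.69, 1.75, 1.80),
                                 labels = c("light", "medium", "heavy")) {
  if (!is.numeric(breaks) || length(breaks) < 2L || anyNA(breaks)) {
    config_error("`breaks` must be a numeric vector of at least two bin edges")
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    config_error("`breaks` must be strictly increasing")
  }
  labels <- as.character(labels)
  if (length(labels) != length(breaks) - 1L) {
    config_error("`labels` must have one entry per bin (length(breaks) - 1)")
  }
  if (anyDuplicated(labels)) config_error("density-group labels must be unique")
  structure(list(breaks = breaks, labels = labels), class = "density_scheme")
}

#' @export
print.density_scheme <- function(x, ...) {
  n <- length(x$labels)
  bounds <- sprintf("[%.4g, %.4g%s", x$breaks[-length(x$breaks)], x$breaks[-1],
                    c(rep(")", n - 1L), "]"))
  cat("Density-group scheme (g/mL):\n")
  cat(paste0("  ", format(x$labels), "  ", bounds, collapse = "\n"), "\n")
  invisible(x)
}

#' Assign buoyant densities to density groups
#'
#' Maps each density to the unique scheme bin containing it; boundary
#' values resolve by the half-open `[low, high)` convention (the topmost
#' bin is closed above). Densities outside the scheme are an error that
#' names the offending sample.
#'
#' @param density Numeric vector of densities (g/mL).
#' @param scheme A [density_group_scheme()].
#' @param sample_id Optional identifiers used in error messages; defaults
#'   to the names of `density` or its indices.
#' @return A factor of group labels with the scheme's level order.
#' @export
assign_density_group <- function(density, scheme = density_group_scheme(),
                                 sample_id = NULL) {
  if (!inherits(scheme, "density_scheme")) config_error("`scheme` must be a `density_scheme`")
  if (!is.numeric(density)) data_error("`density` must be numeric")
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(names(density))) names(density) else as.character(seq_along(density))
  }
  idx <- findInterval(density, scheme$breaks, rightmost.closed = TRUE)
  bad <- !is.na(density) & (idx == 0L | idx > length(scheme$labels))
  if (any(bad)) {
    data_error(sprintf(
      "density outside the group scheme [%g, %g] g/mL for sample(s): %s",
      scheme$breaks[1L], scheme$breaks[length(scheme$breaks)],
      paste(utils::head(sample_id[bad], 5L), collapse = ", ")))
  }
  factor(scheme$labels[idx], levels = scheme$labels)
}
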