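#' Taxon-by-sample feature table
#'
#' The central data container: a numeric matrix of taxa (rows, typically
#' ASVs) by samples (columns, density fractions or density groups of
#' individual cores), tagged with the unit of its values and an optional
#' taxonomy map. Values must be non-negative; taxon and sample identifiers
#' must be unique.
#'
#' @param values Numeric matrix with taxon row names and sample column
#'   names (a data.frame is coerced).
#' @param unit One of `"read_count"`, `"relative_abundance"`,
#'   `"copies_per_ng_dna"`.
#' @param taxonomy Optional data.frame with a `taxon_id` column plus rank
#'   columns (e.g. `phylum`, `genus`).
#' @return An object of class `feature_table`.
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' feature_table(m, "read_count")
feature_table <- function(values,
                          unit = c("read_count", "relative_abundance",
                                   "copies_per_ng_dna"),
                          taxonomy = NULL) {
  unit <- match.arg(unit)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    data_error("`values` must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    data_error("`values` must have taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) data_error("duplicate taxon identifiers")
  if (anyDuplicated(colnames(values))) data_error("duplicate sample identifiers")
  if (anyNA(values)) data_error("feature table values must not be missing")
  if (any(values < 0)) data_error("feature table values must be non-negative")
  if (!is.null(taxonomy)) {
    if (!is.data.frame(taxonomy) || !"taxon_id" %in% names(taxonomy)) {
      data_error("`taxonomy` must be a data.frame with a `taxon_id` column")
    }
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    if (anyDuplicated(taxonomy$taxon_id)) data_error("duplicate taxon_id in taxonomy")
  }
  structure(list(values = values, unit = unit, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d taxa x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  if (!is.null(x$taxonomy)) {
    cat(sprintf("  taxonomy: %s\n",
                paste(setdiff(names(x$taxonomy), "taxon_id"), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' Dimension names of a feature table
#' @param x A `feature_table`.
#' @export
dimnames.feature_table <- function(x) dimnames(x$values)

# Internal: replace values keeping class & checks light.
ft_replace <- function(x, values) {
  x$values <- values
  if (!is.null(x$taxonomy)) {
    x$taxonomy <- x$taxonomy[x$taxonomy$taxon_id %in% rownames(values), ,
                             drop = FALSE]
  }
  x
}

#' Read a feature table from TSV/CSV or BIOM
#'
#' TSV/CSV layout is taxa in rows and samples in columns, with the first
#' column holding taxon identifiers. A JSON sidecar (`<path>.meta.json`),
#' written by [write_feature_table()], restores the value unit and the
#' taxonomy; without a sidecar the unit defaults to `read_count` (or can
#' be given). BIOM (JSON, format 1.0) files are read through the
#' \pkg{biomformat} package and taxonomy is taken from the observation
#' metadata.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"biom"`.
#' @param unit Unit override when no sidecar is present.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, format = c("auto", "tsv", "csv", "biom"),
                               unit = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", biom = "biom",
                     data_error(sprintf("cannot infer format from extension '.%s'", ext)))
  }
  side <- read_sidecar(path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      config_error("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    values <- as.matrix(biomformat::biom_data(b))
    taxonomy <- side$taxonomy
    if (is.null(taxonomy)) {
      om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
      if (is.data.frame(om) && ncol(om) > 0L) {
        taxonomy <- cbind(data.frame(taxon_id = rownames(om),
                                     stringsAsFactors = FALSE), om)
        rownames(taxonomy) <- NULL
      }
    }
  } else {
    sep <- if (format == "tsv") "\t" else ","
    raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                             quote = "\"", fill = FALSE,
                             stringsAsFactors = FALSE, comment.char = "")
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids)) data_error(sprintf("duplicate taxon identifiers in %s", path))
    values <- as.matrix(raw[, -1L, drop = FALSE])
    if (!is.numeric(values)) data_error(sprintf("non-numeric abundance values in %s", path))
    rownames(values) <- ids
    taxonomy <- side$taxonomy
  }
  u <- side$unit
  if (is.null(u)) u <- if (is.null(unit)) "read_count" else unit
  feature_table(values, unit = u, taxonomy = taxonomy)
}

#' Write a feature table to TSV/CSV or BIOM
#'
#' Writes the matrix in the layout read by [read_feature_table()] plus a
#' JSON sidecar `<path>.meta.json` holding the unit and taxonomy, so that
#' a write/read round trip is lossless (bit-identical for integer counts).
#'
#' @param table A [feature_table()].
#' @param path Output file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                format = c("auto", "tsv", "csv", "biom")) {
  stopifnot(inherits(table, "feature_table"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", biom = "biom",
                     data_error(sprintf("cannot infer format from extension '.%s'", ext)))
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      config_error("writing BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::make_biom(table$values)
    biomformat::write_biom(b, path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(taxon_id = rownames(table$values), table$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  side <- list(unit = table$unit)
  if (!is.null(table$taxonomy)) side$taxonomy <- table$taxonomy
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".meta.json")
  if (!file.exists(sc)) return(list())
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!is.null(side$taxonomy)) {
    side$taxonomy <- as.data.frame(side$taxonomy, stringsAsFactors = FALSE)
  }
  side
}

#' Read per-sample gradient metadata
#'
#' Reads a CSV with one row per sequenced sample (density fraction or
#' density group of one core). Mandatory columns: `sample_id`, `core_id`,
#' `wetland`, `redox`, `isotope`, and either `density` (g/mL) or
#' `refractive_index` (converted through `cal`). If `density_group` is
#' absent it is assigned from `scheme`; pre-grouped tables pass through
#' untouched. Densities outside (1.60, 1.85) g/mL draw a warning.
#'
#' @param path CSV file.
#' @param cal [ri_calibration()] used when only refractive index is given.
#' @param scheme [density_group_scheme()] used when `density_group` is absent.
#' @return A data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path, cal = ri_calibration(),
                                 scheme = density_group_scheme()) {
  meta <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "core_id", "wetland", "redox", "isotope")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    data_error(sprintf("metadata file %s is missing required column(s): %s",
                       path, paste(missing_cols, collapse = ", ")))
  }
  if (!"density" %in% names(meta)) {
    if (!"refractive_index" %in% names(meta)) {
      data_error(sprintf(
        "metadata file %s needs a `density` or `refractive_index` column", path))
    }
    meta$density <- as.numeric(ri_to_density(meta$refractive_index, cal))
  }
  if (anyDuplicated(meta$sample_id)) data_error("duplicate sample_id in metadata")
  if (any(is.na(meta$density))) data_error("missing density values in metadata")
  out_of_range <- meta$density <= 1.60 | meta$density >= 1.85
  if (any(out_of_range)) {
    warning(sprintf("%d sample(s) with density outside (1.60, 1.85) g/mL",
                    sum(out_of_range)))
  }
  if (!"density_group" %in% names(meta)) {
    meta$density_group <- as.character(
      assign_density_group(meta$density, scheme, sample_id = meta$sample_id))
  }
  meta
}

#' Read a qPCR totals table
#'
#' Reads a CSV with columns `sample_id` and `copies_per_ng_dna` (mean 16S
#' rRNA gene copies per ng DNA over replicate reactions). Totals must be
#' strictly positive.
#'
#' @param path CSV file.
#' @return A data.frame with columns `sample_id`, `copies_per_ng_dna`.
#' @export
read_qpcr_table <- function(path) {
  q <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "copies_per_ng_dna") %in% names(q))) {
    data_error(sprintf(
      "qPCR file %s must have columns sample_id, copies_per_ng_dna", path))
  }
  if (anyDuplicated(q$sample_id)) data_error("duplicate sample_id in qPCR table")
  if (any(!is.finite(q$copies_per_ng_dna)) || any(q$copies_per_ng_dna <= 0)) {
    data_error("qPCR totals must be finite and > 0")
  }
  q
}
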