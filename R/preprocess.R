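#' Filtering report
#'
#' Records what a filtering or normalization step removed and why, so that
#' sample/taxon attrition is auditable: removed samples and taxa with
#' reasons, the thresholds used, and the before/after table dimensions.
#'
#' @name filter_report
NULL

new_filter_report <- function(step, removed_samples, removed_taxa, thresholds,
                              dim_before, dim_after, extra = list()) {
  rs <- if (length(removed_samples)) {
    data.frame(sample_id = names(removed_samples),
               reason = unname(removed_samples),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(sample_id = character(), reason = character())
  rt <- if (length(removed_taxa)) {
    data.frame(taxon_id = names(removed_taxa), reason = unname(removed_taxa),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(taxon_id = character(), reason = character())
  structure(c(list(step = step, removed_samples = rs, removed_taxa = rt,
                   thresholds = thresholds,
                   dim_before = dim_before, dim_after = dim_after), extra),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s]: %d x %d -> %d x %d (taxa x samples)\n",
              x$step, x$dim_before[1L], x$dim_before[2L],
              x$dim_after[1L], x$dim_after[2L]))
  if (nrow(x$removed_samples)) {
    cat(sprintf("  removed %d sample(s): %s\n", nrow(x$removed_samples),
                paste(utils::head(x$removed_samples$sample_id, 5L), collapse = ", ")))
  }
  if (nrow(x$removed_taxa)) cat(sprintf("  removed %d taxon/taxa\n", nrow(x$removed_taxa)))
  invisible(x)
}

#' Remove samples with outlier sequencing depth
#'
#' Computes each sample's depth (column sum of read counts) and retains
#' samples whose depth lies within `k` standard deviations of the mean
#' depth. Mean and SD are computed once over all input samples (a single
#' pass; the bounds are not re-estimated after removal).
#'
#' @param table A [feature_table()] of read counts (at least 2 samples).
#' @param k SD multiplier (default 2); `Inf` disables the filter.
#' @return A list with elements `table` (filtered) and `report`
#'   (a `filter_report`).
#' @export
#' @examples
#' m <- matrix(c(10, 0, rep(c(60, 40), 5)), nrow = 2,
#'             dimnames = list(c("a", "b"), paste0("s", 1:6)))
#' filter_samples_by_depth(feature_table(m, "read_count"))$report
filter_samples_by_depth <- function(table, k = 2) {
  stopifnot(inherits(table, "feature_table"))
  if (table$unit != "read_count") data_error("depth filtering requires read counts")
  if (ncol(table$values) < 2L) data_error("depth filtering needs at least 2 samples")
  depths <- colSums(table$values)
  m <- mean(depths)
  s <- stats::sd(depths)
  keep <- depths >= m - k * s & depths <= m + k * s
  if (!any(keep)) data_error("depth filter removed every sample")
  removed <- stats::setNames(
    sprintf("depth %g outside mean %.4g +/- %g * sd %.4g", depths[!keep], m, k, s),
    colnames(table$values)[!keep])
  out <- ft_replace(table, table$values[, keep, drop = FALSE])
  report <- new_filter_report(
    "depth", removed, character(),
    thresholds = list(k = k, lower = m - k * s, upper = m + k * s),
    dim_before = dim(table$values), dim_after = dim(out$values),
    extra = list(depth_mean = m, depth_sd = s))
  list(table = out, report = report)
}

#' Remove rare, low-prevalence taxa
#'
#' Retains taxa observed with a per-sample count of at least `min_count`
#' in at least `ceiling(min_prevalence * n_samples)` samples; everything
#' else is removed as too rare to identify confidently.
#'
#' @param table A [feature_table()] of read counts.
#' @param min_count Minimum per-sample count for a detection (default 3).
#' @param min_prevalence Minimum fraction of samples with such a detection
#'   (default 0.02).
#' @return A list with elements `table` and `report`.
#' @export
filter_rare_taxa <- function(table, min_count = 3, min_prevalence = 0.02) {
  stopifnot(inherits(table, "feature_table"))
  if (table$unit != "read_count") data_error("rare-taxon filtering requires read counts")
  n <- ncol(table$values)
  need <- ceiling(min_prevalence * n)
  prevalence <- rowSums(table$values >= min_count)
  keep <- prevalence >= need
  if (!any(keep)) data_error("rare-taxon filter removed every taxon")
  removed <- stats::setNames(
    sprintf("count >= %g in only %d/%d sample(s) (need %d)",
            min_count, prevalence[!keep], n, need),
    rownames(table$values)[!keep])
  out <- ft_replace(table, table$values[keep, , drop = FALSE])
  report <- new_filter_report(
    "rare_taxa", character(), removed,
    thresholds = list(min_count = min_count, min_prevalence = min_prevalence,
                      min_samples = need),
    dim_before = dim(table$values), dim_after = dim(out$values))
  list(table = out, report = report)
}

#' Transform counts to relative abundance
#'
#' Divides each sample column by its total so columns sum to one. An
#' all-zero sample column is an error (it has no composition), reported
#' by sample name.
#'
#' @param table A [feature_table()] of read counts.
#' @return A [feature_table()] with unit `relative_abundance`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$unit != "read_count") data_error("relative-abundance transform expects read counts")
  totals <- colSums(table$values)
  if (any(totals == 0)) {
    data_error(sprintf("all-zero sample column(s): %s",
                       paste(colnames(table$values)[totals == 0], collapse = ", ")))
  }
  out <- ft_replace(table, sweep(table$values, 2L, totals, "/"))
  out$unit <- "relative_abundance"
  out
}

#' QSEQ normalization to absolute abundance
#'
#' Scales relative abundances by each sample's total 16S rRNA gene copies
#' (qPCR), yielding gene copies per ng DNA per taxon: column sums of the
#' result equal the qPCR totals, and within-sample taxon ratios are
#' preserved. Samples without a qPCR record are dropped (with a report
#' entry), mirroring removal for insufficient qPCR data.
#'
#' @param table A [feature_table()] with unit `relative_abundance`.
#' @param qpcr A data.frame with columns `sample_id`, `copies_per_ng_dna`
#'   (see [read_qpcr_table()]).
#' @return A list with elements `table` (unit `copies_per_ng_dna`) and
#'   `report`.
#' @export
qseq_normalize <- function(table, qpcr) {
  stopifnot(inherits(table, "feature_table"))
  if (table$unit != "relative_abundance") {
    data_error("QSEQ normalization expects a relative-abundance table")
  }
  if (!all(c("sample_id", "copies_per_ng_dna") %in% names(qpcr))) {
    data_error("`qpcr` must have columns sample_id and copies_per_ng_dna")
  }
  if (any(!is.finite(qpcr$copies_per_ng_dna)) || any(qpcr$copies_per_ng_dna <= 0)) {
    data_error("qPCR totals must be finite and > 0")
  }
  samples <- colnames(table$values)
  idx <- match(samples, qpcr$sample_id)
  keep <- !is.na(idx)
  if (!any(keep)) data_error("no sample has a qPCR record")
  removed <- stats::setNames(rep("no qPCR record", sum(!keep)), samples[!keep])
  values <- table$values[, keep, drop = FALSE]
  totals <- qpcr$copies_per_ng_dna[idx[keep]]
  out <- ft_replace(table, sweep(values, 2L, totals, "*"))
  out$unit <- "copies_per_ng_dna"
  report <- new_filter_report(
    "qseq", removed, character(), thresholds = list(),
    dim_before = dim(table$values), dim_after = dim(out$values))
  list(table = out, report = report)
}
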