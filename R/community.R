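#' Total absolute abundance of the active community
#'
#' Sums the absolute abundance (gene copies per ng DNA) of active taxa,
#' aggregated to a taxonomic rank (default genus), per replicate core and
#' then averaged within each treatment group. By default only the heavy
#' and medium density groups of labeled (\eqn{^{13}}C) cores are summed —
#' the groups banding above the labeled treatment's community WAD — so
#' the total reflects the community that assimilated the substrate.
#' Density groups missing from a core contribute zero (noted via
#' `message()`); a core contributing none of the requested groups is
#' excluded with a warning. With a single core in a group the dispersion
#' columns are `NA`, not zero.
#'
#' @param table A [feature_table()] with unit `copies_per_ng_dna`.
#' @param metadata Sample metadata (see [read_sample_metadata()]); must
#'   cover the table's samples and include `density_group`.
#' @param active Either a [qsip()] fit (active sets taken per treatment
#'   group) or a character vector of taxon ids applied to every group.
#' @param rank Taxonomy rank to aggregate to (default `"genus"`); taxa
#'   without the rank keep their own id as label. Requires the table's
#'   taxonomy; with no taxonomy, ASVs are reported unaggregated.
#' @param density_groups Density groups to sum (default heavy + medium).
#' @param isotopes Isotope codes of the cores to include (default
#'   `"13C"`).
#' @param group_by Metadata columns defining treatment groups.
#' @return A data.frame of class `community_profile`: one row per
#'   treatment group x taxon with `mean`, `sd`, `se`, `n_cores`; per-core
#'   totals in `attr(, "per_core")`, and per-group active ASV/label counts
#'   in `attr(, "counts")`.
#' @export
total_active_abundance <- function(table, metadata, active,
                                   rank = "genus",
                                   density_groups = c("heavy", "medium"),
                                   isotopes = "13C",
                                   group_by = c("wetland", "redox")) {
  stopifnot(inherits(table, "feature_table"))
  if (table$unit != "copies_per_ng_dna") {
    warning("community totals are meant for QSEQ-normalized absolute abundances")
  }
  need <- c("sample_id", "core_id", "isotope", "density_group", group_by)
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols)) {
    data_error(sprintf("metadata is missing column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  samples <- colnames(table$values)
  meta <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) data_error("metadata does not cover all samples")
  grp_label <- apply(meta[group_by], 1L, paste, collapse = " / ")

  from_fit <- inherits(active, "qsip_fit")
  if (!from_fit && !is.character(active)) {
    data_error("`active` must be a qsip_fit or a character vector of taxon ids")
  }
  if (from_fit && length(active$results) == 0L) data_error("empty fit")

  # taxon -> reporting label at `rank`
  labels <- stats::setNames(rownames(table$values), rownames(table$values))
  phyla <- stats::setNames(rep(NA_character_, nrow(table$values)),
                           rownames(table$values))
  if (!is.null(table$taxonomy)) {
    tx <- table$taxonomy
    m <- match(names(labels), tx$taxon_id)
    if (rank %in% names(tx)) {
      lab <- as.character(tx[[rank]][m])
      ok <- !is.na(m) & !is.na(lab) & nzchar(lab)
      labels[ok] <- lab[ok]
    }
    if ("phylum" %in% names(tx)) phyla[!is.na(m)] <- as.character(tx$phylum[m[!is.na(m)]])
  }

  rows <- list(); per_core <- list(); counts <- list()
  for (g in unique(grp_label)) {
    in_grp <- grp_label == g
    act <- if (from_fit) {
      r <- active$results
      r$taxon_id[r$group == g & r$active]
    } else active
    act <- intersect(act, rownames(table$values))
    if (!length(act)) next
    cores <- unique(meta$core_id[in_grp & meta$isotope %in% isotopes])
    totals <- NULL
    kept_cores <- character()
    for (cid in cores) {
      cols <- which(in_grp & meta$core_id == cid &
                      meta$density_group %in% density_groups)
      if (!length(cols)) {
        warning(sprintf("core %s has none of the requested density groups; excluded", cid))
        next
      }
      miss <- setdiff(density_groups, meta$density_group[cols])
      if (length(miss)) {
        message(sprintf("core %s missing density group(s) %s; contributing 0",
                        cid, paste(miss, collapse = ", ")))
      }
      asv_tot <- rowSums(table$values[act, samples[cols], drop = FALSE])
      tot <- rowsum(asv_tot, labels[act])
      totals <- if (is.null(totals)) tot else {
        all_lab <- union(rownames(totals), rownames(tot))
        a <- matrix(0, length(all_lab), ncol(totals) + 1L,
                    dimnames = list(all_lab, NULL))
        a[rownames(totals), seq_len(ncol(totals))] <- totals
        a[rownames(tot), ncol(totals) + 1L] <- tot
        a
      }
      kept_cores <- c(kept_cores, cid)
    }
    if (is.null(totals)) next
    colnames(totals) <- kept_cores
    nc <- ncol(totals)
    mu <- rowMeans(totals)
    sdv <- if (nc > 1L) apply(totals, 1L, stats::sd) else rep(NA_real_, nrow(totals))
    lab_phy <- phyla[match(rownames(totals), labels)]
    rows[[g]] <- data.frame(
      group = g, taxon = rownames(totals), phylum = unname(lab_phy),
      mean = unname(mu), sd = unname(sdv), se = unname(sdv) / sqrt(nc),
      n_cores = nc, stringsAsFactors = FALSE, row.names = NULL)
    per_core[[g]] <- totals
    counts[[g]] <- data.frame(group = g, n_active_asvs = length(act),
                              n_active_labels = nrow(totals),
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) data_error("no active taxa found in any treatment group")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("community_profile", "data.frame"),
            per_core = per_core,
            counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
            rank = rank, density_groups = density_groups, isotopes = isotopes)
}

#' Background absolute abundance of active taxa
#'
#' As [total_active_abundance()], but summed over all density groups and
#' over both the labeled and unlabeled cores, with per-isotope means: the
#' overall ("background") abundance of the taxa identified as active.
#'
#' @inheritParams total_active_abundance
#' @param density_groups Density groups to sum (default all three).
#' @param isotopes Isotope codes to include (default both treatments);
#'   each isotope is summarized separately.
#' @return A `community_profile` with an `isotope` column.
#' @export
background_abundance <- function(table, metadata, active,
                                 rank = "genus",
                                 density_groups = c("light", "medium", "heavy"),
                                 isotopes = c("12C", "13C"),
                                 group_by = c("wetland", "redox")) {
  parts <- lapply(isotopes, function(iso) {
    p <- total_active_abundance(table, metadata, active, rank = rank,
                                density_groups = density_groups,
                                isotopes = iso, group_by = group_by)
    cbind(isotope = iso, as.data.frame(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("community_profile", "data.frame"),
            rank = rank, density_groups = density_groups, isotopes = isotopes)
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("Active-community profile (%s level; density groups: %s)\n",
              attr(x, "rank") %||% "taxon",
              paste(attr(x, "density_groups"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE, digits = 4)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shannon diversity
#'
#' Shannon's H (natural log) of an abundance vector,
#' \eqn{H = -\sum p_i \ln p_i} over positive entries, computed with
#' \pkg{vegan}'s `diversity()`. For a `community_profile`, H is returned
#' per replicate core from the per-core totals.
#'
#' @param x Non-negative abundance vector (at least one positive entry),
#'   or a [total_active_abundance()] profile.
#' @param ... Unused.
#' @return Numeric H in nats (for profiles, a data.frame per group and
#'   core).
#' @export
#' @examples
#' shannon_diversity(rep(5, 4))  # log(4)
shannon_diversity <- function(x, ...) UseMethod("shannon_diversity")

#' @rdname shannon_diversity
#' @export
shannon_diversity.default <- function(x, ...) {
  if (!is.numeric(x)) data_error("`x` must be numeric")
  if (anyNA(x) || any(x < 0)) data_error("abundances must be non-negative and non-missing")
  if (sum(x) == 0) data_error("Shannon diversity of an all-zero vector is undefined")
  unname(vegan::diversity(matrix(x, nrow = 1L), index = "shannon"))
}

#' @rdname shannon_diversity
#' @export
shannon_diversity.community_profile <- function(x, ...) {
  per_core <- attr(x, "per_core")
  if (is.null(per_core)) data_error("profile carries no per-core totals")
  out <- do.call(rbind, lapply(names(per_core), function(g) {
    m <- per_core[[g]]
    data.frame(group = g, core_id = colnames(m),
               shannon = apply(m, 2L, shannon_diversity),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Venn partition of active-taxon sets
#'
#' Partitions the union of up to five named taxon sets into the
#' \eqn{2^k - 1} disjoint Venn regions (taxa in exactly that combination
#' of sets), with counts and memberships — the shared/unique accounting
#' behind Venn diagrams of active communities.
#'
#' @param active_sets Named list of character vectors (2 to 5 sets,
#'   unique names).
#' @return An object of class `overlap_partition`: data.frame with
#'   columns `region` (set names joined by `&`), `degree` and `count`;
#'   region membership lists in `attr(, "members")`.
#' @export
#' @examples
#' overlap_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
overlap_partition <- function(active_sets) {
  if (!is.list(active_sets) || length(active_sets) < 2L || length(active_sets) > 5L) {
    data_error("`active_sets` must be a named list of 2-5 taxon sets")
  }
  nm <- names(active_sets)
  if (is.null(nm) || any(!nzchar(nm))) data_error("every set must be named")
  if (anyDuplicated(nm)) data_error("duplicate set names")
  sets <- lapply(active_sets, function(s) unique(as.character(s)))
  univ <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1L, dimnames = list(NULL, nm))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- nm
  regions <- apply(combos, 1L, function(inc) paste(nm[as.logical(inc)], collapse = "&"))
  members <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- as.logical(combos[i, ])
    hit <- rowSums(member == matrix(inc, nrow(member), k, byrow = TRUE)) == k
    univ[hit]
  })
  names(members) <- regions
  out <- data.frame(region = regions, degree = rowSums(combos),
                    count = lengths(members),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("overlap_partition", "data.frame"),
            members = members, n_union = length(univ))
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("Overlap partition of %d taxa into %d regions:\n",
              attr(x, "n_union"), nrow(x)))
  print.data.frame(as.data.frame(x)[order(x$degree, x$region), ],
                   row.names = FALSE)
  invisible(x)
}
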