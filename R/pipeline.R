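#' Run the full qSIP pipeline from one configuration
#'
#' Orchestrates an end-to-end run in fixed stage order —
#' `simulate` (or `load`), `preprocess`, `qsip`, `summarize` — writing
#' every stage's outputs under `out_dir` together with a run manifest
#' (`manifest.json`) capturing the configuration snapshot, seed, package
#' version, per-stage row counts, output file digests and timestamps.
#' Deterministic stages re-run bit-identically from the same
#' configuration and seed.
#'
#' `config` is a named list (or path to a YAML file) with sections:
#'
#' * `seed`, `out_dir` — run-level controls;
#' * `simulate` — arguments for [simulation_config()]; *or* `input` —
#'   list with paths `counts`, `metadata`, `qpcr` to load instead;
#' * `preprocess` — `depth_k`, `min_count`, `min_prevalence`;
#' * `qsip` — `n_draws`, `group_by`, `labeled`, `unlabeled`, `ci_method`;
#' * `summarize` — `rank`, `density_groups`.
#'
#' Unknown sections or malformed values raise a `qsip_config_error`
#' before any computation; data problems abort the failing stage with a
#' `qsip_data_error` whose `manifest` field records the stages already
#' completed.
#'
#' @param config Named list or YAML path.
#' @param out_dir Output directory (created); overrides `config$out_dir`.
#' @param seed Seed; overrides `config$seed`.
#' @return The run manifest, an object of class `qsip_manifest`,
#'   invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("`config` must be a list or a YAML file path")
  known <- c("seed", "out_dir", "simulate", "input", "preprocess", "qsip",
             "summarize")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    config_error(sprintf("unknown configuration section(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  seed <- seed %||% config$seed
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) config_error("an output directory is required (`out_dir`)")
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L || is.na(seed))) {
    config_error("`seed` must be a single integer")
  }
  if (!is.null(config$simulate) && !is.null(config$input)) {
    config_error("give either a `simulate` section or an `input` section, not both")
  }
  pp <- validate_args(config$preprocess, c("depth_k", "min_count", "min_prevalence"),
                      "preprocess")
  qa <- validate_args(config$qsip, c("n_draws", "group_by", "labeled",
                                     "unlabeled", "ci_method"), "qsip")
  sa <- validate_args(config$summarize, c("rank", "density_groups"), "summarize")
  sim_cfg <- if (is.null(config$input)) {
    do.call(simulation_config, config$simulate %||% list())  # errors early
  } else NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("qsipr")),
                   started = format(Sys.time(), usetz = TRUE),
                   stages = list(), files = character())
  add_stage <- function(name, ...) {
    manifest$stages[[name]] <<- c(list(status = "ok"), list(...))
  }
  emit <- function(path) manifest$files <<- c(manifest$files, path)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <- list(status = "failed",
                                      error = conditionMessage(e))
      finish_manifest(manifest, out_dir)
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = unique(c("qsip_pipeline_error", class(e))),
        manifest = manifest))
    })
  }

  # stage 1: simulate or load -------------------------------------------
  if (is.null(config$input)) {
    sim <- run_stage("simulate", {
      s <- simulate_qsip_experiment(sim_cfg, seed = seed)
      write_feature_table(s$counts, file.path(out_dir, "counts.tsv"))
      utils::write.csv(s$metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
      utils::write.csv(s$qpcr, file.path(out_dir, "qpcr.csv"), row.names = FALSE)
      utils::write.csv(s$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
      s
    })
    emit(c("counts.tsv", "counts.tsv.meta.json", "metadata.csv", "qpcr.csv",
           "truth.csv"))
    add_stage("simulate", n_taxa = nrow(sim$counts$values),
              n_samples = ncol(sim$counts$values))
    counts <- sim$counts; metadata <- sim$metadata; qpcr <- sim$qpcr
  } else {
    loaded <- run_stage("load", {
      inp <- config$input
      for (f in c("counts", "metadata", "qpcr")) {
        if (is.null(inp[[f]])) config_error(sprintf("`input` section needs a `%s` path", f))
      }
      list(counts = read_feature_table(inp$counts),
           metadata = read_sample_metadata(inp$metadata),
           qpcr = read_qpcr_table(inp$qpcr))
    })
    add_stage("load", n_taxa = nrow(loaded$counts$values),
              n_samples = ncol(loaded$counts$values))
    counts <- loaded$counts; metadata <- loaded$metadata; qpcr <- loaded$qpcr
  }

  # stage 2: preprocess ---------------------------------------------------
  norm <- run_stage("preprocess", {
    f1 <- filter_samples_by_depth(counts, k = pp$depth_k %||% 2)
    f2 <- filter_rare_taxa(f1$table, min_count = pp$min_count %||% 3,
                           min_prevalence = pp$min_prevalence %||% 0.02)
    rel <- to_relative_abundance(f2$table)
    f3 <- qseq_normalize(rel, qpcr)
    reports <- list(depth = f1$report, rare_taxa = f2$report, qseq = f3$report)
    jsonlite::write_json(reports, file.path(out_dir, "filter_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    write_feature_table(f3$table, file.path(out_dir, "normalized.tsv"))
    message(sprintf("preprocess: removed %d sample(s) by depth, %d rare taxa, %d sample(s) without qPCR",
                    nrow(f1$report$removed_samples), nrow(f2$report$removed_taxa),
                    nrow(f3$report$removed_samples)))
    f3$table
  })
  emit(c("normalized.tsv", "normalized.tsv.meta.json", "filter_report.json"))
  add_stage("preprocess", n_taxa = nrow(norm$values), n_samples = ncol(norm$values))

  # stage 3: qsip ---------------------------------------------------------
  fit <- run_stage("qsip", {
    fit <- qsip(norm, metadata,
                group_by = qa$group_by %||% c("wetland", "redox"),
                labeled = qa$labeled %||% "13C",
                unlabeled = qa$unlabeled %||% "12C",
                n_draws = qa$n_draws %||% 1000,
                seed = if (is.null(seed)) NULL else seed + 1L,
                ci_method = qa$ci_method %||% "expanded")
    utils::write.csv(fit$results, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
    fit
  })
  emit("enrichment.csv")
  add_stage("qsip", n_estimates = nrow(fit$results),
            n_active = sum(fit$results$active))

  # stage 4: summarize ----------------------------------------------------
  run_stage("summarize", {
    prof <- total_active_abundance(
      norm, metadata, fit, rank = sa$rank %||% "genus",
      density_groups = sa$density_groups %||% c("heavy", "medium"),
      group_by = qa$group_by %||% c("wetland", "redox"))
    utils::write.csv(as.data.frame(prof),
                     file.path(out_dir, "active_community.csv"), row.names = FALSE)
    utils::write.csv(shannon_diversity(prof),
                     file.path(out_dir, "shannon.csv"), row.names = FALSE)
    emit(c("active_community.csv", "shannon.csv"))
    sets <- active_taxa(fit)
    sets <- sets[lengths(sets) > 0L]
    if (length(sets) >= 2L) {
      ov <- overlap_partition(sets[seq_len(min(5L, length(sets)))])
      jsonlite::write_json(
        list(regions = as.data.frame(ov), members = attr(ov, "members")),
        file.path(out_dir, "overlap.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA)
      emit("overlap.json")
    }
    NULL
  })
  add_stage("summarize")

  manifest <- finish_manifest(manifest, out_dir)
  invisible(manifest)
}

validate_args <- function(section, allowed, name) {
  section <- section %||% list()
  if (!is.list(section)) {
    config_error(sprintf("configuration section `%s` must be a list", name))
  }
  unknown <- setdiff(names(section), allowed)
  if (length(unknown)) {
    config_error(sprintf("unknown `%s` option(s): %s", name,
                         paste(unknown, collapse = ", ")))
  }
  section
}

finish_manifest <- function(manifest, out_dir) {
  files <- unique(manifest$files)
  digests <- vapply(files, function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }, "")
  manifest$files <- data.frame(file = files, md5 = unname(digests),
                               stringsAsFactors = FALSE)
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  out <- structure(manifest, class = "qsip_manifest")
  json <- manifest
  json$config <- rapply(json$config, function(x) x, how = "replace")
  jsonlite::write_json(unclass(json), file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  out
}

#' @export
print.qsip_manifest <- function(x, ...) {
  cat(sprintf("qSIP pipeline run (qsipr %s), seed %s\n", x$package_version,
              x$seed %||% "none"))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    extras <- setdiff(names(st), "status")
    cat(sprintf("  %-10s %s%s\n", s, st$status,
                if (length(extras)) paste0(" (", paste(extras, unlist(st[extras]),
                                                       sep = "=", collapse = ", "), ")")
                else ""))
  }
  cat(sprintf("  %d output file(s)\n", nrow(x$files)))
  invisible(x)
}
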