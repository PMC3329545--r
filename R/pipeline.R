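#' Validate and normalise a pipeline run configuration
#'
#' A run configuration is a plain named list (typically read from a YAML
#' document with [read_run_config()]) describing a full analysis:
#'
#' * `samples`: named list mapping sample id to an expression TSV path,
#'   or the string `"synthetic"` to simulate the default study;
#' * `collections`: named list mapping a type label (`GO`, `pathway`,
#'   `synthetic`) to a GMT or GAF path;
#' * tuning fields with defaults: `collapse` (`"median"`), `min_size`
#'   (3), `max_size` (`NULL`, meaning universe size − 1), `n_perm`
#'   (10000), `alpha` (0.01), `top_k` (20), `min_samples` (2),
#'   `rank_by` (`"es"`), `seed` (1);
#' * optional `focus`: list with `set` and `gene` for a focal report;
#' * optional `synthetic`: list of [synthetic_config()] overrides used
#'   when `samples` is `"synthetic"` (the seed always comes from `seed`);
#' * `out_dir`: output directory.
#'
#' @param config named list as above.
#' @return the validated config with defaults filled, class `run_config`.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(collapse = "median", min_size = 3, max_size = NULL,
                   n_perm = 10000, alpha = 0.01, top_k = 20,
                   min_samples = 2, rank_by = "es", seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  synthetic <- identical(config$samples, "synthetic")
  if (!synthetic) {
    if (!is.list(config$samples) || is.null(names(config$samples)) ||
        length(config$samples) == 0) {
      abort("config field `samples` must be a named list of TSV paths, or \"synthetic\"")
    }
    missing <- unlist(config$samples)[!file.exists(unlist(config$samples))]
    if (length(missing) > 0) {
      abort(paste0("sample path(s) do not exist: ", paste(missing, collapse = ", ")))
    }
    if (is.null(config$collections) || !is.list(config$collections) ||
        is.null(names(config$collections))) {
      abort("config field `collections` must be a named list of GMT/GAF paths")
    }
    missing <- unlist(config$collections)[!file.exists(unlist(config$collections))]
    if (length(missing) > 0) {
      abort(paste0("collection path(s) do not exist: ", paste(missing, collapse = ", ")))
    }
  }
  if (!(config$n_perm >= 1)) abort("config field `n_perm` must be >= 1")
  if (!(config$alpha > 0 && config$alpha < 1)) {
    abort("config field `alpha` must lie in (0, 1)")
  }
  if (!config$collapse %in% c("median", "mean")) {
    abort("config field `collapse` must be \"median\" or \"mean\"")
  }
  if (!config$rank_by %in% c("es", "p")) {
    abort("config field `rank_by` must be \"es\" or \"p\"")
  }
  if (!(config$top_k >= 1 && config$min_samples >= 1 && config$min_size >= 1)) {
    abort("config fields `top_k`, `min_samples`, `min_size` must be >= 1")
  }
  if (is.null(config$out_dir)) abort("config field `out_dir` is required")
  config$seed <- as.integer(config$seed)
  structure(config, class = c("run_config", "list"))
}

#' Read a YAML run configuration
#'
#' @param path YAML file; fields as in [validate_config()]. Relative
#'   sample/collection paths are resolved against the YAML file's
#'   directory.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  config <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rebase <- function(p) {
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  }
  if (is.list(config$samples)) config$samples <- lapply(config$samples, rebase)
  if (is.list(config$collections)) {
    config$collections <- lapply(config$collections, rebase)
  }
  validate_config(config)
}

#' Run the full enrichment pipeline
#'
#' Orchestrates simulate/read -> collapse -> rank -> enrich -> report.
#' For every sample and collection type it writes a per-sample
#' enrichment TSV; for every direction and collection type a
#' cross-sample table; optionally a focal report; and a run-metadata
#' JSON. Identical config and seed give identical outputs.
#'
#' @param config a validated `run_config` (see [validate_config()]); a
#'   plain list is validated first.
#' @param quiet suppress stage messages (default `FALSE`).
#' @return (invisibly) a list with `results` (named by sample), `genes`
#'   (named by sample), `tables` (cross-sample tables), `focus` (or
#'   `NULL`), and `paths` of everything written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) inform(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  stage <- function(name, sample, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed for %s: %s",
                    name, sample, conditionMessage(e)))
    })
  }

  # --- inputs ---------------------------------------------------------
  if (identical(config$samples, "synthetic")) {
    say("simulate: generating the synthetic study (seed %d)", config$seed)
    args <- config$synthetic %||% list()
    args$seed <- config$seed
    study <- generate_study(do.call(synthetic_config, args))
    probes_by_sample <- study$samples
    collections <- list(synthetic = study$collection)
    truth_path <- file.path(config$out_dir, "truth.json")
    write_truth(study$truth, truth_path)
    paths$truth <- truth_path
  } else {
    probes_by_sample <- lapply(setNames(nm = names(config$samples)), function(s) {
      stage("read_expression", s, read_expression_tsv(config$samples[[s]], s))
    })
    collections <- lapply(setNames(nm = names(config$collections)), function(type) {
      p <- config$collections[[type]]
      stage("read_collection", type, {
        if (grepl("\\.gaf(\\.txt)?$", p, ignore.case = TRUE)) read_gaf(p)
        else read_gmt(p, source = type)
      })
    })
  }

  # --- collapse & rank ------------------------------------------------
  genes_by_sample <- lapply(setNames(nm = names(probes_by_sample)), function(s) {
    stage("collapse", s, collapse_probes(probes_by_sample[[s]], config$collapse))
  })
  ranked_by_sample <- lapply(genes_by_sample, rank_genes)
  for (s in names(genes_by_sample)) {
    n_diff <- nrow(flag_differential(genes_by_sample[[s]], config$alpha))
    say("collapse: %s -> %d genes (%d probes), %d differential at alpha=%g",
        s, nrow(genes_by_sample[[s]]), nrow(probes_by_sample[[s]]),
        n_diff, config$alpha)
  }

  # --- enrich ---------------------------------------------------------
  results_by_sample <- list()
  for (s in names(ranked_by_sample)) {
    universe <- ranked_by_sample[[s]]$gene
    per_type <- lapply(setNames(nm = names(collections)), function(type) {
      restricted <- suppressMessages(restrict_to_universe(
        collections[[type]], universe,
        min_size = config$min_size, max_size = config$max_size))
      n_kept <- length(unique(restricted$set))
      say("enrich: %s / %s -> %d sets after size filter", s, type, n_kept)
      stage("enrich", paste(s, type, sep = "/"),
            rank_gene_sets(restricted, ranked_by_sample[[s]],
                           n_perm = config$n_perm,
                           seed = config$seed + match(s, names(ranked_by_sample)),
                           rank_by = config$rank_by))
    })
    combined <- dplyr::bind_rows(lapply(per_type, tidy), .id = "collection")
    res_path <- file.path(config$out_dir, sprintf("enrichment_%s.tsv", s))
    utils::write.table(combined, res_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$results[[s]] <- res_path
    results_by_sample[[s]] <- combined
  }

  # --- cross-sample tables --------------------------------------------
  tables <- list()
  for (type in names(collections)) {
    for (direction in c("up", "down")) {
      key <- paste(type, direction, sep = "_")
      subset_results <- lapply(results_by_sample, function(r) {
        r[r$collection == type, ]
      })
      tbl <- cross_sample_table(subset_results, direction,
                                top_k = config$top_k,
                                min_samples = config$min_samples)
      tbl_path <- file.path(config$out_dir, sprintf("cross_sample_%s.tsv", key))
      utils::write.table(tbl, tbl_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths$tables[[key]] <- tbl_path
      tables[[key]] <- tbl
    }
  }

  # --- focus report ---------------------------------------------------
  focus <- NULL
  if (!is.null(config$focus)) {
    focus <- stage("focus", config$focus$set,
                   focus_report(results_by_sample, config$focus$set,
                                config$focus$gene, genes_by_sample))
    focus_path <- file.path(config$out_dir, "focus_report.tsv")
    utils::write.table(focus, focus_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$focus <- focus_path
  }

  # --- metadata -------------------------------------------------------
  meta <- list(
    seed = config$seed, n_perm = config$n_perm, collapse = config$collapse,
    rank_by = config$rank_by, alpha = config$alpha,
    top_k = config$top_k, min_samples = config$min_samples,
    samples = names(probes_by_sample),
    collections = lapply(collections, function(cc) length(unique(cc$set))),
    package_version = as.character(utils::packageVersion("fluidgsea")),
    r_version = R.version.string
  )
  meta_path <- file.path(config$out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$metadata <- meta_path

  invisible(list(results = results_by_sample, genes = genes_by_sample,
                 tables = tables, focus = focus, paths = paths))
}
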