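#' Cross-sample enrichment table
#'
#' Collates per-sample enrichment results into one row per gene set that
#' is highly ranked in several samples: a set qualifies when its rank in
#' the given direction is at most `top_k` in at least `min_samples`
#' samples. Each sample contributes a `(rank, p)` cell when the set makes
#' its top `top_k`, and is absent (`NA`) otherwise. Rows are ordered by
#' the number of populated cells (descending), then by the best rank,
#' then by set name.
#'
#' @param results_by_sample named list of `gsea_result` tibbles from
#'   [rank_gene_sets()], one per sample (names are sample ids), or a
#'   single tibble with a `sample` column.
#' @param direction `"up"` or `"down"`.
#' @param top_k rank cutoff for a populated cell (default 20).
#' @param min_samples minimum number of populated cells (default 2).
#' @return tibble with columns `direction`, `source`, `set`,
#'   `n_samples`, then `rank_<sample>` and `p_<sample>` pairs per sample;
#'   empty (zero rows) when no set qualifies.
#' @export
cross_sample_table <- function(results_by_sample, direction = c("up", "down"),
                               top_k = 20, min_samples = 2) {
  direction <- match.arg(direction)
  stopifnot(top_k >= 1, min_samples >= 1)
  combined <- bind_sample_results(results_by_sample)
  samples <- unique(combined$sample)
  if (length(samples) < 2) abort("need results from at least 2 samples")

  cells <- combined |>
    dplyr::filter(.data$direction == !!direction, .data$rank <= top_k) |>
    dplyr::select("sample", "source", "set", "rank", "p_value")
  qualifying <- cells |>
    dplyr::count(.data$set, name = "n_samples") |>
    dplyr::filter(.data$n_samples >= min_samples)
  if (nrow(qualifying) == 0) {
    return(tibble::tibble(direction = character(), source = character(),
                          set = character(), n_samples = integer()))
  }
  wide <- cells |>
    dplyr::semi_join(qualifying, by = "set") |>
    tidyr::pivot_wider(id_cols = c("source", "set"),
                       names_from = "sample",
                       values_from = c("rank", "p_value"),
                       names_glue = "{.value}_{sample}") |>
    dplyr::left_join(qualifying, by = "set") |>
    dplyr::mutate(direction = direction, .before = 1)
  # keep a rank/p column pair for every sample, even if never populated
  for (s in samples) {
    for (col in c(paste0("rank_", s), paste0("p_value_", s))) {
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
    }
  }
  rank_cols <- paste0("rank_", samples)
  wide$best_rank <- do.call(pmin, c(wide[rank_cols], na.rm = TRUE))
  wide <- wide |>
    dplyr::arrange(dplyr::desc(.data$n_samples), .data$best_rank, .data$set) |>
    dplyr::select("direction", "source", "set", "n_samples",
                  dplyr::all_of(as.vector(rbind(rank_cols, paste0("p_value_", samples)))))
  wide
}

bind_sample_results <- function(results_by_sample) {
  if (is.data.frame(results_by_sample)) {
    if (!"sample" %in% names(results_by_sample)) {
      abort("a single results tibble must carry a `sample` column")
    }
    return(tibble::as_tibble(unclass_result(results_by_sample)))
  }
  if (!is.list(results_by_sample) || is.null(names(results_by_sample)) ||
      any(names(results_by_sample) == "")) {
    abort("`results_by_sample` must be a named list of gsea_result tibbles")
  }
  dplyr::bind_rows(lapply(results_by_sample, function(r) {
    tibble::as_tibble(unclass_result(r))
  }), .id = "sample")
}

#' Focal pathway and focal gene report
#'
#' Summarises, per sample, how one pathway of interest behaves (the
#' direction with the larger enrichment score, its rank, score and
#' permutation p-value) next to a focal gene's own expression (gene-level
#' log-ratio and t-test p-value). The `concordant` flag records whether
#' the focal gene moved with the pathway: `TRUE` when the sign of its
#' log-ratio matches the pathway direction (up means positive). A focal
#' gene absent from a sample's expression table yields `NA` focal fields
#' for that sample, not an error.
#'
#' @param results_by_sample named list of `gsea_result` tibbles (or a
#'   single tibble with a `sample` column).
#' @param set_name pathway to report; must occur in at least one sample's
#'   results (error otherwise).
#' @param focal_gene gene symbol tracked against the pathway.
#' @param genes_by_sample named list of gene-level tibbles from
#'   [collapse_probes()] (or a single tibble with a `sample` column).
#' @return tibble with one row per sample: `sample`, `set`, `direction`,
#'   `direction_tied`, `rank`, `es`, `p_value`, `focal_gene`,
#'   `focal_log_ratio`, `focal_p_value`, `concordant`.
#' @export
focus_report <- function(results_by_sample, set_name, focal_gene,
                         genes_by_sample) {
  results <- bind_sample_results(results_by_sample)
  genes <- if (is.data.frame(genes_by_sample)) {
    if (!"sample" %in% names(genes_by_sample)) {
      abort("a single gene table must carry a `sample` column")
    }
    genes_by_sample
  } else {
    dplyr::bind_rows(genes_by_sample, .id = "sample")
  }
  hits <- dplyr::filter(results, .data$set == set_name)
  if (nrow(hits) == 0) {
    abort(sprintf("set %s not found in any sample's results", set_name))
  }
  samples <- unique(results$sample)
  rows <- lapply(samples, function(s) {
    h <- dplyr::filter(hits, .data$sample == s)
    if (nrow(h) == 0) {
      abort(sprintf("set %s missing from sample %s", set_name, s))
    }
    up <- h[h$direction == "up", ]
    down <- h[h$direction == "down", ]
    tied <- isTRUE(all.equal(up$es, down$es))
    pick <- if (tied || up$es >= down$es) up else down
    g <- genes[genes$sample == s & genes$gene == focal_gene, ]
    has_focal <- nrow(g) == 1
    lr <- if (has_focal) g$log_ratio else NA_real_
    tibble::tibble(
      sample = s,
      set = set_name,
      direction = pick$direction,
      direction_tied = tied,
      rank = pick$rank,
      es = pick$es,
      p_value = pick$p_value,
      focal_gene = focal_gene,
      focal_log_ratio = lr,
      focal_p_value = if (has_focal) g$p_value else NA_real_,
      concordant = if (has_focal) {
        (pick$direction == "up") == (lr > 0)
      } else NA
    )
  })
  dplyr::bind_rows(rows)
}

#' Render a cross-sample table as text
#'
#' Formats a [cross_sample_table()] as a Markdown pipe table (or TSV)
#' with `rank (p)` cells and `-` for absent entries, mirroring how such
#' tables are conventionally printed.
#'
#' @param tbl a cross-sample table.
#' @param path optional output file; when `NULL` the lines are returned.
#' @param format `"markdown"` or `"tsv"`.
#' @return character vector of lines, invisibly when written to `path`.
#' @export
format_cross_sample <- function(tbl, path = NULL,
                                format = c("markdown", "tsv")) {
  format <- match.arg(format)
  rank_cols <- grep("^rank_", names(tbl), value = TRUE)
  samples <- sub("^rank_", "", rank_cols)
  cells <- vapply(samples, function(s) {
    r <- tbl[[paste0("rank_", s)]]
    p <- tbl[[paste0("p_value_", s)]]
    ifelse(is.na(r), "-", sprintf("%d (%.4e)", as.integer(r), p))
  }, character(nrow(tbl)))
  if (nrow(tbl) == 1) cells <- matrix(cells, nrow = 1)
  header <- c("direction", "type", "gene set", samples)
  body <- cbind(tbl$direction, tbl$source, tbl$set, cells)
  lines <- if (format == "markdown") {
    c(paste0("| ", paste(header, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
      apply(body, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  } else {
    c(paste(header, collapse = "\t"),
      apply(body, 1, paste, collapse = "\t"))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
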