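#' Read a probe-level log-ratio table
#'
#' One row per probe with columns `probe_id`, `gene_symbol` and
#' `log_ratio` (header required, tab-separated). The log-ratio is
#' log2(Cy5/Cy3) of normalised signal, the pleural channel being Cy5 and
#' the ascitic channel Cy3, so positive values mean higher expression in
#' pleural fluid. Probes with an empty gene symbol or a missing/non-finite
#' log-ratio are discarded with a counted warning.
#'
#' @param path path to the tab-separated file.
#' @param sample_id sample label attached as the `sample` column.
#' @return tibble with columns `sample`, `probe_id`, `gene`, `log_ratio`.
#' @export
read_expression_tsv <- function(path, sample_id = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "gene_symbol", "log_ratio")
  if (!all(need %in% names(raw))) {
    abort(sprintf("expression table %s must have columns: %s",
                  path, paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
    probe_id = raw$probe_id,
    gene = trimws(raw$gene_symbol),
    log_ratio = suppressWarnings(as.numeric(raw$log_ratio))
  )
  no_symbol <- !nzchar(out$gene) | is.na(out$gene)
  bad_value <- !is.finite(out$log_ratio)
  n_drop <- sum(no_symbol | bad_value)
  if (n_drop > 0) {
    warn(sprintf(
      "%s: dropped %d of %d probes (%d without gene symbol, %d non-finite log-ratio)",
      basename(path), n_drop, nrow(out), sum(no_symbol), sum(bad_value & !no_symbol)))
  }
  out <- out[!(no_symbol | bad_value), ]
  if (nrow(out) == 0) abort(sprintf("no usable probes left in %s", path))
  out
}

#' Collapse probe measurements to gene-level scores
#'
#' Summarises replicate probes per gene symbol into one log-ratio (median
#' by default, robust to outlier probes) and tests each gene for
#' differential expression with a two-sided one-sample Student's t-test of
#' its probe log-ratios against zero. The p-value is defined only when a
#' gene has at least two probes with non-zero spread; otherwise it is
#' `NA`.
#'
#' @param probes tibble with columns `gene` and `log_ratio`, one row per
#'   probe (see [read_expression_tsv()]); non-finite log-ratios are
#'   dropped with a counted warning.
#' @param method probe summary: `"median"` (default) or `"mean"`.
#' @return tibble with one row per gene: `gene`, `log_ratio`, `p_value`,
#'   `n_probes`; additional identifying columns (e.g. `sample`) are kept
#'   if constant per gene.
#' @examples
#' probes <- tibble::tibble(gene = c("A", "A", "A"),
#'                          log_ratio = c(1.0, 1.1, 0.9))
#' collapse_probes(probes)
#' @export
collapse_probes <- function(probes, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!is.data.frame(probes) || !all(c("gene", "log_ratio") %in% names(probes))) {
    abort("`probes` must have columns `gene` and `log_ratio`")
  }
  bad <- !is.finite(probes$log_ratio) | !nzchar(probes$gene) | is.na(probes$gene)
  if (any(bad)) {
    warn(sprintf("collapse_probes: dropped %d probes with missing symbol or non-finite log-ratio",
                 sum(bad)))
    probes <- probes[!bad, ]
  }
  if (nrow(probes) == 0) abort("no probes left after filtering")
  summarise_fun <- if (method == "median") median else mean
  grouping <- if ("sample" %in% names(probes)) c("sample", "gene") else "gene"
  probes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      p_value = one_sample_t_pvalue(.data$log_ratio),
      n_probes = dplyr::n(),
      log_ratio = summarise_fun(.data$log_ratio),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(grouping), "log_ratio", "p_value", "n_probes")
}

# Two-sided one-sample t-test of x against 0; NA when it is undefined
# (single observation, or zero spread where the statistic diverges).
one_sample_t_pvalue <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  t_stat <- mean(x) / (s / sqrt(n))
  2 * pt(-abs(t_stat), df = n - 1)
}

#' Flag differentially expressed genes
#'
#' Keeps genes whose per-gene t-test p-value is defined and below `alpha`
#' (the conventional 0.01 cut corresponds to a 99% confidence that the
#' gene is differentially expressed). This flag is reporting metadata:
#' ranked lists for enrichment always use all genes.
#'
#' @param genes gene-level tibble from [collapse_probes()].
#' @param alpha significance threshold in (0, 1); default 0.01.
#' @return the qualifying subset of `genes`, input order preserved.
#' @export
flag_differential <- function(genes, alpha = 0.01) {
  stopifnot(is.data.frame(genes), "p_value" %in% names(genes))
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    abort("`alpha` must be a single number in (0, 1)")
  }
  genes[!is.na(genes$p_value) & genes$p_value < alpha, ]
}

#' Build the ranked gene list for enrichment
#'
#' Orders genes by decreasing log-ratio (`direction = "up"`); the
#' down-regulated list is the exact reversal of the up list, so the same
#' running-sum score read off the reversed list measures enrichment of
#' down-regulated genes. Ties in score are broken by stable input order,
#' keeping the ranking deterministic.
#'
#' @param genes gene-level tibble with columns `gene` and `log_ratio`;
#'   gene symbols must be distinct (collapse probes first).
#' @param direction `"up"` (default) or `"down"`.
#' @return tibble with columns `rank`, `gene`, `score`, ordered by rank;
#'   the direction is stored in `attr(, "direction")`.
#' @export
rank_genes <- function(genes, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(genes), all(c("gene", "log_ratio") %in% names(genes)))
  if (nrow(genes) < 2) abort("need at least 2 genes to rank")
  if (anyDuplicated(genes$gene)) {
    abort("duplicate gene symbols; collapse probes to gene level first")
  }
  ord <- order(-genes$log_ratio)  # radix: stable for ties
  if (direction == "down") ord <- rev(ord)
  out <- tibble::tibble(
    rank = seq_len(nrow(genes)),
    gene = genes$gene[ord],
    score = genes$log_ratio[ord]
  )
  attr(out, "direction") <- direction
  out
}
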