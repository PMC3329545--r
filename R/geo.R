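#' Read a GEO-style series-matrix expression table
#'
#' Minimal reader for the processed series-matrix dialect used by GEO
#' two-colour submissions: `!`-prefixed metadata lines, a table delimited
#' by `!series_matrix_table_begin` / `!series_matrix_table_end` (or
#' simply the first non-`!` block), first column `ID_REF`, one column of
#' normalised log2(Cy5/Cy3) values per sample. A platform probe-to-symbol
#' map turns the table into the package's probe tibble dialect. Intended
#' for accession-level reproduction runs against deposited data; it
#' performs no download itself.
#'
#' @param path series-matrix text file.
#' @param probe_map tibble mapping `probe_id` to `gene_symbol`.
#' @param sample_ids optional rename map: names are column headers in the
#'   file, values the sample ids to use.
#' @return probe tibble with columns `sample`, `probe_id`, `gene`,
#'   `log_ratio` (long format, one row per probe and sample).
#' @export
read_series_matrix <- function(path, probe_map, sample_ids = NULL) {
  stopifnot(file.exists(path))
  stopifnot(is.data.frame(probe_map),
            all(c("probe_id", "gene_symbol") %in% names(probe_map)))
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) == 1 && length(end) == 1) {
    block <- lines[(begin + 1):(end - 1)]
  } else {
    block <- lines[!startsWith(lines, "!") & nzchar(lines)]
  }
  tab <- utils::read.delim(text = paste(block, collapse = "\n"),
                           header = TRUE, sep = "\t", check.names = FALSE)
  if (!identical(names(tab)[1], "ID_REF")) {
    abort("series-matrix table must start with an ID_REF column")
  }
  long <- tidyr::pivot_longer(tab, -"ID_REF", names_to = "sample",
                              values_to = "log_ratio")
  if (!is.null(sample_ids)) {
    long$sample <- dplyr::recode(long$sample, !!!as.list(sample_ids))
  }
  out <- long |>
    dplyr::rename(probe_id = "ID_REF") |>
    dplyr::inner_join(
      tibble::tibble(probe_id = as.character(probe_map$probe_id),
                     gene = trimws(probe_map$gene_symbol)),
      by = "probe_id") |>
    dplyr::filter(nzchar(.data$gene), is.finite(.data$log_ratio)) |>
    dplyr::select("sample", "probe_id", "gene", "log_ratio")
  out$probe_id <- as.character(out$probe_id)
  out
}
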