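#' Running-sum enrichment score
#'
#' For a ranked list `L = g1..gN` and a gene set `S` with `N_S` members
#' present in the list, define the running sum
#' `f(i) = (#members at rank <= i) / N_S - (#non-members at rank <= i) / (N - N_S)`.
#' Walking down the list, `f` takes an up increment `1/N_S` at a member
#' and a down increment `1/(N - N_S)` otherwise; the enrichment score is
#' `ES(S) = max_i f(i)`. Because `f(N) = 0`, the score lies in `[0, 1]`,
#' reaching 1 exactly when all members occupy the top `N_S` ranks. It
#' depends only on the member rank positions, never on score magnitudes.
#'
#' @param ranked a ranked gene list from [rank_genes()] (tibble with a
#'   `gene` column in rank order), or a plain character vector of genes in
#'   rank order.
#' @param members character vector of member gene symbols; only members
#'   present in the ranked list count towards `N_S`.
#' @return the enrichment score, a number in `[0, 1]`.
#' @examples
#' genes <- paste0("G", 1:10)
#' enrichment_score(genes, c("G1", "G2", "G3"))  # 1: members at the top
#' enrichment_score(genes, c("G1", "G3", "G5"))  # 5/7
#' @export
enrichment_score <- function(ranked, members) {
  genes <- ranked_gene_vector(ranked)
  pos <- which(genes %in% members)
  es_from_positions(pos, length(genes))
}

ranked_gene_vector <- function(ranked) {
  if (is.character(ranked)) return(ranked)
  if (is.data.frame(ranked) && "gene" %in% names(ranked)) return(ranked$gene)
  abort("`ranked` must be a ranked gene list tibble or a character vector")
}

# ES from sorted member rank positions. f increases only at member
# positions, so the maximum of f is attained at one of them:
# f(p_j) = j/n_s - (p_j - j)/(n - n_s) for the j-th member position p_j.
es_from_positions <- function(positions, n) {
  n_s <- length(positions)
  if (n_s == 0 || n_s >= n) {
    abort(sprintf(
      "degenerate gene set: %d of %d listed genes are members (need 0 < N_S < N)",
      n_s, n))
  }
  p <- sort.int(positions, method = "radix")
  j <- seq_len(n_s)
  max(j / n_s - (p - j) / (n - n_s))
}

#' Exhaustive null distribution of the enrichment score
#'
#' Because the score depends only on which rank positions the members
#' occupy, the exact gene-permutation null for list length `n` and set
#' size `n_s` is the multiset of scores over all `choose(n, n_s)` member
#' position subsets. Practical only for small `n`; the Monte-Carlo null
#' in [permutation_pvalue()] covers the rest.
#'
#' @param n ranked list length.
#' @param n_s set size, `1 <= n_s < n`.
#' @param guard refuse enumeration beyond this many subsets (default 1e6).
#' @return numeric vector of length `choose(n, n_s)` with one score per
#'   subset.
#' @export
exhaustive_null <- function(n, n_s, guard = 1e6) {
  stopifnot(n_s >= 1, n_s < n)
  n_subsets <- choose(n, n_s)
  if (n_subsets > guard) {
    abort(sprintf(
      "choose(%d, %d) = %.3g subsets exceeds the enumeration guard; use the Monte-Carlo null",
      n, n_s, n_subsets))
  }
  apply(combn(n, n_s), 2, es_from_positions, n = n)
}

#' Gene-permutation p-value for an observed enrichment score
#'
#' Permuting gene labels uniformly at random is equivalent to placing the
#' set's `N_S` members on a uniform random `N_S`-subset of rank
#' positions, which is how the null is sampled here. The p-value is the
#' fraction of permutations whose score STRICTLY exceeds the observed
#' one; zero is a legal value (no pseudo-count by default). Setting
#' `smooth = TRUE` adds the conventional +1 to numerator and denominator.
#'
#' @param es_obs observed enrichment score.
#' @param n ranked list length.
#' @param n_s set size, `1 <= n_s < n`.
#' @param n_perm number of permutations (default 10000).
#' @param smooth add-one smoothing, default `FALSE`.
#' @param null optional pre-computed vector of null scores (e.g. shared
#'   across equal-size sets); when supplied, `n_perm` is ignored.
#' @return the permutation p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(es_obs, n, n_s, n_perm = 10000,
                               smooth = FALSE, null = NULL) {
  if (is.null(null)) {
    null <- sample_null(n, n_s, n_perm)
  }
  exceed <- sum(null > es_obs)
  if (smooth) (exceed + 1) / (length(null) + 1) else exceed / length(null)
}

# n_perm Monte-Carlo draws of the null ES for list length n, set size n_s
sample_null <- function(n, n_s, n_perm) {
  vapply(seq_len(n_perm),
         function(i) es_from_positions(sample.int(n, n_s), n),
         numeric(1))
}

#' Score and rank a whole gene-set collection in both directions
#'
#' Computes, for every set in the collection, the running-sum enrichment
#' score and its gene-permutation p-value on the up-regulated list and on
#' its exact reversal (the down-regulated list), then ranks the sets
#' within each direction. The permutation null depends only on the list
#' length and the set size, so by default one batch of `n_perm` draws is
#' shared across all sets of equal size (`share_null = FALSE` draws a
#' fresh null per set, at identical statistical behaviour).
#'
#' @param collection a gene-set collection tibble, ideally already passed
#'   through [restrict_to_universe()]; sets with a degenerate intersected
#'   size (0 or N) raise an error.
#' @param ranked the up-direction ranked list from [rank_genes()].
#' @param n_perm number of permutations per null (default 10000).
#' @param seed integer seed for the permutation stream; `NULL` leaves the
#'   RNG state alone.
#' @param rank_by rank sets within a direction by `"es"` descending
#'   (default) or `"p"` ascending; ties share the smallest rank, rows are
#'   ordered stably by set name within ties.
#' @param share_null reuse one null per set size (default `TRUE`).
#' @param smooth add-one smoothing of p-values, default `FALSE`.
#' @return a `gsea_result` tibble with one row per set and direction:
#'   `set`, `source`, `direction`, `n_s`, `es`, `p_value`, `rank`, `n`;
#'   run metadata (`n_perm`, `seed`, `n_genes`, `n_sets`) is stored in
#'   attributes and surfaced by [glance()].
#' @export
rank_gene_sets <- function(collection, ranked, n_perm = 10000, seed = NULL,
                           rank_by = c("es", "p"), share_null = TRUE,
                           smooth = FALSE) {
  rank_by <- match.arg(rank_by)
  check_collection(collection)
  genes <- ranked_gene_vector(ranked)
  n <- length(genes)
  sets <- collection_sets(collection)
  if (length(sets) == 0) abort("empty collection")
  src <- collection_source(collection)

  if (!is.null(seed)) set.seed(seed)
  pos_up <- lapply(sets, function(m) which(genes %in% m))
  n_s <- lengths(pos_up)
  degenerate <- n_s == 0 | n_s >= n
  if (any(degenerate)) {
    abort(paste0("degenerate set(s) after intersection with the ranked list: ",
                 paste(names(sets)[degenerate], collapse = ", "),
                 "; run restrict_to_universe() first"))
  }
  es_up <- vapply(pos_up, es_from_positions, numeric(1), n = n)
  # member positions on the reversed list
  es_down <- vapply(pos_up, function(p) es_from_positions(n + 1L - p, n),
                    numeric(1))

  if (share_null) {
    nulls <- lapply(setNames(nm = sort(unique(n_s))),
                    function(k) sample_null(n, k, n_perm))
    p_up <- vapply(seq_along(sets), function(i) {
      permutation_pvalue(es_up[i], n, n_s[i], null = nulls[[as.character(n_s[i])]],
                         smooth = smooth)
    }, numeric(1))
    p_down <- vapply(seq_along(sets), function(i) {
      permutation_pvalue(es_down[i], n, n_s[i], null = nulls[[as.character(n_s[i])]],
                         smooth = smooth)
    }, numeric(1))
  } else {
    p_up <- vapply(seq_along(sets), function(i) {
      permutation_pvalue(es_up[i], n, n_s[i], n_perm = n_perm, smooth = smooth)
    }, numeric(1))
    p_down <- vapply(seq_along(sets), function(i) {
      permutation_pvalue(es_down[i], n, n_s[i], n_perm = n_perm, smooth = smooth)
    }, numeric(1))
  }

  res <- dplyr::bind_rows(
    tibble::tibble(set = names(sets), source = src, direction = "up",
                   n_s = unname(as.integer(n_s)), es = unname(es_up),
                   p_value = unname(p_up)),
    tibble::tibble(set = names(sets), source = src, direction = "down",
                   n_s = unname(as.integer(n_s)), es = unname(es_down),
                   p_value = unname(p_down))
  )
  res <- res |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(rank = direction_rank(.data$es, .data$p_value, rank_by)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$direction == "up"), .data$rank, .data$set) |>
    dplyr::mutate(n = n)

  new_gsea_result(res, n_perm = n_perm, seed = seed, rank_by = rank_by,
                  n_genes = n, n_sets = length(sets))
}

direction_rank <- function(es, p_value, rank_by) {
  key <- if (rank_by == "es") -es else p_value
  as.integer(rank(key, ties.method = "min"))
}

collection_source <- function(collection) {
  if (!"source" %in% names(collection)) {
    return(rep(NA_character_, length(unique(collection$set))))
  }
  first <- collection[!duplicated(collection$set), ]
  first$source
}

new_gsea_result <- function(tbl, ...) {
  meta <- list(...)
  structure(tbl,
            class = c("gsea_result", class(tbl)),
            meta = meta)
}

#' @export
print.gsea_result <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Gene set enrichment: %d sets x 2 directions, N = %d genes, %d permutations\n",
              meta$n_sets, meta$n_genes, meta$n_perm))
  NextMethod()
}

#' Tidy and summarise enrichment results
#'
#' `tidy()` returns the result rows as a plain tibble; `glance()` returns
#' a one-row run summary (numbers of sets and genes, permutations, seed,
#' ranking mode).
#'
#' @param x a `gsea_result` from [rank_gene_sets()].
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.gsea_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname tidy.gsea_result
#' @exportS3Method generics::glance
glance.gsea_result <- function(x, ...) {
  meta <- attr(x, "meta")
  tibble::tibble(
    n_sets = meta$n_sets,
    n_genes = meta$n_genes,
    n_perm = meta$n_perm,
    seed = meta$seed %||% NA_integer_,
    rank_by = meta$rank_by
  )
}

unclass_result <- function(x) {
  attr(x, "meta") <- NULL
  class(x) <- setdiff(class(x), "gsea_result")
  x
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write enrichment results with run metadata
#'
#' Emits the result rows as TSV and, alongside, a JSON sidecar holding the
#' run metadata (seed, permutations, list and collection sizes).
#'
#' @param x a `gsea_result`.
#' @param path output TSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_gsea_tsv <- function(x, path) {
  tbl <- unclass_result(x)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- attr(x, "meta") %||% list()
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
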