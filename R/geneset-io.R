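#' Gene-set collections as tidy tibbles
#'
#' A gene-set collection is represented throughout the package as a long
#' tibble with one row per (set, gene) membership and columns:
#'
#' * `set` — set name, unique across the collection,
#' * `gene` — member gene symbol, deduplicated within a set,
#' * `source` — `"GO"`, `"pathway"` or `"synthetic"`.
#'
#' The helpers below construct, read, write and filter such tibbles.
#'
#' @param sets named list of character vectors (names are set names).
#' @param source collection source label, recycled across sets.
#' @return a gene-set collection tibble.
#' @examples
#' gene_set_collection(list(A = c("G1", "G2"), B = c("G2", "G3")))
#' @export
gene_set_collection <- function(sets, source = "synthetic") {
  stopifnot(is.list(sets), length(sets) > 0 || TRUE)
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || anyNA(nm) || any(nm == ""))) {
    abort("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate set name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  members <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (any(lengths(members) == 0)) {
    abort("gene sets must be non-empty")
  }
  out <- tibble::tibble(
    set = rep(nm, lengths(members)),
    gene = unlist(members, use.names = FALSE),
    source = rep(rep_len(source, length(members)), lengths(members))
  )
  out
}

#' Convert a collection tibble to a named list of member vectors
#'
#' @param collection a gene-set collection tibble (see
#'   [gene_set_collection()]).
#' @return named list of character vectors, in first-appearance order.
#' @export
collection_sets <- function(collection) {
  check_collection(collection)
  split(collection$gene, factor(collection$set, levels = unique(collection$set)))
}

check_collection <- function(collection) {
  if (!is.data.frame(collection) ||
      !all(c("set", "gene") %in% names(collection))) {
    abort("`collection` must be a tibble with columns `set` and `gene`")
  }
  invisible(collection)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated carrier for gene-set collections: one set per
#' line as `name<TAB>description<TAB>member1<TAB>member2...`. Member lists
#' are deduplicated; the order of sets is preserved.
#'
#' @param path path to a GMT file.
#' @param source source label stored in the `source` column
#'   (`"GO"`, `"pathway"` or `"synthetic"`).
#' @return a gene-set collection tibble.
#' @seealso [write_gmt()], [read_gaf()]
#' @export
read_gmt <- function(path, source = "pathway") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(set = character(), gene = character(),
                          source = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d in %s: fewer than 3 tab-separated fields",
                  bad[1], path))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  gene_set_collection(sets, source = source)
}

#' Write a collection to GMT
#'
#' @param collection a gene-set collection tibble.
#' @param path output path.
#' @param description description field written in column 2 (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  sets <- collection_sets(collection)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GAF 2.x annotation file
#'
#' Builds one gene set per distinct GO identifier from DIRECT annotations
#' only: rows whose qualifier contains `NOT` are excluded and no
#' propagation up the ontology graph is performed (propagation would need
#' an OBO graph; a pre-propagated file can be supplied instead via
#' `propagate`). The gene identifier is the object-symbol column
#' (column 3), matching expression tables keyed by symbol.
#'
#' @param path path to a GAF 2.x file (`!`-prefixed header lines,
#'   annotation rows with >= 15 tab-separated columns).
#' @param propagate optional function mapping the parsed annotation tibble
#'   (columns `gene`, `go_id`) to a propagated one; default `NULL` (off).
#' @return a gene-set collection tibble with `source = "GO"`.
#' @export
read_gaf <- function(path, propagate = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) {
    warn("GAF file contains no annotation rows; returning an empty collection")
    return(tibble::tibble(set = character(), gene = character(),
                          source = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 15)
  if (length(bad) > 0) {
    abort(sprintf("malformed GAF row %d in %s: fewer than 15 columns",
                  bad[1], path))
  }
  ann <- tibble::tibble(
    gene = trimws(vapply(fields, `[[`, character(1), 3)),
    qualifier = vapply(fields, `[[`, character(1), 4),
    go_id = vapply(fields, `[[`, character(1), 5)
  )
  ann <- dplyr::filter(ann, !grepl("NOT", .data$qualifier, fixed = TRUE))
  ann <- dplyr::distinct(ann, .data$go_id, .data$gene)
  if (!is.null(propagate)) {
    ann <- propagate(ann)
  }
  if (nrow(ann) == 0) {
    warn("all GAF rows were NOT-qualified; returning an empty collection")
    return(tibble::tibble(set = character(), gene = character(),
                          source = character()))
  }
  tibble::tibble(set = ann$go_id, gene = ann$gene, source = "GO")
}

#' Restrict a collection to the measured gene universe
#'
#' Intersects every set with the universe of measured genes and drops sets
#' whose intersected size falls below `min_size`, above `max_size`, or
#' equals the universe size (the running-sum score is degenerate when a
#' set is empty or covers the whole list). A report of dropped sets is
#' attached as the `"dropped"` attribute.
#'
#' @param collection a gene-set collection tibble.
#' @param universe non-empty character vector of measured gene symbols.
#' @param min_size minimum intersected size kept (default 3).
#' @param max_size maximum intersected size kept; default
#'   `length(universe) - 1`.
#' @return the restricted collection tibble; `attr(, "dropped")` is a
#'   tibble of `set`, `size`, `reason` for every discarded set.
#' @export
restrict_to_universe <- function(collection, universe,
                                 min_size = 3, max_size = NULL) {
  check_collection(collection)
  universe <- unique(trimws(as.character(universe)))
  if (length(universe) == 0) abort("`universe` must be non-empty")
  max_size <- max_size %||% max(length(universe) - 1L, min_size)
  stopifnot(min_size >= 1, min_size <= max_size)

  kept <- dplyr::filter(collection, .data$gene %in% universe)
  sizes <- dplyr::count(kept, .data$set, name = "size")
  all_sets <- unique(collection$set)
  sizes <- dplyr::left_join(tibble::tibble(set = all_sets), sizes, by = "set")
  sizes$size[is.na(sizes$size)] <- 0L
  sizes$reason <- dplyr::case_when(
    sizes$size < min_size ~ "below min_size",
    sizes$size > max_size ~ "above max_size",
    sizes$size == length(universe) ~ "covers universe",
    TRUE ~ NA_character_
  )
  dropped <- dplyr::filter(sizes, !is.na(.data$reason))
  out <- dplyr::filter(kept, !(.data$set %in% dropped$set))
  if (nrow(dropped) > 0) {
    inform(sprintf("restrict_to_universe: dropped %d of %d sets",
                   nrow(dropped), length(all_sets)))
  }
  attr(out, "dropped") <- dropped[, c("set", "size", "reason")]
  out
}
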