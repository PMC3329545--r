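# Independent brute-force oracle for the running-sum score: evaluates
# f(i) at every list position directly from the membership indicator,
# never via the member-position shortcut used by the implementation.
brute_force_es <- function(is_member) {
  n <- length(is_member)
  n_s <- sum(is_member)
  stopifnot(n_s > 0, n_s < n)
  f <- cumsum(is_member) / n_s - cumsum(!is_member) / (n - n_s)
  max(f)
}

# Random membership instance: n genes, n_s members at random positions.
random_instance <- function(n_max = 50) {
  n <- sample(3:n_max, 1)
  n_s <- sample(seq_len(n - 1), 1)
  is_member <- rep(FALSE, n)
  is_member[sample.int(n, n_s)] <- TRUE
  is_member
}

ranked_from_membership <- function(is_member) {
  genes <- sprintf("G%04d", seq_along(is_member))
  list(genes = genes, members = genes[is_member])
}

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal GAF 2.x row (17 columns) with the fields the parser reads.
gaf_row <- function(symbol, go_id, qualifier = "") {
  cols <- rep("", 17)
  cols[1] <- "UniProtKB"; cols[2] <- paste0("ID_", symbol)
  cols[3] <- symbol; cols[4] <- qualifier; cols[5] <- go_id
  cols[6] <- "PMID:1"; cols[7] <- "IDA"; cols[9] <- "F"
  cols[12] <- "protein"; cols[13] <- "taxon:9606"; cols[14] <- "20120418"
  cols[15] <- "UniProt"
  paste(cols, collapse = "\t")
}

# Plain results tibble shaped like one sample's enrichment output.
fake_results <- function(sets, direction, ranks, ps = NULL,
                         source = "pathway") {
  ps <- ps %||% rep(0.01, length(sets))
  tibble::tibble(set = sets, source = source, direction = direction,
                 n_s = 10L, es = 1 / ranks, p_value = ps,
                 rank = as.integer(ranks), n = 1000L)
}
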