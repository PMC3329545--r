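#' Configuration for a synthetic paired-fluid study
#'
#' Describes a simulated study of paired two-colour expression profiles
#' with planted gene-set signal. The default configuration mirrors a
#' four-sample design: two pre/post-treatment pairs from an index case
#' (`Ind-B` before, `Ind-A` after), one further chylothorax reference
#' (`FC-r`) and one non-chylothorax hydrops reference (`NFC-r`). Three
#' planted "immune-analogue" sets are shifted up in the three
#' chylothorax-history samples (`Ind-A`, `Ind-B`, `FC-r`) and left null
#' in `NFC-r`; one "lymphangiogenesis-analogue" set is shifted down in
#' the two untreated chylothorax samples (`Ind-B`, `FC-r`) and up in
#' `Ind-A` and `NFC-r`; a focal gene, deliberately NOT a member of that
#' set, shifts concordantly with it in every sample.
#'
#' Each gene's true log-ratio is `Normal(0, sigma_gene^2)` plus
#' `+/- delta * sigma_gene` if planted for the sample; each probe adds
#' `Normal(0, sigma_probe^2)` replicate noise. Deltas are in
#' `sigma_gene` units, so recovery behaviour is scale-free.
#'
#' @param n_genes genes in the universe (default 2000, a desk-scale stand
#'   in for a ~60K-probe array).
#' @param probes_per_gene replicate probes per gene (default 3).
#' @param sigma_gene between-gene spread of true log-ratios (default 1).
#' @param sigma_probe probe replicate noise sd (default 0.2).
#' @param n_sets total sets in the collection, planted included
#'   (default 50).
#' @param size_min,size_max size range for the random background sets.
#' @param planted tibble of planted sets: columns `set`, `size`, `delta`,
#'   then one direction column per sample with values `"up"`, `"down"`
#'   or `"null"`; `NULL` uses the default design above.
#' @param focal_gene symbol reserved for the focal gene (default
#'   `"FOCAL1"`); tied to the last planted set's per-sample directions.
#' @param samples sample ids (default the four-sample design).
#' @param seed integer seed; all generator randomness flows from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, probes_per_gene = 3,
                             sigma_gene = 1, sigma_probe = 0.2,
                             n_sets = 50, size_min = 10, size_max = 60,
                             planted = NULL, focal_gene = "FOCAL1",
                             samples = c("Ind-A", "Ind-B", "FC-r", "NFC-r"),
                             seed = 1L) {
  stopifnot(n_genes >= 10, probes_per_gene >= 1, sigma_gene > 0,
            sigma_probe >= 0, size_min >= 1, size_min <= size_max,
            size_max < n_genes)
  planted <- planted %||% default_planted(samples)
  dir_cols <- setdiff(names(planted), c("set", "size", "delta", "focal"))
  if (!setequal(dir_cols, samples)) {
    abort("planted direction columns must cover exactly the configured samples")
  }
  stopifnot(all(unlist(planted[samples]) %in% c("up", "down", "null")),
            all(planted$delta >= 0),
            sum(planted$size) <= n_genes,
            n_sets >= nrow(planted))
  structure(list(
    n_genes = n_genes, probes_per_gene = probes_per_gene,
    sigma_gene = sigma_gene, sigma_probe = sigma_probe,
    n_sets = n_sets, size_min = size_min, size_max = size_max,
    planted = planted, focal_gene = focal_gene,
    samples = samples, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Default planted design: immune analogues up in the three
# chylothorax-history samples, lymphangiogenesis analogue mixed.
default_planted <- function(samples = c("Ind-A", "Ind-B", "FC-r", "NFC-r")) {
  stopifnot(length(samples) == 4)
  tibble::tibble(
    set = c("IMMUNE_1", "IMMUNE_2", "IMMUNE_3", "LYMPHANGIO"),
    size = 30L,
    delta = 2,
    !!samples[1] := c("up", "up", "up", "up"),
    !!samples[2] := c("up", "up", "up", "down"),
    !!samples[3] := c("up", "up", "up", "down"),
    !!samples[4] := c("null", "null", "null", "up")
  )
}

# Deterministic per-stage substream seeds derived from the config seed.
stage_seed <- function(seed, stage) {
  offsets <- c(collection = 101L, expression = 211L)
  idx <- offsets[[stage]] + sum(utf8ToInt(stage))
  (as.integer(seed) %% 2000000000L) + idx
}

#' Generate the synthetic gene-set collection and its planted truth
#'
#' Realises the planted sets as disjoint random draws from the gene
#' universe (the focal gene is excluded from all memberships) and fills
#' the collection with random background sets of uniform size in
#' `[size_min, size_max]`. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `collection` (gene-set collection tibble, source
#'   `"synthetic"`) and `truth` (see [write_truth()]).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config$seed, "collection"))
  universe <- gene_universe(config)
  assignable <- setdiff(universe, config$focal_gene)
  planted <- config$planted
  pool <- sample(assignable)
  memberships <- list()
  offset <- 0
  for (i in seq_len(nrow(planted))) {
    memberships[[planted$set[i]]] <- sort(pool[offset + seq_len(planted$size[i])])
    offset <- offset + planted$size[i]
  }
  n_bg <- config$n_sets - nrow(planted)
  if (n_bg > 0) {
    bg_sizes <- sample(config$size_min:config$size_max, n_bg, replace = TRUE)
    for (j in seq_len(n_bg)) {
      memberships[[sprintf("BG_%03d", j)]] <- sort(sample(universe, bg_sizes[j]))
    }
  }
  collection <- gene_set_collection(memberships, source = "synthetic")
  truth <- list(
    planted = planted,
    memberships = memberships[planted$set],
    focal_gene = config$focal_gene,
    focal_directions = as.list(planted[nrow(planted), config$samples]),
    samples = config$samples,
    seed = config$seed
  )
  list(collection = collection, truth = truth)
}

gene_universe <- function(config) {
  c(sprintf("G%05d", seq_len(config$n_genes - 1L)), config$focal_gene)
}

#' Generate one synthetic sample-pair of probe measurements
#'
#' Draws the probe-level log-ratio table for one sample under the planted
#' design: true gene effects plus replicate probe noise, with emitted
#' log-ratios rounded to 6 decimals so fixed-seed output is bit-identical
#' across platforms.
#'
#' @param config a [synthetic_config()].
#' @param sample_id one of `config$samples`.
#' @param truth planted truth from [generate_collection()]; regenerated
#'   from the config (deterministically) when omitted.
#' @return probe tibble with columns `sample`, `probe_id`, `gene`,
#'   `log_ratio`.
#' @export
generate_sample_pair <- function(config, sample_id, truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!sample_id %in% config$samples) {
    abort(sprintf("unknown sample id %s", sample_id))
  }
  truth <- truth %||% generate_collection(config)$truth
  set.seed(stage_seed(config$seed, "expression") +
             match(sample_id, config$samples))
  universe <- gene_universe(config)
  mu <- rnorm(length(universe), 0, config$sigma_gene)
  names(mu) <- universe
  planted <- truth$planted
  for (i in seq_len(nrow(planted))) {
    dir <- planted[[sample_id]][i]
    if (dir == "null") next
    shift <- planted$delta[i] * config$sigma_gene * if (dir == "up") 1 else -1
    members <- truth$memberships[[planted$set[i]]]
    mu[members] <- mu[members] + shift
  }
  focal_dir <- planted[[sample_id]][nrow(planted)]
  if (focal_dir != "null") {
    shift <- planted$delta[nrow(planted)] * config$sigma_gene *
      if (focal_dir == "up") 1 else -1
    mu[truth$focal_gene] <- mu[truth$focal_gene] + shift
  }
  k <- config$probes_per_gene
  probes <- tibble::tibble(
    sample = sample_id,
    probe_id = sprintf("P_%s_%d", rep(universe, each = k), rep(seq_len(k), length(universe))),
    gene = rep(universe, each = k),
    log_ratio = round(unname(rep(mu, each = k)) +
                        rnorm(length(universe) * k, 0, config$sigma_probe), 6)
  )
  probes
}

#' Generate the full synthetic study
#'
#' Runs [generate_collection()] and [generate_sample_pair()] for every
#' configured sample, returning everything the downstream pipeline needs
#' plus the planted truth for recovery scoring.
#'
#' @param config a [synthetic_config()].
#' @return list with `samples` (named list of probe tibbles),
#'   `collection`, and `truth`.
#' @export
generate_study <- function(config = synthetic_config()) {
  coll <- generate_collection(config)
  samples <- lapply(setNames(nm = config$samples), function(s) {
    generate_sample_pair(config, s, truth = coll$truth)
  })
  list(samples = samples, collection = coll$collection, truth = coll$truth)
}

#' Serialise and restore the planted truth
#'
#' The truth file records the realised planted memberships, per-sample
#' directions and effect sizes, and the focal gene — everything needed to
#' score signal recovery downstream — as JSON.
#'
#' @param truth planted truth from [generate_collection()].
#' @param path JSON output path.
#' @return `path` invisibly (`write_truth`); the truth list
#'   (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  payload <- truth
  payload$planted <- as.list(truth$planted)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$planted <- tibble::as_tibble(raw$planted)
  raw$memberships <- lapply(raw$memberships, as.character)
  raw$focal_directions <- as.list(raw$focal_directions)
  raw
}
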