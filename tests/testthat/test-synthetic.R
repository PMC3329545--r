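small_config <- function(seed = 1, ...) {
  synthetic_config(n_genes = 200, probes_per_gene = 2, n_sets = 8,
                   size_min = 5, size_max = 15, seed = seed, ...)
}

test_that("collection generation realises the planted design deterministically", {
  cfg <- small_config(seed = 4)
  out <- generate_collection(cfg)
  sets <- collection_sets(out$collection)
  expect_length(sets, cfg$n_sets)
  expect_equal(lengths(sets)[out$truth$planted$set],
               setNames(out$truth$planted$size, out$truth$planted$set))
  # planted sets are disjoint and exclude the focal gene
  planted_members <- unlist(out$truth$memberships)
  expect_false(anyDuplicated(planted_members) > 0)
  expect_false(cfg$focal_gene %in% planted_members)

  p1 <- tempfile(fileext = ".gmt"); p2 <- tempfile(fileext = ".gmt")
  write_gmt(out$collection, p1)
  write_gmt(generate_collection(small_config(seed = 4))$collection, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a planted line carries exactly `size` member fields
  line <- grep("^IMMUNE_1\t", readLines(p1), value = TRUE)
  expect_length(strsplit(line, "\t")[[1]], 2 + 30)
})

test_that("noise-free single-probe samples reproduce the true gene effects", {
  cfg <- synthetic_config(n_genes = 200, probes_per_gene = 1,
                          sigma_probe = 0, n_sets = 5,
                          size_min = 5, size_max = 10, seed = 9)
  probes <- generate_sample_pair(cfg, "FC-r")
  genes <- collapse_probes(probes)
  expect_equal(nrow(genes), 200)
  expect_identical(sort(unique(probes$gene)), sort(genes$gene))
  # single probe per gene: collapse is the identity on log-ratios
  merged <- dplyr::inner_join(probes, genes, by = "gene",
                              suffix = c("_probe", "_gene"))
  expect_equal(merged$log_ratio_probe, merged$log_ratio_gene)
  expect_true(all(is.na(genes$p_value)))
})

test_that("sample generation is seed-deterministic and planted shifts are directional", {
  cfg <- small_config(seed = 12)
  a <- generate_sample_pair(cfg, "Ind-B")
  b <- generate_sample_pair(cfg, "Ind-B")
  expect_identical(a, b)
  other <- generate_sample_pair(cfg, "Ind-A")
  expect_false(identical(a$log_ratio, other$log_ratio))

  # up-planted members sit clearly above the background on average
  truth <- generate_collection(cfg)$truth
  genes <- collapse_probes(generate_sample_pair(cfg, "FC-r", truth))
  immune <- truth$memberships[["IMMUNE_1"]]
  bg <- setdiff(genes$gene, unlist(truth$memberships))
  expect_gt(mean(genes$log_ratio[genes$gene %in% immune]),
            mean(genes$log_ratio[genes$gene %in% bg]) + 1)
  lymph <- truth$memberships[["LYMPHANGIO"]]
  expect_lt(mean(genes$log_ratio[genes$gene %in% lymph]),
            mean(genes$log_ratio[genes$gene %in% bg]) - 1)
})

test_that("the four-sample study encodes the mixed-direction design", {
  cfg <- small_config(seed = 2)
  study <- generate_study(cfg)
  expect_named(study$samples, c("Ind-A", "Ind-B", "FC-r", "NFC-r"))
  planted <- study$truth$planted
  lymph <- planted[planted$set == "LYMPHANGIO", ]
  expect_identical(unlist(lymph[c("Ind-A", "Ind-B", "FC-r", "NFC-r")],
                          use.names = FALSE),
                   c("up", "down", "down", "up"))
  # focal gene's true shift is negative in exactly 2 of 4 samples
  expect_equal(sum(unlist(study$truth$focal_directions) == "down"), 2)
  immune <- planted[grepl("^IMMUNE", planted$set), ]
  expect_true(all(immune[["NFC-r"]] == "null"))
  expect_true(all(unlist(immune[c("Ind-A", "Ind-B", "FC-r")]) == "up"))
})

test_that("the planted truth round-trips through its JSON serialisation", {
  out <- generate_collection(small_config(seed = 8))
  path <- tempfile(fileext = ".json")
  write_truth(out$truth, path)
  back <- read_truth(path)
  expect_equal(back$planted, out$truth$planted)
  expect_identical(back$memberships, out$truth$memberships)
  expect_identical(back$focal_gene, out$truth$focal_gene)
  expect_identical(unlist(back$focal_directions),
                   unlist(out$truth$focal_directions))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_genes = 50, size_min = 10, size_max = 60))
  bad_planted <- tibble::tibble(
    set = "P", size = 10L, delta = 1, `Ind-A` = "up")
  expect_error(synthetic_config(planted = bad_planted), "cover")
  expect_error(generate_sample_pair(small_config(), "NOPE"), "unknown sample")
})
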