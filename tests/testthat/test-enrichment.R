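test_that("the running-sum score matches hand-derived cases", {
  genes <- paste0("G", 1:10)
  expect_equal(enrichment_score(genes, c("G1", "G2", "G3")), 1)
  expect_equal(enrichment_score(genes, c("G1", "G3", "G5")), 5 / 7)
  expect_equal(enrichment_score(genes, c("G8", "G9", "G10")), 0)
  expect_equal(enrichment_score(rev(genes), c("G8", "G9", "G10")), 1)
  # members absent from the list do not count towards N_S
  expect_equal(enrichment_score(genes, c("G1", "G2", "G3", "ZZZ")), 1)
  expect_error(enrichment_score(genes, character(0)), "degenerate")
  expect_error(enrichment_score(genes, genes), "degenerate")
})

test_that("the score equals the brute-force running sum on random instances", {
  set.seed(101)
  for (i in 1:300) {
    is_member <- random_instance(50)
    inst <- ranked_from_membership(is_member)
    expect_equal(enrichment_score(inst$genes, inst$members),
                 brute_force_es(is_member))
  }
})

test_that("score symmetry, bounds, and monotone-transform invariance hold", {
  set.seed(202)
  for (i in 1:200) {
    is_member <- random_instance(40)
    inst <- ranked_from_membership(is_member)
    es_up <- enrichment_score(inst$genes, inst$members)
    es_down_of_rev <- enrichment_score(rev(inst$genes), inst$members)
    expect_gte(es_up, 0)
    expect_lte(es_up, 1)
    expect_equal(enrichment_score(inst$genes, inst$members), es_up)
    expect_equal(es_down_of_rev, brute_force_es(rev(is_member)))
  }
  # ES = 1 iff members fill the top block
  top <- ranked_from_membership(c(rep(TRUE, 4), rep(FALSE, 8)))
  expect_equal(enrichment_score(top$genes, top$members), 1)

  # strictly monotone transforms of the scores never change the ranking,
  # hence never the score
  genes <- tibble::tibble(gene = sprintf("g%02d", 1:20),
                          log_ratio = rnorm(20))
  members <- sample(genes$gene, 6)
  base <- enrichment_score(rank_genes(genes), members)
  for (f in list(function(x) 2 * x + 3, function(x) x^3, exp)) {
    tr <- dplyr::mutate(genes, log_ratio = f(log_ratio))
    expect_equal(enrichment_score(rank_genes(tr), members), base)
  }
})

test_that("the exhaustive null enumerates every member-position subset", {
  null52 <- exhaustive_null(5, 2)
  expect_equal(sort(null52, decreasing = TRUE),
               c(1, 2/3, 2/3, 1/2, 1/2, 1/3, 1/3, 1/6, 0, 0),
               tolerance = 1e-12)
  for (ns in c(1, 3, 6)) {
    expect_length(exhaustive_null(7, ns), choose(7, ns))
  }
  expect_error(exhaustive_null(100, 50), "guard")
})

test_that("permutation p-values match the exhaustive null", {
  genes <- paste0("G", 1:5)
  # members at ranks {2,4}: ES 1/3, exhaustive p 5/10
  es_24 <- enrichment_score(genes, c("G2", "G4"))
  expect_equal(es_24, 1 / 3)
  null <- exhaustive_null(5, 2)
  expect_equal(mean(null > es_24), 0.5)
  set.seed(7)
  expect_equal(permutation_pvalue(es_24, 5, 2, n_perm = 10000), 0.5,
               tolerance = 0.03)

  # members at ranks {3,5}: ES 0, exhaustive p 8/10
  es_35 <- enrichment_score(genes, c("G3", "G5"))
  expect_equal(es_35, 0)
  expect_equal(mean(null > es_35), 0.8)

  # nothing strictly exceeds the maximal score
  expect_equal(permutation_pvalue(1, 5, 2, n_perm = 500), 0)

  # add-one smoothing keeps p away from zero when requested
  expect_gt(permutation_pvalue(1, 5, 2, n_perm = 500, smooth = TRUE), 0)
})

test_that("Monte-Carlo p agrees with the exhaustive p across small cases", {
  set.seed(303)
  n_perm <- 4000
  for (i in 1:15) {
    n <- sample(5:12, 1)
    n_s <- sample(seq_len(n - 1), 1)
    obs <- sort(sample.int(n, n_s))
    es <- enrichment_score(paste0("G", 1:n), paste0("G", obs))
    p_exact <- mean(exhaustive_null(n, n_s) > es)
    p_mc <- permutation_pvalue(es, n, n_s, n_perm = n_perm)
    expect_lt(abs(p_mc - p_exact),
              3 * sqrt(p_exact * (1 - p_exact) / n_perm) + 1e-9)
  }
})

test_that("collection scoring ranks planted block sets in order", {
  genes <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                          log_ratio = seq(5, -5, length.out = 100))
  ranked <- rank_genes(genes)
  coll <- gene_set_collection(list(
    TOP = ranked$gene[1:10],
    MID = ranked$gene[11:20],
    LOW = ranked$gene[21:30]))
  res <- rank_gene_sets(coll, ranked, n_perm = 200, seed = 5)
  up <- tidy(res) |> dplyr::filter(direction == "up")
  expect_identical(up$set[order(up$rank)], c("TOP", "MID", "LOW"))
  expect_identical(up$rank[match(c("TOP", "MID", "LOW"), up$set)], 1:3)
  # block ES agree with direct evaluation
  expect_equal(up$es[up$set == "TOP"],
               enrichment_score(ranked, ranked$gene[1:10]))

  single <- rank_gene_sets(
    gene_set_collection(list(ONLY = ranked$gene[5:12])),
    ranked, n_perm = 50, seed = 1)
  expect_identical(unique(tidy(single)$rank), 1L)

  expect_error(rank_gene_sets(
    gene_set_collection(list(ALL = ranked$gene)), ranked, n_perm = 10),
    "degenerate")
})

test_that("down-direction results equal up-direction results on the reversed list", {
  set.seed(404)
  genes <- tibble::tibble(gene = sprintf("g%03d", 1:60), log_ratio = rnorm(60))
  ranked_up <- rank_genes(genes)
  ranked_down <- rank_genes(genes, "down")
  coll <- gene_set_collection(lapply(setNames(nm = paste0("S", 1:8)), function(i) {
    sample(genes$gene, sample(3:15, 1))
  }))
  res <- tidy(rank_gene_sets(coll, ranked_up, n_perm = 100, seed = 2))
  down <- res[res$direction == "down", ]
  for (i in seq_len(nrow(down))) {
    members <- collection_sets(coll)[[down$set[i]]]
    expect_equal(down$es[i], enrichment_score(ranked_down, members))
  }
})

test_that("shared and per-set nulls give statistically equivalent p-values", {
  set.seed(505)
  genes <- tibble::tibble(gene = sprintf("g%03d", 1:200), log_ratio = rnorm(200))
  ranked <- rank_genes(genes)
  coll <- gene_set_collection(lapply(setNames(nm = paste0("S", 1:10)), function(i) {
    sample(genes$gene, 12)  # equal sizes so sharing actually kicks in
  }))
  n_perm <- 3000
  shared <- tidy(rank_gene_sets(coll, ranked, n_perm = n_perm, seed = 9,
                                share_null = TRUE))
  perset <- tidy(rank_gene_sets(coll, ranked, n_perm = n_perm, seed = 9,
                                share_null = FALSE))
  merged <- dplyr::inner_join(shared, perset,
                              by = c("set", "direction"),
                              suffix = c("_sh", "_ps"))
  expect_equal(merged$es_sh, merged$es_ps)  # ES is deterministic
  tol <- 3 * sqrt(pmax(merged$p_value_sh, 0.01) / n_perm) + 0.01
  expect_true(all(abs(merged$p_value_sh - merged$p_value_ps) < tol))
})

test_that("fixed seeds make collection scoring reproducible", {
  genes <- tibble::tibble(gene = sprintf("g%03d", 1:80), log_ratio = rnorm(80))
  ranked <- rank_genes(genes)
  coll <- gene_set_collection(list(A = ranked$gene[3:12],
                                   B = ranked$gene[40:49]))
  r1 <- tidy(rank_gene_sets(coll, ranked, n_perm = 300, seed = 77))
  r2 <- tidy(rank_gene_sets(coll, ranked, n_perm = 300, seed = 77))
  expect_identical(r1, r2)
})

test_that("the unweighted score agrees with fgsea's positive-deviation statistic", {
  skip_if_not_installed("fgsea")
  set.seed(606)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    names(scores) <- sprintf("g%03d", seq_len(n))
    pos <- sort(sample.int(n, sample(3:10, 1)))
    ours <- enrichment_score(names(scores), names(scores)[pos])
    theirs <- fgsea::calcGseaStat(scores, pos, gseaParam = 0,
                                  scoreType = "pos")
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})
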