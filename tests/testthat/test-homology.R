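test_that("CIP matches its definition and is order-invariant", {
  expect_equal(compute_cip(hsp_tbl(100, 100)), 100)
  expect_equal(compute_cip(hsp_tbl(c(40, 90), c(50, 150))), 65)
  # independent summation oracle on random HSP sets
  set.seed(31)
  for (i in 1:10) {
    n <- sample(2:10, 1)
    len <- sample(50:300, n, replace = TRUE)
    ids <- vapply(len, function(l) sample.int(l, 1), 0L)
    h <- hsp_tbl(ids, len)
    expect_equal(compute_cip(h), 100 * sum(ids) / sum(len))
    expect_equal(compute_cip(h[sample(n), ]), compute_cip(h))
  }
  expect_error(compute_cip(hsp_tbl(0, 100)[0, ]), "zero cumulative")
})

test_that("CALP uses merged aligned length capped at the query", {
  expect_equal(compute_calp(hsp_tbl(95, 100), 100), 100)
  expect_equal(compute_calp(hsp_tbl(c(200, 100), c(200, 150)), 700), 50)
  # two fully-overlapping HSPs of length L on a query of length L -> 100
  h <- hsp_tbl(c(90, 85), c(100, 100), starts = c(1, 1), ends = c(100, 100))
  expect_equal(compute_calp(h, 100), 100)
  expect_error(compute_calp(hsp_tbl(90, 100), 0), "query_length")
})

test_that("overlap merging takes identities from the better HSP", {
  h <- hsp_tbl(c(90, 85), c(100, 100), starts = c(1, 51), ends = c(100, 150))
  m <- merge_hsps(h)
  expect_equal(m$al, 150)
  # 90 from the stronger HSP + half of the weaker one
  expect_equal(m$identities, 90 + 85 / 2)
})

test_that("divergence-dependent thresholds are inclusive", {
  expect_true(classify_pair(70, 70, "close"))
  expect_false(classify_pair(69.9, 95, "close"))
  expect_true(classify_pair(55, 52, "distant"))
  expect_false(classify_pair(55, 49.9, "distant"))
  expect_error(classify_pair(50, 50, "medium"), "unknown divergence")
})

test_that("raising thresholds never increases the number of called pairs", {
  sc <- noise_free_scan()
  sim <- sc$sim
  pa <- pair_alignments(sim$hsps,
                        dplyr::select(sim$genes, gene_id, cds_length))
  n_called <- vapply(c(50, 60, 70, 80, 90), function(t) {
    nrow(call_homologs(pa, sim$genes, sim$divergence,
                       thresholds = c(close = t, distant = t)))
  }, 0L)
  expect_true(all(diff(n_called) <= 0))
})

test_that("best-hit selection keeps the highest CIP, then CALP", {
  pa <- tibble::tibble(
    query_id = c("a1", "a1", "a1"),
    subject_id = c("b1", "b2", "b3"),
    n_hsps = 1, al = 500,
    cip = c(80, 75, 80), calp = c(90, 95, 92))
  genes <- tibble::tibble(
    gene_id = c("a1", "b1", "b2", "b3"),
    genome_id = c("A", "B", "B", "B"))
  hom <- call_homologs(pa, genes, divergence_table(c("A", "B"), "close"))
  expect_equal(nrow(hom), 1)
  expect_equal(hom$gene_b, "b3") # cip tie broken by higher calp
  expect_equal(hom$relation, "ortholog")
})

test_that("self-hits are dropped and paralog pairs deduplicated", {
  pa <- tibble::tibble(
    query_id = c("a1", "a1", "a2"),
    subject_id = c("a1", "a2", "a1"),
    n_hsps = 1, al = 500, cip = 90, calp = 90)
  genes <- tibble::tibble(gene_id = c("a1", "a2"), genome_id = "A")
  hom <- call_homologs(pa, genes, divergence_table("A", "distant"))
  expect_equal(nrow(hom), 1)
  expect_equal(hom$relation, "paralog")
  expect_error(
    call_homologs(pa, genes[1, ], divergence_table("A", "distant")),
    "absent from the gene table")
})

test_that("simulated decoys are rejected; recall and precision are 1", {
  sc <- noise_free_scan()
  m <- homolog_metrics(sc$homologs, sc$sim$ground_truth$true_pairs,
                       relation = "ortholog")
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("called ortholog counts fall as simulated divergence grows", {
  counts <- vapply(c("close", "distant"), function(cls) {
    cfg <- scale_profile(sim_config("plant", seed = 7,
                                    divergence_class = cls), 0.03)
    sim <- simulate_genomes(cfg)
    pa <- pair_alignments(sim$hsps,
                          dplyr::select(sim$genes, gene_id, cds_length))
    hom <- call_homologs(pa, sim$genes, sim$divergence)
    sum(hom$relation == "ortholog")
  }, 0L)
  expect_true(counts["distant"] <= counts["close"])
})

test_that("gene families are the homolog graph's connected components", {
  pairs <- tibble::tibble(gene_a = c("a", "b", "x"),
                          gene_b = c("b", "c", "y"))
  fam <- gene_families(pairs)
  f <- setNames(fam$family_id, fam$gene_id)
  expect_equal(unname(f["a"]), unname(f["c"]))
  expect_false(unname(f["a"]) == unname(f["x"]))
  expect_equal(nrow(fam), 5)
})
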