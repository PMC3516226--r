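test_that("perfect collinear runs chain into single blocks", {
  b <- chain_anchors(anchor_tbl(1:3, 1:3), max_gap = 5)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_anchors, 3L)
  expect_equal(b$orientation, "direct")
  inv <- chain_anchors(anchor_tbl(1:3, c(9, 8, 7)), max_gap = 5)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$orientation, "inverted")
  expect_equal(nrow(chain_anchors(anchor_tbl(integer(0), integer(0)))), 0)
})

test_that("gaps beyond max_gap break chains", {
  b <- chain_anchors(anchor_tbl(c(1, 2, 30, 31), c(1, 2, 30, 31)),
                     max_gap = 5)
  expect_equal(nrow(b), 2)
  expect_equal(sort(b$n_anchors), c(2L, 2L))
})

test_that("chaining matches the exhaustive longest-chain oracle", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    ra <- sample.int(30, n)
    rb <- sample.int(30, n)
    gap <- sample(c(3, 5, 20), 1)
    got <- chain_anchors(anchor_tbl(ra, rb), max_gap = gap)
    want <- oracle_chain_partition(ra, rb, gap)
    expect_equal(nrow(got), length(want), info = sprintf("instance %d", i))
    got_sets <- lapply(seq_len(nrow(got)), function(j) {
      a <- got$anchors[[j]]
      m <- cbind(a$rank_a, a$rank_b)
      m[order(m[, 1]), , drop = FALSE]
    })
    want_sets <- lapply(want, function(w)
      w$ranks[order(w$ranks[, 1]), , drop = FALSE])
    key <- function(m) paste(apply(m, 1, paste, collapse = ","),
                             collapse = ";")
    expect_setequal(vapply(got_sets, key, ""), vapply(want_sets, key, ""))
    ori <- setNames(got$orientation, vapply(got_sets, key, ""))
    for (w in seq_along(want))
      expect_equal(unname(ori[key(want_sets[[w]])]),
                   want[[w]]$orientation)
  }
})

test_that("block anchors are strictly monotone and labeled by trend", {
  sc <- noise_free_scan()
  b <- synteny_blocks(sc$scan)
  for (i in seq_len(nrow(b))) {
    a <- b$anchors[[i]]
    expect_true(all(diff(a$rank_a) > 0))
    d <- diff(a$rank_b)
    if (b$orientation[i] == "direct") expect_true(all(d > 0))
    else expect_true(all(d < 0))
  }
})

test_that("validation enforces match number, density and p-value rules", {
  # four anchors can never validate, whatever the density
  b4 <- tibble::tibble(n_anchors = 4L, cluster_length = 4,
                       anchors = list(tibble::tibble(rank_a = 1:4,
                                                     rank_b = 1:4)))
  v <- validate_block(b4, background = 0.001, n_genes_a = 100,
                      n_anchors_pair = 4, n_shuffles = 100, seed = 1)
  expect_false(v$valid)
  expect_equal(v$reason, "match_number")
  # five anchors spread across a 1000-gene chromosome fail the density rule
  spread <- tibble::tibble(
    n_anchors = 5L, cluster_length = 1000,
    anchors = list(tibble::tibble(rank_a = c(1, 250, 500, 750, 999),
                                  rank_b = c(1, 250, 500, 750, 999))))
  v2 <- validate_block(spread, background = 0.005, n_genes_a = 1000,
                       n_anchors_pair = 5, n_shuffles = 100, seed = 1)
  expect_false(v2$valid)
  expect_equal(v2$reason, "density")
  # five tight anchors on a sparse background validate (density ratio 25)
  tight <- tibble::tibble(
    n_anchors = 5L, cluster_length = 10,
    anchors = list(tibble::tibble(rank_a = c(1, 3, 5, 8, 10),
                                  rank_b = c(2, 4, 5, 7, 9))))
  v3 <- validate_block(tight, background = 0.02, n_genes_a = 1000,
                       n_anchors_pair = 5, n_shuffles = 1000, seed = 7)
  expect_equal(v3$density_ratio, 25)
  expect_true(v3$valid)
  expect_lt(v3$p_value, 0.05)
  expect_error(validate_block(tight, 0.02, 1000, 5, n_shuffles = 50),
               "n_shuffles")
})

test_that("validation is deterministic given the seed", {
  tight <- tibble::tibble(
    n_anchors = 5L, cluster_length = 10,
    anchors = list(tibble::tibble(rank_a = c(1, 3, 5, 8, 10),
                                  rank_b = c(2, 4, 5, 7, 9))))
  v1 <- validate_block(tight, 0.02, 1000, 5, n_shuffles = 500, seed = 11)
  v2 <- validate_block(tight, 0.02, 1000, 5, n_shuffles = 500, seed = 11)
  expect_identical(v1$p_value, v2$p_value)
})

test_that("window-mode Monte-Carlo agrees with the hypergeometric form", {
  cases <- list(c(A = 20, N = 200, L = 10, m = 5),
                c(A = 30, N = 300, L = 30, m = 6))
  for (cs in cases) {
    b <- tibble::tibble(n_anchors = cs[["m"]], cluster_length = cs[["L"]],
                        anchors = list(NULL))
    v <- validate_block(b, background = 0.001, n_genes_a = cs[["N"]],
                        n_anchors_pair = cs[["A"]], n_shuffles = 10000,
                        seed = 3, null = "window")
    closed <- window_p_closed_form(cs[["A"]], cs[["N"]], cs[["L"]],
                                   cs[["m"]])
    expect_lt(abs(v$p_value - closed), 0.01)
  }
})

test_that("coverage summaries use interval unions", {
  mk <- function(s1, e1, s2 = NULL, e2 = NULL) {
    n <- if (is.null(s2)) 1 else 2
    tibble::tibble(
      block_id = sprintf("b%d", seq_len(n)), kind = "orthologous",
      genome_a = "A", chromosome_a = "c1", genome_b = "B",
      chromosome_b = "c1", n_anchors = 5L,
      bp_start_a = c(s1, s2)[seq_len(n)], bp_end_a = c(e1, e2)[seq_len(n)],
      bp_start_b = 1, bp_end_b = 2)
  }
  lens <- tibble::tibble(chromosome_id = "c1", length_bp = 1e6)
  genes <- tibble::tibble(genome_id = "A", chromosome_id = "c1",
                          gene_id = "g", start = 1, end = 1e6)
  expect_equal(coverage_summary(mk(1, 810000), genes, "A", lens)$pct_coverage,
               81)
  expect_equal(coverage_summary(mk(1, 3e5, 500001, 700000), genes, "A",
                                lens)$pct_coverage, 50)
  expect_equal(coverage_summary(mk(1, 6e5, 400001, 1e6), genes, "A",
                                lens)$pct_coverage, 100)
})

test_that("a paralog block with no orthologous coverage is lineage specific", {
  pb <- tibble::tibble(
    block_id = "p1", kind = "paralogous",
    genome_a = "A", chromosome_a = "c1", genome_b = "A",
    chromosome_b = "c2", n_anchors = 5L,
    rank_start_a = 0, rank_end_a = 10, rank_start_b = 0, rank_end_b = 10,
    anchors = list(tibble::tibble(rank_a = 0:4, rank_b = 0:4)))
  dc <- classify_duplications(pb, pb[0, ])
  expect_equal(dc$status, "lineage_specific")
  expect_length(dc$evidence[[1]], 0)
})

test_that("glance and tidy summarise a scan", {
  sc <- noise_free_scan()
  g <- generics::glance(sc$scan)
  expect_equal(g$n_valid, nrow(synteny_blocks(sc$scan)))
  expect_equal(nrow(generics::tidy(sc$scan)), nrow(sc$scan$blocks))
})
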