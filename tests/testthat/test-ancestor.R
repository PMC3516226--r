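occ_tbl <- function(...) {
  rows <- list(...)
  purrr::map(rows, function(r)
    tibble::tibble(genome_id = r[[1]], chromosome_id = r[[2]],
                   segment_id = r[[3]],
                   pos = seq_along(r[[3]]),
                   orient = if (length(r) > 3) r[[4]] else 1L,
                   n_genes = 10L)) |>
    dplyr::bind_rows()
}

test_that("adjacencies need two supporting genomes", {
  # full agreement: a simple path with weight-2 edges
  g <- common_intervals(occ_tbl(list("g1", "c1", c("A", "B", "C")),
                                list("g2", "c1", c("A", "B", "C"))))
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$weight, c(2L, 2L))
  # one genome disagreeing on B/C order: A-B and B-C keep support >= 2,
  # the A-C adjacency seen once is dropped
  g2 <- common_intervals(occ_tbl(list("g1", "c1", c("A", "B", "C")),
                                 list("g2", "c1", c("A", "C", "B")),
                                 list("g3", "c1", c("A", "B", "C"))))
  keys <- paste(g2$edges$seg1, g2$edges$seg2)
  expect_setequal(keys, c("A B", "B C"))
  expect_equal(g2$edges$weight[order(keys)], c(2L, 2L))
  expect_error(common_intervals(occ_tbl(list("g1", "c1", "A"))),
               "two genomes")
})

test_that("a single shared segment yields one singleton CAR", {
  g <- common_intervals(occ_tbl(list("g1", "c1", "A"),
                                list("g2", "c1", "A")))
  cars <- assemble_cars(g)
  expect_equal(nrow(cars), 1)
  expect_equal(cars$segments[[1]]$segment_id, "A")
})

test_that("CAR assembly partitions segments and resolves branches by weight", {
  path4 <- common_intervals(occ_tbl(list("g1", "c1", c("A", "B", "C", "D")),
                                    list("g2", "c1", c("A", "B", "C", "D"))))
  cars <- assemble_cars(path4)
  expect_equal(nrow(cars), 1)
  expect_equal(cars$segments[[1]]$segment_id, c("A", "B", "C", "D"))
  # star at B.h: B-C seen in three genomes, B-D in two; the lighter edge
  # is dropped, leaving two CARs
  star <- common_intervals(occ_tbl(list("g1", "c1", c("B", "C")),
                                   list("g2", "c1", c("B", "C")),
                                   list("g3", "c1", c("B", "D")),
                                   list("g4", "c1", c("B", "D")),
                                   list("g5", "c1", c("B", "C"))))
  cars2 <- assemble_cars(star)
  expect_equal(nrow(cars2), 2)
  joined <- cars2$segments[[which(cars2$n_segments == 2)]]
  expect_setequal(joined$segment_id, c("B", "C"))
  # partition: every node appears exactly once overall
  all_segs <- unlist(purrr::map(cars2$segments, "segment_id"))
  expect_equal(sort(all_segs), c("B", "C", "D"))
})

test_that("orientation-aware adjacencies distinguish reversed joins", {
  # g1 joins A head-to-tail with B; g2 joins A head to B head: different
  # extremity pairs, so neither reaches support 2
  g <- common_intervals(occ_tbl(list("g1", "c1", c("A", "B"), c(1L, 1L)),
                                list("g2", "c1", c("A", "B"), c(1L, -1L))))
  expect_equal(nrow(g$edges), 0)
})

test_that("karyotype statistics sum protogenes and gene space", {
  cars <- tibble::tibble(
    car_id = c("car001", "car002"), n_segments = c(1L, 1L),
    segments = list(tibble::tibble(segment_id = "s1", orient = 1L),
                    tibble::tibble(segment_id = "s2", orient = 1L)))
  seg_fam <- tibble::tibble(
    segment_id = c(rep("s1", 100), rep("s2", 150)),
    family_id = sprintf("f%03d", 1:250),
    min_cds = 1000)
  ak <- karyotype_stats(cars, seg_fam, name = "toy")
  expect_equal(ak$total_protogenes, 250)
  expect_equal(ak$total_gene_space_bp, 250000)
  expect_equal(ak$cars$protogene_count, c(100, 150))
  empty <- karyotype_stats(cars[0, ], seg_fam)
  expect_equal(empty$total_protogenes, 0)
  g <- generics::glance(ak)
  expect_equal(g$n_protochromosomes, 2)
})

test_that("reconstruction recovers the simulated protochromosome count", {
  sc <- noise_free_scan()
  ak <- reconstruct_ancestor(sc$scan)
  expect_equal(ak$n_protochromosomes, sc$sim$ground_truth$ancestor_n)
  expect_equal(ak$total_protogenes, sc$sim$config$n_protogenes)
  # partition invariant: every segment in exactly one CAR
  segs <- unlist(purrr::map(ak$cars$segments, "segment_id"))
  expect_equal(sort(segs), sort(unique(ak$segment_map$segment_id)))
})

test_that("an agreeing extra genome never splits CARs", {
  base <- occ_tbl(list("g1", "c1", c("A", "B", "C")),
                  list("g2", "c1", c("A", "B", "C")))
  more <- dplyr::bind_rows(base,
                           occ_tbl(list("g3", "c1", c("A", "B", "C"))))
  w1 <- common_intervals(base)$edges
  w2 <- common_intervals(more)$edges
  expect_true(all(w2$weight >= w1$weight))
  expect_equal(nrow(assemble_cars(common_intervals(more))), 1)
})
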