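mk_genes <- function(starts, chrom = "c1") {
  tibble::tibble(genome_id = "g", chromosome_id = chrom,
                 gene_id = sprintf("g%03d", seq_along(starts)),
                 start = starts, end = starts + 999, strand = 1,
                 cds_length = 1000)
}

mk_tes <- function(starts, ends, cls = "classI_LTR", chrom = "c1") {
  tibble::tibble(genome_id = "g", chromosome_id = chrom, start = starts,
                 end = ends, te_class = cls)
}

lens <- function(bp, chrom = "c1")
  tibble::tibble(chromosome_id = chrom, length_bp = bp)

test_that("genes fall in the window containing their start", {
  p <- window_profiles(mk_genes(c(10000, 499999, 500001)),
                       mk_tes(numeric(0), numeric(0)), lens(1e6))
  expect_equal(p$gene_count, c(2L, 1L))
  expect_equal(p$window_start, c(1, 500001))
  expect_equal(p$window_end, c(500000, 1000000))
})

test_that("TE coverage is the per-class interval union", {
  p <- window_profiles(mk_genes(1), mk_tes(100001, 200000), lens(5e5))
  expect_equal(p$te_kb_classI_LTR, 100)
  expect_equal(p$te_pct_classI_LTR, 20)
  # overlapping same-class copies count once
  p2 <- window_profiles(mk_genes(1), mk_tes(c(1, 200001), c(3e5, 4e5)),
                        lens(5e5))
  expect_equal(p2$te_kb_classI_LTR, 400)
  # different classes tally independently, even nested
  p3 <- window_profiles(mk_genes(1),
                        dplyr::bind_rows(mk_tes(1, 1e5),
                                         mk_tes(20001, 40000, "classII")),
                        lens(5e5))
  expect_equal(p3$te_kb_classI_LTR, 100)
  expect_equal(p3$te_kb_classII, 20)
  expect_error(window_profiles(mk_genes(1), mk_tes(1, 6e5), lens(5e5)),
               "beyond chromosome")
})

test_that("window gene counts partition the chromosome total", {
  sim <- noise_free_sim()
  g1 <- dplyr::filter(sim$genes, genome_id == "g1")
  t1 <- dplyr::filter(sim$tes, genome_id == "g1")
  l1 <- dplyr::filter(sim$chrom_lengths, genome_id == "g1")
  p <- window_profiles(g1, t1, l1)
  totals <- dplyr::count(dplyr::group_by(p, chromosome_id),
                         wt = gene_count, name = "n")
  truth <- dplyr::count(g1, chromosome_id)
  m <- dplyr::left_join(truth, totals, by = "chromosome_id",
                        suffix = c("_true", "_win"))
  expect_equal(m$n_win, m$n_true)
})

test_that("TE tallies are invariant to fragmenting a TE record", {
  whole <- window_profiles(mk_genes(1), mk_tes(100001, 300000), lens(5e5))
  split <- window_profiles(mk_genes(1),
                           mk_tes(c(100001, 200001), c(200000, 300000)),
                           lens(5e5))
  expect_equal(whole$te_kb_classI_LTR, split$te_kb_classI_LTR)
})

test_that("halving the window never changes chromosome-level totals", {
  sim <- noise_free_sim()
  g1 <- dplyr::filter(sim$genes, genome_id == "g1",
                      chromosome_id == "chr01")
  t1 <- dplyr::filter(sim$tes, genome_id == "g1",
                      chromosome_id == "chr01")
  l1 <- dplyr::filter(sim$chrom_lengths, genome_id == "g1",
                      chromosome_id == "chr01")
  p1 <- window_profiles(g1, t1, l1, window_bp = 500000)
  p2 <- window_profiles(g1, t1, l1, window_bp = 250000)
  expect_equal(sum(p1$gene_count), sum(p2$gene_count))
  expect_equal(sum(p1$te_kb_classI_LTR), sum(p2$te_kb_classI_LTR))
})

test_that("profile summaries average and maximize per class", {
  p <- window_profiles(mk_genes(1), mk_tes(numeric(0), numeric(0)),
                       lens(15e5))
  p$te_pct_classI_LTR <- c(10, 30, 50)
  s <- profile_summary(p)
  expect_equal(s$mean_pct_classI_LTR, 30)
  expect_equal(s$max_pct_classI_LTR, 50)
  expect_equal(s$mean_pct_classII, 0)
  expect_error(profile_summary(p[0, ]), ">= 1 window")
})
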