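test_that("percent-identity HSP rows convert to identity counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2\t95.0\t200\t10\t0\t1\t200\t1\t200\t1e-50\t350",
               "g1\tg3\t40.0\t100\t60\t0\t1\t100\t1\t100\t1e-5\t80"), f)
  x <- read_hsp_table(f, dialect = "pct")
  expect_equal(x$identities, c(190, 40))
  expect_equal(x$hsp_length, c(200, 100))
})

test_that("empty and grouped HSP files are read faithfully", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_equal(nrow(read_hsp_table(f)), 0)
  writeLines(c("a\tb\t90\t100\t10\t0\t1\t100\t1\t100\t0\t1",
               "a\tb\t80\t50\t10\t0\t120\t169\t120\t169\t0\t1",
               "a\tc\t70\t80\t24\t0\t1\t80\t1\t80\t0\t1"), f)
  x <- read_hsp_table(f)
  expect_equal(nrow(x), 3)
  expect_equal(nrow(dplyr::distinct(x, query_id, subject_id)), 2)
})

test_that("malformed or impossible HSP rows raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t90\t100\t10\t0\t1\t100\t1\t100\t0\t1",
               "a\tb\t90\t-5\t10\t0\t1\t5\t1\t5\t0\t1"), f)
  expect_error(read_hsp_table(f), "line 2")
})

test_that("gene ranks follow start order with deterministic ties", {
  g <- tibble::tibble(genome_id = "g", chromosome_id = "c1",
                      gene_id = c("x", "y", "z"),
                      start = c(100, 50, 200), end = c(150, 80, 260),
                      strand = 1, cds_length = 50)
  r <- assign_ranks(g)
  expect_equal(r$rank[match(c("x", "y", "z"), r$gene_id)], c(1L, 0L, 2L))
  # two chromosomes rank independently from zero
  g2 <- dplyr::mutate(g, chromosome_id = "c2",
                      gene_id = paste0(gene_id, "2"))
  r2 <- assign_ranks(dplyr::bind_rows(g, g2))
  expect_equal(sort(r2$rank[r2$chromosome_id == "c2"]), 0:2)
  expect_error(assign_ranks(dplyr::bind_rows(g, g)), "duplicate gene_id")
})

test_that("rank assignment is a permutation of 0..k-1 per chromosome", {
  sim <- noise_free_sim()
  by_chrom <- split(sim$genes$rank,
                    paste(sim$genes$genome_id, sim$genes$chromosome_id))
  for (r in by_chrom) expect_equal(sort(r), seq_along(r) - 1L)
})

test_that("gene order and GFF3 round-trip through write/read unchanged", {
  sim <- noise_free_sim()
  g <- dplyr::filter(sim$genes, genome_id == "g1",
                     chromosome_id == "chr01")[1:10, ]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_order(g, f)
  back <- read_gene_order(f)
  expect_equal(back$gene_id, g$gene_id)
  expect_equal(back$start, g$start)
  expect_equal(back$rank, g$rank)

  gff <- withr::local_tempfile(fileext = ".gff3")
  te <- dplyr::filter(sim$tes, genome_id == "g1")[1:5, ]
  write_gff3_features(g, te, gff)
  back2 <- read_gff3_features(gff)
  expect_equal(nrow(back2$genes), 10)
  expect_equal(sort(back2$genes$gene_id), sort(g$gene_id))
  expect_equal(back2$tes$te_class, te$te_class)
  expect_equal(back2$tes$start, te$start)
})

test_that("block tables round-trip and summarise coverage", {
  sc <- noise_free_scan()
  blocks <- synteny_blocks(sc$scan)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_block_table(blocks, f, genomes = sc$sim$genes)
  back <- read_block_table(f)
  expect_equal(nrow(back), nrow(blocks))
  expect_equal(back$n_anchors, blocks$n_anchors)
  expect_equal(back$anchors[[1]]$gene_a, blocks$anchors[[1]]$gene_a)
  # header-only file for zero blocks
  f0 <- withr::local_tempfile(fileext = ".tsv")
  write_block_table(blocks[0, ], f0)
  expect_equal(nrow(read_block_table(f0)), 0)
  # BED export: two lines per block, 0-based half-open
  bed <- withr::local_tempfile(fileext = ".bed")
  write_block_bed(blocks[1, ], bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_length(lines, 2)
  expect_equal(as.numeric(lines[[1]][2]), blocks$bp_start_a[1] - 1)
})

test_that("CAR tables round-trip", {
  cars <- tibble::tibble(
    car_id = c("car001", "car002"), n_segments = c(2L, 1L),
    segments = list(
      tibble::tibble(segment_id = c("seg001", "seg002"),
                     orient = c(1L, -1L)),
      tibble::tibble(segment_id = "seg003", orient = 1L)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_car_table(cars, f)
  back <- read_car_table(f)
  expect_equal(back$car_id, cars$car_id)
  expect_equal(back$segments[[1]]$orient, c(1L, -1L))
  expect_equal(back$segments[[2]]$segment_id, "seg003")
})
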