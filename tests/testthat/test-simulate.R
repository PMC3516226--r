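test_that("the simulation is reproducible from its seed", {
  cfg <- scale_profile(sim_config("plant", seed = 5), 0.02)
  a <- simulate_genomes(cfg)
  b <- simulate_genomes(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$hsps, b$hsps)
  expect_identical(a$tes, b$tes)
  cfg2 <- cfg
  cfg2$seed <- 6
  c2 <- simulate_genomes(cfg2)
  expect_false(identical(a$genes$start, c2$genes$start))
  # same summary dimensions under a different seed
  expect_equal(length(unique(c2$genes$genome_id)),
               length(unique(a$genes$genome_id)))
})

test_that("a zero-event, zero-loss descendant is the ancestor itself", {
  cfg <- scale_profile(
    sim_config("plant", seed = 9,
               lineages = list(list(name = "d1", wgd = 0, n_fis = 0,
                                    n_fus = 0, n_inv = 0),
                               list(name = "d2", wgd = 0, n_fis = 0,
                                    n_fus = 0, n_inv = 0))), 0.05)
  sim <- simulate_genomes(cfg)
  d1 <- dplyr::filter(sim$genes, genome_id == "d1")
  expect_equal(length(unique(d1$chromosome_id)),
               sim$ground_truth$ancestor_n)
  # identical gene content and order in family space
  d2 <- dplyr::filter(sim$genes, genome_id == "d2")
  expect_equal(d1$family_id, d2$family_id)
  pa <- pair_alignments(sim$hsps,
                        dplyr::select(sim$genes, gene_id, cds_length))
  hom <- call_homologs(pa, sim$genes, sim$divergence)
  m <- homolog_metrics(hom, sim$ground_truth$true_pairs, "ortholog")
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("scaling a profile scales gene counts only", {
  cfg <- sim_config("plant")
  s <- scale_profile(cfg, 0.1)
  expect_equal(s$n_protogenes, 1200)
  expect_equal(s$n_protochromosomes, cfg$n_protochromosomes)
  expect_identical(scale_profile(cfg, 1)$n_protogenes, cfg$n_protogenes)
  expect_error(scale_profile(cfg, 0), "factor")
  expect_error(scale_profile(cfg, -2), "factor")
})

test_that("emitted identities track the configured divergence model", {
  cfg <- scale_profile(sim_config("plant", seed = 4), 0.03)
  sim <- simulate_genomes(cfg)
  truth <- sim$ground_truth$true_pairs
  key <- paste(pmin(sim$hsps$query_id, sim$hsps$subject_id),
               pmax(sim$hsps$query_id, sim$hsps$subject_id))
  tkey <- paste(pmin(truth$gene_a, truth$gene_b),
                pmax(truth$gene_a, truth$gene_b))
  true_hsps <- sim$hsps[key %in% tkey, ]
  decoy_hsps <- sim$hsps[!key %in% tkey, ]
  expect_gt(mean(true_hsps$pct_identity), 80) # close-class model
  expect_lt(mean(decoy_hsps$pct_identity), 50)
  expect_gt(nrow(decoy_hsps), 0)
})

test_that("plant TE landscapes are peaky, animal ones homogeneous", {
  plant <- simulate_genomes(scale_profile(sim_config("plant", seed = 21,
    lineages = list(list(name = "p1", wgd = 0, n_fis = 0, n_fus = 0,
                         n_inv = 0))), 0.35))
  cov_p <- dplyr::filter(plant$ground_truth$te_coverage,
                         te_class == "classI_LTR")
  expect_gte(cov_p$max_pct, 2 * cov_p$mean_pct)
  animal <- simulate_genomes(scale_profile(sim_config("animal", seed = 22,
    lineages = list(list(name = "a1", wgd = 0, n_fis = 0, n_fus = 0,
                         n_inv = 0))), 0.25))
  cov_a <- dplyr::filter(animal$ground_truth$te_coverage,
                         te_class == "classI_nonLTR")
  expect_lte(cov_a$max_pct, 1.5 * cov_a$mean_pct)
})

test_that("ground-truth families cover every emitted gene exactly once", {
  sim <- noise_free_sim()
  fam <- sim$ground_truth$families
  expect_equal(sort(fam$gene_id), sort(sim$genes$gene_id))
  expect_equal(anyDuplicated(fam$gene_id), 0L)
})

test_that("random rearrangement instances replay to their end state", {
  inst <- random_rearrangement_instance(n_chrom = 3, n_segments = 6,
                                        n_events = 3, seed = 77)
  sc <- replay(inst$start, inst$events)
  expect_true(karyotypes_equal(sc$end, inst$end))
  expect_lte(n_chromosomes(inst$end), 6)
})
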