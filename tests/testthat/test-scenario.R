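seg_multiset <- function(k) sort(paste0(k$colors, ".", k$copies)[
  unlist(lapply(k$chromosomes, abs))])

test_that("events obey the chromosome-count law", {
  k5 <- karyotype(as.list(LETTERS[1:5]))
  expect_equal(n_chromosomes(apply_event(k5, ev_wgd())), 10)
  k <- karyotype(list(c("A", "B"), c("C", "D")))
  expect_equal(n_chromosomes(apply_event(k, ev_fission(1, 1))), 3)
  expect_equal(n_chromosomes(apply_event(k, ev_fusion(1, 2))), 1)
  expect_equal(n_chromosomes(apply_event(k, ev_inversion(1, 1, 2))), 2)
  expect_equal(n_chromosomes(apply_event(k, ev_translocation(1, 1, 2, 1))),
               2)
  expect_error(apply_event(k, ev_fusion(1, 1)), "itself")
  expect_error(apply_event(k, ev_fission(1, 5)), "breakpoint")
})

test_that("segment content is conserved by shuffling events", {
  k <- karyotype(list(c("A", "B", "C"), c("D", "E")))
  before <- seg_multiset(k)
  for (ev in list(ev_fission(1, 2), ev_fusion(2, 1, flip2 = TRUE),
                  ev_inversion(1, 1, 2), ev_translocation(1, 1, 2, 1)))
    expect_equal(seg_multiset(apply_event(k, ev)), before)
  wgd <- apply_event(k, ev_wgd())
  expect_equal(length(seg_multiset(wgd)), 2 * length(before))
})

test_that("replay folds events and records the n trace", {
  k <- karyotype(as.list(LETTERS[1:3]))
  sc <- replay(k, list())
  expect_true(karyotypes_equal(sc$end, k))
  sc2 <- replay(apply_event(k, ev_wgd()),
                list(ev_fusion(1, 2), ev_fusion(1, 2)))
  expect_equal(sc2$trace$n, c(5, 4))
  expect_error(replay(k, list(ev_fission(9, 1))), "event 1")
})

test_that("fusion products classify as TCF, CCF or complex", {
  tcf <- classify_fusion(c("red", "red"), c("blue", "blue"),
                         c("red", "red", "blue", "blue"))
  expect_equal(tcf$mode, "TCF")
  expect_equal(unname(tcf$elementary["Cfus"]), 1L)
  ccf <- classify_fusion(c("red", "red"), c("blue", "blue"),
                         c("red", "blue", "blue", "red"))
  expect_equal(ccf$mode, "CCF")
  expect_equal(unname(ccf$elementary["Cfis"]), 1L)
  expect_equal(unname(ccf$elementary["Cfus"]), 2L)
  cx <- classify_fusion(c("red", "blue"), c("green", "red"),
                        c("red", "green", "red", "blue"))
  expect_equal(cx$mode, "complex")
})

test_that("count arithmetic reproduces published chromosome numbers", {
  expect_equal(count_final(10, c("wgd", "+3")), 23)
  expect_equal(count_final(23, c("wgd", "-6")), 40)
  expect_equal(count_final(30, c("+57", "-22")), 65)
  expect_equal(count_final(39, c("+31", "-50")), 20)
  expect_equal(count_final(21, c("+6", "-15")), 12)
  expect_equal(count_final(5, "wgd"), 10)
  tr <- count_trace(12, c("+2", "-4"))
  expect_equal(tr$n, c(14, 10))
  expect_error(count_trace(3, "-5"), "fell to")
  expect_equal(nrow(count_trace(5, character(0))), 0)
})

test_that("count_trace equals segment-level replay on simulated scenarios", {
  for (sd in c(3, 14)) {
    cfg <- scale_profile(sim_config("plant", seed = sd), 0.03)
    sim <- simulate_genomes(cfg)
    sc <- sim$ground_truth$scenarios
    for (i in seq_len(nrow(sc)))
      expect_equal(count_final(sc$start_n[i], sc$steps[[i]]),
                   sc$n_final[i])
  }
})

test_that("canonical equality ignores chromosome order and reading strand", {
  a <- karyotype(list(c("A", "B"), c("C")))
  b <- karyotype(list(c("C"), c("-B", "-A")))
  expect_true(karyotypes_equal(a, b))
  c2 <- karyotype(list(c("B", "A"), c("C")))
  expect_false(karyotypes_equal(a, c2))
})

test_that("minimal scenarios are found exactly on small instances", {
  k <- karyotype(list(c("A", "B"), c("C"), c("D")))
  same <- infer_min_events(k, k, budget = 3)
  expect_equal(same$n_events, 0L)
  fused <- apply_event(k, ev_fusion(2, 3))
  one <- infer_min_events(k, fused, budget = 3)
  expect_equal(one$n_events, 1L)
  expect_equal(one$scenario$events[[1]]$kind, "fusion_tcf")
  # unreachable within a tiny budget is reported, not invented
  far <- replay(k, list(ev_fission(1, 1), ev_fusion(1, 3),
                        ev_fusion(1, 2)))$end
  expect_equal(infer_min_events(k, far, budget = 1)$status, "not_found")
})

test_that("BFS minimum bounds the generating count; heuristic bounds BFS", {
  for (i in 1:12) {
    inst <- random_rearrangement_instance(n_chrom = 3, n_segments = 6,
                                          n_events = 1 + (i %% 4),
                                          seed = 500 + i)
    ex <- infer_min_events(inst$start, inst$end, budget = 4)
    expect_equal(ex$status, "found")
    expect_lte(ex$n_events, inst$n_events)
    expect_true(karyotypes_equal(ex$scenario$end, inst$end))
    h <- infer_min_events(inst$start, inst$end, mode = "heuristic")
    expect_gte(h$n_events, ex$n_events)
    expect_true(karyotypes_equal(h$scenario$end, inst$end))
  }
})

test_that("shipped lineage scripts reproduce published numbers except the flagged three", {
  r <- replay_lineages()
  expect_true(all(r$match[!r$flagged]))
  expect_true(all(!r$match[r$flagged]))
  expect_equal(sort(r$id[r$flagged]),
               c("chicken", "chimpanzee", "human"))
  moderns <- r[r$role == "modern" & !r$flagged, ]
  expect_true(all(moderns$computed_n == moderns$stated_n))
})

test_that("scenario tidiers expose the trace and the event tally", {
  k <- karyotype(as.list(LETTERS[1:4]))
  sc <- replay(k, list(ev_wgd(), ev_fusion(1, 2)))
  expect_equal(generics::tidy(sc)$n, c(8, 7))
  g <- generics::glance(sc)
  expect_equal(g$n_wgd, 1L)
  expect_equal(g$n_end, 7L)
})
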