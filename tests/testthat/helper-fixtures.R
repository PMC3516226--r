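# Shared fixtures, built in code. Expensive simulations are memoised per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  v <- get0(key, envir = .fixture_cache)
  if (is.null(v)) {
    v <- build()
    assign(key, v, envir = .fixture_cache)
  }
  v
}

# a small noise-free three-genome simulation (no WGD, no loss, no decoys
# beyond defaults) used across homology/synteny/ancestor tests
noise_free_sim <- function() {
  memo("noise_free", function() {
    cfg <- scale_profile(sim_config("plant", seed = 42), 0.1)
    simulate_genomes(cfg)
  })
}

noise_free_scan <- function() {
  memo("noise_free_scan", function() {
    sim <- noise_free_sim()
    pa <- pair_alignments(sim$hsps,
                          dplyr::select(sim$genes, gene_id, cds_length))
    hom <- call_homologs(pa, sim$genes, sim$divergence)
    list(sim = sim, homologs = hom,
         scan = detect_synteny(hom, sim$genes, n_shuffles = 300, seed = 5))
  })
}

# a minimal HSP tibble with the columns the homology module needs
hsp_tbl <- function(identities, lengths, starts = NULL, ends = NULL,
                    query = "q", subject = "s") {
  n <- length(identities)
  if (is.null(starts)) {
    ends <- cumsum(lengths)
    starts <- ends - lengths + 1
  }
  tibble::tibble(query_id = query, subject_id = subject,
                 pct_identity = 100 * identities / lengths,
                 hsp_length = lengths, identities = identities,
                 query_start = starts, query_end = ends,
                 subject_start = starts, subject_end = ends,
                 e_value = 1e-30, bit_score = 100)
}

# brute-force chaining oracle: enumerate every subset of the anchors,
# keep valid gap-bounded monotone chains, and peel greedily longest-first
# with the same tie rules as the implementation (prefer direct, then the
# lexicographically smallest index sequence)
oracle_chain_partition <- function(ra, rb, max_gap) {
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  valid_chain <- function(idx, dir) {
    if (length(idx) == 1) return(TRUE)
    da <- diff(ra[idx])
    db <- dir * diff(rb[idx])
    all(da >= 1 & da <= max_gap & db >= 1 & db <= max_gap)
  }
  lex_less <- function(a, b) { # numeric lexicographic order
    k <- min(length(a), length(b))
    d <- which(a[seq_len(k)] != b[seq_len(k)])
    if (length(d) > 0) return(a[d[1]] < b[d[1]])
    length(a) < length(b)
  }
  best_chain <- function(avail) {
    n <- length(avail)
    best <- NULL; best_dir <- NULL
    for (mask in seq_len(2^n - 1)) {
      idx <- avail[which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)]
      for (dir in c(1, -1)) {
        if (!valid_chain(idx, dir)) next
        better <- is.null(best) || length(idx) > length(best) ||
          (length(idx) == length(best) &&
             (dir > best_dir ||
                (dir == best_dir && lex_less(idx, best))))
        if (better) { best <- idx; best_dir <- dir }
      }
    }
    list(idx = best, dir = best_dir)
  }
  avail <- seq_along(ra)
  chains <- list()
  while (length(avail) > 0) {
    b <- best_chain(avail)
    chains[[length(chains) + 1L]] <-
      list(ranks = cbind(ra[b$idx], rb[b$idx]),
           orientation = if (length(b$idx) < 2 || b$dir == 1)
             "direct" else "inverted")
    avail <- setdiff(avail, b$idx)
  }
  chains
}

# anchors tibble on one chromosome pair, for chain_anchors
anchor_tbl <- function(ra, rb) {
  tibble::tibble(genome_a = "A", chromosome_a = "c1", genome_b = "B",
                 chromosome_b = "c1",
                 gene_a = sprintf("a%02d", seq_along(ra)),
                 gene_b = sprintf("b%02d", seq_along(rb)),
                 rank_a = ra, rank_b = rb, sign = 1L,
                 kind = "orthologous")
}
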