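#' Project homolog pairs onto gene orders as anchors
#'
#' Each homolog pair becomes an anchor carrying the gene ranks of its two
#' members and a relative orientation sign (the product of the member
#' strands).
#'
#' @param homologs homolog-pair tibble ([call_homologs()]).
#' @param genes ranked gene table.
#' @return anchor tibble: genomes, chromosomes, genes, `rank_a`, `rank_b`,
#'   `sign`, `kind` (orthologous/paralogous).
#' @export
anchors_from_homologs <- function(homologs, genes) {
  g <- select(genes, gene_id = "gene_id", genome = "genome_id",
              chromosome = "chromosome_id", rank = "rank",
              strand = "strand")
  a <- homologs |>
    inner_join(g, by = c(gene_a = "gene_id")) |>
    rename(chromosome_a = "chromosome", rank_a = "rank",
           strand_a = "strand") |>
    select(-"genome") |>
    inner_join(g, by = c(gene_b = "gene_id")) |>
    rename(chromosome_b = "chromosome", rank_b = "rank",
           strand_b = "strand") |>
    select(-"genome")
  tibble(genome_a = a$genome_a, chromosome_a = a$chromosome_a,
         genome_b = a$genome_b, chromosome_b = a$chromosome_b,
         gene_a = a$gene_a, gene_b = a$gene_b,
         rank_a = a$rank_a, rank_b = a$rank_b,
         sign = a$strand_a * a$strand_b,
         kind = ifelse(a$relation == "paralog", "paralogous", "orthologous"))
}

# longest gap-bounded monotone chain in one direction.
# anchors must be sorted by (rank_a, rank_b); returns indices of the
# lexicographically smallest maximum-length chain, or NULL.
longest_chain_dir <- function(ra, rb, max_gap, dir) {
  n <- length(ra)
  f <- rep(1L, n)
  for (i in seq(n - 1L, 1L, length.out = max(0L, n - 1L))) {
    for (j in seq(i + 1L, n, length.out = n - i)) {
      da <- ra[j] - ra[i]
      db <- dir * (rb[j] - rb[i])
      if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap &&
          f[j] + 1L > f[i]) f[i] <- f[j] + 1L
    }
  }
  m <- max(f)
  chain <- integer(0)
  need <- m
  last <- 0L
  for (i in seq_len(n)) {
    if (f[i] != need) next
    ok <- length(chain) == 0 || {
      da <- ra[i] - ra[last]
      db <- dir * (rb[i] - rb[last])
      da >= 1 && da <= max_gap && db >= 1 && db <= max_gap
    }
    if (ok) {
      chain <- c(chain, i)
      last <- i
      need <- need - 1L
      if (need == 0L) break
    }
  }
  chain
}

# greedy longest-chain-first partition of one chromosome pair's anchors
chain_partition <- function(ra, rb, max_gap) {
  idx <- order(ra, rb)
  ra <- ra[idx]; rb <- rb[idx]
  remaining <- seq_along(ra)
  chains <- list()
  while (length(remaining) > 0) {
    up <- longest_chain_dir(ra[remaining], rb[remaining], max_gap, 1L)
    dn <- longest_chain_dir(ra[remaining], rb[remaining], max_gap, -1L)
    # prefer the longer chain; ties prefer the direct orientation
    pick_up <- length(up) >= length(dn)
    ch <- if (pick_up) up else dn
    dir <- if (pick_up) "direct" else "inverted"
    if (length(ch) < 2) dir <- "direct"
    chains[[length(chains) + 1L]] <-
      list(idx = idx[remaining[ch]], orientation = dir)
    remaining <- remaining[-ch]
  }
  chains
}

#' Chain anchors into candidate collinear blocks
#'
#' Within each chromosome pair, anchors are partitioned into maximal
#' gap-bounded monotone chains: consecutive anchors of a chain differ by at
#' most `max_gap` gene ranks on both sides and follow a single direction
#' (direct or inverted). Chains are extracted greedily, longest first, so
#' each anchor belongs to at most one block per chromosome pair.
#'
#' @param anchors anchor tibble ([anchors_from_homologs()]).
#' @param max_gap maximum rank gap between consecutive anchors (default 20,
#'   the nominal cluster length).
#' @return candidate block tibble with an `anchors` list-column,
#'   `n_anchors`, rank spans, `cluster_length` and `orientation`.
#' @export
chain_anchors <- function(anchors, max_gap = 20) {
  if (nrow(anchors) == 0) return(empty_block_tbl())
  groups <- anchors |>
    distinct(.data$genome_a, .data$chromosome_a, .data$genome_b,
             .data$chromosome_b, .data$rank_a, .data$rank_b,
             .keep_all = TRUE) |>
    group_by(.data$genome_a, .data$chromosome_a, .data$genome_b,
             .data$chromosome_b, .data$kind) |>
    group_split()
  out <- purrr::map(groups, function(g) {
    chains <- chain_partition(g$rank_a, g$rank_b, max_gap)
    purrr::map(chains, function(ch) {
      a <- g[ch$idx, ] |> arrange(.data$rank_a)
      span_a <- max(a$rank_a) - min(a$rank_a) + 1
      span_b <- max(a$rank_b) - min(a$rank_b) + 1
      tibble(kind = a$kind[1],
             genome_a = a$genome_a[1], chromosome_a = a$chromosome_a[1],
             genome_b = a$genome_b[1], chromosome_b = a$chromosome_b[1],
             n_anchors = nrow(a),
             rank_start_a = min(a$rank_a), rank_end_a = max(a$rank_a),
             rank_start_b = min(a$rank_b), rank_end_b = max(a$rank_b),
             cluster_length = max(span_a, span_b),
             orientation = ch$orientation,
             anchors = list(select(a, "gene_a", "gene_b", "rank_a",
                                   "rank_b", "sign")))
    }) |> bind_rows()
  }) |> bind_rows()
  out$block_id <- sprintf("blk%05d", seq_len(nrow(out)))
  select(out, "block_id", dplyr::everything())
}

empty_block_tbl <- function() {
  tibble(block_id = character(), kind = character(),
         genome_a = character(), chromosome_a = character(),
         genome_b = character(), chromosome_b = character(),
         n_anchors = integer(), rank_start_a = double(),
         rank_end_a = double(), rank_start_b = double(),
         rank_end_b = double(), cluster_length = double(),
         orientation = character(), anchors = list())
}

# run body with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  body()
}

#' Longest gap-bounded monotone chain over a set of anchors
#'
#' The collinearity statistic used by the block validator: the longest run
#' of anchors whose consecutive members differ by 1 to `max_gap` gene
#' ranks on both sides and keep one direction (direct or inverted).
#'
#' @param rank_a,rank_b anchor gene ranks.
#' @param max_gap chaining gap bound.
#' @return integer chain length.
#' @export
max_chain_len <- function(rank_a, rank_b, max_gap = 20) {
  .max_chain_cpp(as.integer(rank_a), as.integer(rank_b),
                 as.integer(max_gap))
}

# Bonferroni bound on P(some monotone subsequence of length m among A
# uniformly ordered anchors): 2 * C(A, m) / m!; a gap-bounded chain is a
# monotone subsequence, so the bound holds for the chain statistic too
chain_p_bound <- function(A, m) {
  if (m > A) return(0)
  min(1, 2 * exp(lchoose(A, m) - lfactorial(m)))
}

# simulated null of the chain statistic under within-chromosome rank
# permutation: n_anchors anchors scattered uniformly over both chromosomes
chain_null_dist <- function(n_genes_a, n_genes_b, n_anchors, max_gap,
                            n_shuffles, seed) {
  with_local_seed(seed, function()
    .chain_null_cpp(as.integer(n_genes_a), as.integer(n_genes_b),
                    as.integer(min(n_anchors, n_genes_a, n_genes_b)),
                    as.integer(max_gap), as.integer(n_shuffles)))
}

#' Closed-form null probability for anchor co-clustering in a fixed window
#'
#' Under permutation of gene ranks, the number of the chromosome pair's
#' `n_anchors` anchors falling inside a fixed window of `window` gene ranks
#' (out of `n_genes`) is exactly Hypergeometric(n_genes, n_anchors,
#' window). Returns `P(count >= m)` — the closed form matched by the
#' Monte-Carlo `"window"` null of [validate_block()].
#'
#' @param n_anchors anchors on the chromosome pair.
#' @param n_genes genes on the scanned chromosome.
#' @param window window length in gene ranks.
#' @param m match number.
#' @return probability.
#' @export
window_p_closed_form <- function(n_anchors, n_genes, window, m) {
  stats::phyper(m - 1, window, n_genes - window, n_anchors,
                lower.tail = FALSE)
}

#' Statistically validate a candidate block (CloseUp-equivalent test)
#'
#' A block is valid when (a) its match number is at least `min_match`
#' (default 5), (b) its local anchor density `n_anchors / cluster_length`
#' is at least `min_density_ratio` (default 2) times the background
#' density, and (c) its Monte-Carlo collinearity p-value is below `alpha`.
#'
#' Two null statistics are available; both model the permutation of gene
#' ranks within chromosomes, which scatters the chromosome pair's anchors
#' uniformly over both rank spaces. The default (`null = "chain"`) tests
#' the nonrandomness of the *order*: the longest gap-bounded strictly
#' monotone run among the scattered anchors is compared with the block's
#' match number; a subsequence-counting bound (`2 C(A,m)/m!`)
#' short-circuits the simulation when the probability is negligible.
#' `null = "window"` tests positional co-clustering instead: the count of
#' anchors falling in a fixed window of `cluster_length` ranks, whose
#' null is exactly hypergeometric (see [window_p_closed_form()]).
#'
#' @param block one-row candidate block tibble ([chain_anchors()]).
#' @param background background anchor density for the chromosome pair, in
#'   anchors per gene (see [detect_synteny()] for the default computation).
#' @param n_genes_a,n_genes_b genes on the two chromosomes (`n_genes_b`
#'   defaults to `n_genes_a`).
#' @param n_anchors_pair anchors attributable to the null on this
#'   chromosome pair (in the peeled scheme of [detect_synteny()], anchors
#'   not already absorbed by stronger validated blocks).
#' @param n_shuffles Monte-Carlo permutations (at least 100).
#' @param seed RNG seed for the permutations.
#' @param min_match,min_density_ratio,alpha acceptance parameters.
#' @param null `"chain"` (collinearity, default) or `"window"`
#'   (positional clustering).
#' @param max_gap gap bound of the chain statistic (chain null).
#' @param null_dist optional precomputed null statistic sample (reused
#'   across blocks sharing the same null).
#' @return one-row tibble: `density_ratio`, `p_value`, `valid`, `reason`.
#' @export
validate_block <- function(block, background, n_genes_a, n_anchors_pair,
                           n_shuffles = 1000, seed = 1, min_match = 5,
                           min_density_ratio = 2, alpha = 0.05,
                           null = c("chain", "window"), max_gap = 20,
                           n_genes_b = n_genes_a, null_dist = NULL) {
  null <- match.arg(null)
  pk_assert(n_shuffles >= 100,
            "n_shuffles must be >= 100 for a stable p-value")
  m <- block$n_anchors[1]
  L <- block$cluster_length[1]
  density_ratio <- (m / L) / background
  A <- n_anchors_pair
  if (null == "chain") {
    if (is.null(null_dist) && chain_p_bound(A, m) < 1e-6) {
      p <- 0
    } else {
      if (is.null(null_dist))
        null_dist <- chain_null_dist(n_genes_a, n_genes_b, A, max_gap,
                                     n_shuffles, seed)
      p <- mean(null_dist >= m)
    }
  } else {
    Lw <- min(L, n_genes_a)
    Aw <- min(A, n_genes_a)
    p <- with_local_seed(seed, function()
      mean(vapply(seq_len(n_shuffles), function(i)
        sum(sample.int(n_genes_a, Aw) <= Lw) >= m, NA)))
  }
  reason <- if (m < min_match) "match_number"
  else if (density_ratio < min_density_ratio) "density"
  else if (p >= alpha) "p_value"
  else NA_character_
  tibble(density_ratio = density_ratio, p_value = p,
         valid = is.na(reason), reason = reason)
}

#' Detect and validate synteny and duplication blocks
#'
#' The full block-detection stage: homolog pairs are projected to anchors,
#' chained into candidate blocks per chromosome pair, and validated with
#' the CloseUp-equivalent test (match number 5, density ratio 2, cluster
#' length 20, Monte-Carlo p < 0.05). The background density passed to the
#' validator is the chance co-localization rate on both chromosomes,
#' `A * L0 / (Na * Nb)` anchors per gene, with `A` the anchors on the
#' chromosome pair, `Na`/`Nb` the chromosome gene counts and `L0` the
#' nominal cluster length.
#'
#' @param homologs homolog-pair tibble.
#' @param genes ranked gene table.
#' @param max_gap chaining gap bound in gene ranks.
#' @param min_match,min_density_ratio,cluster_length_ref,alpha validation
#'   parameters (defaults 5, 2, 20, 0.05).
#' @param n_shuffles Monte-Carlo permutations per block.
#' @param seed master seed; each block gets a derived seed.
#' @return a `synteny_scan` object: list with `blocks` (all candidates,
#'   with `valid` flag, bp spans, `density_ratio`, `p_value`), `anchors`,
#'   and `params`. Use [synteny_blocks()] for the validated subset.
#' @export
detect_synteny <- function(homologs, genes, max_gap = 20, min_match = 5,
                           min_density_ratio = 2, cluster_length_ref = 20,
                           n_shuffles = 1000, alpha = 0.05, seed = 1,
                           null = c("chain", "window")) {
  null <- match.arg(null)
  anchors <- anchors_from_homologs(homologs, genes)
  cand <- chain_anchors(anchors, max_gap = max_gap)
  gene_counts <- genes |>
    dplyr::count(.data$genome_id, .data$chromosome_id, name = "n_genes")
  nk <- setNames(gene_counts$n_genes,
                 paste(gene_counts$genome_id, gene_counts$chromosome_id))
  if (nrow(cand) > 0) {
    pair_counts <- anchors |>
      dplyr::count(.data$genome_a, .data$chromosome_a, .data$genome_b,
                   .data$chromosome_b, name = "n_anchors_pair")
    cand <- left_join(cand, pair_counts,
                      by = c("genome_a", "chromosome_a",
                             "genome_b", "chromosome_b"))
    # blocks of a chromosome pair are validated strongest-first, each
    # against the anchors not already absorbed by an accepted block
    # (peeling), so a real small block next to a large one is not judged
    # against the large block's own anchors; the simulated null is cached
    # by its (Na, Nb, A) signature
    null_cache <- new.env(parent = emptyenv())
    get_null <- function(na, nb, A, m) {
      if (null != "chain" || chain_p_bound(A, m) < 1e-6) return(NULL)
      key <- paste(na, nb, A)
      nd <- get0(key, envir = null_cache)
      if (is.null(nd)) {
        nd <- chain_null_dist(na, nb, A, max_gap, n_shuffles,
                              seed + na + 7L * nb + 13L * A)
        assign(key, nd, envir = null_cache)
      }
      nd
    }
    absorbed <- new.env(parent = emptyenv())
    res <- vector("list", nrow(cand))
    for (i in order(-cand$n_anchors)) {
      b <- cand[i, ]
      pair_key <- paste(b$genome_a, b$chromosome_a, b$genome_b,
                        b$chromosome_b)
      used <- get0(pair_key, envir = absorbed) %||% 0L
      na <- unname(nk[paste(b$genome_a, b$chromosome_a)])
      nb <- unname(nk[paste(b$genome_b, b$chromosome_b)])
      A <- max(b$n_anchors, b$n_anchors_pair - used)
      bg <- b$n_anchors_pair * cluster_length_ref / (na * nb)
      v <- validate_block(b, background = bg, n_genes_a = na,
                          n_genes_b = nb, n_anchors_pair = A,
                          n_shuffles = n_shuffles, seed = seed + i,
                          min_match = min_match,
                          min_density_ratio = min_density_ratio,
                          alpha = alpha, null = null, max_gap = max_gap,
                          null_dist = get_null(na, nb, A, b$n_anchors))
      if (v$valid)
        assign(pair_key, used + b$n_anchors, envir = absorbed)
      res[[i]] <- v
    }
    cand <- bind_cols(cand, bind_rows(res))
    cand <- add_bp_spans(cand, genes)
  } else {
    cand <- mutate(cand, n_anchors_pair = integer(),
                   density_ratio = double(), p_value = double(),
                   valid = logical(), reason = character(),
                   bp_start_a = double(), bp_end_a = double(),
                   bp_start_b = double(), bp_end_b = double())
  }
  structure(list(blocks = cand, anchors = anchors,
                 params = list(max_gap = max_gap, min_match = min_match,
                               min_density_ratio = min_density_ratio,
                               cluster_length_ref = cluster_length_ref,
                               n_shuffles = n_shuffles, alpha = alpha,
                               seed = seed),
                 genes = genes),
            class = "synteny_scan")
}

add_bp_spans <- function(blocks, genes) {
  pos <- setNames(seq_len(nrow(genes)), genes$gene_id)
  span <- function(ids) {
    g <- genes[pos[ids], ]
    c(min(g$start), max(g$end))
  }
  sp <- purrr::map(seq_len(nrow(blocks)), function(i) {
    a <- blocks$anchors[[i]]
    sa <- span(a$gene_a)
    sb <- span(a$gene_b)
    tibble(bp_start_a = sa[1], bp_end_a = sa[2],
           bp_start_b = sb[1], bp_end_b = sb[2])
  }) |> bind_rows()
  bind_cols(blocks, sp)
}

#' Validated blocks of a synteny scan
#' @param scan a `synteny_scan` object.
#' @param kind optionally restrict to `"orthologous"` or `"paralogous"`.
#' @return tibble of validated blocks.
#' @export
synteny_blocks <- function(scan, kind = NULL) {
  b <- filter(scan$blocks, .data$valid)
  if (!is.null(kind)) b <- filter(b, .data$kind == !!kind)
  b
}

#' @export
print.synteny_scan <- function(x, ...) {
  b <- x$blocks
  cat(sprintf("<synteny_scan> %d candidate blocks, %d validated (%d orthologous, %d paralogous)\n",
              nrow(b), sum(b$valid),
              sum(b$valid & b$kind == "orthologous"),
              sum(b$valid & b$kind == "paralogous")))
  invisible(x)
}

# >=1 anchor of ortholog block `o` inside a copy span on genome `side`
anchor_overlap <- function(o, chrom, lo, hi, side) {
  a <- o$anchors[[1]]
  if (side == "a")
    o$chromosome_a == chrom && any(a$rank_a >= lo & a$rank_a <= hi)
  else
    o$chromosome_b == chrom && any(a$rank_b >= lo & a$rank_b <= hi)
}

# copies of a paralog block as (chromosome, rank range) pairs
block_copies <- function(b) {
  list(list(chrom = b$chromosome_a, lo = b$rank_start_a, hi = b$rank_end_a),
       list(chrom = b$chromosome_b, lo = b$rank_start_b, hi = b$rank_end_b))
}

# ortholog blocks linking genome g1 copy region to genome g2 copy region
links_copy <- function(orth, g1, copy1, g2, copy2) {
  hits <- character(0)
  for (i in seq_len(nrow(orth))) {
    o <- orth[i, ]
    if (o$genome_a == g1 && o$genome_b == g2) {
      if (anchor_overlap(o, copy1$chrom, copy1$lo, copy1$hi, "a") &&
          anchor_overlap(o, copy2$chrom, copy2$lo, copy2$hi, "b"))
        hits <- c(hits, o$block_id)
    } else if (o$genome_a == g2 && o$genome_b == g1) {
      if (anchor_overlap(o, copy2$chrom, copy2$lo, copy2$hi, "a") &&
          anchor_overlap(o, copy1$chrom, copy1$lo, copy1$hi, "b"))
        hits <- c(hits, o$block_id)
    }
  }
  hits
}

#' Classify duplicated blocks as shared-ancestral or lineage-specific
#'
#' A duplicated (paralogous) block in genome A descends from a
#' pre-speciation duplication — and is classified `ancestral` — when both
#' of its copies lie at positions orthologous (sharing at least one anchor
#' of a validated ortholog block each) to the two copies of a duplicated
#' block in some other genome B. Otherwise it is `lineage_specific`
#' (post-speciation).
#'
#' @param paralog_blocks validated paralogous block tibble.
#' @param ortholog_blocks validated orthologous block tibble.
#' @return tibble: `block_id`, `genome_id`, `status`, `evidence`
#'   (list-column of supporting cross-genome block ids).
#' @export
classify_duplications <- function(paralog_blocks, ortholog_blocks) {
  if (nrow(paralog_blocks) == 0)
    return(tibble(block_id = character(), genome_id = character(),
                  status = character(), evidence = list()))
  purrr::map(seq_len(nrow(paralog_blocks)), function(i) {
    p <- paralog_blocks[i, ]
    gA <- p$genome_a
    cp <- block_copies(p)
    status <- "lineage_specific"
    evidence <- character(0)
    others <- unique(c(paralog_blocks$genome_a,
                       ortholog_blocks$genome_a,
                       ortholog_blocks$genome_b))
    for (gB in setdiff(others, gA)) {
      qs <- filter(paralog_blocks, .data$genome_a == gB)
      for (j in seq_len(nrow(qs))) {
        q <- qs[j, ]
        cq <- block_copies(q)
        for (perm in list(c(1, 2), c(2, 1))) {
          e1 <- links_copy(ortholog_blocks, gA, cp[[1]], gB, cq[[perm[1]]])
          e2 <- links_copy(ortholog_blocks, gA, cp[[2]], gB, cq[[perm[2]]])
          if (length(e1) > 0 && length(e2) > 0) {
            status <- "ancestral"
            evidence <- unique(c(evidence, q$block_id, e1[1], e2[1]))
          }
        }
      }
    }
    tibble(block_id = p$block_id, genome_id = gA, status = status,
           evidence = list(evidence))
  }) |> bind_rows()
}

#' Coverage summary in the orthologs-blocks-percent schema
#'
#' Number of anchors, number of blocks, and percent of the genome covered
#' by the union of block spans (interval union, so overlapping blocks are
#' not double counted; percentage rounded to integer).
#'
#' @param blocks block tibble (validated).
#' @param genes ranked gene table (used for genome length when
#'   `genome_lengths` is absent).
#' @param genome genome id to summarise.
#' @param genome_lengths optional tibble `chromosome_id`, `length_bp`.
#' @return one-row tibble: `genome_id`, `n_anchors`, `n_blocks`,
#'   `pct_coverage`.
#' @export
coverage_summary <- function(blocks, genes, genome, genome_lengths = NULL) {
  sides <- bind_rows(
    blocks |> filter(.data$genome_a == genome) |>
      select(chromosome = "chromosome_a", start = "bp_start_a",
             end = "bp_end_a"),
    blocks |> filter(.data$genome_b == genome) |>
      select(chromosome = "chromosome_b", start = "bp_start_b",
             end = "bp_end_b"))
  n_blocks <- sum(blocks$genome_a == genome | blocks$genome_b == genome)
  n_anchors <- sum(blocks$n_anchors[blocks$genome_a == genome |
                                      blocks$genome_b == genome])
  if (is.null(genome_lengths)) {
    genome_lengths <- genes |>
      filter(.data$genome_id == genome) |>
      group_by(chromosome_id = .data$chromosome_id) |>
      summarise(length_bp = max(.data$end), .groups = "drop")
  }
  total_len <- sum(genome_lengths$length_bp)
  covered <- 0
  for (ch in unique(sides$chromosome)) {
    s <- filter(sides, .data$chromosome == ch)
    covered <- covered +
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s$start, s$end))))
  }
  tibble(genome_id = genome, n_anchors = n_anchors, n_blocks = n_blocks,
         pct_coverage = round(100 * covered / total_len))
}
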