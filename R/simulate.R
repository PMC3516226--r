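# Genome-evolution simulator: a protochromosome ancestor evolved through
# scripted WGD / fission / fusion / inversion events with post-duplication
# gene loss, divergence-dependent identity decay of emitted HSPs, and
# plant-like (nested hot-spot) or animal-like (homogeneous) TE landscapes.
# Every emitted gene descends from a known family, so the ground-truth
# ledger carries the answers the pipeline is expected to recover.

#' Simulation configuration
#'
#' Defaults encode the study conditions: a plant-like ancestor of 5
#' protochromosomes (animal-like: 10), 12,000 protogenes (animal-like:
#' 16,000; scale down with [scale_profile()] for desk-scale runs),
#' identity models straddling the 70/50 CIP/CALP thresholds (close pairs
#' mean 85%, distant 60%, paralogs 65%, sd 5), ~2 HSP fragments per pair
#' covering 95% of the query, decoy (non-homologous) HSPs at 10% of the
#' true-pair count around 40% identity, and TE landscapes targeting the
#' published window coverages (plant class I hot-spots up to ~58%, mean
#' ~23%; animal homogeneous ~9% LTR / ~33% non-LTR).
#'
#' @param mode `"plant"` or `"animal"`; sets ancestor size and TE model.
#' @param n_protochromosomes,n_protogenes ancestor dimensions.
#' @param lineages list of per-lineage event budgets, each a list with
#'   `name` and counts `wgd`, `n_fis`, `n_fus`, `n_inv`.
#' @param gene_loss_rate probability that a duplicated family loses one
#'   copy (chosen uniformly) after WGD.
#' @param random_gene_loss per-gene deletion probability in descendants
#'   (annotation/fractionation noise, independent of duplication).
#' @param divergence_class class of every cross-genome pair (`"close"` or
#'   `"distant"`); intra-genome comparisons are always `"distant"` (WGDs
#'   are ancient).
#' @param identity named list of `c(mean, sd)` percent-identity models for
#'   `close`, `distant` and `paralog` pairs.
#' @param hsp_fragments_mean,hsp_coverage fragmentation model: mean HSP
#'   count per pair, fraction of the query covered.
#' @param decoy_rate,decoy_identity decoy HSP injection.
#' @param min_segment_genes rearrangement breakpoints keep at least this
#'   many genes on each side, so no simulated segment falls below the
#'   block-detection scale.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(mode = c("plant", "animal"),
                       n_protochromosomes = NULL, n_protogenes = NULL,
                       lineages = NULL, gene_loss_rate = 0,
                       random_gene_loss = 0,
                       divergence_class = "close",
                       identity = list(close = c(mean = 85, sd = 5),
                                       distant = c(mean = 60, sd = 5),
                                       paralog = c(mean = 65, sd = 5)),
                       hsp_fragments_mean = 2, hsp_coverage = 0.95,
                       decoy_rate = 0.1, decoy_identity = 40,
                       min_segment_genes = 25, seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    n_protochromosomes = n_protochromosomes %||%
      if (mode == "plant") 5L else 10L,
    n_protogenes = n_protogenes %||%
      if (mode == "plant") 12000L else 16000L,
    lineages = lineages %||% list(
      list(name = "g1", wgd = 0L, n_fis = 1L, n_fus = 1L, n_inv = 0L),
      list(name = "g2", wgd = 0L, n_fis = 1L, n_fus = 0L, n_inv = 0L),
      list(name = "g3", wgd = 0L, n_fis = 0L, n_fus = 1L, n_inv = 0L)),
    gene_loss_rate = gene_loss_rate,
    random_gene_loss = random_gene_loss,
    divergence_class = divergence_class,
    identity = identity,
    hsp_fragments_mean = hsp_fragments_mean,
    hsp_coverage = hsp_coverage,
    decoy_rate = decoy_rate, decoy_identity = decoy_identity,
    min_segment_genes = min_segment_genes,
    gene_len = c(meanlog = log(1200), sdlog = 0.35),
    gene_gap_mean = if (mode == "plant") 4000 else 8000,
    te = if (mode == "plant")
      list(hotspot_frac = 0.15,
           classI_LTR = list(hot = c(57, 2), bg = c(17, 3)),
           classI_nonLTR = list(bg = c(3, 1)),
           classII = list(bg = c(5, 1.5)))
    else
      list(hotspot_frac = 0,
           classI_LTR = list(bg = c(9, 1.5)),
           classI_nonLTR = list(bg = c(33, 3)),
           classII = list(bg = c(3, 1))),
    seed = seed)
  pk_assert(cfg$gene_loss_rate >= 0 && cfg$gene_loss_rate <= 1 &&
              cfg$random_gene_loss >= 0 && cfg$random_gene_loss <= 1,
            "probabilities must be in [0, 1]")
  pk_assert(cfg$n_protochromosomes >= 1 && cfg$n_protogenes >= 1,
            "counts must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Scale a simulation profile down for desk-scale runs
#'
#' Scales gene counts (and hence chromosome lengths) by `factor`, leaving
#' rates and models unchanged.
#'
#' @param config a `sim_config`.
#' @param factor scaling factor in (0, 1].
#' @return the scaled `sim_config`.
#' @export
scale_profile <- function(config, factor) {
  pk_assert(is.numeric(factor) && factor > 0 && factor <= 1,
            "scale factor must be in (0, 1]")
  config$n_protogenes <- max(config$n_protochromosomes,
                             as.integer(round(config$n_protogenes * factor)))
  config
}

rtrunc_norm <- function(n, mean, sd, lo = 5, hi = 99.5) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

# lineage genomes are lists of chromosomes; each chromosome is a tibble
# (family_id, anc_chrom, copy, strand, cds_length)

sim_ancestor <- function(cfg) {
  n <- cfg$n_protogenes
  per <- diff(round(seq(0, n, length.out = cfg$n_protochromosomes + 1)))
  fam <- sprintf("fam%05d", seq_len(n))
  cds <- round(rlnorm(n, cfg$gene_len["meanlog"], cfg$gene_len["sdlog"]))
  idx <- 0L
  lapply(seq_len(cfg$n_protochromosomes), function(ci) {
    take <- idx + seq_len(per[ci])
    idx <<- idx + per[ci]
    tibble(family_id = fam[take], anc_chrom = sprintf("P%02d", ci),
           copy = 1L, strand = 1L, cds_length = cds[take])
  })
}

flip_genes <- function(ch) {
  out <- ch[rev(seq_len(nrow(ch))), ]
  out$strand <- -out$strand
  out
}

# one random applicable event; returns list(genome, step) where step is the
# count-arithmetic op ("+1", "-1", "wgd") or NULL for inversions
apply_random_event <- function(genome, kind, min_seg, ccf_prob = 0) {
  lens <- vapply(genome, nrow, 0L)
  if (kind == "wgd") {
    bump <- max(vapply(genome, function(ch) max(ch$copy), 0L))
    dup <- lapply(genome, function(ch) {
      ch$copy <- ch$copy + bump
      ch
    })
    return(list(genome = c(genome, dup), step = "wgd"))
  }
  if (kind == "fission") {
    ok <- which(lens >= 2 * min_seg)
    if (length(ok) == 0) return(NULL)
    i <- if (length(ok) == 1) ok else sample(ok, 1)
    pos <- sample(seq(min_seg, lens[i] - min_seg), 1)
    genome[[length(genome) + 1L]] <- genome[[i]][(pos + 1):lens[i], ]
    genome[[i]] <- genome[[i]][seq_len(pos), ]
    return(list(genome = genome, step = "+1"))
  }
  if (kind == "fusion") {
    if (length(genome) < 2) return(NULL)
    ij <- sample(length(genome), 2)
    a <- genome[[ij[1]]]
    b <- genome[[ij[2]]]
    if (runif(1) < 0.5) a <- flip_genes(a)
    if (runif(1) < 0.5) b <- flip_genes(b)
    fused <- if (runif(1) < ccf_prob && nrow(a) >= 2 * min_seg) {
      pos <- sample(seq(min_seg, nrow(a) - min_seg), 1) # nested (CCF)
      bind_rows(a[seq_len(pos), ], b, a[(pos + 1):nrow(a), ])
    } else bind_rows(a, b) # telomeric (TCF)
    genome[[ij[1]]] <- fused
    genome[[ij[2]]] <- NULL
    return(list(genome = genome, step = "-1"))
  }
  if (kind == "inversion") {
    ok <- which(lens >= 2 * min_seg)
    if (length(ok) == 0) return(NULL)
    i <- if (length(ok) == 1) ok else sample(ok, 1)
    L <- lens[i]
    from <- sample(seq_len(L - min_seg + 1), 1)
    to <- min(L, from + min_seg - 1 + rpois(1, min_seg))
    ch <- genome[[i]]
    ch[from:to, ] <- flip_genes(ch[from:to, ])
    genome[[i]] <- ch
    return(list(genome = genome, step = NULL))
  }
  pk_stop("unknown simulated event kind '%s'", kind)
}

sim_lineage <- function(genome, budget, cfg) {
  steps <- character(0)
  ccf_prob <- if (cfg$mode == "plant") 0.5 else 0
  for (w in seq_len(budget$wgd %||% 0)) {
    r <- apply_random_event(genome, "wgd", cfg$min_segment_genes)
    genome <- r$genome
    steps <- c(steps, r$step)
  }
  others <- sample(c(rep("fission", budget$n_fis %||% 0),
                     rep("fusion", budget$n_fus %||% 0),
                     rep("inversion", budget$n_inv %||% 0)))
  for (kind in others) {
    r <- apply_random_event(genome, kind, cfg$min_segment_genes, ccf_prob)
    if (is.null(r)) next
    genome <- r$genome
    if (!is.null(r$step)) steps <- c(steps, r$step)
  }
  list(genome = genome, steps = steps)
}

# post-WGD diploidization: each multi-copy family loses one uniformly
# chosen copy with probability `rate`; random per-gene loss follows
apply_gene_loss <- function(genome, rate, random_rate) {
  flat <- bind_rows(purrr::imap(genome, function(ch, i)
    mutate(ch, .chrom = i, .row = row_number())))
  drop <- tibble(.chrom = integer(), .row = integer())
  if (rate > 0) {
    dup <- flat |>
      group_by(.data$family_id) |>
      filter(n() > 1) |>
      group_split()
    lost <- purrr::map(dup, function(g) {
      if (runif(1) < rate) g[sample(nrow(g), 1), c(".chrom", ".row")]
      else NULL
    })
    drop <- bind_rows(drop, bind_rows(lost))
  }
  if (random_rate > 0) {
    keepable <- anti_join(flat, drop, by = c(".chrom", ".row"))
    hit <- runif(nrow(keepable)) < random_rate
    drop <- bind_rows(drop, keepable[hit, c(".chrom", ".row")])
  }
  if (nrow(drop) == 0) return(genome)
  for (ci in unique(drop$.chrom)) {
    rows <- drop$.row[drop$.chrom == ci]
    if (length(rows) >= nrow(genome[[ci]])) # never empty a chromosome
      rows <- rows[-1]
    if (length(rows) > 0) genome[[ci]] <- genome[[ci]][-rows, ]
  }
  genome
}

# lay a lineage genome onto bp coordinates
materialize_genome <- function(genome, name, gap_mean) {
  purrr::imap(genome, function(ch, ci) {
    n <- nrow(ch)
    gaps <- round(rexp(n, 1 / gap_mean)) + 200
    starts <- cumsum(gaps + dplyr::lag(ch$cds_length, default = 0))
    tibble(genome_id = name, chromosome_id = sprintf("chr%02d", ci),
           gene_id = sprintf("%s_%s_c%d", name, ch$family_id, ch$copy),
           family_id = ch$family_id, anc_chrom = ch$anc_chrom,
           copy = ch$copy, start = starts,
           end = starts + ch$cds_length - 1, strand = ch$strand,
           cds_length = ch$cds_length)
  }) |> bind_rows()
}

sim_hsps <- function(pairs, gene_len, cfg) {
  if (nrow(pairs) == 0) return(empty_hsp_tbl())
  mm <- vapply(cfg$identity, `[[`, 0, 1)
  ss <- vapply(cfg$identity, `[[`, 0, 2)
  pct <- rtrunc_norm(nrow(pairs), mm[pairs$model], ss[pairs$model])
  k <- pmax(1L, rpois(nrow(pairs), cfg$hsp_fragments_mean - 1) + 1L)
  qlen <- unname(gene_len[pairs$query_id])
  idx <- rep(seq_len(nrow(pairs)), k)
  frag <- unlist(lapply(k, seq_len))
  ktot <- k[idx]
  slot <- floor(qlen[idx] / ktot)
  flen <- pmax(10, floor(slot * cfg$hsp_coverage))
  qs <- (frag - 1) * slot + 1
  qe <- qs + flen - 1
  tibble(query_id = pairs$query_id[idx], subject_id = pairs$subject_id[idx],
         pct_identity = pct[idx], hsp_length = flen,
         identities = round_half_away(pct[idx] / 100 * flen),
         query_start = qs, query_end = qe,
         subject_start = qs, subject_end = qe,
         e_value = 10^(-pmin(180, flen * pct[idx] / 100)),
         bit_score = round(2 * flen * pct[idx] / 100, 1))
}

#' Run the genome-evolution simulator
#'
#' Builds the protochromosome ancestor, applies shared (pre-speciation)
#' events, speciates the configured lineages and applies their events,
#' removes duplicated gene copies at the diploidization loss rate, lays
#' genes onto bp coordinates, emits per-pair HSP tables (true homologs at
#' the configured identity models plus sub-threshold decoys), draws TE
#' annotations from the plant- or animal-like spatial model, and records
#' the full ground truth.
#'
#' @param config a [sim_config()].
#' @param pre_speciation optional shared event budget (same shape as a
#'   lineage spec) applied to the ancestor before speciation.
#' @return a `paleo_sim` list: `genes`, `hsps`, `tes`, `chrom_lengths`,
#'   `divergence`, `config` and `ground_truth` (`ancestor_n`, `families`,
#'   `true_pairs`, `true_segments`, `scenarios`, `te_coverage`).
#' @export
simulate_genomes <- function(config, pre_speciation = NULL) {
  with_local_seed(config$seed, function() {
    anc <- sim_ancestor(config)
    if (!is.null(pre_speciation)) {
      r <- sim_lineage(anc, pre_speciation, config)
      anc <- r$genome
      anc <- apply_gene_loss(anc, config$gene_loss_rate, 0)
    }
    ancestor_n <- length(anc)
    ancestor_max_copy <- max(vapply(anc, function(ch) max(ch$copy), 0L))
    lineage_out <- purrr::map(config$lineages, function(sp) {
      r <- sim_lineage(anc, sp, config)
      g <- apply_gene_loss(r$genome, config$gene_loss_rate,
                           config$random_gene_loss)
      list(name = sp$name, genome = g, steps = r$steps)
    })
    genes <- purrr::map(lineage_out, function(lo)
      materialize_genome(lo$genome, lo$name, config$gene_gap_mean)) |>
      bind_rows() |>
      assign_ranks()
    chrom_lengths <- genes |>
      group_by(.data$genome_id, .data$chromosome_id) |>
      summarise(length_bp = max(.data$end) + 5000, .groups = "drop")
    # round chromosome length to full windows half the time is unneeded;
    # keep the natural length
    truth_pairs <- true_homolog_pairs(genes, config$divergence_class,
                                      ancestor_max_copy)
    hsp_pairs <- bind_rows(
      truth_pairs |>
        transmute(query_id = .data$gene_a, subject_id = .data$gene_b,
                  model = .data$model),
      truth_pairs |>
        transmute(query_id = .data$gene_b, subject_id = .data$gene_a,
                  model = .data$model))
    gene_len <- setNames(genes$cds_length, genes$gene_id)
    hsps <- sim_hsps(hsp_pairs, gene_len, config)
    # decoys: random cross-family pairs at sub-threshold identity
    n_decoy <- round(config$decoy_rate * nrow(truth_pairs))
    if (n_decoy > 0) {
      qi <- sample(genes$gene_id, n_decoy, replace = TRUE)
      si <- sample(genes$gene_id, n_decoy, replace = TRUE)
      fam <- setNames(genes$family_id, genes$gene_id)
      keep <- fam[qi] != fam[si]
      dq <- qi[keep]; ds <- si[keep]
      if (length(dq) > 0) {
        dcfg <- config
        dcfg$identity$decoy <- c(mean = config$decoy_identity, sd = 3)
        dcfg$hsp_coverage <- 0.5
        dcfg$hsp_fragments_mean <- 1
        dec <- sim_hsps(tibble(query_id = dq, subject_id = ds,
                               model = "decoy"), gene_len, dcfg)
        hsps <- bind_rows(hsps, dec)
      }
    }
    te <- sim_tes(chrom_lengths, config)
    genome_ids <- vapply(lineage_out, `[[`, "", "name")
    div <- divergence_table(genome_ids, config$divergence_class)
    div$class[div$genome_a == div$genome_b] <- "distant"
    n_chrom <- genes |>
      distinct(.data$genome_id, .data$chromosome_id) |>
      dplyr::count(.data$genome_id, name = "n")
    n_of <- setNames(n_chrom$n, n_chrom$genome_id)
    scen <- purrr::map(lineage_out, function(lo)
      tibble(lineage = lo$name, start_n = ancestor_n,
             steps = list(lo$steps),
             n_final = unname(n_of[lo$name]))) |>
      bind_rows()
    structure(list(
      genes = genes, hsps = hsps, tes = te$tes,
      chrom_lengths = chrom_lengths, divergence = div, config = config,
      ground_truth = list(
        ancestor_n = ancestor_n,
        families = genes |>
          arrange(.data$genome_id, .data$chromosome_id, .data$rank) |>
          group_by(.data$genome_id, .data$chromosome_id) |>
          mutate(run_id = paste(.data$genome_id, .data$chromosome_id,
                                cumsum(c(1L, as.integer(
                                  paste(.data$anc_chrom, .data$copy)[-1] !=
                                    paste(.data$anc_chrom,
                                          .data$copy)[-n()]))))) |>
          ungroup() |>
          select("gene_id", "genome_id", "family_id", "anc_chrom",
                 "copy", "run_id"),
        true_pairs = truth_pairs,
        true_segments = true_segments(genes),
        scenarios = scen,
        te_coverage = te$coverage)),
      class = "paleo_sim")
  })
}

# All same-family gene pairs. The identity model of a pair reflects its
# divergence date: same-genome pairs and cross-genome pairs whose copies
# split at a pre-speciation WGD follow the (older) paralog model;
# cross-genome pairs that split at speciation follow the divergence-class
# model. `ancestor_max_copy` is the highest copy index present at
# speciation: copies above it arose later, inside one lineage.
true_homolog_pairs <- function(genes, divergence_class = "close",
                               ancestor_max_copy = 1L) {
  g <- select(genes, "gene_id", "genome_id", "family_id", "copy")
  x <- inner_join(g, g, by = "family_id", suffix = c("_a", "_b"),
                  relationship = "many-to-many") |>
    filter(.data$gene_id_a < .data$gene_id_b)
  same_genome <- x$genome_id_a == x$genome_id_b
  pre_split <- x$copy_a <= ancestor_max_copy &
    x$copy_b <= ancestor_max_copy & x$copy_a != x$copy_b
  tibble(gene_a = x$gene_id_a, gene_b = x$gene_id_b,
         genome_a = x$genome_id_a, genome_b = x$genome_id_b,
         copy_a = x$copy_a, copy_b = x$copy_b,
         relation = ifelse(same_genome, "paralog", "ortholog"),
         model = ifelse(same_genome | pre_split, "paralog",
                        divergence_class))
}

true_segments <- function(genes) {
  genes |>
    arrange(.data$genome_id, .data$chromosome_id, .data$rank) |>
    group_by(.data$genome_id, .data$chromosome_id) |>
    mutate(seg_break = cumsum(
      c(1L, as.integer(paste(.data$anc_chrom, .data$copy)[-1] !=
                         paste(.data$anc_chrom, .data$copy)[-n()])))) |>
    group_by(.data$genome_id, .data$chromosome_id, .data$seg_break) |>
    summarise(anc_chrom = first(.data$anc_chrom), copy = first(.data$copy),
              start_rank = min(.data$rank), end_rank = max(.data$rank),
              n_genes = n(), .groups = "drop")
}

sim_tes <- function(chrom_lengths, cfg, window_bp = 500000) {
  tes <- list()
  cov <- list()
  for (i in seq_len(nrow(chrom_lengths))) {
    gid <- chrom_lengths$genome_id[i]
    chrom <- chrom_lengths$chromosome_id[i]
    len <- chrom_lengths$length_bp[i]
    n_win <- ceiling(len / window_bp)
    w0 <- (seq_len(n_win) - 1) * window_bp
    w1 <- pmin(w0 + window_bp, len)
    hot <- runif(n_win) < cfg$te$hotspot_frac
    for (cls in TE_CLASSES) {
      m <- cfg$te[[cls]]
      target <- if (!is.null(m$hot))
        ifelse(hot, rnorm(n_win, m$hot[1], m$hot[2]),
               rnorm(n_win, m$bg[1], m$bg[2]))
      else rnorm(n_win, m$bg[1], m$bg[2])
      target <- pmin(90, pmax(0, target))
      for (w in seq_len(n_win)) {
        wlen <- w1[w] - w0[w]
        bp <- round(target[w] / 100 * wlen)
        if (bp < 50) { target[w] <- 0; next }
        n_iv <- max(1L, min(5L, rpois(1, 3)))
        slot <- floor(wlen / n_iv)
        part <- diff(round(seq(0, bp, length.out = n_iv + 1)))
        part <- pmin(part, slot - 2)
        starts <- w0[w] + (seq_len(n_iv) - 1) * slot +
          floor((slot - part) / 2) + 1
        keep <- part >= 50
        if (!any(keep)) { target[w] <- 0; next }
        iv <- tibble(genome_id = gid, chromosome_id = chrom,
                     start = starts[keep], end = starts[keep] +
                       part[keep] - 1, te_class = cls)
        target[w] <- 100 * sum(part[keep]) / wlen
        # nested copies inside plant hot-spots (union coverage unchanged)
        if (!is.null(m$hot) && hot[w] && nrow(iv) > 0) {
          big <- which.max(iv$end - iv$start)
          mid <- floor((iv$start[big] + iv$end[big]) / 2)
          iv <- bind_rows(iv, tibble(genome_id = gid,
                                     chromosome_id = chrom,
                                     start = mid,
                                     end = min(iv$end[big], mid + 5000),
                                     te_class = cls))
        }
        tes[[length(tes) + 1L]] <- iv
      }
      cov[[length(cov) + 1L]] <-
        tibble(genome_id = gid, chromosome_id = chrom, te_class = cls,
               window = seq_len(n_win), realized_pct = target)
    }
  }
  list(tes = bind_rows(tes),
       coverage = bind_rows(cov) |>
         group_by(.data$genome_id, .data$te_class) |>
         summarise(mean_pct = mean(.data$realized_pct),
                   max_pct = max(.data$realized_pct), .groups = "drop"))
}

#' Random rearrangement instance for parsimony benchmarking
#'
#' Builds a small random karyotype and applies a known number of random
#' segment-conserving events (fission, telomeric fusion with random end
#' joins, inversion), keeping the chromosome count within bounds. The
#' generating event count is an upper bound on the true minimal distance.
#'
#' @param n_chrom starting chromosomes.
#' @param n_segments total segments (distinct colors).
#' @param n_events events to apply.
#' @param max_chrom chromosome-count ceiling during the walk.
#' @param seed RNG seed.
#' @return list `start`, `events`, `end`, `n_events`.
#' @export
random_rearrangement_instance <- function(n_chrom = 3, n_segments = 6,
                                          n_events = 3, max_chrom = 6,
                                          seed = 1) {
  pk_assert(n_segments >= n_chrom, "need at least one segment per chromosome")
  with_local_seed(seed, function() {
    per <- diff(sort(c(0, sample(seq_len(n_segments - 1),
                                 n_chrom - 1), n_segments)))
    cols <- LETTERS[seq_len(n_segments)]
    idx <- 0L
    chroms <- lapply(per, function(k) {
      out <- cols[idx + seq_len(k)]
      idx <<- idx + k
      out
    })
    start <- karyotype(chroms, name = "start")
    k <- start
    events <- list()
    tries <- 0L
    while (length(events) < n_events && tries < 200) {
      tries <- tries + 1L
      lens <- lengths(k$chromosomes)
      nch <- n_chromosomes(k)
      kind <- sample(c("fission", "fusion", "inversion"), 1)
      ev <- NULL
      if (kind == "fission" && any(lens >= 2) && nch < max_chrom) {
        i <- resample(which(lens >= 2))
        ev <- ev_fission(i, sample(lens[i] - 1L, 1))
      } else if (kind == "fusion" && nch >= 2) {
        ij <- sample(nch, 2)
        ev <- ev_fusion(ij[1], ij[2], runif(1) < 0.5, runif(1) < 0.5)
      } else if (kind == "inversion") {
        i <- resample(seq_len(nch))
        L <- lens[i]
        a <- sample(L, 1)
        b <- min(L, a + sample(0:(L - 1), 1))
        if (!(a == 1 && b == L)) ev <- ev_inversion(i, a, b)
      }
      if (is.null(ev)) next
      k2 <- apply_event(k, ev)
      if (canonical_key(k2) == canonical_key(k)) next # no-op move
      k <- k2
      events[[length(events) + 1L]] <- ev
    }
    list(start = start, events = events, end = k,
         n_events = length(events))
  })
}

resample <- function(x) if (length(x) == 1) x else sample(x, 1)
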