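# Contiguous ancestral region (CAR) reconstruction: project validated
# ortholog blocks onto a shared segment space, keep segment adjacencies
# supported by >= 2 genomes, and read off maximal simple paths.

#' Refine validated blocks into shared ancestral segments
#'
#' Computes the common refinement of all validated ortholog blocks on the
#' gene-family space: each block side covers the families lying inside its
#' rank span, and families covered by exactly the same set of blocks form
#' one segment. Any breakpoint observed in any genome therefore splits the
#' segments, so independently arisen junctions in different lineages are
#' kept apart.
#'
#' @param blocks validated orthologous block tibble.
#' @param genes ranked gene table.
#' @param families tibble `gene_id`, `family_id` ([gene_families()]).
#' @return tibble `family_id`, `segment_id`, `canon_pos` (ordering of the
#'   family within its segment, taken from the reference genome).
#' @export
blocks_to_segments <- function(blocks, genes, families) {
  pk_assert(nrow(blocks) > 0, "no blocks to refine")
  g <- genes |>
    select("gene_id", "genome_id", "chromosome_id", "rank") |>
    inner_join(families, by = "gene_id")
  membership <- purrr::map(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    fams <- g |>
      filter((.data$genome_id == b$genome_a &
                .data$chromosome_id == b$chromosome_a &
                .data$rank >= b$rank_start_a & .data$rank <= b$rank_end_a) |
               (.data$genome_id == b$genome_b &
                  .data$chromosome_id == b$chromosome_b &
                  .data$rank >= b$rank_start_b &
                  .data$rank <= b$rank_end_b)) |>
      distinct(.data$family_id)
    tibble(family_id = fams$family_id, block_id = b$block_id)
  }) |> bind_rows()
  vec <- membership |>
    group_by(.data$family_id) |>
    summarise(sig = paste(sort(unique(.data$block_id)), collapse = ","),
              .groups = "drop")
  vec$segment_id <- sprintf("seg%03d",
                            as.integer(factor(vec$sig,
                                              levels = unique(vec$sig))))
  # canonical within-segment order: family rank in the first genome
  # carrying the segment
  ref <- g |>
    arrange(.data$genome_id, .data$chromosome_id, .data$rank) |>
    distinct(.data$family_id, .keep_all = TRUE)
  out <- vec |>
    left_join(select(ref, "family_id", "rank"), by = "family_id") |>
    group_by(.data$segment_id) |>
    mutate(canon_pos = dplyr::row_number(.data$rank)) |>
    ungroup()
  select(out, "family_id", "segment_id", "canon_pos")
}

#' Project segments onto each genome as ordered occurrences
#'
#' Walks each chromosome's anchored genes in rank order; maximal runs of
#' genes belonging to the same segment become occurrences, positioned at
#' their mean rank and oriented by the direction of the segment's
#' canonical family order along the run.
#'
#' @param genes ranked gene table.
#' @param families tibble `gene_id`, `family_id`.
#' @param segment_map tibble from [blocks_to_segments()].
#' @return tibble `genome_id`, `chromosome_id`, `segment_id`, `pos`,
#'   `orient`, ordered by position within each chromosome.
#' @export
segment_occurrences <- function(genes, families, segment_map) {
  g <- genes |>
    select("gene_id", "genome_id", "chromosome_id", "rank") |>
    inner_join(families, by = "gene_id") |>
    inner_join(segment_map, by = "family_id") |>
    arrange(.data$genome_id, .data$chromosome_id, .data$rank)
  g |>
    group_by(.data$genome_id, .data$chromosome_id) |>
    mutate(run = cumsum(c(1L, as.integer(
      .data$segment_id[-1] != .data$segment_id[-n()])))) |>
    group_by(.data$genome_id, .data$chromosome_id, .data$run) |>
    summarise(segment_id = first(.data$segment_id),
              pos = mean(.data$rank),
              orient = run_orientation(.data$canon_pos),
              n_genes = n(), .groups = "drop") |>
    arrange(.data$genome_id, .data$chromosome_id, .data$pos) |>
    select("genome_id", "chromosome_id", "segment_id", "pos", "orient",
           "n_genes")
}

run_orientation <- function(canon_pos) {
  if (length(canon_pos) < 2) return(1L)
  s <- suppressWarnings(stats::cor(seq_along(canon_pos), canon_pos,
                                   method = "spearman"))
  if (is.na(s) || s >= 0) 1L else -1L
}

# extremities of a signed segment: tail enters a forward-read segment,
# head leaves it
adjacency_key <- function(seg1, or1, seg2, or2) {
  e1 <- paste0(seg1, ifelse(or1 > 0, ".h", ".t")) # right end of seg1
  e2 <- paste0(seg2, ifelse(or2 > 0, ".t", ".h")) # left end of seg2
  paste(pmin(e1, e2), pmax(e1, e2), sep = "--")
}

#' Common intervals: segment adjacencies supported by several genomes
#'
#' Consecutive segments on a chromosome define an adjacency between two
#' segment extremities (orientation-aware, so a reversed pair joins
#' different extremities). An adjacency is considered ancestral when it is
#' observed in at least `min_support` distinct genomes.
#'
#' @param occurrences tibble from [segment_occurrences()] (needs >= 2
#'   genomes).
#' @param min_support minimum number of supporting genomes (default 2).
#' @return list with `nodes` (segment ids) and `edges` (tibble `ext1`,
#'   `ext2`, `seg1`, `seg2`, `weight`).
#' @export
common_intervals <- function(occurrences, min_support = 2) {
  pk_assert(length(unique(occurrences$genome_id)) >= 2,
            "common intervals need at least two genomes")
  adj <- occurrences |>
    group_by(.data$genome_id, .data$chromosome_id) |>
    group_split() |>
    purrr::map(function(g) {
      if (nrow(g) < 2) return(NULL)
      i <- seq_len(nrow(g) - 1L)
      tibble(genome_id = g$genome_id[1],
             key = adjacency_key(g$segment_id[i], g$orient[i],
                                 g$segment_id[i + 1L], g$orient[i + 1L]))
    }) |>
    bind_rows()
  nodes <- sort(unique(occurrences$segment_id))
  if (is.null(adj) || nrow(adj) == 0)
    return(list(nodes = nodes,
                edges = tibble(ext1 = character(), ext2 = character(),
                               seg1 = character(), seg2 = character(),
                               weight = integer())))
  edges <- adj |>
    distinct(.data$genome_id, .data$key) |>
    dplyr::count(.data$key, name = "weight") |>
    filter(.data$weight >= min_support)
  parts <- strsplit(edges$key, "--", fixed = TRUE)
  edges <- tibble(ext1 = vapply(parts, `[`, "", 1),
                  ext2 = vapply(parts, `[`, "", 2),
                  weight = as.integer(edges$weight))
  edges$seg1 <- sub("\\.[ht]$", "", edges$ext1)
  edges$seg2 <- sub("\\.[ht]$", "", edges$ext2)
  edges <- filter(edges, .data$seg1 != .data$seg2)
  list(nodes = nodes, edges = edges)
}

# component sizes (in segments) of the adjacency graph
component_sizes <- function(nodes, edges) {
  idx <- setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  findi <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(edges))) {
    a <- findi(idx[[edges$seg1[e]]]); b <- findi(idx[[edges$seg2[e]]])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  tabulate(vapply(seq_along(nodes), findi, 0L), length(nodes))
}

#' Assemble contiguous ancestral regions from the adjacency graph
#'
#' Branches (an extremity with more than one retained adjacency) are
#' resolved by dropping the lowest-weight incident edge; among tied edges
#' the one whose removal minimizes the variance of the resulting path
#' lengths is dropped, remaining ties lexicographically. Cycles are broken
#' at their lowest-weight edge. Every segment ends up in exactly one CAR.
#'
#' @param graph list from [common_intervals()].
#' @return CAR tibble: `car_id`, `n_segments`, `segments` (list-column of
#'   `segment_id`, `orient`).
#' @export
assemble_cars <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  edges$key <- paste(edges$ext1, edges$ext2, sep = "--")
  drop_one <- function(edges, cand_idx) {
    if (length(cand_idx) == 1) return(edges[-cand_idx, ])
    vars <- vapply(cand_idx, function(ci) {
      sz <- component_sizes(nodes, edges[-ci, ])
      v <- var(sz[sz > 0])
      if (is.na(v)) 0 else v
    }, 0)
    best <- cand_idx[vars == min(vars)]
    if (length(best) > 1) best <- best[order(edges$key[best])][length(best)]
    edges[-best, ]
  }
  repeat {
    ext_count <- table(c(edges$ext1, edges$ext2))
    over <- names(ext_count)[ext_count > 1]
    if (length(over) == 0) break
    ext <- sort(over)[1]
    inc <- which(edges$ext1 == ext | edges$ext2 == ext)
    wmin <- min(edges$weight[inc])
    edges <- drop_one(edges, inc[edges$weight[inc] == wmin])
  }
  # break cycles: walk paths from free extremities, then sweep leftovers
  adj <- setNames(vector("list", 0), character(0))
  link <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(edges))) {
    assign(edges$ext1[e], edges$ext2[e], envir = link)
    assign(edges$ext2[e], edges$ext1[e], envir = link)
  }
  other_end <- function(ext) {
    seg <- sub("\\.[ht]$", "", ext)
    side <- sub("^.*\\.", "", ext)
    paste0(seg, if (side == "h") ".t" else ".h")
  }
  visited <- new.env(parent = emptyenv())
  cars <- list()
  walk_from <- function(start_ext) {
    segs <- character(0); ors <- integer(0)
    ext <- start_ext
    repeat {
      seg <- sub("\\.[ht]$", "", ext)
      assign(seg, TRUE, envir = visited)
      # entering at the tail reads the segment forward
      ors <- c(ors, if (endsWith(ext, ".t")) 1L else -1L)
      segs <- c(segs, seg)
      out <- other_end(ext)
      nxt <- get0(out, envir = link)
      if (is.null(nxt)) break
      nxt_seg <- sub("\\.[ht]$", "", nxt)
      if (!is.null(get0(nxt_seg, envir = visited))) break
      ext <- nxt
    }
    tibble(segment_id = segs, orient = ors)
  }
  for (node in nodes) {
    for (side in c(".t", ".h")) {
      ext <- paste0(node, side)
      if (!is.null(get0(node, envir = visited))) next
      if (is.null(get0(ext, envir = link))) {
        cars[[length(cars) + 1L]] <- walk_from(ext)
        break
      }
    }
  }
  for (node in nodes) { # leftovers are cycles; break at the sorted start
    if (is.null(get0(node, envir = visited)))
      cars[[length(cars) + 1L]] <- walk_from(paste0(node, ".t"))
  }
  tibble(car_id = sprintf("car%03d", seq_along(cars)),
         n_segments = vapply(cars, nrow, 0L),
         segments = cars)
}

#' Ancestral-karyotype totals
#'
#' Sums protogene counts and conserved gene-space size (the minimal
#' physical size: per family, the shortest conserved CDS length) over a
#' set of CARs.
#'
#' @param cars CAR tibble ([assemble_cars()]).
#' @param segment_families tibble `segment_id`, `family_id`, `min_cds`.
#' @param name ancestor name (e.g. `"APK"`, `"AVK"`).
#' @return an `ancestral_karyotype` object: `name`,
#'   `n_protochromosomes`, per-CAR `cars` tibble with `protogene_count`
#'   and `gene_space_bp`, and the totals.
#' @export
karyotype_stats <- function(cars, segment_families, name = "ancestor") {
  if (nrow(cars) == 0) {
    cars$protogene_count <- integer(0)
    cars$gene_space_bp <- double(0)
    return(structure(list(name = name, n_protochromosomes = 0L,
                          cars = cars, total_protogenes = 0L,
                          total_gene_space_bp = 0),
                     class = "ancestral_karyotype"))
  }
  per_car <- purrr::map(seq_len(nrow(cars)), function(i) {
    fams <- segment_families |>
      filter(.data$segment_id %in% cars$segments[[i]]$segment_id) |>
      distinct(.data$family_id, .keep_all = TRUE)
    tibble(protogene_count = nrow(fams),
           gene_space_bp = sum(fams$min_cds))
  }) |> bind_rows()
  cars <- bind_cols(cars, per_car)
  structure(list(name = name, n_protochromosomes = nrow(cars),
                 cars = cars,
                 total_protogenes = sum(cars$protogene_count),
                 total_gene_space_bp = sum(cars$gene_space_bp)),
            class = "ancestral_karyotype")
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat(sprintf("<ancestral_karyotype '%s'> %d CAR(s), %d protogenes, gene space %.2f Mb\n",
              x$name, x$n_protochromosomes, x$total_protogenes,
              x$total_gene_space_bp / 1e6))
  invisible(x)
}

#' Reconstruct an ancestral karyotype from a synteny scan
#'
#' End-to-end ancestor stage: validated ortholog blocks are clustered into
#' shared segments, projected onto each genome, adjacencies supported by
#' at least `min_support` genomes are kept, CARs assembled, and protogene
#' statistics computed (families from the homolog graph restricted to
#' validated blocks; gene-space size from the shortest conserved CDS per
#' family).
#'
#' @param scan a `synteny_scan` ([detect_synteny()]) over >= 2 genomes.
#' @param name ancestor name.
#' @param min_support minimum genome support for an ancestral adjacency.
#' @param min_segment_genes drop segment occurrences carried by fewer
#'   anchored genes than this (stray singletons).
#' @return an `ancestral_karyotype` object (with `segment_map` and
#'   `occurrences` attached for inspection).
#' @export
reconstruct_ancestor <- function(scan, name = "ancestor", min_support = 2,
                                 min_segment_genes = 2) {
  blocks <- synteny_blocks(scan, kind = "orthologous")
  pk_assert(nrow(blocks) > 0, "no validated orthologous blocks")
  # families restricted to validated blocks
  anchor_pairs <- bind_rows(blocks$anchors) |>
    distinct(.data$gene_a, .data$gene_b)
  fams <- gene_families(anchor_pairs)
  seg_map <- blocks_to_segments(blocks, scan$genes, fams)
  occ <- segment_occurrences(scan$genes, fams, seg_map) |>
    filter(.data$n_genes >= min_segment_genes)
  graph <- common_intervals(occ, min_support = min_support)
  cars <- assemble_cars(graph)
  fam_cds <- scan$genes |>
    select("gene_id", "cds_length") |>
    inner_join(fams, by = "gene_id") |>
    group_by(.data$family_id) |>
    summarise(min_cds = min(.data$cds_length), .groups = "drop")
  seg_fam <- seg_map |>
    inner_join(fam_cds, by = "family_id") |>
    select("segment_id", "family_id", "min_cds")
  ak <- karyotype_stats(cars, seg_fam, name = name)
  ak$segment_map <- seg_map
  ak$occurrences <- occ
  ak
}
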