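#' Merge overlapping HSPs on the query
#'
#' Overlapping query intervals are merged before cumulative statistics are
#' computed: each query base is claimed by the HSP with the highest identity
#' fraction covering it, so the aligned length (AL) is the length of the
#' interval union and the identity count of an overlap comes from the
#' higher-identity HSP. This keeps CALP at or below 100.
#'
#' @param hsps tibble of HSPs for one query/subject pair.
#' @return list with `al` (merged aligned length) and `identities`
#'   (effective identity count over the merged intervals).
#' @export
merge_hsps <- function(hsps) {
  pk_assert(nrow(hsps) >= 1, "no HSPs to merge")
  # fast path: no query overlap, the common case
  o <- order(hsps$query_start)
  if (all(hsps$query_end[o][-nrow(hsps)] < hsps$query_start[o][-1]))
    return(list(al = sum(hsps$hsp_length), identities = sum(hsps$identities)))
  ord <- order(-hsps$identities / hsps$hsp_length, hsps$query_start)
  claimed <- NULL # IRanges of already-claimed query positions
  al <- 0
  ids <- 0
  for (i in ord) {
    iv <- IRanges::IRanges(hsps$query_start[i], hsps$query_end[i])
    new <- if (is.null(claimed)) iv else IRanges::setdiff(iv, claimed)
    got <- sum(IRanges::width(new))
    if (got > 0) {
      span <- hsps$query_end[i] - hsps$query_start[i] + 1
      frac <- got / span
      al <- al + frac * hsps$hsp_length[i]
      ids <- ids + frac * hsps$identities[i]
      claimed <- if (is.null(claimed)) iv else
        IRanges::reduce(c(claimed, iv))
    }
  }
  list(al = al, identities = ids)
}

#' Cumulative identity percentage (CIP)
#'
#' CIP = 100 * (sum of HSP identity counts) / (cumulative aligned length AL).
#' HSPs are assumed non-overlapping on the query (see [merge_hsps()]);
#' the result is invariant to HSP order.
#'
#' @param hsps tibble of HSPs with `identities` and `hsp_length`.
#' @return CIP in percent.
#' @export
compute_cip <- function(hsps) {
  al <- sum(hsps$hsp_length)
  pk_assert(al > 0, "zero cumulative aligned length")
  100 * sum(hsps$identities) / al
}

#' Cumulative aligned length percentage (CALP)
#'
#' CALP = 100 * AL / query length, with AL taken from overlap-merged HSPs
#' and capped at 100.
#'
#' @param hsps tibble of HSPs (with query coordinates).
#' @param query_length length of the query CDS in bp.
#' @return CALP in percent.
#' @export
compute_calp <- function(hsps, query_length) {
  pk_assert(query_length >= 1, "query_length must be >= 1")
  al <- min(merge_hsps(hsps)$al, query_length)
  100 * al / query_length
}

#' Summarise HSPs into per-pair cumulative alignment statistics
#'
#' Groups HSPs by (query, subject) and computes AL, CIP and CALP per pair
#' after overlap merging on the query.
#'
#' @param hsps HSP tibble ([read_hsp_table()]).
#' @param query_lengths tibble `gene_id`, `cds_length` (or a gene table).
#' @return tibble: `query_id`, `subject_id`, `n_hsps`, `al`, `cip`, `calp`.
#' @export
pair_alignments <- function(hsps, query_lengths) {
  if (nrow(hsps) == 0)
    return(tibble(query_id = character(), subject_id = character(),
                  n_hsps = integer(), al = double(), cip = double(),
                  calp = double()))
  qlen <- setNames(query_lengths$cds_length, query_lengths$gene_id)
  miss <- setdiff(unique(hsps$query_id), names(qlen))
  if (length(miss) > 0)
    pk_stop("query gene '%s' has no known CDS length", miss[1])
  x <- hsps |>
    arrange(.data$query_id, .data$subject_id, .data$query_start) |>
    group_by(.data$query_id, .data$subject_id) |>
    mutate(.overlap = dplyr::lag(cummax(.data$query_end), default = 0) >=
             .data$query_start)
  # fast path: pairs without query overlap need no interval merging
  plain <- x |>
    filter(!any(.data$.overlap)) |>
    summarise(n_hsps = n(), al = sum(.data$hsp_length),
              ids = sum(.data$identities), .groups = "drop")
  merged <- x |>
    filter(any(.data$.overlap)) |>
    group_split() |>
    purrr::map(function(g) {
      m <- merge_hsps(g)
      tibble(query_id = g$query_id[1], subject_id = g$subject_id[1],
             n_hsps = nrow(g), al = m$al, ids = m$identities)
    }) |>
    bind_rows()
  out <- bind_rows(plain, merged)
  ql <- unname(qlen[out$query_id])
  al_cap <- pmin(out$al, ql)
  tibble(query_id = out$query_id, subject_id = out$subject_id,
         n_hsps = out$n_hsps, al = al_cap,
         cip = ifelse(out$al > 0, 100 * out$ids / out$al, 0),
         calp = 100 * al_cap / ql)
}

#' Divergence-dependent CIP/CALP filter
#'
#' A pair passes when both CIP and CALP reach the threshold for its
#' divergence class: 70% for closely related genomes (common ancestor
#' < 50 Mya), 50% for distantly related ones (> 50 Mya). Comparisons are
#' inclusive, so boundary values pass.
#'
#' @param cip,calp percentages in `[0, 100]` (vectorized).
#' @param divergence_class `"close"` or `"distant"` (vectorized).
#' @param thresholds named numeric, defaults `c(close = 70, distant = 50)`.
#' @return logical vector: `TRUE` where the pair passes.
#' @export
classify_pair <- function(cip, calp, divergence_class,
                          thresholds = c(close = 70, distant = 50)) {
  bad <- setdiff(unique(divergence_class), names(thresholds))
  if (length(bad) > 0) pk_stop("unknown divergence class '%s'", bad[1])
  pk_assert(all(cip >= 0 & cip <= 100 & calp >= 0 & calp <= 100),
            "CIP/CALP outside [0, 100]")
  t <- unname(thresholds[divergence_class])
  cip >= t & calp >= t
}

#' Build a divergence table for a set of genomes
#'
#' Convenience constructor giving every genome pair (including each genome
#' with itself, used for paralog calling) the same divergence class.
#'
#' @param genome_ids character vector of genome identifiers.
#' @param class `"close"` or `"distant"`.
#' @return tibble `genome_a`, `genome_b`, `class` (unordered pairs + self).
#' @export
divergence_table <- function(genome_ids, class = "close") {
  g <- sort(unique(genome_ids))
  grid <- expand.grid(genome_a = g, genome_b = g, stringsAsFactors = FALSE)
  grid <- grid[grid$genome_a <= grid$genome_b, ]
  tibble(genome_a = grid$genome_a, genome_b = grid$genome_b, class = class)
}

lookup_divergence <- function(divergence, ga, gb) {
  key <- paste(pmin(ga, gb), pmax(ga, gb))
  tab <- setNames(divergence$class,
                  paste(pmin(divergence$genome_a, divergence$genome_b),
                        pmax(divergence$genome_a, divergence$genome_b)))
  out <- unname(tab[key])
  if (anyNA(out))
    pk_stop("no divergence class for genome pair '%s'", key[is.na(out)][1])
  out
}

#' Call ortholog and paralog pairs from cumulative alignment statistics
#'
#' Applies the CIP/CALP filter at the divergence-dependent thresholds, then,
#' for every query gene and target genome, retains the passing candidate
#' with the highest CIP (ties: higher CALP, then lexicographic subject id) —
#' "the highest cumulative identity over the longest cumulative length".
#' Self-hits are dropped; intra-genome (paralog) pairs are deduplicated as
#' unordered pairs. With `reciprocal = TRUE`, cross-genome pairs are kept
#' only when each member is the other's retained best hit.
#'
#' @param pairs per-pair alignment tibble ([pair_alignments()]).
#' @param genes gene table mapping `gene_id` to `genome_id`.
#' @param divergence divergence table (`genome_a`, `genome_b`, `class`).
#' @param thresholds CIP/CALP thresholds by class.
#' @param reciprocal require reciprocal best hits for orthologs.
#' @return tibble of homolog pairs: `gene_a`, `gene_b`, `genome_a`,
#'   `genome_b`, `relation` (ortholog/paralog), `cip`, `calp`,
#'   `divergence_class`.
#' @export
call_homologs <- function(pairs, genes, divergence,
                          thresholds = c(close = 70, distant = 50),
                          reciprocal = FALSE) {
  gmap <- setNames(genes$genome_id, genes$gene_id)
  miss <- setdiff(unique(c(pairs$query_id, pairs$subject_id)), names(gmap))
  if (length(miss) > 0)
    pk_stop("gene '%s' absent from the gene table", miss[1])
  x <- pairs |>
    filter(.data$query_id != .data$subject_id) |>
    mutate(genome_q = unname(gmap[.data$query_id]),
           genome_s = unname(gmap[.data$subject_id]))
  if (nrow(x) == 0) return(empty_homolog_tbl())
  x$divergence_class <- lookup_divergence(divergence, x$genome_q, x$genome_s)
  x <- filter(x, classify_pair(.data$cip, .data$calp,
                               .data$divergence_class, thresholds))
  if (nrow(x) == 0) return(empty_homolog_tbl())
  best <- x |>
    arrange(.data$query_id, .data$genome_s, dplyr::desc(.data$cip),
            dplyr::desc(.data$calp), .data$subject_id) |>
    group_by(.data$query_id, .data$genome_s) |>
    slice(1) |>
    ungroup()
  if (reciprocal) {
    key <- paste(best$query_id, best$subject_id)
    rev_key <- paste(best$subject_id, best$query_id)
    best <- best[key %in% rev_key | best$genome_q == best$genome_s, ]
  }
  out <- best |>
    mutate(relation = ifelse(.data$genome_q == .data$genome_s,
                             "paralog", "ortholog"),
           gene_a = pmin(.data$query_id, .data$subject_id),
           gene_b = pmax(.data$query_id, .data$subject_id)) |>
    group_by(.data$gene_a, .data$gene_b) |>
    slice_max(.data$cip, n = 1, with_ties = FALSE) |>
    ungroup()
  tibble(gene_a = out$gene_a, gene_b = out$gene_b,
         genome_a = unname(gmap[out$gene_a]),
         genome_b = unname(gmap[out$gene_b]),
         relation = out$relation, cip = out$cip, calp = out$calp,
         divergence_class = out$divergence_class)
}

empty_homolog_tbl <- function() {
  tibble(gene_a = character(), gene_b = character(),
         genome_a = character(), genome_b = character(),
         relation = character(), cip = double(), calp = double(),
         divergence_class = character())
}

#' Gene families from the homolog graph
#'
#' Connected components of the homolog-pair graph; every gene named in a
#' pair belongs to exactly one family.
#'
#' @param homologs homolog-pair tibble ([call_homologs()]).
#' @return tibble `gene_id`, `family_id`.
#' @export
gene_families <- function(homologs) {
  genes <- sort(unique(c(homologs$gene_a, homologs$gene_b)))
  if (length(genes) == 0)
    return(tibble(gene_id = character(), family_id = character()))
  parent <- seq_along(genes)
  idx <- setNames(seq_along(genes), genes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- idx[homologs$gene_a]
  ib <- idx[homologs$gene_b]
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(genes), find, 0L)
  fam <- sprintf("fam%05d", as.integer(factor(roots, levels = unique(roots))))
  tibble(gene_id = genes, family_id = fam)
}
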