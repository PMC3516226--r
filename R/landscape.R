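#' Windowed gene and TE landscape profiles
#'
#' Tiles each chromosome with fixed-size windows (default 500 kb, the last
#' window truncated at the chromosome end) and computes, per window, the
#' number of annotated genes and the cumulative size covered by each
#' transposable-element class (class I LTR, class I non-LTR, class II).
#' Genes are assigned to the window containing their start coordinate, so
#' window counts always partition the chromosome total; same-class TE
#' copies are union-merged so overlapping or nested copies are counted
#' once, while different classes are tallied independently.
#'
#' @param genes gene tibble (one chromosome or several).
#' @param tes TE tibble (`chromosome_id`, `start`, `end`, `te_class`).
#' @param chrom_lengths tibble `chromosome_id`, `length_bp`.
#' @param window_bp window size in bp (default 500000).
#' @param gene_assign `"start"` (default) or `"overlap"` (count a gene in
#'   every window it overlaps).
#' @return a `window_profile` tibble: `chromosome_id`, `window`,
#'   `window_start`, `window_end` (1-based inclusive), `window_len`,
#'   `gene_count`, and per class `te_kb_<class>` and `te_pct_<class>`.
#' @export
window_profiles <- function(genes, tes, chrom_lengths, window_bp = 500000,
                            gene_assign = c("start", "overlap")) {
  gene_assign <- match.arg(gene_assign)
  pk_assert(window_bp >= 1, "window_bp must be >= 1")
  out <- purrr::map(seq_len(nrow(chrom_lengths)), function(ci) {
    chrom <- chrom_lengths$chromosome_id[ci]
    len <- chrom_lengths$length_bp[ci]
    g <- filter(genes, .data$chromosome_id == chrom)
    t <- filter(tes, .data$chromosome_id == chrom)
    if (nrow(g) > 0 && any(g$end > len))
      pk_stop("gene beyond chromosome end on %s", chrom)
    if (nrow(t) > 0 && any(t$end > len))
      pk_stop("TE beyond chromosome end on %s", chrom)
    n_win <- ceiling(len / window_bp)
    # 0-based half-open tiling internally
    w0 <- (seq_len(n_win) - 1) * window_bp
    w1 <- pmin(w0 + window_bp, len)
    gene_count <- if (nrow(g) == 0) rep(0L, n_win) else {
      if (gene_assign == "start") {
        tabulate(pmin(floor((g$start - 1) / window_bp) + 1, n_win), n_win)
      } else {
        first <- floor((g$start - 1) / window_bp) + 1
        last <- pmin(floor((g$end - 1) / window_bp) + 1, n_win)
        tabulate(unlist(purrr::map2(first, last, seq)), n_win)
      }
    }
    prof <- tibble(chromosome_id = chrom, window = seq_len(n_win),
                   window_start = w0 + 1, window_end = w1,
                   window_len = w1 - w0, gene_count = gene_count)
    for (cls in TE_CLASSES) {
      tc <- filter(t, .data$te_class == cls)
      cov_bp <- rep(0, n_win)
      if (nrow(tc) > 0) {
        merged <- IRanges::reduce(IRanges::IRanges(tc$start, tc$end))
        for (w in seq_len(n_win)) {
          win <- IRanges::IRanges(w0[w] + 1, w1[w])
          cov_bp[w] <- sum(IRanges::width(IRanges::intersect(merged, win)))
        }
      }
      prof[[paste0("te_kb_", cls)]] <- cov_bp / 1000
      prof[[paste0("te_pct_", cls)]] <- 100 * cov_bp / prof$window_len
    }
    prof
  }) |> bind_rows()
  class(out) <- c("window_profile", class(out))
  out
}

#' Summarise a window profile
#'
#' Per-class mean and maximum window TE coverage (percent of window) and
#' the mean gene density, over all windows of the profile.
#'
#' @param profiles a `window_profile` tibble ([window_profiles()]).
#' @return one-row tibble: per class `mean_pct_<class>` / `max_pct_<class>`
#'   plus `mean_genes_per_mb`.
#' @export
profile_summary <- function(profiles) {
  pk_assert(nrow(profiles) >= 1, "profile summary needs >= 1 window")
  out <- tibble(.rows = 1)
  for (cls in TE_CLASSES) {
    p <- profiles[[paste0("te_pct_", cls)]]
    out[[paste0("mean_pct_", cls)]] <- mean(p)
    out[[paste0("max_pct_", cls)]] <- max(p)
  }
  out$mean_genes_per_mb <-
    1e6 * sum(profiles$gene_count) / sum(profiles$window_len)
  out
}
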