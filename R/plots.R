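# ggplot2 views of the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dot plot of a synteny scan
#'
#' Anchors of validated blocks plotted in gene-rank space, one facet per
#' chromosome pair, colored by block orientation.
#'
#' @param object a `synteny_scan`.
#' @param kind restrict to `"orthologous"` or `"paralogous"` blocks.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.synteny_scan <- function(object, kind = NULL, ...) {
  b <- synteny_blocks(object, kind = kind)
  pk_assert(nrow(b) > 0, "no validated blocks to plot")
  df <- purrr::map(seq_len(nrow(b)), function(i)
    mutate(b$anchors[[i]],
           pair = paste0(b$genome_a[i], ":", b$chromosome_a[i], " vs ",
                         b$genome_b[i], ":", b$chromosome_b[i]),
           orientation = b$orientation[i])) |>
    bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                                   colour = .data$orientation)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = "gene rank (genome A)", y = "gene rank (genome B)",
                  colour = "orientation") +
    ggplot2::theme_minimal()
}

#' Gene and TE landscape curves
#'
#' The windowed profile view: gene counts per window on top, cumulative
#' TE size (kb per window, one curve per class) below.
#'
#' @param object a `window_profile` tibble ([window_profiles()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.window_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::starts_with("te_kb_"),
                              names_prefix = "te_kb_",
                              names_to = "te_class", values_to = "kb")
  genes <- distinct(as_tibble(object), .data$chromosome_id, .data$window,
                    .data$window_start, .data$gene_count)
  p1 <- ggplot2::ggplot(genes,
                        ggplot2::aes(x = .data$window_start / 1e6,
                                     y = .data$gene_count)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chromosome_id, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "genes / window") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(long,
                        ggplot2::aes(x = .data$window_start / 1e6,
                                     y = .data$kb,
                                     colour = .data$te_class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chromosome_id, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(classI_LTR = "black",
                                            classI_nonLTR = "purple",
                                            classII = "grey50")) +
    ggplot2::labs(x = "position (Mb)", y = "TE kb / window",
                  colour = "TE class") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE))
    patchwork::wrap_plots(p1, p2, ncol = 1) else p2
}

#' Painted karyotype plot
#'
#' Chromosomes drawn as stacked segments colored by ancestral origin.
#'
#' @param object a `karyotype`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.karyotype <- function(object, ...) {
  lbl <- object$colors
  df <- purrr::imap(object$chromosomes, function(ch, i)
    tibble(chromosome = i, pos = seq_along(ch),
           color = lbl[abs(ch)],
           orient = ifelse(ch > 0, "+", "-"))) |>
    bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$chromosome),
                                   y = .data$pos, fill = .data$color)) +
    ggplot2::geom_tile(colour = "white", width = 0.7) +
    ggplot2::labs(x = "chromosome", y = "segment",
                  fill = "ancestral origin",
                  title = object$name) +
    ggplot2::theme_minimal()
}
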