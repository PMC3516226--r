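#' Read a tabular BLAST HSP table
#'
#' Reads one local-alignment fragment (HSP, high-scoring pair) per row from
#' the 12-column tab-separated alignment format (`outfmt 6`-like:
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore). The `"nident"` dialect expects a 13th column with
#' an explicit identity count; in the `"pct"` dialect the identity count is
#' derived as `round(pident/100 * length)` (half away from zero, reversible
#' to one decimal for HSPs up to 5 kb).
#'
#' @param path path to a tab-separated HSP file (no header).
#' @param dialect `"pct"` (12 columns, identity as a percentage) or
#'   `"nident"` (13 columns, explicit identity count).
#' @return A tibble with one row per HSP: `query_id`, `subject_id`,
#'   `pct_identity`, `hsp_length`, `identities`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end`, `e_value`, `bit_score`.
#' @export
read_hsp_table <- function(path, dialect = c("pct", "nident")) {
  dialect <- match.arg(dialect)
  pk_assert(file.exists(path), "HSP file not found: %s", path)
  cols <- c("query_id", "subject_id", "pct_identity", "hsp_length",
            "mismatches", "gap_opens", "query_start", "query_end",
            "subject_start", "subject_end", "e_value", "bit_score")
  if (dialect == "nident") cols <- c(cols, "identities")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       comment = "#",
                       col_types = readr::cols(
                         query_id = "c", subject_id = "c",
                         .default = readr::col_double()))
  if (nrow(x) == 0) return(empty_hsp_tbl())
  bad <- which(is.na(x$hsp_length) | is.na(x$pct_identity) |
                 is.na(x$query_start) | is.na(x$query_end))
  if (length(bad) > 0)
    pk_stop("malformed HSP row at line %d of %s", bad[1], path)
  if (any(x$hsp_length <= 0))
    pk_stop("non-positive HSP length at line %d of %s",
            which(x$hsp_length <= 0)[1], path)
  if (any(x$query_start > x$query_end))
    pk_stop("query_start > query_end at line %d of %s",
            which(x$query_start > x$query_end)[1], path)
  if (dialect == "pct") {
    x$identities <- round_half_away(x$pct_identity / 100 * x$hsp_length)
  } else {
    x$pct_identity <- 100 * x$identities / x$hsp_length
  }
  pk_assert(all(x$identities >= 0 & x$identities <= x$hsp_length),
            "identity count outside [0, hsp_length] in %s", path)
  tibble::as_tibble(x[, c("query_id", "subject_id", "pct_identity",
                          "hsp_length", "identities", "query_start",
                          "query_end", "subject_start", "subject_end",
                          "e_value", "bit_score")])
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

empty_hsp_tbl <- function() {
  tibble(query_id = character(), subject_id = character(),
         pct_identity = double(), hsp_length = double(),
         identities = double(), query_start = double(),
         query_end = double(), subject_start = double(),
         subject_end = double(), e_value = double(), bit_score = double())
}

#' Write an HSP table in the tabular alignment dialect
#'
#' @param hsps tibble as returned by [read_hsp_table()].
#' @param path output path.
#' @param dialect `"pct"` or `"nident"` (adds the identity-count column).
#' @return `path`, invisibly.
#' @export
write_hsp_table <- function(hsps, path, dialect = c("pct", "nident")) {
  dialect <- match.arg(dialect)
  out <- tibble(
    q = hsps$query_id, s = hsps$subject_id,
    pident = sprintf("%.1f", hsps$pct_identity),
    len = hsps$hsp_length,
    mm = hsps$hsp_length - hsps$identities, go = 0,
    qs = hsps$query_start, qe = hsps$query_end,
    ss = hsps$subject_start, se = hsps$subject_end,
    ev = hsps$e_value, bs = hsps$bit_score)
  if (dialect == "nident") out$nident <- hsps$identities
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene-order table
#'
#' Reads the tab-separated gene-order format (columns `genome_id`,
#' `chromosome_id`, `gene_id`, `start`, `end`, `strand`, optional
#' `cds_length`) and assigns 0-based gene ranks along each chromosome by
#' ascending start coordinate (ties broken by `gene_id`).
#'
#' @param path path to the TSV (with header).
#' @return tibble of gene records with a `rank` column; one row per gene.
#' @export
read_gene_order <- function(path) {
  pk_assert(file.exists(path), "gene-order file not found: %s", path)
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         genome_id = "c", chromosome_id = "c", gene_id = "c",
                         .default = readr::col_double()))
  need <- c("genome_id", "chromosome_id", "gene_id", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    pk_stop("gene-order file %s lacks column(s): %s", path,
            paste(miss, collapse = ", "))
  if (!"cds_length" %in% names(x)) x$cds_length <- x$end - x$start + 1
  assign_ranks(x)
}

#' Assign gene ranks along chromosomes
#'
#' Ranks are 0-based, consecutive and unique per chromosome, ordered by
#' ascending start (ties by `gene_id`). Errors on duplicated gene ids
#' within a genome or on `start > end`.
#'
#' @param genes tibble with at least `genome_id`, `chromosome_id`,
#'   `gene_id`, `start`, `end`.
#' @return the same tibble, sorted, with a `rank` column.
#' @export
assign_ranks <- function(genes) {
  pk_assert(all(genes$start <= genes$end), "gene with start > end")
  dup <- genes |>
    dplyr::count(.data$genome_id, .data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0)
    pk_stop("duplicate gene_id '%s' in genome '%s'",
            dup$gene_id[1], dup$genome_id[1])
  genes |>
    arrange(.data$genome_id, .data$chromosome_id, .data$start,
            .data$gene_id) |>
    group_by(.data$genome_id, .data$chromosome_id) |>
    mutate(rank = row_number() - 1L) |>
    ungroup()
}

#' Write a gene-order table
#' @param genes gene tibble (see [read_gene_order()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_order <- function(genes, path) {
  keep <- intersect(c("genome_id", "chromosome_id", "gene_id", "start",
                      "end", "strand", "cds_length"), names(genes))
  readr::write_tsv(genes[, keep], path)
  invisible(path)
}

#' Read gene and TE features from GFF3
#'
#' Genes are `gene` features; transposable elements are
#' `transposable_element` features carrying a `te_class` attribute
#' (one of `classI_LTR`, `classI_nonLTR`, `classII`). The genome identifier
#' is taken from the GFF3 `source` column.
#'
#' @param path GFF3 file.
#' @return list with elements `genes` (ranked gene tibble) and `tes`
#'   (tibble `genome_id`, `chromosome_id`, `start`, `end`, `te_class`).
#' @export
read_gff3_features <- function(path) {
  pk_assert(file.exists(path), "GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  genes <- df[df$type == "gene", , drop = FALSE]
  tes <- df[df$type == "transposable_element", , drop = FALSE]
  gene_tbl <- tibble(
    genome_id = as.character(genes$source),
    chromosome_id = as.character(genes$seqnames),
    gene_id = as.character(genes$ID),
    start = as.double(genes$start), end = as.double(genes$end),
    strand = ifelse(as.character(genes$strand) == "-", -1, 1),
    cds_length = as.double(genes$end) - as.double(genes$start) + 1)
  te_class <- if (nrow(tes) > 0 && "te_class" %in% names(tes))
    as.character(tes$te_class) else character(nrow(tes))
  bad <- setdiff(unique(te_class), TE_CLASSES)
  if (length(bad) > 0)
    pk_stop("unknown te_class '%s' in %s", bad[1], path)
  te_tbl <- tibble(
    genome_id = as.character(tes$source),
    chromosome_id = as.character(tes$seqnames),
    start = as.double(tes$start), end = as.double(tes$end),
    te_class = te_class)
  list(genes = assign_ranks(gene_tbl), tes = te_tbl)
}

#' Write gene and TE features to GFF3
#' @param genes ranked gene tibble (may be `NULL`).
#' @param tes TE tibble (may be `NULL`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_features <- function(genes, tes, path) {
  rows <- list()
  if (!is.null(genes) && nrow(genes) > 0) {
    rows$genes <- data.frame(
      seqnames = genes$chromosome_id, start = genes$start, end = genes$end,
      strand = ifelse(genes$strand < 0, "-", "+"),
      source = genes$genome_id, type = "gene", ID = genes$gene_id,
      te_class = NA_character_, stringsAsFactors = FALSE)
  }
  if (!is.null(tes) && nrow(tes) > 0) {
    rows$tes <- data.frame(
      seqnames = tes$chromosome_id, start = tes$start, end = tes$end,
      strand = "+", source = tes$genome_id, type = "transposable_element",
      ID = sprintf("te%06d", seq_len(nrow(tes))), te_class = tes$te_class,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  pk_assert(!is.null(df), "nothing to write to %s", path)
  gr <- GenomicRanges::makeGRangesFromDataFrame(df, keep.extra.columns = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# serialize block anchors for the TSV round trip
serialize_anchors <- function(a) {
  paste(sprintf("%s|%s|%d|%d|%d", a$gene_a, a$gene_b,
                as.integer(a$rank_a), as.integer(a$rank_b),
                as.integer(a$sign)), collapse = ",")
}

deserialize_anchors <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "|", fixed = TRUE)
  tibble(gene_a = vapply(parts, `[`, "", 1),
         gene_b = vapply(parts, `[`, "", 2),
         rank_a = as.integer(vapply(parts, `[`, "", 3)),
         rank_b = as.integer(vapply(parts, `[`, "", 4)),
         sign = as.integer(vapply(parts, `[`, "", 5)))
}

#' Write a synteny/duplication block table
#'
#' One row per block (genomes, chromosomes, rank and bp spans, anchor count,
#' orientation, p-value, serialized anchors), preceded by `#`-comment
#' summary lines, one per genome pair, in the `n_anchors-n_blocks-%coverage`
#' schema.
#'
#' @param blocks block tibble (see [detect_synteny()]).
#' @param path output path.
#' @param genomes optional gene tibble used to compute the coverage summary.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(blocks, path, genomes = NULL) {
  if (nrow(blocks) == 0) {
    header <- "# summary\tnone\t0-0-0"
  } else {
    pairs_tbl <- distinct(blocks, .data$genome_a, .data$genome_b)
    header <- vapply(seq_len(nrow(pairs_tbl)), function(i) {
      b <- filter(blocks, .data$genome_a == pairs_tbl$genome_a[i],
                  .data$genome_b == pairs_tbl$genome_b[i])
      cov <- if (is.null(genomes)) NA_real_ else
        coverage_summary(b, genomes, pairs_tbl$genome_a[i])$pct_coverage
      sprintf("# summary\t%s:%s\t%d-%d-%s",
              pairs_tbl$genome_a[i], pairs_tbl$genome_b[i],
              sum(b$n_anchors), nrow(b),
              ifelse(is.na(cov), "NA", as.character(cov)))
    }, "")
  }
  flat <- blocks
  flat$anchors <- vapply(blocks$anchors, serialize_anchors, "")
  body <- sub("\n$", "", readr::format_tsv(flat))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a block table written by [write_block_table()]
#' @param path block TSV path.
#' @return block tibble with a rebuilt `anchors` list-column.
#' @export
read_block_table <- function(path) {
  pk_assert(file.exists(path), "block file not found: %s", path)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         block_id = "c", kind = "c", genome_a = "c",
                         chromosome_a = "c", genome_b = "c",
                         chromosome_b = "c", orientation = "c",
                         anchors = "c", valid = "l",
                         .default = readr::col_double()))
  x$anchors <- lapply(x$anchors, deserialize_anchors)
  x
}

#' Write / read a contiguous-ancestral-region (CAR) table
#'
#' The segment order of each CAR is serialized as `segment:+,segment:-`.
#'
#' @param cars CAR tibble (see [assemble_cars()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_car_table <- function(cars, path) {
  flat <- cars
  flat$segments <- vapply(cars$segments, function(s)
    paste(sprintf("%s:%s", s$segment_id, ifelse(s$orient < 0, "-", "+")),
          collapse = ","), "")
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_car_table
#' @export
read_car_table <- function(path) {
  pk_assert(file.exists(path), "CAR file not found: %s", path)
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(car_id = "c", segments = "c",
                                               .default = readr::col_double()))
  x$segments <- lapply(x$segments, function(s) {
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble(segment_id = vapply(parts, `[`, "", 1),
           orient = ifelse(vapply(parts, `[`, "", 2) == "-", -1L, 1L))
  })
  x
}

#' Export blocks as BED (0-based half-open) intervals
#'
#' Each block contributes one BED line per side, named by block id.
#'
#' @param blocks block tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_block_bed <- function(blocks, path) {
  if (nrow(blocks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- bind_rows(
    tibble(chrom = paste(blocks$genome_a, blocks$chromosome_a, sep = ":"),
           start = as.integer(blocks$bp_start_a - 1),
           end = as.integer(blocks$bp_end_a),
           name = blocks$block_id,
           score = pmin(1000L, blocks$n_anchors * 10L),
           strand = "+"),
    tibble(chrom = paste(blocks$genome_b, blocks$chromosome_b, sep = ":"),
           start = as.integer(blocks$bp_start_b - 1),
           end = as.integer(blocks$bp_end_b),
           name = blocks$block_id,
           score = pmin(1000L, blocks$n_anchors * 10L),
           strand = ifelse(blocks$orientation == "inverted", "-", "+")))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
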