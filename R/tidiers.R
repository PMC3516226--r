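# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a synteny scan into its block table
#' @param x a `synteny_scan`.
#' @param ... unused.
#' @return tibble of candidate blocks with validation columns.
#' @export
tidy.synteny_scan <- function(x, ...) x$blocks

#' One-row summary of a synteny scan
#' @param x a `synteny_scan`.
#' @param ... unused.
#' @return one-row tibble: candidate/validated block counts, anchors in
#'   validated blocks, per-kind counts.
#' @export
glance.synteny_scan <- function(x, ...) {
  b <- x$blocks
  v <- filter(b, .data$valid)
  tibble(n_candidates = nrow(b), n_valid = nrow(v),
         n_orthologous = sum(v$kind == "orthologous"),
         n_paralogous = sum(v$kind == "paralogous"),
         n_anchors = sum(v$n_anchors),
         median_p = stats::median(v$p_value))
}

#' Tidy an ancestral karyotype into its CAR table
#' @param x an `ancestral_karyotype`.
#' @param ... unused.
#' @return per-CAR tibble with protogene counts and gene-space size.
#' @export
tidy.ancestral_karyotype <- function(x, ...) x$cars

#' One-row summary of an ancestral karyotype
#' @param x an `ancestral_karyotype`.
#' @param ... unused.
#' @return one-row tibble: `name`, `n_protochromosomes`,
#'   `total_protogenes`, `total_gene_space_bp`.
#' @export
glance.ancestral_karyotype <- function(x, ...) {
  tibble(name = x$name, n_protochromosomes = x$n_protochromosomes,
         total_protogenes = x$total_protogenes,
         total_gene_space_bp = x$total_gene_space_bp)
}

#' Tidy a replayed scenario into its per-step trace
#' @param x a `pk_scenario` ([replay()]).
#' @param ... unused.
#' @return tibble `step`, `kind`, `n`.
#' @export
tidy.pk_scenario <- function(x, ...) x$trace

#' One-row summary of a replayed scenario
#' @param x a `pk_scenario`.
#' @param ... unused.
#' @return one-row tibble with event counts and start/end chromosome
#'   numbers.
#' @export
glance.pk_scenario <- function(x, ...) {
  kinds <- vapply(x$events, `[[`, "", "kind")
  tibble(n_events = length(kinds),
         n_wgd = sum(kinds == "wgd"),
         n_fission = sum(kinds == "fission"),
         n_fusion = sum(kinds %in% c("fusion_tcf", "fusion_ccf")),
         n_start = n_chromosomes(x$start),
         n_end = n_chromosomes(x$end))
}
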