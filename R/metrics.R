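# Evaluation helpers comparing pipeline output with a simulation's
# ground-truth ledger.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Recall and precision of homolog calling against simulated truth
#'
#' @param called homolog-pair tibble ([call_homologs()]).
#' @param truth ground-truth pair tibble (`gene_a`, `gene_b`, `relation`).
#' @param relation optionally restrict to `"ortholog"` or `"paralog"`.
#' @return one-row tibble: `n_called`, `n_truth`, `recall`, `precision`.
#' @export
homolog_metrics <- function(called, truth, relation = NULL) {
  if (!is.null(relation)) {
    called <- filter(called, .data$relation == !!relation)
    truth <- filter(truth, .data$relation == !!relation)
  }
  ck <- pair_key(called$gene_a, called$gene_b)
  tk <- pair_key(truth$gene_a, truth$gene_b)
  tp <- sum(ck %in% tk)
  tibble(n_called = length(ck), n_truth = length(tk),
         recall = if (length(tk) == 0) NA_real_ else tp / length(tk),
         precision = if (length(ck) == 0) NA_real_ else tp / length(ck))
}

#' Block-recovery F1 against the simulator's segment map
#'
#' Compares the gene pairs captured inside validated blocks with the
#' ground-truth homolog pairs of the simulation: precision over anchors in
#' validated blocks, recall over true pairs, F1 their harmonic mean.
#' When `runs` (the ground-truth ledger's per-gene segment-run labels) is
#' supplied, recall is restricted to pairs whose shared segment carries at
#' least `min_run` pairs — a conserved run below the validator's match
#' number is undetectable by construction, in this method as in the one it
#' models.
#'
#' @param scan a `synteny_scan`.
#' @param truth ground-truth pair tibble.
#' @param kind block kind to evaluate (default orthologous).
#' @param runs optional tibble `gene_id`, `run_id` (ground-truth ledger).
#' @param min_run minimum pairs per shared run counted as recoverable.
#' @return one-row tibble: `n_pred`, `n_truth`, `precision`, `recall`,
#'   `f1`.
#' @export
block_f1 <- function(scan, truth, kind = "orthologous", runs = NULL,
                     min_run = 5) {
  blocks <- synteny_blocks(scan, kind = kind)
  rel <- if (kind == "orthologous") "ortholog" else "paralog"
  truth <- filter(truth, .data$relation == rel)
  if (!is.null(runs)) {
    run_of <- setNames(runs$run_id, runs$gene_id)
    combo <- paste(run_of[truth$gene_a], run_of[truth$gene_b])
    truth <- truth[combo %in% names(which(table(combo) >= min_run)), ]
  }
  pred <- if (nrow(blocks) == 0) character(0) else {
    a <- bind_rows(blocks$anchors)
    unique(pair_key(a$gene_a, a$gene_b))
  }
  tk <- unique(pair_key(truth$gene_a, truth$gene_b))
  tp <- sum(pred %in% tk)
  precision <- if (length(pred) == 0) 0 else tp / length(pred)
  recall <- if (length(tk) == 0) NA_real_ else tp / length(tk)
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(n_pred = length(pred), n_truth = length(tk),
         precision = precision, recall = recall, f1 = f1)
}
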