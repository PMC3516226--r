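#' Shipped lineage scenario scripts (chromosome-count arithmetic)
#'
#' Loads the packaged count-level scenario scripts for the plant and animal
#' lineage histories: each script starts from its clade ancestor's
#' chromosome number and applies the published series of whole-genome
#' duplications/triplications, fissions and fusions. Three scripts
#' (chicken, human, chimpanzee) are flagged: their published event counts
#' do not satisfy the count law and are shipped as printed.
#'
#' @param path optional path to an alternative YAML script file.
#' @return tibble: `kingdom`, `id`, `role`, `start_n`, `steps`
#'   (list-column), `stated_n`, `flagged`.
#' @export
lineage_scenarios <- function(path = NULL) {
  path <- path %||% system.file("extdata", "scenarios", "fig1_counts.yaml",
                                package = "paleokaryo", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  purrr::imap(y, function(entries, kingdom) {
    purrr::map(entries, function(e)
      tibble(kingdom = kingdom, id = e$id, role = e$role,
             start_n = as.integer(e$start_n),
             steps = list(as.character(unlist(e$steps))),
             stated_n = as.integer(e$stated_n),
             flagged = isTRUE(e$flagged)))
  }) |> bind_rows()
}

#' Replay all shipped lineage scripts and compare to the stated numbers
#'
#' Runs [count_trace()] on every script from [lineage_scenarios()] and
#' reports the computed final chromosome number next to the published one.
#' Scripts whose printed arithmetic is internally inconsistent are flagged
#' and expected to mismatch.
#'
#' @param scripts scenario tibble, default [lineage_scenarios()].
#' @return the tibble with `computed_n` and `match` columns added.
#' @export
replay_lineages <- function(scripts = lineage_scenarios()) {
  scripts$computed_n <-
    purrr::map2_int(scripts$start_n, scripts$steps,
                    function(n0, st) as.integer(count_final(n0, st)))
  scripts$match <- scripts$computed_n == scripts$stated_n
  scripts
}
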