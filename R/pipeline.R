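#' Pipeline configuration
#'
#' One configuration object drives the whole pipeline
#' (simulate, homology, synteny, ancestor, scenario, landscape). All
#' randomness flows from the single master `seed`, from which each stage
#' derives its own sub-seed, so a rerun with the same configuration is
#' reproducible end to end.
#'
#' @param sim a [sim_config()] (its seed is overridden by the derived
#'   stage seed).
#' @param thresholds CIP/CALP thresholds by divergence class.
#' @param max_gap,min_match,min_density_ratio,cluster_length_ref,
#'   n_shuffles,alpha synteny-stage parameters.
#' @param window_bp landscape window size.
#' @param steps character vector of stages to run.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = c(close = 70, distant = 50),
                            max_gap = 20, min_match = 5,
                            min_density_ratio = 2, cluster_length_ref = 20,
                            n_shuffles = 1000, alpha = 0.05,
                            window_bp = 500000,
                            steps = c("simulate", "homology", "synteny",
                                      "ancestor", "scenario", "landscape"),
                            seed = 1) {
  structure(list(sim = sim, thresholds = thresholds, max_gap = max_gap,
                 min_match = min_match,
                 min_density_ratio = min_density_ratio,
                 cluster_length_ref = cluster_length_ref,
                 n_shuffles = n_shuffles, alpha = alpha,
                 window_bp = window_bp, steps = steps, seed = seed),
            class = "pipeline_config")
}

stage_seed <- function(master, stage) {
  master * 101 + match(stage, c("simulate", "homology", "synteny",
                                "ancestor", "scenario", "landscape"))
}

#' Run the full pipeline into an output directory
#'
#' Executes the enabled stages in dependency order — simulation, homolog
#' calling, synteny/duplication detection, ancestral-karyotype
#' reconstruction, scenario replay, landscape profiling — writing each
#' stage's tables under `out_dir` and a `manifest.json` recording
#' parameters, seeds and per-output checksums. The run is resumable: a
#' stage whose output files already exist is skipped unless one of its
#' upstream stages was re-executed in this call (or `force` is set).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param force rerun all stages even when outputs exist.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  ran <- character(0)
  outputs <- list(
    simulate = c("genes.tsv", "hsps.tsv", "tes.gff3", "divergence.tsv"),
    homology = "homologs.tsv",
    synteny = c("blocks.tsv", "blocks.bed"),
    ancestor = c("cars.tsv", "ancestor.json"),
    scenario = "scenarios.tsv",
    landscape = c("profiles.tsv", "profile_summary.tsv"))
  path <- function(f) file.path(out_dir, f)
  need_run <- function(stage, deps) {
    force || any(deps %in% ran) ||
      !all(file.exists(vapply(outputs[[stage]], path, "")))
  }
  wrap_stage <- function(stage, body) {
    tryCatch(body(), error = function(e)
      pk_stop("pipeline stage '%s' failed: %s", stage,
              conditionMessage(e)))
  }

  if ("simulate" %in% config$steps) {
    if (need_run("simulate", character(0))) {
      wrap_stage("simulate", function() {
        cfg <- config$sim
        cfg$seed <- stage_seed(config$seed, "simulate")
        sim <- simulate_genomes(cfg)
        res$sim <<- sim
        write_gene_order(sim$genes, path("genes.tsv"))
        write_hsp_table(sim$hsps, path("hsps.tsv"), dialect = "nident")
        write_gff3_features(NULL, sim$tes, path("tes.gff3"))
        readr::write_tsv(sim$divergence, path("divergence.tsv"))
        saveRDS(sim, path("sim.rds"))
        ran <<- c(ran, "simulate")
      })
    } else res$sim <- readRDS(path("sim.rds"))
  }
  sim <- res$sim
  pk_assert(!is.null(sim), "pipeline needs the simulate stage")

  if ("homology" %in% config$steps &&
      need_run("homology", "simulate")) {
    wrap_stage("homology", function() {
      pa <- pair_alignments(sim$hsps,
                            select(sim$genes, "gene_id", "cds_length"))
      hom <- call_homologs(pa, sim$genes, sim$divergence,
                           thresholds = config$thresholds)
      res$homologs <<- hom
      readr::write_tsv(hom, path("homologs.tsv"))
      ran <<- c(ran, "homology")
    })
  } else if ("homology" %in% config$steps) {
    res$homologs <- readr::read_tsv(path("homologs.tsv"),
                                    show_col_types = FALSE)
  }

  if ("synteny" %in% config$steps && need_run("synteny", "homology")) {
    wrap_stage("synteny", function() {
      scan <- detect_synteny(res$homologs, sim$genes,
                             max_gap = config$max_gap,
                             min_match = config$min_match,
                             min_density_ratio = config$min_density_ratio,
                             cluster_length_ref = config$cluster_length_ref,
                             n_shuffles = config$n_shuffles,
                             alpha = config$alpha,
                             seed = stage_seed(config$seed, "synteny"))
      res$scan <<- scan
      write_block_table(synteny_blocks(scan), path("blocks.tsv"),
                        genomes = sim$genes)
      write_block_bed(synteny_blocks(scan), path("blocks.bed"))
      saveRDS(scan, path("scan.rds"))
      ran <<- c(ran, "synteny")
    })
  } else if ("synteny" %in% config$steps) {
    res$scan <- readRDS(path("scan.rds"))
  }

  if ("ancestor" %in% config$steps && need_run("ancestor", "synteny")) {
    wrap_stage("ancestor", function() {
      ak <- reconstruct_ancestor(res$scan)
      res$ancestor <<- ak
      write_car_table(select(ak$cars, "car_id", "n_segments", "segments"),
                      path("cars.tsv"))
      jsonlite::write_json(glance(ak), path("ancestor.json"),
                           auto_unbox = TRUE, digits = NA)
      ran <<- c(ran, "ancestor")
    })
  }

  if ("scenario" %in% config$steps && need_run("scenario", "simulate")) {
    wrap_stage("scenario", function() {
      sc <- sim$ground_truth$scenarios
      sc$replayed_n <- purrr::map2_int(sc$start_n, sc$steps,
                                       function(n0, st)
                                         as.integer(count_final(n0, st)))
      sc$match <- sc$replayed_n == sc$n_final
      res$scenarios <<- sc
      flat <- mutate(sc, steps = vapply(.data$steps, paste, "",
                                        collapse = ","))
      readr::write_tsv(flat, path("scenarios.tsv"))
      ran <<- c(ran, "scenario")
    })
  }

  if ("landscape" %in% config$steps && need_run("landscape", "simulate")) {
    wrap_stage("landscape", function() {
      prof <- purrr::map(unique(sim$genes$genome_id), function(g) {
        window_profiles(filter(sim$genes, .data$genome_id == g),
                        filter(sim$tes, .data$genome_id == g),
                        filter(sim$chrom_lengths, .data$genome_id == g),
                        window_bp = config$window_bp) |>
          mutate(genome_id = g)
      }) |> bind_rows()
      res$profiles <<- prof
      readr::write_tsv(as_tibble(prof), path("profiles.tsv"))
      summ <- prof |>
        group_by(.data$genome_id) |>
        group_split() |>
        purrr::map(function(p)
          mutate(profile_summary(p), genome_id = p$genome_id[1])) |>
        bind_rows()
      readr::write_tsv(summ, path("profile_summary.tsv"))
      ran <<- c(ran, "landscape")
    })
  }

  files <- unlist(outputs[intersect(config$steps, names(outputs))])
  files <- files[file.exists(vapply(files, path, ""))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("paleokaryo")),
    seed = config$seed,
    stages_run = ran,
    steps_enabled = config$steps,
    parameters = config[c("thresholds", "max_gap", "min_match",
                          "min_density_ratio", "cluster_length_ref",
                          "n_shuffles", "alpha", "window_bp")],
    outputs = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(path(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}
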