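#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline in one flat list: the DEG call
#' (`fdr_deg`, `min_abs_log2`, `pseudo_rpkm`), the enrichment test
#' (`enrich_alpha`), the second-round cutoffs (`crucial_cutoffs`), and the
#' simulation seed.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fdr_deg = 0.001,
    min_abs_log2 = 1,
    pseudo_rpkm = 0.001,
    enrich_alpha = 0.05,
    crucial_cutoffs = crucial_cutoffs(),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  utils::modifyList(cfg, over)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with flat keys as in [pipeline_config()].
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_stages <- function() {
  c("simulate", "rpkm", "test", "classify", "enrich", "network",
    "cluster", "report")
}

stage_dependencies <- function() {
  list(simulate = character(), rpkm = "simulate", test = "simulate",
       classify = "test", enrich = "classify", network = "classify",
       cluster = "test", report = c("classify", "enrich", "network"))
}

#' Run one pipeline stage
#'
#' Stages pass their results through the shared `state` environment-like
#' list and write per-stage TSV/JSON artefacts under `out_dir`. A stage
#' whose prerequisite has not yet populated `state` raises an error naming
#' the missing stage.
#'
#' Stage outputs: `simulate` writes the count table and annotation maps;
#' `rpkm` the log2 RPKM matrix; `test` the per-comparison test tables;
#' `classify` the category assignment with crucial flags; `enrich` the
#' enrichment tables for the crucial set; `network` the six projections as
#' edge lists with a statistics JSON; `cluster` merge heights of the
#' expression dendrogram; `report` a single JSON summary (category totals,
#' crucial counts per mask, enrichment counts, network statistics).
#'
#' @param stage One of `simulate`, `rpkm`, `test`, `classify`, `enrich`,
#'   `network`, `cluster`, `report`.
#' @param state Named list carrying earlier stage results; start with
#'   `list()`. For real (non-simulated) data, pre-populate `counts` and
#'   `annotations` instead of running `simulate`.
#' @param config A [pipeline_config()] list.
#' @param out_dir Output directory, created if needed.
#' @param sim_config Optional [simulation_config()] for the simulate stage
#'   (defaults to `simulation_config(seed = config$seed)`).
#' @return The updated `state`, with a `manifest` entry appended.
#' @export
run_stage <- function(stage, state = list(), config = pipeline_config(),
                      out_dir = tempfile("droughtdeg-run-"),
                      sim_config = NULL) {
  stage <- match.arg(stage, pipeline_stages())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  deps <- stage_dependencies()[[stage]]
  provided <- names(state$outputs)
  if (stage != "simulate" && is.null(state$counts)) {
    abort("Missing stage output: run 'simulate' first (or supply counts/annotations in `state`).")
  }
  for (d in deps) {
    if (d %in% c("test", "classify", "enrich", "network") &&
        !d %in% provided) {
      abort(paste0("Stage '", stage, "' requires output of stage '", d, "'."))
    }
  }
  paths <- character()

  if (stage == "simulate") {
    if (is.null(sim_config)) sim_config <- simulation_config(seed = config$seed)
    sim <- simulate_experiment(sim_config)
    state$counts <- sim$counts
    state$annotations <- sim$annotations
    state$truth <- sim$truth
    paths <- c(counts = file.path(out_dir, "counts.tsv"),
               pathways = file.path(out_dir, "gene_pathway.tsv"),
               processes = file.path(out_dir, "gene_process.tsv"))
    write_count_table(sim$counts, paths[["counts"]])
    write_annotation_map(sim$annotations, paths[["pathways"]],
                         paths[["processes"]])
  } else if (stage == "rpkm") {
    m <- expression_matrix(state$counts, config$pseudo_rpkm)
    state$log2_rpkm <- m
    paths <- c(rpkm = file.path(out_dir, "log2_rpkm.tsv"))
    readr::write_tsv(as_tibble(as.data.frame(m), rownames = "gene_id"),
                     paths[["rpkm"]])
  } else if (stage == "test") {
    res <- call_all_degs(state$counts, fdr_max = config$fdr_deg,
                         min_abs_log2 = config$min_abs_log2,
                         pseudo_rpkm = config$pseudo_rpkm)
    state$test <- res
    paths <- c(test = file.path(out_dir, "deg_tests.tsv"))
    readr::write_tsv(as_tibble(res), paths[["test"]])
  } else if (stage == "classify") {
    sets <- filter_pathway_annotated(deg_sets(state$test), state$annotations)
    part <- venn_partition(sets)
    asg <- assign_categories(part)
    asg <- filter_crucial(asg, ratio_table(state$test),
                          cutoffs = config$crucial_cutoffs)
    state$classify <- asg
    paths <- c(classify = file.path(out_dir, "categories.tsv"))
    readr::write_tsv(as_tibble(asg), paths[["classify"]])
  } else if (stage == "enrich") {
    crucial <- state$classify$gene_id[state$classify$crucial]
    state$enrich <- list(
      pathway = enrich(crucial, state$annotations, "pathway",
                       alpha = config$enrich_alpha),
      process = enrich(crucial, state$annotations, "process",
                       alpha = config$enrich_alpha)
    )
    paths <- c(enrich_pathway = file.path(out_dir, "enrich_pathway.tsv"),
               enrich_process = file.path(out_dir, "enrich_process.tsv"))
    readr::write_tsv(as_tibble(state$enrich$pathway), paths[["enrich_pathway"]])
    readr::write_tsv(as_tibble(state$enrich$process), paths[["enrich_process"]])
  } else if (stage == "network") {
    crucial <- state$classify$gene_id[state$classify$crucial]
    tri <- build_tripartite(crucial, state$annotations)
    nets <- project_all(tri)
    state$network <- list(tripartite = tri, projections = nets)
    paths <- setNames(
      file.path(out_dir, paste0("net_", gsub("-", "_", names(nets)), ".tsv")),
      paste0("net_", names(nets)))
    for (i in seq_along(nets)) export_network(nets[[i]], paths[[i]], "tsv")
    stats_path <- file.path(out_dir, "network_stats.json")
    jsonlite::write_json(purrr::map(nets, ~ as.list(glance(.x))),
                         stats_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, network_stats = stats_path)
  } else if (stage == "cluster") {
    m <- expression_matrix(state$counts, config$pseudo_rpkm)
    keep <- apply(m, 1, function(r) !all(r == r[1]))
    hc <- hclust_average(distance_matrix(m[keep, , drop = FALSE], "euclidean"))
    state$cluster <- hc
    paths <- c(cluster = file.path(out_dir, "cluster_heights.tsv"))
    readr::write_tsv(tibble(merge_order = seq_along(hc$height),
                            height = hc$height), paths[["cluster"]])
  } else if (stage == "report") {
    asg <- state$classify
    crucial <- asg[asg$crucial, ]
    report <- list(
      schema_version = "1.0",
      n_genes = nrow(state$counts),
      deg_counts = as.list(setNames(glance(state$test)$n_deg,
                                    glance(state$test)$comparison)),
      category_totals = as.list(setNames(category_totals(asg)$n,
                                         category_totals(asg)$category)),
      crucial_total = nrow(crucial),
      crucial_per_mask = as.list(setNames(count(crucial, .data$mask)$n,
                                          count(crucial, .data$mask)$mask)),
      unique_pathways = nrow(pathway_involvement(crucial$gene_id,
                                                 state$annotations)),
      enriched_pathways = sum(state$enrich$pathway$enriched),
      enriched_processes = sum(state$enrich$process$enriched),
      network = purrr::map(state$network$projections,
                           ~ as.list(glance(.x)))
    )
    state$report <- report
    paths <- c(report = file.path(out_dir, "report.json"))
    jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                         digits = NA)
  }

  entry <- tibble(stage = stage, output = unname(paths),
                  md5 = unname(tools::md5sum(paths)))
  state$outputs <- c(state$outputs, setNames(list(paths), stage))
  state$manifest <- bind_rows(state$manifest, entry)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = config[setdiff(names(config), "crucial_cutoffs")],
         seed = config$seed,
         version = as.character(utils::packageVersion("droughtdeg")),
         files = state$manifest),
    manifest_path, auto_unbox = TRUE, digits = NA)
  state
}

#' Run the full pipeline
#'
#' Convenience chain over [run_stage()] in dependency order.
#'
#' @inheritParams run_stage
#' @param stages Stages to run, default all in order.
#' @return Final `state` with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("droughtdeg-run-"),
                         sim_config = NULL,
                         stages = pipeline_stages(),
                         state = list()) {
  for (s in stages) {
    state <- run_stage(s, state, config, out_dir, sim_config)
  }
  state
}
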