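# Pipeline orchestration: stage sequence score-mcq -> propagate ->
# hierarchy -> enrich, file-format round-trips, manifests, and the
# packaged synthetic preset. All randomness traces to the single
# `rng_seed` in the run configuration.

#' Default run configuration
#'
#' Flat list of every stage parameter with its default; input paths are
#' filled in by the caller (or by [simulate_preset()]). CLI overrides
#' win over config-file values, which win over these defaults.
#'
#' @param ... named overrides of any default
#' @return a `run_config` list
#' @export
default_run_config <- function(...) {
  cfg <- list(
    # inputs
    network_path = NULL, seeds_path = NULL, traits_path = NULL,
    annotations_path = NULL, items_path = NULL, responses_path = NULL,
    weight_column = 3L,
    # mcq stage
    min_consistency = 0.75, max_missing = 0L, flag_uniform = TRUE,
    # propagation stage
    alpha = 0.5, n_null = 100L, nps_threshold = 3, degree_bins = 10L,
    # hierarchy stage
    resolution_max = 5, resolution_steps = 10L,
    jaccard_threshold = 0.75, persistence_min = 5L, ci_threshold = 0.75,
    # enrichment stage
    fdr_level = 0.05, universe = "network",
    # global
    rng_seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    dd_param_error(paste("unknown config key(s):", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a seed gene list (plain list or GMT)
#'
#' Plain format: one gene id per line, `#` comments allowed. A file whose
#' lines carry >= 2 tab-separated fields is read as GMT and the union of
#' its sets is used.
#'
#' @param path file path
#' @return character vector of gene ids
#' @export
read_seed_list <- function(path) {
  if (!file.exists(path)) dd_param_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) dd_format_error(sprintf("empty seed file: %s", path))
  if (any(grepl("\t", lines, fixed = TRUE)))
    unique(unlist(read_gmt(path), use.names = FALSE))
  else unique(trimws(lines))
}

#' Write the packaged synthetic preset to a directory
#'
#' Generates the standard synthetic study: a 2000-gene planted-partition
#' network of 80 tight blocks in a sparse background (the regime where a
#' specific gene's null heat is rarely elevated, so proximity z-scores
#' resolve the planted signal), a 16-gene seed set split across the
#' first two blocks, six trait gene-sets with graded block overlap
#' (including a negative control), one annotation term-set per block,
#' the default questionnaire item bank, and simulated choice profiles.
#' Everything is written as plain text (TSV/GMT/CSV) so a full run needs
#' no other inputs.
#'
#' @param out_dir output directory (created if needed)
#' @param rng_seed integer seed governing all generated data
#' @param preset one of "full" (default), "network" (network, seeds,
#'   traits only) or "mcq" (items and responses only)
#' @return named list of written file paths, invisibly
#' @export
simulate_preset <- function(out_dir, rng_seed = 1L, preset = "full") {
  preset <- match.arg(preset, c("full", "network", "mcq"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (preset %in% c("full", "network")) {
    # 80 blocks of 25 genes: dense within (0.3), sparse between (0.002)
    net <- gen_network(2000, 80, p_within = 0.3, p_between = 0.002,
                       weight_range = c(0.1, 1),
                       rng_seed = derive_seed(rng_seed, 1L))
    seeds <- unique(c(
      gen_seed_set(net, community_id = 1L, size = 10, purity = 1,
                   rng_seed = derive_seed(rng_seed, 2L)),
      gen_seed_set(net, community_id = 2L, size = 6, purity = 1,
                   rng_seed = derive_seed(rng_seed, 6L))))
    comms <- split(names(net$membership), net$membership)
    names(comms) <- paste0("block", names(comms))
    overlap <- matrix(0, 6, 4,
                      dimnames = list(paste0("trait", 1:6),
                                      paste0("block", 1:4)))
    overlap["trait1", "block1"] <- 0.5
    overlap["trait2", "block2"] <- 0.5
    overlap["trait3", "block1"] <- 0.25; overlap["trait3", "block2"] <- 0.25
    overlap["trait4", "block3"] <- 0.5
    overlap["trait5", "block4"] <- 0.2
    # trait6 has no planted overlap: a negative control
    traits <- gen_trait_sets(net, comms[paste0("block", 1:4)], overlap,
                             sizes = 30,
                             rng_seed = derive_seed(rng_seed, 3L))
    anno <- stats::setNames(comms, paste0("term_", names(comms)))

    paths$network <- file.path(out_dir, "network.tsv")
    write_edge_list(net, paths$network)
    paths$seeds <- file.path(out_dir, "seeds.txt")
    writeLines(seeds, paths$seeds)
    paths$traits <- file.path(out_dir, "traits.gmt")
    write_gmt(traits, paths$traits)
    paths$annotations <- file.path(out_dir, "annotations.gmt")
    write_gmt(anno, paths$annotations)
  }

  if (preset %in% c("full", "mcq")) {
    items <- mcq_item_bank()
    grid <- candidate_grid(items)
    n_part <- 40L
    true_log10_k <- with_seed(derive_seed(rng_seed, 4L),
                              stats::runif(n_part, log10(min(grid)),
                                           log10(max(grid))))
    responses <- gen_mcq_cohort(true_log10_k, items, noise_temperature = 1,
                                rng_seed = derive_seed(rng_seed, 5L))
    paths$items <- file.path(out_dir, "items.csv")
    utils::write.csv(items, paths$items, row.names = FALSE, quote = FALSE)
    paths$responses <- file.path(out_dir, "responses.csv")
    utils::write.csv(responses, paths$responses, row.names = FALSE,
                     quote = FALSE)
    paths$true_log10_k <- file.path(out_dir, "true_log10_k.tsv")
    write_tsv_plain(data.frame(participant_id = responses$participant_id,
                               true_log10_k = true_log10_k),
                    paths$true_log10_k)
  }
  invisible(paths)
}

#' @noRd
stage_error <- function(stage, e) {
  dd_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          "ddnetmap_stage_error")
}

#' Run the full pipeline
#'
#' Executes, in order, questionnaire scoring (when item/response inputs
#' are configured), seed propagation with NPS calibration, hierarchy
#' assembly on the proximal subnetwork, and trait enrichment. Every
#' stage writes its table under `out_dir`, and a manifest JSON records
#' the configuration, seeds, and every exclusion count. Re-running with
#' the same config and seed reproduces byte-identical stage tables.
#'
#' @param config a `run_config` (see [default_run_config()])
#' @param out_dir output directory
#' @return named list of outputs (`discounting`, `nps`, `hierarchy`,
#'   `enrichment`, `manifest`) invisibly; files under `out_dir`
#' @export
run_all <- function(config, out_dir) {
  if (!inherits(config, "run_config")) dd_param_error("config must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in c("network_path", "seeds_path", "traits_path")) {
    p <- config[[key]]
    if (is.null(p) || !file.exists(p))
      dd_param_error(sprintf("required input '%s' missing or not found: %s",
                             key, p %||% "<unset>"))
  }
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  outputs <- list()
  counts <- list()

  # ---- stage: score-mcq (optional) ----
  if (!is.null(config$items_path) && !is.null(config$responses_path)) {
    tryCatch({
      items <- read_mcq_items(config$items_path)
      responses <- read_mcq_responses(config$responses_path)
      scored <- score_cohort(responses, items,
                             min_consistency = config$min_consistency,
                             max_missing = config$max_missing,
                             flag_uniform = config$flag_uniform)
      qc <- attr(scored, "qc_summary")
      counts$participants_total <- qc$n_total
      counts$participants_excluded <- qc$n_excluded
      note("score-mcq: %d participants, %d excluded by QC",
           qc$n_total, qc$n_excluded)
      outputs$discounting <- scored
      write_tsv_plain(scored, file.path(out_dir, "discounting.tsv"))
    }, ddnetmap_error = function(e) stage_error("score-mcq", e),
       error = function(e) stage_error("score-mcq", e))
  }

  # ---- stage: propagate ----
  prop <- tryCatch({
    network <- read_edge_list(config$network_path, config$weight_column)
    seeds <- read_seed_list(config$seeds_path)
    counts$network_genes <- length(network$genes)
    counts$self_loops_dropped <- network$report$self_loops_dropped
    counts$duplicate_edges_dropped <- network$report$duplicates_dropped
    res <- withCallingHandlers(
      netprop(network, seeds, alpha = config$alpha, n_null = config$n_null,
              nps_threshold = config$nps_threshold,
              degree_bins = config$degree_bins,
              rng_seed = derive_seed(config$rng_seed, 11L)),
      warning = function(w) {
        note("propagate: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    counts$seeds_used <- length(res$seeds_used)
    counts$seeds_dropped <- length(res$seeds_dropped)
    counts$zero_heat_genes <- sum(res$nps$flags == "zero_heat")
    counts$selected_genes <- length(res$selected)
    note("propagate: %d seeds, %d genes selected at NPS > %g",
         length(res$seeds_used), length(res$selected), config$nps_threshold)
    outputs$network <- network
    write_tsv_plain(res$nps, file.path(out_dir, "nps.tsv"))
    res
  }, ddnetmap_error = function(e) stage_error("propagate", e),
     error = function(e) stage_error("propagate", e))

  # ---- stage: hierarchy ----
  hierarchy <- tryCatch({
    grid <- seq(config$resolution_max / config$resolution_steps,
                config$resolution_max, length.out = config$resolution_steps)
    h <- build_systems_map(outputs$network, prop$selected, prop$seeds_used,
                           resolution_grid = grid,
                           jaccard_threshold = config$jaccard_threshold,
                           persistence_min = config$persistence_min,
                           ci_threshold = config$ci_threshold,
                           partition_seed = derive_seed(config$rng_seed, 12L))
    validate_hierarchy(h, config$ci_threshold)
    counts$communities <- nrow(h$nodes)
    note("hierarchy: %d communities, %d containment edges",
         nrow(h$nodes), nrow(h$edges))
    write_hierarchy(h, out_dir)
    h
  }, ddnetmap_error = function(e) stage_error("hierarchy", e),
     error = function(e) stage_error("hierarchy", e))
  outputs$nps <- prop
  outputs$hierarchy <- hierarchy

  # ---- stage: enrich ----
  outputs$enrichment <- tryCatch({
    traits <- read_gmt(config$traits_path)
    universe <- if (identical(config$universe, "selected"))
      attr(hierarchy, "subnetwork")$genes else outputs$network$genes
    tab <- enrich_hierarchy(hierarchy, traits, universe,
                            fdr_level = config$fdr_level)
    note("enrich: %d tests, %d significant at FDR %g",
         nrow(tab), sum(tab$significant), config$fdr_level)
    if (!is.null(config$annotations_path)) {
      anno <- read_gmt(config$annotations_path)
      lab <- annotate_communities(hierarchy, anno, universe,
                                  config$fdr_level)
      write_tsv_plain(lab, file.path(out_dir, "annotations.tsv"))
      outputs$annotations <- lab
    }
    write_tsv_plain(tab, file.path(out_dir, "enrichment.tsv"))
    tab
  }, ddnetmap_error = function(e) stage_error("enrich", e),
     error = function(e) stage_error("enrich", e))

  manifest <- list(
    package = "ddnetmap",
    version = as.character(utils::packageVersion("ddnetmap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[!vapply(config, is.null, logical(1))],
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  outputs$manifest <- manifest
  invisible(outputs)
}

#' Write hierarchy node and edge tables
#'
#' @param hierarchy a `community_hierarchy`
#' @param out_dir directory for `hierarchy_nodes.tsv` /
#'   `hierarchy_edges.tsv`
#' @return the two paths, invisibly
#' @export
write_hierarchy <- function(hierarchy, out_dir) {
  nodes <- hierarchy$nodes
  nodes_flat <- data.frame(
    community_id = nodes$community_id,
    size = nodes$size,
    resolution_first = nodes$resolution_first,
    resolution_last = nodes$resolution_last,
    persistence = nodes$persistence,
    genes = vapply(nodes$genes, function(g) paste(sort(g), collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE
  )
  np <- file.path(out_dir, "hierarchy_nodes.tsv")
  ep <- file.path(out_dir, "hierarchy_edges.tsv")
  write_tsv_plain(nodes_flat, np)
  write_tsv_plain(hierarchy$edges, ep)
  invisible(c(nodes = np, edges = ep))
}

#' Read hierarchy tables back into a community_hierarchy
#' @param out_dir directory containing the node/edge TSVs
#' @return a `community_hierarchy`
#' @export
read_hierarchy <- function(out_dir) {
  np <- file.path(out_dir, "hierarchy_nodes.tsv")
  ep <- file.path(out_dir, "hierarchy_edges.tsv")
  if (!file.exists(np) || !file.exists(ep))
    dd_param_error(sprintf("hierarchy tables not found under %s", out_dir))
  nodes <- utils::read.delim(np, stringsAsFactors = FALSE)
  nodes$genes <- I(strsplit(nodes$genes, ",", fixed = TRUE))
  edges <- utils::read.delim(ep, stringsAsFactors = FALSE)
  roots <- setdiff(nodes$community_id, edges$child)
  structure(list(nodes = nodes, edges = edges, root = roots),
            class = "community_hierarchy")
}
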