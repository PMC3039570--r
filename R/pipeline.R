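#' Demo pipeline configuration
#'
#' A complete [run_pipeline()] configuration at demonstration scale.  Any
#' element can be overridden via `...` (nested lists are replaced whole).
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param ... Overrides merged over the defaults.
#' @return Named list.
#' @export
demo_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    sim = list(n_proteins = 200L, n_nodes = 250L, n_bp_terms = 10L),
    infer = list(fdr_max = 0.0025, calibrate = TRUE),
    abundance = list(quantile = 0.25),
    goflux = list(n_networks = 20L, alpha = 0.01),
    compare = list(n_resamples = 200L, subsample = 100L),
    stages = c("synth", "infer", "abundance", "topology", "pathpos",
               "goflux", "compare")
  )
  utils::modifyList(cfg, list(...))
}

#' Run the whole pipeline end to end
#'
#' Executes the stages synth → infer → abundance → topology → pathpos →
#' goflux → compare in dependency order, writing each stage's outputs as
#' plain-text tables/JSON under `out_dir`.  A stage is skipped when its
#' outputs already exist and neither its configuration nor any upstream
#' stage changed, so deleting one intermediate file re-executes only the
#' affected stage and everything downstream.  A machine-readable run
#' report (per-stage status, output checksums, row counts and headline
#' numbers) is written to `run_report.json` even when a stage fails;
#' failure halts all downstream stages.
#'
#' @param config List from [demo_config()] (or a YAML file path with the
#'   same structure).
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly (list).
#' @export
run_pipeline <- function(config = demo_config(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read a config file", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(out_dir, "run_state.json")
  state <- if (file.exists(state_path)) {
    jsonlite::read_json(state_path, simplifyVector = TRUE)
  } else list()

  stages <- list(
    synth = stage_synth, infer = stage_infer, abundance = stage_abundance,
    topology = stage_topology, pathpos = stage_pathpos,
    goflux = stage_goflux, compare = stage_compare
  )
  report <- list(config = config, stages = list())
  env <- new.env(parent = emptyenv())
  upstream_ran <- FALSE
  failed <- FALSE

  for (nm in names(stages)) {
    if (!nm %in% config$stages) next
    entry <- list(status = "skipped")
    hash <- stage_hash(config, nm)
    outputs <- stage_outputs(nm, out_dir)
    fresh <- !upstream_ran && identical(state[[nm]], hash) &&
      all(file.exists(outputs))
    if (failed) {
      entry$status <- "halted"
    } else if (fresh && !stage_needs_memory(nm, env)) {
      entry$status <- "skipped"
      entry$outputs <- checksum_outputs(outputs)
      stage_load(nm, out_dir, env)
    } else {
      res <- tryCatch({
        stages[[nm]](config, out_dir, env)
        state[[nm]] <- hash
        list(status = "completed")
      }, error = function(e) list(status = "failed", error = conditionMessage(e)))
      entry$status <- res$status
      if (res$status == "failed") {
        entry$error <- res$error
        failed <- TRUE
      } else {
        upstream_ran <- TRUE
        entry$outputs <- checksum_outputs(outputs)
        entry$counts <- env$counts[[nm]]
      }
    }
    report$stages[[nm]] <- entry
  }

  report$headline <- env$headline
  jsonlite::write_json(state, state_path, auto_unbox = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}

validate_run_config <- function(config) {
  required <- c("seed", "stages")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("invalid pipeline config; missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(config$stages,
                     c("synth", "infer", "abundance", "topology", "pathpos",
                       "goflux", "compare"))
  if (length(unknown) > 0) {
    stop("invalid pipeline config; unknown stage(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

stage_hash <- function(config, nm) {
  sub <- config[intersect(c("seed", "sim", nm), names(config))]
  digest_chr(jsonlite::toJSON(sub, auto_unbox = TRUE))
}

digest_chr <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(x), tmp)
  unname(tools::md5sum(tmp))
}

stage_outputs <- function(nm, out_dir) {
  f <- switch(nm,
    synth = c("proteome.tsv", "gene_map.tsv", "psm_a.tsv", "psm_b.tsv",
              "interactome_edges.tsv", "annotations.tsv", "node_labels.tsv",
              "pathway_edges.tsv", "pathway_assignments.tsv",
              "ground_truth.json"),
    infer = c("groups.tsv", "calibration.json"),
    abundance = c("abundance.tsv", "abundance_summary.tsv", "central.txt",
                  "classes.tsv"),
    topology = "topology.tsv",
    pathpos = c("node_positions.tsv", "protein_positions.tsv"),
    goflux = c("flux.tsv", "flux_summary.json"),
    compare = "compare.json"
  )
  file.path(out_dir, f)
}

checksum_outputs <- function(paths) {
  lapply(stats::setNames(paths, basename(paths)),
         function(p) unname(tools::md5sum(p)))
}

# stages needing in-memory inputs reload them from disk when skipped
stage_needs_memory <- function(nm, env) FALSE

stage_load <- function(nm, out_dir, env) {
  p <- function(f) file.path(out_dir, f)
  switch(nm,
    synth = {
      env$proteome <- readr::read_tsv(p("proteome.tsv"), col_types = "ccc")
      env$gene_map <- readr::read_tsv(p("gene_map.tsv"), col_types = "cc")
      env$psm_a <- read_psm_tsv(p("psm_a.tsv"))
      env$psm_b <- read_psm_tsv(p("psm_b.tsv"))
      edges <- readr::read_tsv(p("interactome_edges.tsv"), col_types = "cc")
      g <- igraph::graph_from_data_frame(edges, directed = FALSE)
      ann <- readr::read_tsv(p("annotations.tsv"), col_types = "cc")
      lab <- readr::read_tsv(p("node_labels.tsv"), col_types = "cli")
      env$graph <- annotate_graph(g, ann, lab)
      env$pathway_edges <- readr::read_tsv(p("pathway_edges.tsv"),
                                           col_types = "ccc")
      env$assignments <- readr::read_tsv(p("pathway_assignments.tsv"),
                                         col_types = "ccc")
    },
    infer = {
      env$groups <- readr::read_tsv(p("groups.tsv"), col_types = readr::cols())
    },
    abundance = {
      env$abundance_summary <- readr::read_tsv(p("abundance_summary.tsv"),
                                               col_types = readr::cols())
      env$central <- readLines(p("central.txt"))
    },
    invisible(NULL)
  )
  invisible(NULL)
}

note_counts <- function(env, nm, counts) {
  if (is.null(env$counts)) env$counts <- list()
  env$counts[[nm]] <- counts
}

stage_synth <- function(config, out_dir, env) {
  p <- function(f) file.path(out_dir, f)
  sim_args <- c(list(seed = config$seed), config$sim)
  cfg <- do.call(sim_config, sim_args)
  proteome <- sim_proteome(cfg)
  psm <- sim_psm_tables(proteome, cfg)
  net <- sim_annotated_interactome(cfg)
  pw <- sim_pathways(cfg)

  readr::write_tsv(proteome, p("proteome.tsv"))
  readr::write_tsv(psm$ground_truth$gene_map, p("gene_map.tsv"))
  write_psm_tsv(dplyr::filter(psm$psm, .data$engine == "A"), p("psm_a.tsv"))
  write_psm_tsv(dplyr::filter(psm$psm, .data$engine == "B"), p("psm_b.tsv"))
  write_edge_tsv(net$graph, p("interactome_edges.tsv"))
  nodes <- graph_nodes(net$graph)
  readr::write_tsv(
    nodes |> dplyr::select("node", "terms") |> tidyr::unnest("terms") |>
      dplyr::rename(term = "terms"),
    p("annotations.tsv"))
  readr::write_tsv(nodes |> dplyr::select("node", "central", "n_detected"),
                   p("node_labels.tsv"))
  readr::write_tsv(pw$edges, p("pathway_edges.tsv"))
  readr::write_tsv(pw$assignments, p("pathway_assignments.tsv"))
  jsonlite::write_json(
    list(common_set = psm$ground_truth$common_set,
         planted_flux_pair = net$ground_truth$planted_flux_pair,
         flux_multiplier = net$ground_truth$flux_multiplier,
         central_nodes = net$ground_truth$central_nodes),
    p("ground_truth.json"))

  env$sim_cfg <- cfg
  env$proteome <- proteome
  env$gene_map <- psm$ground_truth$gene_map
  env$psm_a <- dplyr::filter(psm$psm, .data$engine == "A")
  env$psm_b <- dplyr::filter(psm$psm, .data$engine == "B")
  env$graph <- net$graph
  env$pathway_edges <- pw$edges
  env$assignments <- pw$assignments
  note_counts(env, "synth", list(
    n_proteins = nrow(proteome), n_psms = nrow(psm$psm),
    n_nodes = igraph::vcount(net$graph), n_edges = igraph::ecount(net$graph)))
}

stage_infer <- function(config, out_dir, env) {
  p <- function(f) file.path(out_dir, f)
  if (isTRUE(config$infer$calibrate)) {
    cal <- calibrate_group_fdr(env$psm_a, env$psm_b, env$proteome,
                               default_thresholds_grid(),
                               gene_map = env$gene_map,
                               fdr_max = config$infer$fdr_max %||% 0.0025)
    th <- cal$thresholds
    jsonlite::write_json(
      c(glance(cal), list(grid = tidy(cal))),
      p("calibration.json"), auto_unbox = TRUE, digits = NA)
  } else {
    th <- inference_thresholds()
    cal <- NULL
    jsonlite::write_json(list(calibrated = FALSE), p("calibration.json"),
                         auto_unbox = TRUE)
  }
  groups <- infer_proteins(env$psm_a, env$psm_b, env$proteome,
                           thresholds = th, gene_map = env$gene_map)
  groups_as_table(groups, p("groups.tsv"))
  env$groups <- groups_as_table(groups)
  env$groups_raw <- groups
  note_counts(env, "infer", list(
    n_groups = nrow(groups), n_decoy_groups = sum(groups$is_decoy)))
}

stage_abundance <- function(config, out_dir, env) {
  p <- function(f) file.path(out_dir, f)
  groups <- env$groups_raw
  if (is.null(groups)) {
    # rebuilt from the flattened table when the infer stage was skipped
    flat <- env$groups
    groups <- flat |>
      dplyr::mutate(members = strsplit(.data$members, ";", fixed = TRUE),
                    peptides = strsplit(.data$peptides, ";", fixed = TRUE))
  }
  detections <- groups |>
    dplyr::filter(!.data$is_decoy) |>
    dplyr::transmute(protein_id = .data$group_id, cell_line = .data$cell_line,
                     n_observed = .data$n_peptides)
  am <- abundance_matrix(detections, env$proteome)
  summ <- abundance_summary(am)
  n_cl <- env$sim_cfg$n_cell_lines %||%
    max(length(unique(detections$cell_line)), 1L)
  central <- central_proteome(summ, n_cell_lines = n_cl)
  classes <- abundance_classes(summ, central)
  readr::write_tsv(am, p("abundance.tsv"))
  readr::write_tsv(summ, p("abundance_summary.tsv"))
  writeLines(central, p("central.txt"))
  readr::write_tsv(tibble::as_tibble(classes), p("classes.tsv"))
  env$abundance_summary <- summ
  env$central <- central
  if (is.null(env$headline)) env$headline <- list()
  env$headline$central_size <- length(central)
  env$headline$class_sizes <- as.list(table(classes$class))
  note_counts(env, "abundance", list(
    n_quantified = nrow(summ), central_size = length(central)))
}

stage_topology <- function(config, out_dir, env) {
  prof <- topology_measures(env$graph)
  readr::write_tsv(prof, file.path(out_dir, "topology.tsv"))
  env$topology <- prof
  note_counts(env, "topology", list(n_nodes = nrow(prof)))
}

stage_pathpos <- function(config, out_dir, env) {
  npos <- pathway_positions(env$pathway_edges)
  ppos <- protein_positions(npos, env$assignments)
  readr::write_tsv(npos, file.path(out_dir, "node_positions.tsv"))
  readr::write_tsv(ppos, file.path(out_dir, "protein_positions.tsv"))
  note_counts(env, "pathpos", list(n_positioned = nrow(ppos)))
}

stage_goflux <- function(config, out_dir, env) {
  res <- withr::with_seed(config$seed + 55L, {
    go_flux(env$graph,
            n_networks = config$goflux$n_networks %||% 20L,
            alpha = config$goflux$alpha %||% 0.01)
  })
  readr::write_tsv(tibble::as_tibble(res), file.path(out_dir, "flux.tsv"))
  jsonlite::write_json(glance(res), file.path(out_dir, "flux_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (is.null(env$headline)) env$headline <- list()
  env$headline$n_significant_fluxes <- sum(res$significant)
  note_counts(env, "goflux", list(n_pairs = nrow(res),
                                  n_significant = sum(res$significant)))
}

stage_compare <- function(config, out_dir, env) {
  res <- withr::with_seed(config$seed + 66L, {
    prof <- env$topology %||% topology_measures(env$graph)
    central_nodes <- graph_nodes(env$graph) |>
      dplyr::filter(.data$central) |> dplyr::pull("node")
    a <- prof$degree[prof$node %in% central_nodes]
    b <- prof$degree[!prof$node %in% central_nodes]
    bootstrap_chi2(a, b,
                   n_resamples = config$compare$n_resamples %||% 200L,
                   subsample = config$compare$subsample %||% 100L)
  })
  jsonlite::write_json(tidy(res), file.path(out_dir, "compare.json"),
                       auto_unbox = TRUE, digits = NA)
  note_counts(env, "compare", list(statistic = res$statistic,
                                   p_value = res$p_value))
}
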