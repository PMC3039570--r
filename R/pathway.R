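#' Relative positions of nodes along pathway graphs
#'
#' For each node of each pathway the relative position is
#' d_s / (d_s + d_e), where d_s is the directed shortest-path length from
#' the closest source (in-degree 0) and d_e the shortest length to the
#' closest end (out-degree 0); sources sit at 0, ends at 1.  With
#' `method = "average"` the shortest path to the *closest* source/end is
#' replaced by the mean over all shortest paths to every reachable
#' source/end, an alternative measure that yields nearly identical
#' positions.
#'
#' Cyclic pathways are handled by condensing strongly connected components
#' first: every member of a component inherits the component's position,
#' which guarantees that sources and ends exist.  Nodes with no edges at
#' all are excluded with a warning.
#'
#' @param edges Tibble with columns `pathway_id`, `from`, `to` (directed
#'   edges).
#' @param method `"closest"` (default) or `"average"`.
#' @return Tibble with `pathway_id`, `node`, `position` in \[0, 1\].
#' @export
pathway_positions <- function(edges, method = c("closest", "average")) {
  method <- match.arg(method)
  stopifnot(all(c("pathway_id", "from", "to") %in% names(edges)))
  edges |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::group_modify(~ pathway_positions_one(.x, method)) |>
    dplyr::ungroup()
}

pathway_positions_one <- function(e, method) {
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  if (length(iso) > 0) {
    warning("excluding node(s) isolated from all sources and ends: ",
            paste(utils::head(iso, 3), collapse = ", "), call. = FALSE)
    g <- igraph::delete_vertices(g, iso)
  }
  # condensation: each strongly connected component becomes one node of a
  # DAG, so every condensed node lies on some source-to-end path
  scc <- igraph::components(g, mode = "strong")
  cg <- igraph::contract(g, scc$membership)
  cg <- igraph::simplify(cg)
  igraph::V(cg)$name <- as.character(seq_len(igraph::vcount(cg)))

  indeg <- igraph::degree(cg, mode = "in")
  outdeg <- igraph::degree(cg, mode = "out")
  sources <- which(indeg == 0)
  ends <- which(outdeg == 0)

  d_from_src <- igraph::distances(cg, v = sources, mode = "out")
  d_to_end <- igraph::distances(cg, v = ends, mode = "in")
  pos <- vapply(seq_len(igraph::vcount(cg)), function(v) {
    ds <- d_from_src[, v]; de <- d_to_end[, v]
    ds <- ds[is.finite(ds)]; de <- de[is.finite(de)]
    ds <- if (method == "closest") min(ds) else mean(ds)
    de <- if (method == "closest") min(de) else mean(de)
    if (ds + de == 0) return(0.5)  # component that is source and end at once
    ds / (ds + de)
  }, numeric(1))

  tibble::tibble(
    node = igraph::V(g)$name,
    position = pos[scc$membership]
  ) |> dplyr::arrange(.data$node)
}

#' Per-protein relative pathway positions
#'
#' Two-level unweighted averaging: a protein occurring at several nodes of
#' one pathway gets the mean of those node positions; occurrences across
#' several pathways are then averaged with equal weight per pathway.
#' Proteins sitting in complexes simply inherit each complex node's
#' position.
#'
#' @param node_positions Output of [pathway_positions()].
#' @param assignments Tibble with `pathway_id`, `node`, `protein_id`.
#' @return Tibble with `protein_id`, `position`, `n_pathways`, `n_nodes`.
#' @export
protein_positions <- function(node_positions, assignments) {
  assignments |>
    dplyr::inner_join(node_positions, by = c("pathway_id", "node")) |>
    dplyr::group_by(.data$protein_id, .data$pathway_id) |>
    dplyr::summarise(position = mean(.data$position),
                     n_nodes = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(position = mean(.data$position),
                     n_pathways = dplyr::n(),
                     n_nodes = sum(.data$n_nodes), .groups = "drop")
}

#' Positional profiles of protein sets along pathways
#'
#' Bins each set's protein positions into five equal bins on \[0, 1\] and
#' reports membership lists for the three named regions used in positional
#' GO analysis: source (0--0.2), center (0.4--0.6) and end (0.8--1).
#'
#' @param positions Output of [protein_positions()].
#' @param protein_sets Named list of character vectors of protein ids.
#' @return A `positional_profile` object: list with `histogram` (tibble
#'   `set`, `bin`, `n`) and `regions` (tibble `set`, `region`,
#'   `protein_id`).
#' @export
positional_profile <- function(positions, protein_sets) {
  stopifnot(length(protein_sets) > 0, !is.null(names(protein_sets)))
  breaks <- seq(0, 1, by = 0.2)
  hist_tbl <- purrr::imap(protein_sets, function(ids, nm) {
    p <- positions$position[positions$protein_id %in% ids]
    bin <- cut(p, breaks, include.lowest = TRUE)
    tibble::tibble(set = nm, bin = levels(bin)) |>
      dplyr::left_join(
        tibble::tibble(bin = as.character(bin)) |> dplyr::count(.data$bin),
        by = "bin") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }) |> dplyr::bind_rows()

  region_of <- function(p) {
    dplyr::case_when(
      p <= 0.2 ~ "source",
      p > 0.4 & p <= 0.6 ~ "center",
      p > 0.8 ~ "end",
      TRUE ~ NA_character_
    )
  }
  regions <- purrr::imap(protein_sets, function(ids, nm) {
    sub <- positions[positions$protein_id %in% ids, ]
    tibble::tibble(set = nm, region = region_of(sub$position),
                   protein_id = sub$protein_id) |>
      dplyr::filter(!is.na(.data$region))
  }) |> dplyr::bind_rows()

  structure(list(histogram = hist_tbl, regions = regions),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("<positional_profile>\n")
  print(tidyr::pivot_wider(x$histogram, names_from = "bin", values_from = "n"))
  invisible(x)
}
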