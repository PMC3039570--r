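#' Five topology measures for every node of a PPI network
#'
#' Computes the five connectivity measures used to profile protein sets in
#' an interactome: node degree, betweenness centrality (raw shortest-path
#' counts with even splitting among equal-length paths; set
#' `normalized = TRUE` for the ratio form), eigenvector centrality
#' (computed on the largest connected component and scaled to unit
#' Euclidean norm; nodes outside that component get 0), the local
#' clustering coefficient (0 for nodes of degree < 2), and the k-core
#' score (the largest k such that the node belongs to a k-core).
#'
#' @param graph Undirected simple igraph object.
#' @param normalized Report betweenness as the ratio of shortest paths
#'   rather than the raw count (default FALSE).
#' @return Tibble with columns `node`, `degree`, `betweenness`,
#'   `eigenvector`, `clustering`, `kcore`.
#' @export
topology_measures <- function(graph, normalized = FALSE) {
  stopifnot(igraph::vcount(graph) > 0)
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = normalized)
  clus <- igraph::transitivity(graph, type = "localundirected", isolates = "zero")
  core <- igraph::coreness(graph)

  comp <- igraph::components(graph)
  eig <- stats::setNames(numeric(igraph::vcount(graph)),
                         igraph::V(graph)$name)
  main <- which(comp$membership == which.max(comp$csize))
  if (length(main) == 1) {
    eig[main] <- 1
  } else {
    sub <- igraph::induced_subgraph(graph, main)
    # ARPACK uses a random start vector; pin it for reproducibility
    v <- withr::with_seed(20240901L,
                          igraph::eigen_centrality(sub)$vector)
    v <- v / sqrt(sum(v^2))
    eig[igraph::V(sub)$name] <- v
  }

  tibble::tibble(
    node = igraph::V(graph)$name,
    degree = as.numeric(deg),
    betweenness = as.numeric(btw),
    eigenvector = as.numeric(eig[igraph::V(graph)$name]),
    clustering = as.numeric(clus),
    kcore = as.numeric(core)
  )
}

#' Histogram of shortest-path distances between two node sets
#'
#' Finite shortest-path lengths over all unordered pairs (a, b) with a in
#' `set_a`, b in `set_b`, a != b; a pair contained in both sets is counted
#' once.  Unreachable pairs are tallied separately.
#'
#' @param graph Undirected igraph object.
#' @param set_a,set_b Character vectors of node names.
#' @return Tibble with `distance`, `n`; unreachable-pair count in attribute
#'   `n_unreachable`.
#' @export
shortest_path_distribution <- function(graph, set_a, set_b) {
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  nm <- igraph::V(graph)$name
  unknown <- setdiff(c(set_a, set_b), nm)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(utils::head(unknown, 3), collapse = ", "),
         call. = FALSE)
  }
  d <- igraph::distances(graph, v = set_a, to = set_b)
  pairs <- expand.grid(a = set_a, b = set_b, stringsAsFactors = FALSE)
  pairs$dist <- d[cbind(match(pairs$a, set_a), match(pairs$b, set_b))]
  pairs <- pairs[pairs$a != pairs$b, ]
  key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
  pairs <- pairs[!duplicated(key), ]
  finite <- pairs[is.finite(pairs$dist), ]
  out <- finite |>
    dplyr::count(distance = .data$dist, name = "n") |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$distance)
  attr(out, "n_unreachable") <- sum(!is.finite(pairs$dist))
  out
}

#' Induced subnetwork on a node set
#'
#' Extracts the subgraph made of the given nodes and every edge whose two
#' endpoints both belong to the set (e.g. the central interactome: direct
#' interactions between central-proteome proteins).  All vertex attributes
#' are preserved.
#'
#' @param graph igraph object.
#' @param node_set Character vector of node names (must all exist).
#' @return igraph object.
#' @export
extract_subnetwork <- function(graph, node_set) {
  unknown <- setdiff(node_set, igraph::V(graph)$name)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(utils::head(unknown, 3), collapse = ", "),
         call. = FALSE)
  }
  igraph::induced_subgraph(graph, node_set)
}

#' Power-law exponent of a degree distribution
#'
#' Ordinary least squares on log10(frequency) versus log10(degree) of the
#' empirical degree histogram, omitting zero degrees and empty bins — the
#' reporting convention behind exponents read off log-log distribution
#' plots.  A maximum-likelihood alternative (continuous Pareto fit,
#' reported as the negative density exponent) is available via
#' `method = "mle"`.
#'
#' @param degrees Integer vector of node degrees.
#' @param method `"ols"` (default) or `"mle"`.
#' @return Slope (negative for heavy-tailed distributions).
#' @export
powerlaw_exponent <- function(degrees, method = c("ols", "mle")) {
  method <- match.arg(method)
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 3) {
    stop("need at least 3 distinct positive degrees to fit a power law",
         call. = FALSE)
  }
  if (method == "ols") {
    x <- log10(as.numeric(names(tab)))
    y <- log10(as.numeric(tab))
    unname(stats::coef(stats::lm(y ~ x))[2])
  } else {
    xmin <- min(degrees)
    alpha <- 1 + length(degrees) / sum(log(degrees / (xmin - 0.5)))
    -alpha
  }
}

#' Tidy view of a graph's nodes and attributes
#'
#' @param graph igraph object.
#' @return Tibble with `node` plus every vertex attribute (list attributes
#'   such as term sets stay list columns).
#' @export
graph_nodes <- function(graph) {
  attrs <- igraph::vertex_attr(graph)
  nm <- attrs$name %||% as.character(seq_len(igraph::vcount(graph)))
  attrs$name <- NULL
  tibble::tibble(node = nm, !!!attrs)
}

#' Write / read an edge list as TSV
#'
#' @param graph igraph object (undirected).
#' @param path File path.
#' @param directed Read the edge list as directed (default FALSE).
#' @return `read_edge_tsv()` returns an igraph object.
#' @export
write_edge_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  readr::write_tsv(tibble::tibble(from = el[, 1], to = el[, 2]), path)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path, directed = FALSE) {
  el <- readr::read_tsv(path, col_types = readr::cols(
    from = readr::col_character(), to = readr::col_character()))
  igraph::graph_from_data_frame(el, directed = directed)
}

#' Write an annotated graph as GraphML
#'
#' List-valued term annotations are collapsed to `;`-separated strings
#' (GraphML carries scalar attributes only); [read_graphml()] restores the
#' list form.
#'
#' @param graph igraph object with optional `terms` list attribute.
#' @param path File path.
#' @export
write_graphml <- function(graph, path) {
  if (!is.null(igraph::V(graph)$terms)) {
    igraph::V(graph)$terms <- vapply(igraph::V(graph)$terms, paste,
                                     character(1), collapse = ";")
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!is.null(igraph::V(g)$terms)) {
    igraph::V(g)$terms <- strsplit(igraph::V(g)$terms, ";", fixed = TRUE)
  }
  g
}

#' Attach term annotations and membership labels to a graph
#'
#' @param graph igraph object with named vertices.
#' @param annotations Tibble with `node` (or `protein_id`) and `term`; terms
#'   are collected into a per-node set.  Nodes without annotations get an
#'   empty set.
#' @param labels Optional tibble with `node` plus label columns (e.g.
#'   `central`, `n_detected`) copied onto matching vertices.
#' @return The annotated igraph object.
#' @export
annotate_graph <- function(graph, annotations, labels = NULL) {
  nmcol <- if ("node" %in% names(annotations)) "node" else "protein_id"
  sets <- split(annotations$term, annotations[[nmcol]])
  nm <- igraph::V(graph)$name
  igraph::V(graph)$terms <- lapply(nm, function(v) {
    s <- sets[[v]]
    if (is.null(s)) character(0) else sort(unique(s))
  })
  if (!is.null(labels)) {
    i <- match(nm, labels$node)
    for (col in setdiff(names(labels), "node")) {
      igraph::vertex_attr(graph, col) <- labels[[col]][i]
    }
  }
  graph
}
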