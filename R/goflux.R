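#' GO slim vocabulary with is-a parents
#'
#' Light container for a slimmed biological-process vocabulary: the term
#' ids, the is-a parent relation, and optional human-readable names.  The
#' parent relation must be acyclic.
#'
#' @param parents Tibble with columns `term`, `parent` (one row per is-a
#'   edge); terms without parents may be absent from `term`.
#' @param terms Optional character vector of all term ids (defaults to
#'   every id seen in `parents`).
#' @param term_names Optional named character vector of display names.
#' @return A list of class `go_slim` with elements `terms`, `parents`
#'   (named list term -> character vector of parents), `term_names`.
#' @export
go_slim <- function(parents, terms = NULL, term_names = NULL) {
  stopifnot(all(c("term", "parent") %in% names(parents)))
  all_terms <- sort(unique(c(terms, parents$term, parents$parent)))
  if (nrow(parents) > 0) {
    g <- igraph::graph_from_data_frame(parents[, c("term", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) {
      stop("the is-a parent relation contains a cycle", call. = FALSE)
    }
  }
  plist <- split(parents$parent, parents$term)
  structure(list(terms = all_terms, parents = plist, term_names = term_names),
            class = "go_slim")
}

#' Transitive ancestors of a term
#'
#' @param term Single term id.
#' @param slim A [go_slim()].
#' @return Character vector of all (transitive) ancestors, excluding the
#'   term itself.
#' @export
term_ancestors <- function(term, slim) {
  stopifnot(inherits(slim, "go_slim"))
  if (!term %in% slim$terms) {
    stop(sprintf("unknown term '%s'", term), call. = FALSE)
  }
  anc <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    parents <- unique(unlist(slim$parents[frontier], use.names = FALSE))
    parents <- setdiff(parents, anc)
    anc <- c(anc, parents)
    frontier <- parents
  }
  sort(anc)
}

#' Remove ancestors from a term set
#'
#' Drops every term that is a (transitive) ancestor of another term in the
#' same set, leaving the most specific annotation (an antichain).  Applied
#' per protein before flux counting so broad parent terms do not
#' trivially re-create the ontology structure in the flux map.
#'
#' @param term_set Character vector of term ids.
#' @param slim A [go_slim()].
#' @return Pruned character vector.
#' @export
prune_ancestors <- function(term_set, slim) {
  term_set <- unique(term_set)
  if (length(term_set) <= 1) {
    if (length(term_set) == 1) term_ancestors(term_set, slim)  # id validation
    return(term_set)
  }
  anc_union <- unique(unlist(lapply(term_set, term_ancestors, slim = slim),
                             use.names = FALSE))
  sort(setdiff(term_set, anc_union))
}

#' Prune every node's annotation in a graph
#'
#' @param graph igraph with `terms` vertex attribute.
#' @param slim A [go_slim()].
#' @return Graph with pruned `terms`.
#' @export
prune_graph_annotations <- function(graph, slim) {
  igraph::V(graph)$terms <- lapply(igraph::V(graph)$terms, prune_ancestors,
                                   slim = slim)
  graph
}

#' Flux counts between biological-process term pairs
#'
#' For every PPI edge, each unordered pair of terms from the two
#' endpoints' annotation sets is counted (an edge between a protein
#' annotated A, B and one annotated C, D, E contributes one count to each
#' of AC, AD, AE, BC, BD, BE); counts are summed over all edges.  With the
#' default `per_edge = "unique"` an edge contributes at most 1 to any
#' pair (in particular same-term pairs are counted once per edge);
#' `per_edge = "cross"` counts the full cross-product multiplicity.
#' Edges with an unannotated endpoint contribute nothing and are tallied
#' in attribute `n_skipped_edges`.
#'
#' @param graph igraph with `terms` vertex attribute (list of character
#'   vectors); annotations should already be most-specific (see
#'   [prune_graph_annotations()]).
#' @param per_edge `"unique"` or `"cross"`.
#' @return Tibble with `term_i`, `term_j` (term_i <= term_j), `flux`.
#' @export
flux_counts <- function(graph, per_edge = c("unique", "cross")) {
  per_edge <- match.arg(per_edge)
  tl <- igraph::V(graph)$terms
  if (is.null(tl)) stop("graph has no 'terms' vertex attribute", call. = FALSE)
  el <- igraph::as_edgelist(graph, names = FALSE)
  skipped <- 0L
  keys <- vector("list", nrow(el))
  for (e in seq_len(nrow(el))) {
    tu <- tl[[el[e, 1]]]; tv <- tl[[el[e, 2]]]
    if (length(tu) == 0 || length(tv) == 0) {
      skipped <- skipped + 1L
      next
    }
    a <- rep(tu, each = length(tv))
    b <- rep(tv, times = length(tu))
    k <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    keys[[e]] <- if (per_edge == "unique") unique(k) else k
  }
  tab <- table(unlist(keys, use.names = FALSE))
  if (length(tab) == 0) {
    out <- tibble::tibble(term_i = character(0), term_j = character(0),
                          flux = integer(0))
  } else {
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- tibble::tibble(
      term_i = vapply(parts, `[`, character(1), 1),
      term_j = vapply(parts, `[`, character(1), 2),
      flux = as.integer(tab)
    ) |> dplyr::arrange(.data$term_i, .data$term_j)
  }
  attr(out, "n_skipped_edges") <- skipped
  out
}

#' Degree-preserving edge rewiring (double edge swaps)
#'
#' Randomizes an undirected simple graph by repeated double edge swaps
#' ((a,b),(c,d) -> (a,d),(c,b)), accepting only swaps that keep the graph
#' simple, until `n_swaps` swaps have been *accepted*.  Every node keeps
#' its degree exactly; all vertex attributes stay attached to their nodes.
#'
#' @param graph Undirected simple igraph.
#' @param n_swaps Number of accepted swaps (default 10x the edge count).
#' @param max_tries Abort after this many proposals (default 100x
#'   `n_swaps`), signalling a graph too constrained to randomize.
#' @return Rewired igraph.
#' @export
rewire_preserving_degree <- function(graph, n_swaps = 10L * igraph::ecount(graph),
                                     max_tries = 100L * n_swaps) {
  m <- igraph::ecount(graph)
  n <- igraph::vcount(graph)
  if (m < 2 || n_swaps == 0) return(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  adj <- matrix(FALSE, n, n)
  adj[el] <- TRUE
  adj[el[, 2:1]] <- TRUE
  accepted <- 0L
  tries <- 0L
  while (accepted < n_swaps) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "graph too constrained to rewire: %d of %d swaps accepted after %d proposals",
        accepted, n_swaps, tries - 1L), call. = FALSE)
    }
    e <- sample.int(m, 2L)
    a <- el[e[1], 1]; b <- el[e[1], 2]
    c_ <- el[e[2], 1]; d <- el[e[2], 2]
    if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (a == d || c_ == b) next
    if (adj[a, d] || adj[c_, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d] <- adj[d, c_] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c_, b] <- adj[b, c_] <- TRUE
    el[e[1], ] <- c(a, d)
    el[e[2], ] <- c(c_, b)
    accepted <- accepted + 1L
  }
  g2 <- igraph::graph_from_edgelist(el, directed = FALSE)
  # carry over vertex attributes (degrees are preserved per node id)
  missing <- n - igraph::vcount(g2)
  if (missing > 0) g2 <- igraph::add_vertices(g2, missing)
  for (at in igraph::vertex_attr_names(graph)) {
    igraph::vertex_attr(g2, at) <- igraph::vertex_attr(graph, at)
  }
  g2
}

#' Randomized annotated-network ensemble
#'
#' The null model behind flux normalization: each replicate rewires the
#' interaction topology with degree-preserving double edge swaps and
#' permutes the per-node term *sets* uniformly across nodes.  Node degrees
#' and GO term frequencies are each preserved exactly, but decoupled from
#' one another; membership labels (central, detection counts) stay on
#' their nodes, whose degrees are unchanged, so the label-degree structure
#' matches the original data.
#'
#' @param graph igraph with `terms` vertex attribute.
#' @param n_networks Ensemble size (default 100).
#' @param n_swaps Accepted swaps per replicate (default 10x edges).
#' @return List of igraph objects.
#' @export
randomize_annotated <- function(graph, n_networks = 100L,
                                n_swaps = 10L * igraph::ecount(graph)) {
  lapply(seq_len(n_networks), function(i) {
    g2 <- rewire_preserving_degree(graph, n_swaps = n_swaps)
    perm <- sample.int(igraph::vcount(g2))
    igraph::V(g2)$terms <- igraph::V(g2)$terms[perm]
    g2
  })
}

#' Normalized flux scores against a null ensemble
#'
#' Splits the ensemble into a fitting part (first `fit_fraction`,
#' default 90%) used to estimate each pair's null mean and standard
#' deviation, and a held-out part whose standardized fluxes pool into the
#' empirical null distribution of NScores.  For each pair,
#' NScore = (flux - mean_random) / sd_random; pairs whose observed NScore
#' exceeds the null distribution's (1 - alpha) quantile are significant.
#' Pairs with zero null standard deviation are excluded and reported.
#'
#' @param observed Flux tibble from [flux_counts()].
#' @param ensemble List of igraph objects (from [randomize_annotated()]) or
#'   of flux tibbles.
#' @param alpha Significance level (default 0.01).
#' @param fit_fraction Fraction of replicates used for null moments.
#' @param cutoff_method `"empirical"` (held-out quantile, default) or
#'   `"gaussian"` (normal fit to the held-out NScores).
#' @param per_edge Pair counting mode, see [flux_counts()].
#' @return A `flux_result`: tibble with `term_i`, `term_j`, `flux`,
#'   `mean_random`, `sd_random`, `nscore`, `significant`; attributes
#'   `cutoff`, `alpha`, `n_fit`, `n_heldout`, `excluded_pairs`.
#' @export
nscore_fluxes <- function(observed, ensemble, alpha = 0.01,
                          fit_fraction = 0.9,
                          cutoff_method = c("empirical", "gaussian"),
                          per_edge = "unique") {
  cutoff_method <- match.arg(cutoff_method)
  r <- length(ensemble)
  stopifnot(r >= 12)
  fluxes <- lapply(ensemble, function(x) {
    if (igraph::is_igraph(x)) flux_counts(x, per_edge = per_edge) else x
  })
  pair_key <- function(tbl) paste(tbl$term_i, tbl$term_j, sep = "\r")
  keys <- sort(unique(c(pair_key(observed),
                        unlist(lapply(fluxes, pair_key), use.names = FALSE))))
  mat <- matrix(0, nrow = length(keys), ncol = r,
                dimnames = list(keys, NULL))
  for (i in seq_len(r)) {
    mat[pair_key(fluxes[[i]]), i] <- fluxes[[i]]$flux
  }
  obs <- stats::setNames(numeric(length(keys)), keys)
  obs[pair_key(observed)] <- observed$flux

  n_fit <- min(max(1L, floor(fit_fraction * r)), r - 1L)
  fit <- mat[, seq_len(n_fit), drop = FALSE]
  held <- mat[, seq(n_fit + 1L, r), drop = FALSE]
  mu <- rowMeans(fit)
  sdv <- apply(fit, 1, stats::sd)

  usable <- sdv > 0
  null_ns <- (held[usable, , drop = FALSE] - mu[usable]) / sdv[usable]
  cutoff <- if (cutoff_method == "empirical") {
    stats::quantile(null_ns, 1 - alpha, names = FALSE)
  } else {
    mean(null_ns) + stats::qnorm(1 - alpha) * stats::sd(null_ns)
  }

  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- tibble::tibble(
    term_i = vapply(parts, `[`, character(1), 1),
    term_j = vapply(parts, `[`, character(1), 2),
    flux = unname(obs),
    mean_random = unname(mu),
    sd_random = unname(sdv),
    nscore = unname(ifelse(usable, (obs - mu) / sdv, NA_real_)),
    significant = FALSE
  )
  out$significant <- usable & !is.na(out$nscore) & out$nscore > cutoff
  excluded <- out[!usable, c("term_i", "term_j")]
  structure(out, cutoff = cutoff, alpha = alpha, n_fit = n_fit,
            n_heldout = r - n_fit, excluded_pairs = excluded,
            class = c("flux_result", class(out)))
}

#' Full flux analysis on one annotated graph
#'
#' Prunes annotations to their most specific terms, counts observed
#' fluxes, builds the randomized ensemble and scores NScores.
#'
#' @param graph igraph with `terms` vertex attribute.
#' @param slim Optional [go_slim()] for ancestor pruning.
#' @param n_networks Ensemble size.
#' @param alpha Significance level.
#' @param per_edge Pair counting mode.
#' @return A `flux_result` (see [nscore_fluxes()]).
#' @export
go_flux <- function(graph, slim = NULL, n_networks = 100L, alpha = 0.01,
                    per_edge = "unique") {
  if (!is.null(slim)) graph <- prune_graph_annotations(graph, slim)
  observed <- flux_counts(graph, per_edge = per_edge)
  ensemble <- randomize_annotated(graph, n_networks = n_networks)
  nscore_fluxes(observed, ensemble, alpha = alpha, per_edge = per_edge)
}

#' Flux analysis in three network regimes
#'
#' Partitions the edges of an interactome into (i) both endpoints in the
#' central set, (ii) exactly one endpoint central with the other detected
#' in at most `max_lines` cell lines, (iii) neither endpoint central, and
#' runs the full flux analysis with its own null ensemble on each regime.
#'
#' @param graph igraph with `terms`, `central` (logical) and `n_detected`
#'   vertex attributes.
#' @param slim Optional [go_slim()].
#' @param n_networks Ensemble size per regime.
#' @param alpha Significance level.
#' @param max_lines Detection-count ceiling for the cross regime's
#'   non-central endpoint (default 5).
#' @return Named list of `flux_result` objects
#'   (`within_central`, `central_to_outside`, `outside`); empty regimes
#'   yield NULL with a warning.
#' @export
flux_regimes <- function(graph, slim = NULL, n_networks = 100L, alpha = 0.01,
                         max_lines = 5L) {
  central <- igraph::V(graph)$central
  nd <- igraph::V(graph)$n_detected
  stopifnot(!is.null(central), !is.null(nd))
  el <- igraph::as_edgelist(graph, names = FALSE)
  u <- el[, 1]; v <- el[, 2]
  regime <- dplyr::case_when(
    central[u] & central[v] ~ "within_central",
    xor(central[u], central[v]) &
      ifelse(central[u], nd[v], nd[u]) <= max_lines ~ "central_to_outside",
    !central[u] & !central[v] ~ "outside",
    TRUE ~ "other"
  )
  run_one <- function(nm) {
    ix <- which(regime == nm)
    if (length(ix) == 0) {
      warning(sprintf("regime '%s' has no edges", nm), call. = FALSE)
      return(NULL)
    }
    sub <- igraph::subgraph_from_edges(graph, ix, delete.vertices = TRUE)
    go_flux(sub, slim = slim, n_networks = n_networks, alpha = alpha)
  }
  list(
    within_central = run_one("within_central"),
    central_to_outside = run_one("central_to_outside"),
    outside = run_one("outside")
  )
}

#' Expected number of significant pairs under the null
#'
#' Pure arithmetic of the calibration: at significance level `alpha`, the
#' expected number of significant term pairs in a null network equals
#' `alpha` times the number of evaluated pairs.  With self-pairs included,
#' `n_terms` terms give n(n+1)/2 pairs; without, n(n-1)/2.
#'
#' @param n_terms Vocabulary size (used when `n_pairs` is missing).
#' @param alpha Significance level.
#' @param include_self Count same-term pairs (default TRUE).
#' @param n_pairs Directly specified pair-universe size.
#' @return Expected count (numeric).
#' @export
expected_significant_pairs <- function(n_terms = NULL, alpha = 0.01,
                                       include_self = TRUE, n_pairs = NULL) {
  if (is.null(n_pairs)) {
    stopifnot(!is.null(n_terms))
    n_pairs <- if (include_self) n_terms * (n_terms + 1) / 2
               else n_terms * (n_terms - 1) / 2
  }
  alpha * n_pairs
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf(
    "<flux_result> %d pairs, %d significant at alpha = %g (NScore cutoff %.3f)\n",
    nrow(x), sum(x$significant), attr(x, "alpha"), attr(x, "cutoff")))
  NextMethod()
}
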