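#' Generate a scale-free annotated interactome with a planted flux pair
#'
#' Grows an undirected simple graph by preferential attachment (heavy-tailed
#' degree distribution), annotates every node with 1--4 biological-process
#' terms drawn from a skewed frequency vector, and optionally plants an
#' enriched flux between one pair of terms by adding edges between nodes
#' carrying the two terms until the pair's count reaches
#' `flux_multiplier` times its unplanted count.  Nodes are labelled as
#' central-proteome members with probability proportional to
#' `(degree + 1)^central_attachment`, so the central set has elevated
#' connectivity; central nodes get `n_detected = n_cell_lines`, others a
#' random smaller count.
#'
#' @param config A [sim_config()].
#' @return List with
#'   * `graph`: igraph object with vertex attributes `name`, `terms`
#'     (list of character vectors), `central` (logical), `n_detected`;
#'   * `ground_truth`: list with `planted_flux_pair`, `flux_multiplier`,
#'     `base_flux` (the pair's count before planting) and `central_nodes`.
#' @export
sim_annotated_interactome <- function(config) {
  stopifnot(inherits(config, "sim_config"),
            config$n_nodes >= config$n_bp_terms,
            config$flux_multiplier >= 1)
  withr::with_seed(config$seed + 33L, {
    g <- igraph::sample_pa(config$n_nodes, power = 1, m = config$pa_m,
                           directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("N%05d", seq_len(config$n_nodes))

    terms <- bp_term_ids(config$n_bp_terms)
    w <- 1 / seq_along(terms)^0.8
    tr <- config$terms_per_node
    k <- sample(seq(tr[1], tr[2]), config$n_nodes, replace = TRUE)
    k <- pmin(k, length(terms))
    igraph::V(g)$terms <- lapply(k, function(ki) sort(sample(terms, ki, prob = w)))

    pair <- config$planted_flux_pair
    stopifnot(all(pair %in% terms))
    base_flux <- pair_flux(g, pair)
    target <- round(config$flux_multiplier * base_flux)
    if (target > base_flux) {
      tl <- igraph::V(g)$terms
      has1 <- which(vapply(tl, function(t) pair[1] %in% t, logical(1)))
      has2 <- which(vapply(tl, function(t) pair[2] %in% t, logical(1)))
      # prefer endpoints annotated with the planted term only, so the
      # added edges raise no other pair's flux
      pure <- lengths(tl) == 1L
      cand <- expand.grid(u = has1, v = has2)
      cand <- cand[cand$u != cand$v, ]
      key <- paste(pmin(cand$u, cand$v), pmax(cand$u, cand$v))
      cand <- cand[!duplicated(key), ]
      existing <- igraph::as_edgelist(g, names = FALSE)
      ekey <- paste(pmin(existing[, 1], existing[, 2]),
                    pmax(existing[, 1], existing[, 2]))
      cand <- cand[!paste(pmin(cand$u, cand$v), pmax(cand$u, cand$v)) %in% ekey, ]
      cand <- cand[order(!(pure[cand$u] & pure[cand$v])), ]
      need <- target - base_flux
      if (nrow(cand) < need) {
        stop(sprintf(
          "cannot plant flux: need %d extra edges but only %d simple-graph slots remain",
          need, nrow(cand)), call. = FALSE)
      }
      n_pure <- sum(pure[cand$u] & pure[cand$v])
      pick <- if (need <= n_pure) {
        cand[sample.int(n_pure, need), ]
      } else {
        cand[c(seq_len(n_pure),
               n_pure + sample.int(nrow(cand) - n_pure, need - n_pure)), ]
      }
      g <- igraph::add_edges(g, rbind(pick$u, pick$v))
    }

    deg <- igraph::degree(g)
    n_central <- round(config$frac_central_nodes * config$n_nodes)
    central_ix <- sample(seq_len(config$n_nodes), n_central,
                         prob = (deg + 1)^config$central_attachment)
    central <- seq_len(config$n_nodes) %in% central_ix
    igraph::V(g)$central <- central
    nd <- integer(config$n_nodes)
    nd[central] <- config$n_cell_lines
    if (config$n_cell_lines > 1) {
      nd[!central] <- sample.int(config$n_cell_lines - 1L, sum(!central),
                                 replace = TRUE)
    } else {
      nd[!central] <- 1L
    }
    igraph::V(g)$n_detected <- nd

    list(
      graph = g,
      ground_truth = list(
        planted_flux_pair = pair,
        flux_multiplier = config$flux_multiplier,
        base_flux = base_flux,
        central_nodes = igraph::V(g)$name[central]
      )
    )
  })
}

# count of one unordered term pair over all edges (each edge contributes at
# most 1, consistent with flux_counts(per_edge = "unique"))
pair_flux <- function(g, pair) {
  el <- igraph::as_edgelist(g, names = FALSE)
  tl <- igraph::V(g)$terms
  if (nrow(el) == 0) return(0L)
  a1 <- vapply(tl, function(t) pair[1] %in% t, logical(1))
  a2 <- vapply(tl, function(t) pair[2] %in% t, logical(1))
  if (pair[1] == pair[2]) {
    sum(a1[el[, 1]] & a1[el[, 2]])
  } else {
    sum((a1[el[, 1]] & a2[el[, 2]]) | (a2[el[, 1]] & a1[el[, 2]]))
  }
}

#' Generate source-to-sink pathway DAGs
#'
#' For each requested size builds a connected directed acyclic graph: a
#' random in-tree rooted at node 1 (the source) plus extra forward edges,
#' so every node lies on a path from a source (in-degree 0) to an end
#' (out-degree 0).  Size 2 gives a single edge.  Nodes are assigned 1--2
#' proteins from a deliberately small pool so proteins repeat across
#' pathways (as real proteins do).
#'
#' @param config A [sim_config()].
#' @return List with `edges` (tibble `pathway_id`, `from`, `to`) and
#'   `assignments` (tibble `pathway_id`, `node`, `protein_id`).
#' @export
sim_pathways <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$pathway_sizes < 2)) {
    stop("every pathway size must be >= 2", call. = FALSE)
  }
  withr::with_seed(config$seed + 44L, {
    edges <- purrr::imap(config$pathway_sizes, function(s, i) {
      pid <- sprintf("PW%02d", i)
      node <- function(j) sprintf("%s_n%02d", pid, j)
      from <- vapply(2:s, function(j) sample.int(j - 1L, 1L), integer(1))
      e <- tibble::tibble(pathway_id = pid, from = node(from), to = node(2:s))
      n_extra <- max(0L, round(0.3 * s) - 1L)
      if (n_extra > 0 && s >= 3) {
        for (x in seq_len(n_extra)) {
          j <- sample(3:s, 1L)
          i2 <- sample.int(j - 1L, 1L)
          e <- dplyr::bind_rows(e, tibble::tibble(
            pathway_id = pid, from = node(i2), to = node(j)))
        }
      }
      dplyr::distinct(e)
    }) |> dplyr::bind_rows()

    nodes <- dplyr::bind_rows(
      edges |> dplyr::transmute(pathway_id = .data$pathway_id, node = .data$from),
      edges |> dplyr::transmute(pathway_id = .data$pathway_id, node = .data$to)
    ) |> dplyr::distinct()
    pool_size <- max(2L, min(config$n_proteins, ceiling(nrow(nodes) / 2)))
    pool <- sprintf("P%05d", sample.int(max(config$n_proteins, pool_size), pool_size))
    k <- sample(1:2, nrow(nodes), replace = TRUE)
    assignments <- tibble::tibble(
      pathway_id = rep(nodes$pathway_id, k),
      node = rep(nodes$node, k),
      protein_id = sample(pool, sum(k), replace = TRUE)
    ) |> dplyr::distinct()

    list(edges = edges, assignments = assignments)
  })
}
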