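# Brute-force oracles, independent of the package's implementation paths.

# exhaustive tryptic digest: enumerate every substring and keep those whose
# boundaries are valid cleavage points with at most `mc` internal sites
oracle_digest <- function(sequence, mc = 1L, min_length = 6L) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n == 0) return(character(0))
  is_site <- function(i) {
    # cleavage after position i
    i >= 1 && i < n && aa[i] %in% c("K", "R") && aa[i + 1] != "P"
  }
  peps <- character(0)
  for (s in 1:n) {
    for (e in s:n) {
      if (e - s + 1 < min_length) next
      ok_start <- s == 1 || is_site(s - 1)
      ok_end <- e == n || is_site(e)
      if (!ok_start || !ok_end) next
      internal <- sum(vapply(s:(e - 1), is_site, logical(1)))
      if (e == s) internal <- 0
      if (internal > mc) next
      peps <- c(peps, paste(aa[s:e], collapse = ""))
    }
  }
  unique(peps)
}

oracle_peptide_mass <- function(pep) {
  masses <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  sum(masses[strsplit(pep, "")[[1]]]) + 18.010565
}

# random simple undirected graph as a 0/1 adjacency matrix
oracle_random_graph <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- stats::rbinom(length(upper), 1, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(as.character(1:n), as.character(1:n))
  adj
}

# all-pairs shortest-path distances by BFS on the adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in 1:n) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

# number of shortest paths between every pair, by dynamic programming over
# nodes in order of distance from the source
oracle_path_counts <- function(adj, d, s) {
  n <- nrow(adj)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(d[s, ])
  for (v in ord) {
    if (v == s || !is.finite(d[s, v])) next
    pred <- which(adj[v, ] > 0 & d[s, ] == d[s, v] - 1)
    sigma[v] <- sum(sigma[pred])
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sig <- lapply(1:n, function(s) oracle_path_counts(adj, d, s))
  btw <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      for (v in 1:n) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sig[[s]][v] * sig[[t]][v] / sig[[s]][t]
        }
      }
    }
  }
  btw
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(1:n, function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_kcore <- function(adj) {
  n <- nrow(adj)
  core <- rep(NA_integer_, n)
  active <- rep(TRUE, n)
  k <- 0L
  while (any(active)) {
    repeat {
      degs <- rowSums(adj[, active, drop = FALSE])
      victims <- which(active & degs <= k)
      if (length(victims) == 0) break
      core[victims] <- k
      active[victims] <- FALSE
      if (!any(active)) break
    }
    k <- k + 1L
  }
  core
}

oracle_eigenvector <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  comp_of <- integer(n)
  cid <- 0L
  for (v in 1:n) {
    if (comp_of[v] == 0) {
      cid <- cid + 1L
      comp_of[is.finite(d[v, ])] <- cid
    }
  }
  sizes <- tabulate(comp_of)
  main <- which(comp_of == which.max(sizes))
  out <- numeric(n)
  if (length(main) == 1) {
    out[main] <- 1
  } else {
    ev <- eigen(adj[main, main, drop = FALSE], symmetric = TRUE)
    v1 <- abs(ev$vectors[, 1])
    out[main] <- v1 / sqrt(sum(v1^2))
  }
  out
}

# unique largest component? (eigenvector comparison only defined then)
oracle_unique_largest_component <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  comp_of <- integer(n)
  cid <- 0L
  for (v in 1:n) {
    if (comp_of[v] == 0) {
      cid <- cid + 1L
      comp_of[is.finite(d[v, ])] <- cid
    }
  }
  sizes <- tabulate(comp_of)
  sum(sizes == max(sizes)) == 1
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# transitive-closure ancestor oracle for a parent table
oracle_ancestors <- function(term, parents_tbl) {
  anc <- character(0)
  frontier <- term
  repeat {
    p <- unique(parents_tbl$parent[parents_tbl$term %in% frontier])
    p <- setdiff(p, anc)
    if (length(p) == 0) break
    anc <- c(anc, p)
    frontier <- p
  }
  sort(anc)
}
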