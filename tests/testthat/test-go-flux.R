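toy_slim <- function() {
  # root -> {meta, signal}; meta -> {lipid, nucleo}; signal -> kinase
  go_slim(tibble::tibble(
    term = c("meta", "signal", "lipid", "nucleo", "kinase"),
    parent = c("root", "root", "meta", "meta", "signal")
  ))
}

test_that("ancestor pruning leaves the most specific antichain", {
  slim <- toy_slim()
  expect_equal(prune_ancestors("lipid", slim), "lipid")
  expect_setequal(prune_ancestors(c("lipid", "meta"), slim), "lipid")
  expect_setequal(prune_ancestors(c("lipid", "nucleo", "root"), slim),
                  c("lipid", "nucleo"))
  expect_error(prune_ancestors("unheard_of", slim), "unknown term")
  expect_error(go_slim(tibble::tibble(term = c("a", "b"), parent = c("b", "a"))),
               "cycle")
})

test_that("pruning equals the transitive-closure oracle on random DAG sets", {
  withr::with_seed(61, {
    n_terms <- 12
    terms <- sprintf("T%02d", 1:n_terms)
    # random DAG: each term may point to lower-indexed parents
    parents <- dplyr::bind_rows(lapply(2:n_terms, function(i) {
      k <- sample(0:min(2, i - 1), 1)
      if (k == 0) return(NULL)
      tibble::tibble(term = terms[i],
                     parent = sample(terms[seq_len(i - 1)], k))
    }))
    slim <- go_slim(parents, terms = terms)
    for (rep in 1:20) {
      s <- sample(terms, sample(2:6, 1))
      anc <- unique(unlist(lapply(s, oracle_ancestors, parents_tbl = parents)))
      expect_setequal(prune_ancestors(s, slim), setdiff(s, anc))
    }
  })
})

test_that("an edge P1{A,B} - P2{C,D,E} yields the six unit pair counts", {
  g <- igraph::make_graph(~ P1 - P2)
  igraph::V(g)$terms <- list(c("A", "B"), c("C", "D", "E"))
  f <- flux_counts(g)
  expect_equal(nrow(f), 6)
  expect_setequal(paste(f$term_i, f$term_j),
                  c("A C", "A D", "A E", "B C", "B D", "B E"))
  expect_true(all(f$flux == 1))
})

test_that("same-term pairs count once per edge; counts add over edges", {
  g <- igraph::make_graph(~ P1 - P2)
  igraph::V(g)$terms <- list("A", "A")
  f <- flux_counts(g)
  expect_equal(f$flux[f$term_i == "A" & f$term_j == "A"], 1L)

  g2 <- igraph::make_graph(~ P1 - P2, P3 - P4)
  igraph::V(g2)$terms <- list(c("A", "B"), "C", c("A", "B"), "C")
  f2 <- flux_counts(g2)
  expect_true(all(f2$flux == 2))

  # cross-product multiplicity mode counts mirrored pairs twice
  g3 <- igraph::make_graph(~ P1 - P2)
  igraph::V(g3)$terms <- list(c("A", "B"), c("A", "B"))
  expect_equal(sum(flux_counts(g3)$flux), 3)            # AA, AB, BB once each
  expect_equal(sum(flux_counts(g3, per_edge = "cross")$flux), 4)

  # unannotated endpoints contribute nothing but are tallied
  g4 <- igraph::make_graph(~ P1 - P2)
  igraph::V(g4)$terms <- list(character(0), "A")
  f4 <- flux_counts(g4)
  expect_equal(nrow(f4), 0)
  expect_equal(attr(f4, "n_skipped_edges"), 1L)
})

test_that("flux counting is invariant to edge order, endpoint order and isolated nodes", {
  withr::with_seed(71, {
    adj <- oracle_random_graph(15, 0.3)
    g <- adj_to_igraph(adj)
    igraph::V(g)$terms <- replicate(15, sample(LETTERS[1:5], sample(1:3, 1)),
                                    simplify = FALSE)
    ref <- flux_counts(g)
    el <- igraph::as_edgelist(g)
    perm <- el[sample.int(nrow(el)), 2:1]
    g2 <- igraph::graph_from_edgelist(perm, directed = FALSE)
    igraph::V(g2)$terms <-
      igraph::V(g)$terms[match(igraph::V(g2)$name, igraph::V(g)$name)]
    expect_equal(flux_counts(g2), ref, ignore_attr = TRUE)

    g3 <- igraph::add_vertices(g, 3, terms = list("A", "B", "C"))
    expect_equal(flux_counts(g3), ref, ignore_attr = TRUE)
  })
})

test_that("randomization preserves per-node degrees and term frequencies, decoupled", {
  withr::with_seed(81, {
    cfg <- sim_config(seed = 26, n_nodes = 200, n_bp_terms = 8)
    g <- sim_annotated_interactome(cfg)$graph
    # plant a degree <-> set-size correlation so decoupling is observable
    deg <- igraph::degree(g)
    sizes <- 1L + findInterval(rank(deg, ties.method = "first"),
                               c(50, 100, 150))
    terms <- bp <- sprintf("BP%03d", 1:8)
    igraph::V(g)$terms <- lapply(sizes, function(k) sample(bp, k))
    expect_gt(cor(deg, lengths(igraph::V(g)$terms), method = "spearman"), 0.5)

    reps <- randomize_annotated(g, n_networks = 50)
    for (r in reps[1:5]) {
      expect_identical(igraph::degree(r), igraph::degree(g))
      expect_identical(sort(table(unlist(igraph::V(r)$terms))),
                       sort(table(unlist(igraph::V(g)$terms))))
      expect_true(igraph::is_simple(r))
    }
    cors <- vapply(reps, function(r) {
      cor(igraph::degree(r), lengths(igraph::V(r)$terms), method = "spearman")
    }, numeric(1))
    expect_lt(abs(mean(cors)), 3 * stats::sd(cors) / sqrt(length(cors)))
  })
})

test_that("rewiring refuses graphs too constrained to swap", {
  star <- igraph::make_star(4, mode = "undirected")
  expect_error(rewire_preserving_degree(star, n_swaps = 5, max_tries = 200),
               "too constrained")
})

test_that("NScore standardizes against the fitted null moments", {
  pair_tbl <- function(flux) tibble::tibble(term_i = "A", term_j = "B",
                                            flux = flux)
  # 18 fit replicates with sd > 0, 2 held out
  ens <- c(lapply(rep(c(9, 11), 9), pair_tbl), lapply(c(10, 12), pair_tbl))
  res0 <- nscore_fluxes(pair_tbl(10), ens)          # flux == mean -> 0
  expect_equal(res0$nscore, 0)
  sdv <- stats::sd(rep(c(9, 11), 9))
  res2 <- nscore_fluxes(pair_tbl(10 + 2 * sdv), ens)
  expect_equal(res2$nscore, 2)

  # zero-variance pairs are excluded and reported
  ens_const <- c(lapply(rep(10, 18), pair_tbl), lapply(c(10, 10), pair_tbl))
  resc <- nscore_fluxes(pair_tbl(15), ens_const)
  expect_true(is.na(resc$nscore))
  expect_equal(nrow(attr(resc, "excluded_pairs")), 1)
})

test_that("a planted flux pair at multiplier 3 is recovered with few false pairs", {
  cfg <- sim_config(seed = 7, n_nodes = 600, n_bp_terms = 15,
                    flux_multiplier = 3)
  net <- sim_annotated_interactome(cfg)
  res <- withr::with_seed(11, go_flux(net$graph, n_networks = 40))
  pair <- sort(net$ground_truth$planted_flux_pair)
  tbl <- tibble::as_tibble(res)
  planted <- tbl[tbl$term_i == pair[1] & tbl$term_j == pair[2], ]
  expect_true(planted$significant)
  others <- tbl[!(tbl$term_i == pair[1] & tbl$term_j == pair[2]), ]
  fp <- mean(others$significant, na.rm = TRUE)
  expect_lt(fp, 0.01 + 3 * sqrt(0.01 * 0.99 / nrow(others)))
})

test_that("regimes partition edges and degenerate splits warn", {
  cfg <- sim_config(seed = 28, n_nodes = 250, n_bp_terms = 8)
  g <- sim_annotated_interactome(cfg)$graph
  central <- igraph::V(g)$central
  nd <- igraph::V(g)$n_detected
  el <- igraph::as_edgelist(g, names = FALSE)
  in_i <- central[el[, 1]] & central[el[, 2]]
  in_iii <- !central[el[, 1]] & !central[el[, 2]]
  one <- xor(central[el[, 1]], central[el[, 2]])
  in_ii <- one & ifelse(central[el[, 1]], nd[el[, 2]], nd[el[, 1]]) <= 5
  expect_true(all(in_i + in_ii + in_iii <= 1))       # pairwise disjoint
  expect_lte(sum(in_i) + sum(in_ii) + sum(in_iii), nrow(el))

  res <- suppressWarnings(withr::with_seed(17, flux_regimes(g, n_networks = 15)))
  expect_named(res, c("within_central", "central_to_outside", "outside"))
  expect_s3_class(res$within_central, "flux_result")

  g_all <- g
  igraph::V(g_all)$central <- TRUE
  w <- testthat::capture_warnings(
    res_all <- withr::with_seed(17, flux_regimes(g_all, n_networks = 15)))
  expect_true(any(grepl("no edges", w)))
  expect_null(res_all$central_to_outside)
  expect_null(res_all$outside)
})

test_that("the null expectation is the significance level times the pair universe", {
  expect_equal(expected_significant_pairs(n_terms = 50, alpha = 0.01), 12.75)
  expect_equal(expected_significant_pairs(n_pairs = 1275, alpha = 0.01), 12.75)
  expect_equal(expected_significant_pairs(n_terms = 50, include_self = FALSE),
               12.25)
})
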