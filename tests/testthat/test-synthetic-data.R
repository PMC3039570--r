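test_that("one seed determines every generated artifact exactly", {
  cfg <- sim_config(seed = 9, n_proteins = 60, n_nodes = 80, n_bp_terms = 6,
                    pathway_sizes = c(4, 7))
  p1 <- sim_proteome(cfg); p2 <- sim_proteome(cfg)
  expect_identical(p1, p2)
  t1 <- sim_psm_tables(p1, cfg); t2 <- sim_psm_tables(p2, cfg)
  expect_identical(t1, t2)
  n1 <- sim_annotated_interactome(cfg); n2 <- sim_annotated_interactome(cfg)
  expect_identical(igraph::as_edgelist(n1$graph), igraph::as_edgelist(n2$graph))
  expect_identical(igraph::V(n1$graph)$terms, igraph::V(n2$graph)$terms)
  w1 <- sim_pathways(cfg); w2 <- sim_pathways(cfg)
  expect_identical(w1, w2)
})

test_that("generated proteins digest into >= 1 peptide of length >= 6", {
  cfg <- sim_config(seed = 1, n_proteins = 1)
  p <- sim_proteome(cfg)
  peps <- tryptic_peptides(p$sequence)
  expect_gte(length(peps), 1)
  expect_true(all(nchar(peps) >= 6))
  expect_error(sim_proteome(sim_config(n_proteins = 0)), "empty")
})

test_that("proteome has the requested number of uniquely identified records", {
  p <- sim_proteome(sim_config(seed = 7, n_proteins = 100))
  expect_equal(nrow(p), 100)
  expect_equal(length(unique(p$protein_id)), 100)
  # isoform partners share their base protein's gene and peptides
  iso <- p |> dplyr::count(gene_id) |> dplyr::filter(n > 1)
  expect_gt(nrow(iso), 0)
  pair <- p[p$gene_id == iso$gene_id[1], ]
  expect_true(all(tryptic_peptides(pair$sequence[1]) %in%
                  tryptic_peptides(pair$sequence[2])))
})

test_that("common-set planting and incorrect-match fractions behave as configured", {
  cfg <- sim_config(seed = 4, n_proteins = 40, frac_common = 1,
                    isoform_rate = 0)
  p <- sim_proteome(cfg)
  tabs <- sim_psm_tables(p, cfg)
  lines_per_protein <- tabs$psm |>
    dplyr::filter(!.data$is_decoy) |>
    dplyr::mutate(protein_id = sub(";.*", "", .data$protein_ids)) |>
    dplyr::distinct(.data$protein_id, .data$cell_line) |>
    dplyr::count(.data$protein_id)
  expect_true(all(lines_per_protein$n == cfg$n_cell_lines))
  expect_setequal(tabs$ground_truth$common_set, p$protein_id)

  cfg0 <- sim_config(seed = 4, n_proteins = 40, decoy_rate = 0,
                     false_target_rate = 0)
  tabs0 <- sim_psm_tables(sim_proteome(cfg0), cfg0)
  expect_false(any(tabs0$psm$is_decoy))
  expect_true(all(tabs0$ground_truth$psm_truth$truth == "true"))

  # ground truth covers every generated PSM
  expect_true(all(tabs$psm$spectrum_id %in%
                  tabs$ground_truth$psm_truth$spectrum_id))
})

test_that("observed conflict fraction tracks conflict_rate", {
  cfg <- sim_config(seed = 12, n_proteins = 300, conflict_rate = 0.1,
                    both_engine_prob = 1)
  tabs <- sim_psm_tables(sim_proteome(cfg), cfg)
  wide <- tabs$psm |>
    dplyr::select("spectrum_id", "engine", "peptide") |>
    tidyr::pivot_wider(names_from = "engine", values_from = "peptide")
  both <- wide[!is.na(wide$A) & !is.na(wide$B), ]
  frac <- mean(both$A != both$B)
  se <- sqrt(0.1 * 0.9 / nrow(both))
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("interactome is simple, heavy-tailed, with degree-biased central set", {
  cfg <- sim_config(seed = 5, n_nodes = 400, n_bp_terms = 8)
  net <- sim_annotated_interactome(cfg)
  g <- net$graph
  expect_true(igraph::is_simple(g))
  expect_equal(igraph::vcount(g), 400)
  expect_true(all(lengths(igraph::V(g)$terms) >= 1))
  deg <- igraph::degree(g)
  central <- igraph::V(g)$central
  expect_gt(mean(deg[central]), mean(deg[!central]))
  expect_true(all(igraph::V(g)$n_detected[central] == cfg$n_cell_lines))
})

test_that("5000-node preferential-attachment degree slope is steeper than -1", {
  cfg <- sim_config(seed = 2, n_nodes = 5000, pa_m = 2)
  net <- sim_annotated_interactome(cfg)
  slope <- powerlaw_exponent(igraph::degree(net$graph))
  expect_lt(slope, -1)
})

test_that("unplanted pair flux sits within 3 sd of its randomized-ensemble null", {
  cfg <- sim_config(seed = 6, n_nodes = 300, n_bp_terms = 8,
                    flux_multiplier = 1)
  net <- sim_annotated_interactome(cfg)
  g <- net$graph
  pair <- sort(net$ground_truth$planted_flux_pair)
  obs <- flux_counts(g)
  obs_val <- obs$flux[obs$term_i == pair[1] & obs$term_j == pair[2]]
  null_vals <- withr::with_seed(31, {
    vapply(randomize_annotated(g, n_networks = 25), function(r) {
      f <- flux_counts(r)
      v <- f$flux[f$term_i == pair[1] & f$term_j == pair[2]]
      if (length(v) == 0) 0 else v
    }, numeric(1))
  })
  expect_lt(abs(obs_val - mean(null_vals)), 3 * stats::sd(null_vals))
})

test_that("pathway generation yields connected DAGs with sources and ends", {
  cfg <- sim_config(seed = 3, pathway_sizes = c(2, 5, 9, 14))
  pw <- sim_pathways(cfg)
  for (pid in unique(pw$edges$pathway_id)) {
    e <- pw$edges[pw$edges$pathway_id == pid, ]
    g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE)
    expect_true(igraph::is_dag(g))
    expect_true(igraph::is_connected(g, mode = "weak"))
    expect_gte(sum(igraph::degree(g, mode = "in") == 0), 1)
    expect_gte(sum(igraph::degree(g, mode = "out") == 0), 1)
  }
  e2 <- pw$edges[pw$edges$pathway_id == "PW01", ]
  expect_equal(nrow(e2), 1)  # size 2: single edge
  expect_error(sim_pathways(sim_config(pathway_sizes = 1)), ">= 2")
  # assignments reference existing nodes and repeat proteins across pathways
  nodes <- unique(c(pw$edges$from, pw$edges$to))
  expect_true(all(pw$assignments$node %in% nodes))
  reps <- pw$assignments |>
    dplyr::distinct(.data$pathway_id, .data$protein_id) |>
    dplyr::count(.data$protein_id)
  expect_gt(max(reps$n), 1)
})

test_that("generated tables round-trip through their readers", {
  cfg <- sim_config(seed = 8, n_proteins = 30, n_nodes = 40)
  p <- sim_proteome(cfg)
  tabs <- sim_psm_tables(p, cfg)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_psm_tsv(tabs$psm, tmp)
  back <- read_psm_tsv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tabs$psm))

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(p, fa)
  pb <- read_proteome_fasta(fa)
  expect_equal(pb$protein_id, p$protein_id)
  expect_equal(pb$sequence, p$sequence)
  expect_equal(pb$gene_id, p$gene_id)

  net <- sim_annotated_interactome(cfg)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net$graph, gml)
  g2 <- read_graphml(gml)
  expect_equal(igraph::vcount(g2), igraph::vcount(net$graph))
  expect_equal(igraph::V(g2)$terms[[1]], igraph::V(net$graph)$terms[[1]])
})
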