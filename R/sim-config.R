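#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic study: proteome size, number of
#' cell lines, the fraction of proteins planted as commonly expressed, the
#' score distributions of the two search engines for true and incorrect
#' matches, interactome size and annotation vocabulary, the planted
#' biological-process flux pair, and pathway sizes.  The defaults describe
#' the study conditions every simulation-based test runs under: seven cell
#' lines, two engines with an ion-score-like and a z-score-like scale, and
#' well-separated target and decoy score distributions.
#'
#' @param seed Integer seed; one seed determines every generated artifact.
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param n_cell_lines Number of cell lines (default 7).
#' @param frac_common Fraction of proteins planted as expressed in every
#'   cell line, in \[0, 1\].
#' @param isoform_rate Fraction of proteins that receive a splice-variant
#'   partner sharing all of the base protein's peptides (exercises grouping
#'   and the splice-variant rule).
#' @param peptides_per_line Integer range (length-2) of distinct peptides
#'   observed per expressed protein, cell line and spectrum set.
#' @param target_score_params,decoy_score_params Lists with elements `A` and
#'   `B`, each `c(mean =, sd =)`: Gaussian score distributions per engine
#'   for correct matches and for incorrect/decoy matches.  Engine A mimics
#'   an ion-score scale, engine B a z-score scale.
#' @param false_target_rate Fraction of spectra that are incorrect matches
#'   to target proteins (drawn from the decoy score distribution but not
#'   decoy-flagged) — the planted false identifications FDR control must
#'   keep out.
#' @param decoy_rate Fraction of spectra matched to reversed-sequence decoy
#'   accessions (decoy-flagged).
#' @param conflict_rate Fraction of two-engine spectra assigned different
#'   peptides by the two engines.
#' @param both_engine_prob Probability a spectrum is observed by both
#'   engines.
#' @param n_nodes,pa_m Interactome size and preferential-attachment edges
#'   per new node.
#' @param n_bp_terms Size of the biological-process vocabulary.
#' @param terms_per_node Integer range of terms annotated per node.
#' @param planted_flux_pair Character pair of BP terms whose flux is
#'   enriched; `flux_multiplier` scales it relative to its unplanted count.
#' @param flux_multiplier Enrichment multiplier (1 = no planting).
#' @param frac_central_nodes Fraction of interactome nodes labelled central.
#' @param central_attachment Exponent of the degree bias used when sampling
#'   central nodes (0 = uniform; 1 = degree-proportional, giving the
#'   central set elevated connectivity).
#' @param pathway_sizes Integer vector of pathway node counts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 1000L,
                       n_cell_lines = 7L,
                       frac_common = 0.3,
                       isoform_rate = 0.04,
                       peptides_per_line = c(3L, 6L),
                       target_score_params = list(A = c(mean = 45, sd = 12),
                                                  B = c(mean = 8, sd = 1.5)),
                       decoy_score_params = list(A = c(mean = 8, sd = 4),
                                                 B = c(mean = 1.5, sd = 1)),
                       false_target_rate = 0.05,
                       decoy_rate = 0.05,
                       conflict_rate = 0.02,
                       both_engine_prob = 0.8,
                       n_nodes = 600L,
                       pa_m = 2L,
                       n_bp_terms = 15L,
                       terms_per_node = c(1L, 4L),
                       planted_flux_pair = NULL,
                       flux_multiplier = 1,
                       frac_central_nodes = 0.3,
                       central_attachment = 1,
                       pathway_sizes = c(5L, 8L, 12L, 20L)) {
  cfg <- list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    n_cell_lines = as.integer(n_cell_lines), frac_common = frac_common,
    isoform_rate = isoform_rate, peptides_per_line = as.integer(peptides_per_line),
    target_score_params = target_score_params,
    decoy_score_params = decoy_score_params,
    false_target_rate = false_target_rate, decoy_rate = decoy_rate,
    conflict_rate = conflict_rate, both_engine_prob = both_engine_prob,
    n_nodes = as.integer(n_nodes), pa_m = as.integer(pa_m),
    n_bp_terms = as.integer(n_bp_terms),
    terms_per_node = as.integer(terms_per_node),
    planted_flux_pair = planted_flux_pair,
    flux_multiplier = flux_multiplier,
    frac_central_nodes = frac_central_nodes,
    central_attachment = central_attachment,
    pathway_sizes = as.integer(pathway_sizes)
  )
  validate_sim_config(cfg)
  if (is.null(cfg$planted_flux_pair)) {
    cfg$planted_flux_pair <- bp_term_ids(cfg$n_bp_terms)[1:2]
  }
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$frac_common >= 0, cfg$frac_common <= 1,
    cfg$n_proteins >= 0, cfg$n_cell_lines >= 1,
    cfg$false_target_rate >= 0, cfg$decoy_rate >= 0,
    cfg$conflict_rate >= 0, cfg$conflict_rate <= 1,
    cfg$both_engine_prob >= 0, cfg$both_engine_prob <= 1,
    cfg$n_nodes >= 0, cfg$pa_m >= 1, cfg$n_bp_terms >= 2,
    length(cfg$peptides_per_line) == 2,
    length(cfg$terms_per_node) == 2,
    cfg$flux_multiplier > 0,
    all(cfg$pathway_sizes >= 2) || length(cfg$pathway_sizes) == 0
  )
  for (eng in c("A", "B")) {
    stopifnot(all(c("mean", "sd") %in% names(cfg$target_score_params[[eng]])),
              all(c("mean", "sd") %in% names(cfg$decoy_score_params[[eng]])))
  }
  invisible(cfg)
}

bp_term_ids <- function(n) sprintf("BP%03d", seq_len(n))

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d proteins x %d cell lines (frac_common %.2f)\n",
              x$seed, x$n_proteins, x$n_cell_lines, x$frac_common))
  cat(sprintf("  interactome %d nodes (m = %d), %d BP terms, planted pair %s x%.1f\n",
              x$n_nodes, x$pa_m, x$n_bp_terms,
              paste(x$planted_flux_pair, collapse = "-"), x$flux_multiplier))
  cat(sprintf("  pathways: %s nodes\n", paste(x$pathway_sizes, collapse = ", ")))
  invisible(x)
}
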