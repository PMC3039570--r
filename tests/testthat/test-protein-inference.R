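psm_row <- function(spectrum, peptide, score, protein = "P1",
                    cell_line = "CL1", engine = "A", decoy = FALSE,
                    pvalue = NA_real_) {
  if (engine == "B" && is.na(pvalue)) pvalue <- pnorm(score, lower.tail = FALSE)
  tibble::tibble(spectrum_id = spectrum, cell_line = cell_line,
                 engine = engine, peptide = peptide, score = score,
                 pvalue = pvalue, protein_ids = protein, is_decoy = decoy)
}

test_that("merging keeps agreeing spectra, drops conflicts, unions the rest", {
  a <- dplyr::bind_rows(
    psm_row("S1", "PEPTIDEK", 30),
    psm_row("S2", "PEPTIDEK", 25),
    psm_row("S3", "AAAAAAK", 40)
  )
  b <- dplyr::bind_rows(
    psm_row("S1", "PEPTIDEK", 5, engine = "B"),
    psm_row("S2", "ELVISLIVESK", 6, engine = "B"),
    psm_row("S4", "CCCCCCR", 7, engine = "B")
  )
  m <- merge_engine_results(a, b)
  expect_setequal(m$spectrum_id, c("S1", "S3", "S4"))   # S2 conflicts
  expect_equal(attr(m, "n_conflicts"), 1L)
  s1 <- m[m$spectrum_id == "S1", ]
  expect_equal(s1$score_a, 30)
  expect_equal(s1$score_b, 5)
  expect_true(is.na(m$score_b[m$spectrum_id == "S3"]))

  expect_error(merge_engine_results(dplyr::bind_rows(a, a[1, ]), b),
               "duplicated spectrum_id")

  # discarding conflicts is contraction-only: merged spectra are a subset
  expect_true(all(m$spectrum_id %in% union(a$spectrum_id, b$spectrum_id)))
})

test_that("two-peptide rule exports additional peptides above the lower threshold", {
  prot <- tibble::tibble(protein_id = "P1",
                         sequence = strrep("AAAAAAK", 10))
  a <- dplyr::bind_rows(
    psm_row("S1", "AAAAAAK", 19),
    psm_row("S2", "AAAAAAR", 20),
    psm_row("S3", "CCCCCCK", 12),  # additional only
    psm_row("S4", "DDDDDDK", 9)    # below additional
  )
  b <- psm_row("S9", "ZZZZ", 0, engine = "B")[0, ]
  ev <- apply_identification_rules(merge_engine_results(a, b), prot)
  expect_setequal(ev$peptide, c("AAAAAAK", "AAAAAAR", "CCCCCCK"))
})

test_that("single peptide hits need the SPH score and 2.5% coverage", {
  # 41 residues; one 7-residue peptide covers 17% of a 41-aa protein
  prot <- tibble::tibble(
    protein_id = c("P1", "P2"),
    sequence = c(paste0("AAAAAAK", strrep("C", 34)),
                 paste0("AAAAAAK", strrep("C", 280)))
  )
  empty_b <- psm_row("S0", "X", 0, engine = "B")[0, ]
  # score 49 < 50: rejected despite ample coverage
  ev1 <- apply_identification_rules(
    merge_engine_results(psm_row("S1", "AAAAAAK", 49), empty_b), prot)
  expect_equal(nrow(ev1), 0)
  # score 55 with coverage 7/41 = 17%: accepted
  ev2 <- apply_identification_rules(
    merge_engine_results(psm_row("S2", "AAAAAAK", 55), empty_b), prot)
  expect_equal(ev2$protein_id, "P1")
  # engine B z = 6.5 but coverage 7/287 = 2.4% < 2.5%: rejected
  empty_a <- psm_row("S0", "X", 0)[0, ]
  ev3 <- apply_identification_rules(
    merge_engine_results(empty_a,
                         psm_row("S3", "AAAAAAK", 6.5, protein = "P2",
                                 engine = "B")),
    prot)
  expect_equal(nrow(ev3), 0)
  # coverage needs the sequence: unknown accession is a hard error
  expect_error(apply_identification_rules(
    merge_engine_results(psm_row("S4", "AAAAAAK", 55, protein = "PX"),
                         empty_b), prot), "PX")
})

evidence_tbl <- function(...) {
  sets <- list(...)
  dplyr::bind_rows(purrr::imap(sets, function(peps, prot) {
    tibble::tibble(cell_line = "CL1", protein_id = prot, peptide = peps)
  }))
}

test_that("grouping merges identical sets and absorbs strict subsets", {
  g1 <- group_proteins(evidence_tbl(P1 = c("p1", "p2"), P2 = c("p1", "p2")))
  expect_equal(nrow(g1), 1)
  expect_setequal(g1$members[[1]], c("P1", "P2"))
  expect_setequal(g1$specific_peptides[[1]], c("p1", "p2"))

  g2 <- group_proteins(evidence_tbl(P1 = c("p1", "p2"), P2 = "p2"))
  expect_equal(nrow(g2), 1)
  expect_setequal(g2$members[[1]], c("P1", "P2"))

  # without absorption the subset protein stands alone and, having no
  # specific peptide, is discarded
  g2b <- group_proteins(evidence_tbl(P1 = c("p1", "p2"), P2 = "p2"),
                        absorb_subsets = FALSE)
  expect_equal(nrow(g2b), 1)
  expect_equal(g2b$members[[1]], "P1")
})

test_that("groups without a specific peptide are discarded", {
  ev <- evidence_tbl(P1 = c("p1", "p2"), P2 = c("p2", "p3"),
                     P3 = c("p1", "p3"))
  g <- group_proteins(ev)
  expect_equal(nrow(g), 0)

  # brute-force cross-check of specificity on a surviving configuration
  ev2 <- evidence_tbl(P1 = c("p1", "p2"), P2 = c("p2", "p3"))
  g2 <- group_proteins(ev2)
  tally <- table(unlist(g2$peptides))
  for (i in seq_len(nrow(g2))) {
    expect_setequal(g2$specific_peptides[[i]],
                    g2$peptides[[i]][tally[g2$peptides[[i]]] == 1])
  }
})

test_that("grouping is idempotent and order-independent", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      prots <- paste0("P", 1:8)
      ev <- dplyr::bind_rows(lapply(prots, function(p) {
        tibble::tibble(cell_line = "CL1", protein_id = p,
                       peptide = sample(paste0("pep", 1:10),
                                        sample(2:5, 1)))
      }))
      g_ref <- group_proteins(ev)
      g_perm <- group_proteins(ev[sample.int(nrow(ev)), ])
      expect_equal(g_perm, g_ref)
    }
  })
})

test_that("splice-variant filter keeps single-gene groups only", {
  gm <- tibble::tibble(protein_id = c("P1a", "P1b", "P2", "P3"),
                       gene_id = c("G1", "G1", "G2", "G3"))
  groups <- group_proteins(evidence_tbl(P1a = c("p1", "p2"),
                                        P1b = c("p1", "p2"),
                                        P2 = "p9", P3 = "p7"))
  kept <- splice_variant_filter(groups, gm)
  expect_equal(nrow(kept), 3)  # the P1a/P1b pair plus two singletons

  mixed <- group_proteins(evidence_tbl(P1a = c("p1", "p2"),
                                       P2 = c("p1", "p2")))
  expect_equal(nrow(splice_variant_filter(mixed, gm)), 0)

  expect_error(splice_variant_filter(groups, gm[-1, ]), "P1a")
})

test_that("FDR calibration picks the least stringent passing candidate", {
  cfg <- sim_config(seed = 13, n_proteins = 150)
  prot <- sim_proteome(cfg)
  tabs <- sim_psm_tables(prot, cfg)
  pa <- dplyr::filter(tabs$psm, .data$engine == "A")
  pb <- dplyr::filter(tabs$psm, .data$engine == "B")
  cal <- calibrate_group_fdr(pa, pb, prot, default_thresholds_grid(),
                             gene_map = tabs$ground_truth$gene_map)
  expect_s3_class(cal, "fdr_calibration")
  expect_true(cal$passed)
  expect_lte(cal$achieved_fdr, 0.0025)
  # on these score distributions the estimate is monotone along the grid
  fdr <- cal$grid_results$fdr
  expect_true(all(diff(fdr) <= 1e-12))

  # all-decoy input raises the failure flag
  pa_d <- dplyr::mutate(pa, is_decoy = TRUE,
                        protein_ids = paste0(
                          "DECOY_", sub("^DECOY_", "",
                                        sub(";.*", "", .data$protein_ids))),
                        score = .data$score * 0 + 60)
  expect_warning(
    cal_d <- calibrate_group_fdr(pa_d, pb[0, ], prot,
                                 default_thresholds_grid()),
    "no candidate")
  expect_false(cal_d$passed)
})

test_that("realized group FDR against planted truth honours the bound", {
  fdrs <- vapply(c(17, 18, 19), function(seed) {
    cfg <- sim_config(seed = seed, n_proteins = 250)
    prot <- sim_proteome(cfg)
    tabs <- sim_psm_tables(prot, cfg)
    pa <- dplyr::filter(tabs$psm, .data$engine == "A")
    pb <- dplyr::filter(tabs$psm, .data$engine == "B")
    cal <- calibrate_group_fdr(pa, pb, prot, default_thresholds_grid(),
                               gene_map = tabs$ground_truth$gene_map)
    groups <- infer_proteins(pa, pb, prot, thresholds = cal$thresholds,
                             gene_map = tabs$ground_truth$gene_map)
    truth <- tabs$ground_truth$psm_truth
    true_peps <- unique(tabs$psm$peptide[
      tabs$psm$spectrum_id %in% truth$spectrum_id[truth$truth == "true"]])
    tg <- groups[!groups$is_decoy, ]
    false_grp <- vapply(tg$peptides, function(p) !any(p %in% true_peps),
                        logical(1))
    mean(false_grp)
  }, numeric(1))
  # realized false-discovery proportion within 3 binomial sd of the bound
  expect_lt(mean(fdrs), 0.0025 + 3 * sqrt(0.0025 * 0.9975 / 1000))
})

test_that("every accepted peptide passed its engine's additional threshold", {
  cfg <- sim_config(seed = 23, n_proteins = 120)
  prot <- sim_proteome(cfg)
  tabs <- sim_psm_tables(prot, cfg)
  pa <- dplyr::filter(tabs$psm, .data$engine == "A")
  pb <- dplyr::filter(tabs$psm, .data$engine == "B")
  th <- inference_thresholds()
  m <- merge_engine_results(pa, pb)
  ev <- apply_identification_rules(m, prot, th)
  scores <- m |>
    dplyr::select("peptide", "score_a", "score_b")
  joined <- dplyr::inner_join(ev, scores, by = "peptide",
                              relationship = "many-to-many")
  best <- joined |>
    dplyr::group_by(.data$cell_line, .data$protein_id, .data$peptide) |>
    dplyr::summarise(
      a = suppressWarnings(max(.data$score_a, na.rm = TRUE)),
      b = suppressWarnings(max(.data$score_b, na.rm = TRUE)),
      .groups = "drop")
  expect_true(all(best$a >= th$a_additional | best$b >= th$b_additional_z))
})
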