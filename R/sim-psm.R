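#' Generate per-cell-line, per-engine PSM tables with ground truth
#'
#' Simulates the exports of two database search engines over a synthetic
#' proteome.  Proteins in the planted common set receive spectra in every
#' cell line; other proteins are expressed in a random strict subset of the
#' cell lines.  Each spectrum is observed by both engines with probability
#' `both_engine_prob`; a fraction `conflict_rate` of two-engine spectra is
#' assigned a different peptide by engine B (such spectra must be discarded
#' at merge time).  Correct matches draw scores from
#' `target_score_params`; two kinds of incorrect matches draw from
#' `decoy_score_params`: *false target* matches (not decoy-flagged — the
#' planted false identifications that FDR control must exclude) and
#' *decoy* matches against reversed-sequence accessions (`DECOY_` prefix,
#' decoy-flagged) used to estimate the FDR.
#'
#' @param proteome Output of [sim_proteome()].
#' @param config The [sim_config()] used to generate `proteome`.
#' @return List with elements
#'   * `psm`: tibble with columns `spectrum_id`, `cell_line`, `engine`,
#'     `peptide`, `score`, `pvalue`, `protein_ids` (`;`-separated), `is_decoy`;
#'   * `ground_truth`: list with `common_set`, `expressed`
#'     (`protein_id` x `cell_line`), `psm_truth` (`spectrum_id`, `truth` in
#'     `"true"/"false"/"decoy"`, `conflict`), and `gene_map` covering target
#'     and decoy accessions.
#' @export
sim_psm_tables <- function(proteome, config) {
  stopifnot(inherits(config, "sim_config"), nrow(proteome) > 0)
  withr::with_seed(config$seed + 22L, {
    ids <- proteome$protein_id
    n <- length(ids)
    lines <- sprintf("CL%d", seq_len(config$n_cell_lines))

    n_common <- round(config$frac_common * n)
    if (config$frac_common > 0 && n_common < 1) {
      warning("frac_common * n_proteins < 1: common set is empty", call. = FALSE)
    }
    common_set <- sort(sample(ids, n_common))

    other <- setdiff(ids, common_set)
    expressed <- dplyr::bind_rows(
      tidyr::expand_grid(protein_id = common_set, cell_line = lines),
      if (length(other) > 0 && config$n_cell_lines > 1) {
        k <- sample.int(config$n_cell_lines - 1L, length(other), replace = TRUE)
        tibble::tibble(
          protein_id = rep(other, k),
          cell_line = unlist(lapply(k, function(ki) sample(lines, ki)))
        )
      }
    ) |> dplyr::arrange(.data$protein_id, .data$cell_line)

    digests <- lapply(proteome$sequence, tryptic_peptides)
    names(digests) <- ids
    pep_index <- tibble::tibble(
      protein_id = rep(ids, lengths(digests)),
      peptide = unlist(digests, use.names = FALSE)
    )
    pep_owner <- pep_index |>
      dplyr::group_by(.data$peptide) |>
      dplyr::summarise(
        protein_ids = paste(sort(unique(.data$protein_id)), collapse = ";"),
        .groups = "drop"
      )
    known_pep <- pep_owner$peptide

    # --- correct matches -------------------------------------------------
    pp <- config$peptides_per_line
    npep <- sample(seq(pp[1], pp[2]), nrow(expressed), replace = TRUE)
    npep <- pmin(npep, lengths(digests)[expressed$protein_id])
    true_tbl <- tibble::tibble(
      protein_id = rep(expressed$protein_id, npep),
      cell_line = rep(expressed$cell_line, npep),
      peptide = unlist(purrr::map2(expressed$protein_id, npep,
                                   function(p, k) sample(digests[[p]], k))),
      truth = "true"
    ) |>
      dplyr::left_join(pep_owner, by = "peptide")

    n_true <- nrow(true_tbl)

    # --- planted false target matches -----------------------------------
    n_false <- round(config$false_target_rate * n_true)
    false_tbl <- if (n_false > 0) {
      claim <- expressed[sample.int(nrow(expressed), n_false, replace = TRUE), ]
      tibble::tibble(
        protein_id = claim$protein_id,
        cell_line = claim$cell_line,
        peptide = vapply(sample(true_tbl$peptide, n_false, replace = TRUE),
                         scramble_peptide, character(1), avoid = known_pep,
                         USE.NAMES = FALSE),
        truth = "false",
        protein_ids = claim$protein_id
      )
    }

    # --- decoy matches ---------------------------------------------------
    n_decoy <- round(config$decoy_rate * n_true)
    decoy_tbl <- if (n_decoy > 0) {
      src <- sample(true_tbl$peptide, n_decoy, replace = TRUE)
      rev_pep <- vapply(src, function(p) {
        r <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
        if (r %in% known_pep || r == p) scramble_peptide(p, known_pep) else r
      }, character(1), USE.NAMES = FALSE)
      tibble::tibble(
        protein_id = paste0("DECOY_", sample(ids, n_decoy, replace = TRUE)),
        cell_line = sample(lines, n_decoy, replace = TRUE),
        peptide = rev_pep,
        truth = "decoy",
        protein_ids = NA_character_
      ) |>
        dplyr::mutate(protein_ids = .data$protein_id)
    }

    spectra <- dplyr::bind_rows(true_tbl, false_tbl, decoy_tbl) |>
      dplyr::mutate(spectrum_id = sprintf("S%07d", dplyr::row_number()),
                    is_decoy = .data$truth == "decoy")

    # --- engine observation, conflicts, scores ---------------------------
    both <- stats::runif(nrow(spectra)) < config$both_engine_prob
    only_engine <- sample(c("A", "B"), nrow(spectra), replace = TRUE)
    conflict <- both & stats::runif(nrow(spectra)) < config$conflict_rate

    draw_scores <- function(engine_rows, engine) {
      tp <- config$target_score_params[[engine]]
      dp <- config$decoy_score_params[[engine]]
      is_true <- engine_rows$truth == "true"
      mu <- ifelse(is_true, tp[["mean"]], dp[["mean"]])
      sd <- ifelse(is_true, tp[["sd"]], dp[["sd"]])
      stats::rnorm(nrow(engine_rows), mu, sd)
    }

    rows_a <- spectra[both | only_engine == "A", ]
    rows_b <- spectra[both | only_engine == "B", ]
    conflict_b <- spectra$spectrum_id[conflict]
    rows_b$peptide[rows_b$spectrum_id %in% conflict_b] <-
      vapply(rows_b$peptide[rows_b$spectrum_id %in% conflict_b],
             scramble_peptide, character(1), avoid = known_pep, USE.NAMES = FALSE)

    sa <- draw_scores(rows_a, "A")
    sb <- draw_scores(rows_b, "B")
    psm <- dplyr::bind_rows(
      rows_a |> dplyr::mutate(engine = "A", score = sa, pvalue = NA_real_),
      rows_b |> dplyr::mutate(engine = "B", score = sb,
                              pvalue = stats::pnorm(sb, lower.tail = FALSE))
    ) |>
      dplyr::select("spectrum_id", "cell_line", "engine", "peptide",
                    "score", "pvalue", "protein_ids", "is_decoy") |>
      dplyr::arrange(.data$spectrum_id, .data$engine)

    gene_map <- dplyr::bind_rows(
      proteome[, c("protein_id", "gene_id")],
      proteome |>
        dplyr::transmute(protein_id = paste0("DECOY_", .data$protein_id),
                         gene_id = paste0("DECOY_", .data$gene_id))
    )

    list(
      psm = psm,
      ground_truth = list(
        common_set = common_set,
        expressed = expressed,
        psm_truth = spectra |>
          dplyr::mutate(conflict = .data$spectrum_id %in% conflict_b) |>
          dplyr::select("spectrum_id", "truth", "conflict"),
        gene_map = gene_map
      )
    )
  })
}

# permute a peptide's interior so the sequence differs from the original and
# matches no known peptide; terminal residue (K/R) is preserved
scramble_peptide <- function(pep, avoid = character(0)) {
  ch <- strsplit(pep, "")[[1]]
  n <- length(ch)
  for (i in 1:8) {
    cand <- c(sample(ch[-n]), ch[n])
    cand_s <- paste(cand, collapse = "")
    if (cand_s != pep && !cand_s %in% avoid) return(cand_s)
  }
  # degenerate interiors: substitute a residue instead of permuting
  repl <- setdiff(setdiff(names(residue_masses), c("K", "R", "P")), ch[1])
  ch[1] <- repl[1]
  paste(ch, collapse = "")
}

#' Write / read PSM tables as TSV
#'
#' Columns: `spectrum_id`, `cell_line`, `engine`, `peptide`, `score`,
#' `pvalue`, `protein_ids` (`;`-separated accessions), `is_decoy`.
#'
#' @param psm PSM tibble.
#' @param path File path.
#' @export
write_psm_tsv <- function(psm, path) {
  readr::write_tsv(psm, path)
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    spectrum_id = readr::col_character(),
    cell_line = readr::col_character(),
    engine = readr::col_character(),
    peptide = readr::col_character(),
    score = readr::col_double(),
    pvalue = readr::col_double(),
    protein_ids = readr::col_character(),
    is_decoy = readr::col_logical()
  ))
}
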