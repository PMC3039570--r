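#' Generate a synthetic proteome
#'
#' Builds random protein sequences as concatenations of tryptic "blocks":
#' stretches of 6--13 residues ending in K or R, never starting with P, with
#' no internal K/R.  Digesting such a sequence with [tryptic_peptides()] is
#' guaranteed to yield at least one peptide of length >= 6 per protein.  A
#' fraction of proteins (`isoform_rate`) come as splice-variant pairs: the
#' partner carries all of the base protein's blocks plus two extra ones and
#' shares its gene, so the pair produces shared peptides and exercises
#' protein grouping and the splice-variant rule downstream.
#'
#' @param config A [sim_config()].
#' @return Tibble with `protein_id`, `gene_id`, `sequence`
#'   (`n_proteins` rows, unique ids), deterministic under `config$seed`.
#' @export
sim_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_proteins < 1) {
    stop("cannot generate an empty proteome (n_proteins = 0)", call. = FALSE)
  }
  withr::with_seed(config$seed + 11L, {
    n <- config$n_proteins
    n_pairs <- min(floor(config$isoform_rate * n), floor(n / 2))
    # proteins 1..2*n_pairs form isoform pairs (odd = base, even = partner)
    base_idx <- seq_len(n)
    partner_of <- rep(NA_integer_, n)
    if (n_pairs > 0) partner_of[2L * seq_len(n_pairs)] <- 2L * seq_len(n_pairs) - 1L

    blocks <- vector("list", n)
    for (i in base_idx) {
      if (!is.na(partner_of[i])) {
        blocks[[i]] <- c(blocks[[partner_of[i]]], make_blocks(2L))
      } else {
        blocks[[i]] <- make_blocks(sample(8:18, 1L))
      }
    }
    gene_idx <- ifelse(is.na(partner_of), base_idx, partner_of)
    tibble::tibble(
      protein_id = sprintf("P%05d", base_idx),
      gene_id = sprintf("G%05d", gene_idx),
      sequence = vapply(blocks, paste, character(1), collapse = "")
    )
  })
}

# random tryptic blocks: [not KRP][not KR]{4,11}[KR]
make_blocks <- function(k) {
  aa <- names(residue_masses)
  aa_no_kr <- setdiff(aa, c("K", "R"))
  aa_no_krp <- setdiff(aa_no_kr, "P")
  vapply(seq_len(k), function(i) {
    len <- sample(5:12, 1L)
    paste0(
      sample(aa_no_krp, 1L),
      paste(sample(aa_no_kr, len - 1L, replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1L)
    )
  }, character(1))
}

#' Write / read a proteome as FASTA
#'
#' @param proteome Tibble with `protein_id`, `sequence` (and optionally
#'   `gene_id`, stored in the description line).
#' @param path File path.
#' @return `write_proteome_fasta()` returns `path` invisibly;
#'   `read_proteome_fasta()` returns a tibble with `protein_id`, `gene_id`
#'   (NA when absent) and `sequence`.
#' @export
write_proteome_fasta <- function(proteome, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA i/o", call. = FALSE)
  }
  seqs <- Biostrings::AAStringSet(proteome$sequence)
  names(seqs) <- if ("gene_id" %in% names(proteome)) {
    paste(proteome$protein_id, paste0("gene=", proteome$gene_id))
  } else {
    proteome$protein_id
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA i/o", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  gene <- ifelse(grepl("gene=", hdr), sub("^.*gene=(\\S+).*$", "\\1", hdr), NA_character_)
  tibble::tibble(protein_id = id, gene_id = gene,
                 sequence = unname(as.character(seqs)))
}
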