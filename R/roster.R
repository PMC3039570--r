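#' Read a protein roster (one protein per row)
#'
#' Reads a roster TSV (columns `accession`, `entry_name`, `gene_name`)
#' such as a deposited central-proteome list, and returns it with one row
#' per protein.
#'
#' @param path TSV file path.
#' @return Tibble of roster entries.
#' @seealso [synthetic_central_roster()] for the bundled synthetic
#'   stand-in roster.
#' @export
read_protein_roster <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Synthetic stand-in central-proteome roster
#'
#' Generates a *synthetic* roster of `n` proteins with the shape of a
#' deposited central-proteome list (accession, entry name, gene name).
#' The entries are fabricated placeholders — the bundled copy at
#' `inst/extdata/central_proteome_roster_synthetic.tsv` mirrors only the
#' reported size of such a list (1,124 proteins), not its content, and
#' exists so roster-handling code has a file to exercise without the
#' original deposition.
#'
#' @param n Number of entries (default 1124).
#' @return Tibble with `accession`, `entry_name`, `gene_name`.
#' @export
synthetic_central_roster <- function(n = 1124L) {
  i <- seq_len(n)
  tibble::tibble(
    accession = sprintf("SYN%05d", i),
    entry_name = sprintf("CPROT%04d_SYN", i),
    gene_name = sprintf("CPG%04d", i)
  )
}
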