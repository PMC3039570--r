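#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) of the 20 standard amino-acid
#' residues (as residues, i.e. without the water of the free peptide).
#'
#' @format Named numeric vector of length 20.
#' @export
residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.010565

#' Monoisotopic peptide mass
#'
#' Computes the monoisotopic mass \[M\] of peptides from residue masses plus
#' one water.
#'
#' @param peptide Character vector of peptide sequences over the 20 standard
#'   one-letter amino-acid codes.
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("PEPTIDEK")
#' @export
peptide_mass <- function(peptide) {
  vapply(peptide, function(p) {
    aa <- strsplit(p, "")[[1]]
    check_standard_residues(aa, p)
    sum(residue_masses[aa]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

check_standard_residues <- function(aa, seq_label) {
  bad <- which(!aa %in% names(residue_masses))
  if (length(bad) > 0) {
    stop(sprintf(
      "non-standard residue '%s' at position %d of sequence '%s'",
      aa[bad[1]], bad[1],
      if (nchar(seq_label) > 25) paste0(substr(seq_label, 1, 25), "...") else seq_label
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after K or R except when the next residue is P,
#' and returns the distinct peptides with up to `missed_cleavages` internal
#' missed cleavage sites and length at least `min_length`.
#'
#' @param sequence Single protein sequence (standard residues only).
#' @param missed_cleavages Maximum number of internal missed cleavage sites
#'   (default 1, matching typical search-engine settings).
#' @param min_length Minimum peptide length in residues (default 6).
#' @return Character vector of distinct peptide sequences.
#' @examples
#' tryptic_peptides("AAAAAAKAAAAAAR")
#' @export
tryptic_peptides <- function(sequence, missed_cleavages = 1L, min_length = 6L) {
  stopifnot(length(sequence) == 1L, missed_cleavages >= 0L)
  if (nchar(sequence) == 0L) return(character(0))
  aa <- strsplit(sequence, "")[[1]]
  check_standard_residues(aa, sequence)
  n <- length(aa)
  # cleavage after position i when aa[i] is K/R and aa[i+1] is not P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n else integer(0))
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  peps <- character(0)
  n_frag <- length(starts)
  for (i in seq_len(n_frag)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > n_frag) break
      len <- ends[j] - starts[i] + 1L
      if (len >= min_length) {
        peps <- c(peps, paste(aa[starts[i]:ends[j]], collapse = ""))
      }
    }
  }
  unique(peps)
}

#' Count observable tryptic peptides in an instrument mass range
#'
#' The "observable" peptide count used as the emPAI denominator: distinct
#' tryptic peptides (up to one missed cleavage by default, minimum length 6)
#' whose monoisotopic mass lies within the instrument mass range.  The
#' default range of 698--2370 Da covers the peptide population a typical
#' LC-MS/MS acquisition actually samples.
#'
#' @param sequence Single protein sequence.
#' @param mass_min,mass_max Mass window bounds in Da (defaults 698 and 2370).
#' @param missed_cleavages,min_length Digest settings, see
#'   [tryptic_peptides()].
#' @return Integer count.
#' @examples
#' count_observable_peptides("AAAAAAKAAAAAAR")
#' @export
count_observable_peptides <- function(sequence, mass_min = 698, mass_max = 2370,
                                      missed_cleavages = 1L, min_length = 6L) {
  stopifnot(mass_min < mass_max)
  peps <- tryptic_peptides(sequence, missed_cleavages = missed_cleavages,
                           min_length = min_length)
  if (length(peps) == 0L) return(0L)
  m <- peptide_mass(peps)
  sum(m >= mass_min & m <= mass_max)
}
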