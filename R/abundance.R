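#' Exponentially modified protein abundance index (emPAI)
#'
#' emPAI = 10^(observed/observable) - 1, where `n_observed` is the number of
#' distinct peptides actually identified for a protein and `n_observable`
#' the number of tryptic peptides within the instrument mass range (see
#' [count_observable_peptides()]).
#'
#' @param n_observed Nonnegative counts of observed distinct peptides.
#' @param n_observable Positive counts of observable peptides (recycled).
#' @return Numeric vector of emPAI values (>= 0).
#' @examples
#' empai(0, 10)   # 0
#' empai(10, 10)  # 9
#' @export
empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1)) {
    stop("emPAI is undefined for proteins with no observable peptide (n_observable = 0)",
         call. = FALSE)
  }
  if (any(n_observed < 0)) stop("n_observed must be >= 0", call. = FALSE)
  10^(n_observed / n_observable) - 1
}

#' Per-protein, per-cell-line emPAI abundance table
#'
#' Joins a detection table (distinct observed peptides per protein and cell
#' line) with per-protein observable-peptide counts derived from the protein
#' sequences, and computes emPAI.  Proteins absent from a cell line simply
#' have no row for that line: absence is "not detected", never zero
#' abundance.
#'
#' @param detections Data frame with columns `protein_id`, `cell_line`,
#'   `n_observed`.
#' @param proteome Data frame with columns `protein_id`, `sequence`.
#' @param mass_min,mass_max Instrument mass range in Da for observable
#'   peptides.
#' @param missed_cleavages,min_length Digest settings.
#' @return Tibble with columns `protein_id`, `cell_line`, `n_observed`,
#'   `n_observable`, `empai`.
#' @export
abundance_matrix <- function(detections, proteome, mass_min = 698,
                             mass_max = 2370, missed_cleavages = 1L,
                             min_length = 6L) {
  stopifnot(all(c("protein_id", "cell_line", "n_observed") %in% names(detections)),
            all(c("protein_id", "sequence") %in% names(proteome)))
  missing <- setdiff(unique(detections$protein_id), proteome$protein_id)
  if (length(missing) > 0) {
    stop("proteins without sequence: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  obs <- proteome |>
    dplyr::filter(.data$protein_id %in% detections$protein_id) |>
    dplyr::mutate(n_observable = vapply(
      .data$sequence, count_observable_peptides, integer(1),
      mass_min = mass_min, mass_max = mass_max,
      missed_cleavages = missed_cleavages, min_length = min_length,
      USE.NAMES = FALSE
    )) |>
    dplyr::select("protein_id", "n_observable")
  detections |>
    tibble::as_tibble() |>
    dplyr::inner_join(obs, by = "protein_id") |>
    dplyr::mutate(empai = empai(pmin(.data$n_observed, .data$n_observable),
                                .data$n_observable)) |>
    dplyr::arrange(.data$protein_id, .data$cell_line)
}

#' Summarize abundance across cell lines
#'
#' One row per protein: in how many cell lines it was detected and the
#' median emPAI over the cell lines where it was detected (absent lines are
#' not imputed as zero).
#'
#' @param abundance Output of [abundance_matrix()] (long tibble with
#'   `protein_id`, `cell_line`, `empai`).
#' @return Tibble with `protein_id`, `n_detected`, `median_empai`.
#' @export
abundance_summary <- function(abundance) {
  abundance |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(n_detected = dplyr::n_distinct(.data$cell_line),
                     median_empai = stats::median(.data$empai),
                     .groups = "drop")
}

#' Central proteome: proteins detected in (almost) every cell line
#'
#' The strict intersection across all cell lines when
#' `required = n_cell_lines`; a relaxed variant (e.g. 6 of 7) probes the
#' robustness of the set to single-line dropouts.
#'
#' @param summary Output of [abundance_summary()], or any data frame with
#'   `protein_id` and `n_detected`.
#' @param n_cell_lines Total number of cell lines analyzed.
#' @param required Minimum number of cell lines a protein must be detected
#'   in (default: all of them).
#' @return Character vector of protein ids.
#' @export
central_proteome <- function(summary, n_cell_lines, required = n_cell_lines) {
  stopifnot(required >= 1, required <= n_cell_lines)
  sort(summary$protein_id[summary$n_detected >= required])
}

#' Abundance classes: Top.CL, Low.C.Prot, Top.C.Prot
#'
#' Partitions proteins into the three comparison classes used throughout the
#' downstream analyses: `top_cl`, the top-quantile median-emPAI proteins
#' among those *not* commonly expressed (detected in at most
#' `topcl_max_lines` cell lines); and `low_cprot` / `top_cprot`, the bottom
#' and top quantile of the central proteome by median emPAI.  Values tied at
#' a quantile boundary are excluded from the class, so a nominal 25% class
#' can hold slightly fewer members.
#'
#' @param summary Output of [abundance_summary()].
#' @param central Character vector of central-proteome protein ids.
#' @param quantile Class size as a fraction, in (0, 0.5] (default 0.25).
#' @param topcl_max_lines Maximum `n_detected` for Top.CL candidates
#'   (default 5).
#' @return A `set_partition` object: tibble with `protein_id`, `class`
#'   (one of `"top_cl"`, `"low_cprot"`, `"top_cprot"`), with the quantile
#'   stored as an attribute.
#' @export
abundance_classes <- function(summary, central, quantile = 0.25,
                              topcl_max_lines = 5L) {
  stopifnot(quantile > 0, quantile <= 0.5)
  if (length(central) == 0) {
    warning("empty central set: abundance classes are empty", call. = FALSE)
  }
  cl_tbl <- summary |>
    dplyr::filter(.data$n_detected <= topcl_max_lines,
                  !.data$protein_id %in% central)
  cen_tbl <- summary |> dplyr::filter(.data$protein_id %in% central)

  top_cl <- quantile_class(cl_tbl, quantile, side = "top")
  low_cprot <- quantile_class(cen_tbl, quantile, side = "bottom")
  top_cprot <- quantile_class(cen_tbl, quantile, side = "top")

  out <- dplyr::bind_rows(
    tibble::tibble(protein_id = top_cl, class = "top_cl"),
    tibble::tibble(protein_id = low_cprot, class = "low_cprot"),
    tibble::tibble(protein_id = top_cprot, class = "top_cprot")
  )
  structure(out, quantile = quantile, class = c("set_partition", class(out)))
}

# Top/bottom `q` fraction by median emPAI with boundary ties excluded:
# members whose value equals the first value outside the nominal class are
# dropped, which is how a 25% class can fall below its nominal size.
quantile_class <- function(tbl, q, side = c("top", "bottom")) {
  side <- match.arg(side)
  n <- nrow(tbl)
  if (n == 0) return(character(0))
  k <- floor(q * n)
  if (k == 0) return(character(0))
  v <- tbl$median_empai
  ord <- order(v, tbl$protein_id, decreasing = (side == "top"))
  sel <- ord[seq_len(k)]
  if (k < n) {
    boundary <- v[ord[k + 1L]]
    sel <- sel[v[sel] != boundary]
  }
  sort(tbl$protein_id[sel])
}
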