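#' Bootstrapped chi-squared comparison of two distributions
#'
#' Compares two numeric samples without the excessive sensitivity a plain
#' chi-squared test shows on large datasets: in each of `n_resamples`
#' rounds, `subsample` points are drawn with replacement from each sample,
#' both draws are binned into `bins` equal-probability bins defined on the
#' pooled draw, and the two-sample chi-squared statistic is computed.  The
#' reported statistic is the median over rounds; its P-value comes from
#' the chi-squared distribution with `bins - 1` degrees of freedom.
#'
#' Because the median is a concentrated estimate, the null P-values of
#' this procedure are not uniform: the test rejects at close to the
#' nominal rate when the parent samples hold about twice the subsample
#' size, and becomes increasingly conservative for larger parents (see the
#' methods vignette).
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param n_resamples Number of resampling rounds (default 1000).
#' @param subsample Points drawn per sample per round (default 500).
#' @param bins Number of bins (default 10).
#' @param binning `"quantile"` (equal-probability on the pooled draw,
#'   default) or `"width"` (equal-width).
#' @return A `chi2_comparison` object: list with `statistic` (median
#'   chi-squared), `p_value`, `df`, `mean_shift` (mean(a) - mean(b)),
#'   `n_resamples`, `subsample`, `bins`.
#' @export
bootstrap_chi2 <- function(sample_a, sample_b, n_resamples = 1000L,
                           subsample = 500L, bins = 10L,
                           binning = c("quantile", "width")) {
  binning <- match.arg(binning)
  stopifnot(bins >= 2, length(sample_a) > 0, length(sample_b) > 0)
  if (length(unique(c(sample_a, sample_b))) < 2) {
    stop("degenerate input: pooled sample is constant", call. = FALSE)
  }
  stats_v <- vapply(seq_len(n_resamples), function(i) {
    xa <- sample(sample_a, subsample, replace = TRUE)
    xb <- sample(sample_b, subsample, replace = TRUE)
    pooled <- c(xa, xb)
    br <- if (binning == "quantile") {
      stats::quantile(pooled, probs = seq(0, 1, length.out = bins + 1),
                      names = FALSE)
    } else {
      seq(min(pooled), max(pooled), length.out = bins + 1)
    }
    br[1] <- -Inf
    br[length(br)] <- Inf
    br <- unique(br)
    ca <- tabulate(findInterval(xa, br, left.open = TRUE), length(br) - 1L)
    cb <- tabulate(findInterval(xb, br, left.open = TRUE), length(br) - 1L)
    chi2_homogeneity(rbind(ca, cb))
  }, numeric(1))
  med <- stats::median(stats_v)
  structure(
    list(statistic = med,
         p_value = stats::pchisq(med, df = bins - 1, lower.tail = FALSE),
         df = bins - 1L, mean_shift = mean(sample_a) - mean(sample_b),
         n_resamples = n_resamples, subsample = subsample, bins = bins),
    class = "chi2_comparison"
  )
}

# Pearson chi-squared statistic of an r x c contingency table
chi2_homogeneity <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- e > 0
  sum((tab[keep] - e[keep])^2 / e[keep])
}

#' @export
print.chi2_comparison <- function(x, ...) {
  cat(sprintf(
    "<chi2_comparison> median chi2 = %.3f (df %d), P = %.3g, mean shift %.3g\n",
    x$statistic, x$df, x$p_value, x$mean_shift))
  invisible(x)
}

#' Length-matched bootstrap shift estimate
#'
#' Estimates how much a feature (e.g. exon count, ortholog-species count)
#' is shifted in a target protein set relative to a reference collection,
#' while controlling for sequence length: the reference is stratified by
#' the target's length deciles, and each bootstrap draw samples reference
#' proteins stratum by stratum to match the target's length distribution.
#' The shift is mean(feature | target) minus the mean of the bootstrap
#' draw means, with a percentile interval.
#'
#' @param target Data frame of the target set with columns
#'   `sequence_length` and the feature.
#' @param reference Data frame of the reference collection with the same
#'   columns.
#' @param feature Name of the feature column.
#' @param n_draws Number of bootstrap draws (default 200).
#' @param conf Interval coverage (default 0.95).
#' @return List of class `shift_estimate`: `shift`, `conf_low`,
#'   `conf_high`, `n_draws`, `target_mean`, `draw_means`.
#' @export
length_matched_bootstrap <- function(target, reference, feature,
                                     n_draws = 200L, conf = 0.95) {
  stopifnot(feature %in% names(target), feature %in% names(reference),
            "sequence_length" %in% names(target),
            "sequence_length" %in% names(reference))
  br <- stats::quantile(target$sequence_length, probs = seq(0, 1, 0.1),
                        names = FALSE)
  br[1] <- -Inf
  br[length(br)] <- Inf
  br <- unique(br)
  t_stratum <- cut(target$sequence_length, br)
  r_stratum <- cut(reference$sequence_length, br)
  counts <- table(t_stratum)
  empty <- names(counts)[counts > 0 & !names(counts) %in% unique(as.character(r_stratum))]
  if (length(empty) > 0) {
    warning("reference has no proteins in length stratum ",
            paste(empty, collapse = ", "), "; stratum dropped", call. = FALSE)
  }
  ref_by <- split(reference[[feature]], r_stratum)
  draw_means <- vapply(seq_len(n_draws), function(i) {
    vals <- unlist(lapply(names(counts), function(s) {
      k <- counts[[s]]
      pool <- ref_by[[s]]
      if (k == 0 || length(pool) == 0) return(numeric(0))
      sample(pool, k, replace = TRUE)
    }), use.names = FALSE)
    mean(vals)
  }, numeric(1))
  t_mean <- mean(target[[feature]])
  shifts <- t_mean - draw_means
  qs <- stats::quantile(shifts, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  structure(
    list(shift = t_mean - mean(draw_means), conf_low = qs[1],
         conf_high = qs[2], n_draws = n_draws, target_mean = t_mean,
         draw_means = draw_means),
    class = "shift_estimate"
  )
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> %.3g [%.3g, %.3g] over %d length-matched draws\n",
              x$shift, x$conf_low, x$conf_high, x$n_draws))
  invisible(x)
}

#' Number of species with at least one ortholog
#'
#' @param ortholog_table Tibble with columns `protein_id`, `species`,
#'   `ortholog_id`.
#' @param protein Optional single accession; when given, returns a scalar
#'   count (0 for absent proteins).
#' @return Tibble with `protein_id`, `n_species`, or a scalar.
#' @export
count_ortholog_species <- function(ortholog_table, protein = NULL) {
  counts <- ortholog_table |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                     .groups = "drop")
  if (is.null(protein)) return(counts)
  i <- match(protein, counts$protein_id)
  if (is.na(i)) 0L else counts$n_species[i]
}

#' Association between two protein sets over a universe
#'
#' Tests whether membership in `set_a` and membership in `set_b` are
#' associated, with the same bootstrapped chi-squared machinery as
#' [bootstrap_chi2()]: each round draws `subsample` universe members with
#' replacement, tabulates the 2x2 membership table, and computes its
#' chi-squared statistic; the median statistic is referred to the
#' chi-squared distribution with 1 degree of freedom.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all ids.
#' @param n_resamples,subsample Resampling parameters.
#' @return A `chi2_comparison` with `df = 1`; `mean_shift` holds the
#'   observed minus expected overlap.
#' @export
set_association <- function(set_a, set_b, universe, n_resamples = 1000L,
                            subsample = 500L) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  stats_v <- vapply(seq_len(n_resamples), function(i) {
    ix <- sample.int(length(universe), subsample, replace = TRUE)
    tab <- table(factor(in_a[ix], c(FALSE, TRUE)),
                 factor(in_b[ix], c(FALSE, TRUE)))
    chi2_homogeneity(tab)
  }, numeric(1))
  med <- stats::median(stats_v)
  exp_overlap <- length(set_a) * length(set_b) / length(universe)
  structure(
    list(statistic = med,
         p_value = stats::pchisq(med, df = 1, lower.tail = FALSE),
         df = 1L, mean_shift = sum(in_a & in_b) - exp_overlap,
         n_resamples = n_resamples, subsample = subsample, bins = 4L),
    class = "chi2_comparison"
  )
}

#' Coverage of a GO term by a protein set
#'
#' Fraction of the universe's proteins annotated with `term` (or, when a
#' slim is supplied, with `term` or any of its descendants) that belong to
#' `protein_set`.
#'
#' @param protein_set Character vector of protein ids.
#' @param term Term id.
#' @param annotations Tibble with `protein_id`, `term`.
#' @param slim Optional [go_slim()] to include descendant terms.
#' @return Fraction in \[0, 1\].
#' @export
term_coverage <- function(protein_set, term, annotations, slim = NULL) {
  terms <- term
  if (!is.null(slim)) {
    desc <- slim$terms[vapply(slim$terms,
                              function(t) term %in% term_ancestors(t, slim),
                              logical(1))]
    terms <- c(term, desc)
  }
  annotated <- unique(annotations$protein_id[annotations$term %in% terms])
  if (length(annotated) == 0) {
    stop(sprintf("term '%s' has no annotations in the universe", term),
         call. = FALSE)
  }
  length(intersect(annotated, protein_set)) / length(annotated)
}
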