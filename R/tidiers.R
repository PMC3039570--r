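#' Tidy and glance methods for result objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated quantity,
#' `glance()` a one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.chi2_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value, df = x$df,
                 mean_shift = x$mean_shift)
}

#' @rdname tidiers
#' @export
glance.chi2_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value, df = x$df,
                 n_resamples = x$n_resamples, subsample = x$subsample,
                 bins = x$bins)
}

#' @rdname tidiers
#' @export
tidy.shift_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$shift, conf.low = x$conf_low,
                 conf.high = x$conf_high)
}

#' @rdname tidiers
#' @export
glance.shift_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$shift, conf.low = x$conf_low,
                 conf.high = x$conf_high, n_draws = x$n_draws,
                 target_mean = x$target_mean)
}

#' @rdname tidiers
#' @export
tidy.flux_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidiers
#' @export
glance.flux_result <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x), n_significant = sum(x$significant),
                 cutoff = attr(x, "cutoff"), alpha = attr(x, "alpha"),
                 n_fit = attr(x, "n_fit"), n_heldout = attr(x, "n_heldout"),
                 n_excluded = nrow(attr(x, "excluded_pairs")))
}

#' @rdname tidiers
#' @export
tidy.fdr_calibration <- function(x, ...) {
  x$grid_results
}

#' @rdname tidiers
#' @export
glance.fdr_calibration <- function(x, ...) {
  tibble::tibble(chosen = x$chosen, achieved_fdr = x$achieved_fdr,
                 fdr_max = x$fdr_max, passed = x$passed)
}

#' @rdname tidiers
#' @export
tidy.set_partition <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidiers
#' @export
glance.set_partition <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::count(.data$class, name = "n") |>
    tidyr::pivot_wider(names_from = "class", values_from = "n") |>
    dplyr::mutate(quantile = attr(x, "quantile"))
}
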