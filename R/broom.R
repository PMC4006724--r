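# broom-style accessors for fitted/called result objects.

#' Tidy a set of called asynchronous domains
#'
#' @param x A `timex_ards` tibble.
#' @param ... Unused.
#' @return A plain tibble, one row per domain (without the `cores`
#'   list-column; use `x$cores` for core sub-intervals).
#' @export
tidy.timex_ards <- function(x, ...) {
  out <- as_tibble(x)
  out$n_cores <- map_int(out$cores, nrow)
  out$cores <- NULL
  out
}

#' One-row summary of an ARD call
#'
#' @param x A `timex_ards` tibble.
#' @param ... Unused.
#' @return Tibble: domain count, candidate-island count, FDR level, total
#'   asynchronous span, and delay summaries.
#' @export
glance.timex_ards <- function(x, ...) {
  tibble(n_ards = nrow(x),
         n_candidate_islands = attr(x, "n_candidates") %||% NA_integer_,
         fdr = attr(x, "fdr") %||% NA_real_,
         total_span_bp = sum(x$end - x$start),
         mean_abs_delay_min = if (nrow(x) > 0) mean(abs(x$delay_minutes)) else NA_real_,
         max_abs_delay_min = if (nrow(x) > 0) max(abs(x$delay_minutes)) else NA_real_)
}

#' Tidy a power-study grid
#'
#' @param x A `timex_power_grid`.
#' @param ... Unused.
#' @return The grid as a plain tibble.
#' @export
tidy.timex_power_grid <- function(x, ...) as_tibble(x)

#' One-row summary of a power study
#'
#' @param x A `timex_power_grid`.
#' @param ... Unused.
#' @return Tibble: grid dimensions, pooled island counts and pooled
#'   empirical FDR.
#' @export
glance.timex_power_grid <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_sizes = dplyr::n_distinct(x$size),
         n_excesses = dplyr::n_distinct(x$excess),
         n_regions_per_cell = attr(x, "n_regions") %||% NA_integer_,
         pooled_fdr = sum(x$n_islands_false) / max(1, sum(x$n_islands)),
         seed = attr(x, "seed") %||% NA_integer_)
}
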