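# Sub-domain timing "ripples" and nascent-strand clusters. Classical peak
# callers struggle on timing profiles because of the very uneven baseline,
# so peaks are exposed by subtracting a coarse Gaussian smooth (which
# removes them) from a fine one (which retains them), and calling positive
# runs of the residual.

#' Dual-sigma smoothing residual
#'
#' `smooth(track, sigma_fine) - smooth(track, sigma_coarse)`: features
#' narrower than the coarse scale survive in the residual; the megabase
#' baseline cancels.
#'
#' @param track A [new_track()].
#' @param sigma_fine,sigma_coarse Smoothing sigmas in bp (fine < coarse;
#'   defaults 20 kb and 100 kb).
#' @return Residual track, covered where both smooths are.
#' @export
dual_smooth_residual <- function(track, sigma_fine = 2e4, sigma_coarse = 1e5) {
  if (sigma_fine >= sigma_coarse) abort("`sigma_fine` must be < `sigma_coarse`")
  fine <- gaussian_smooth(track, sigma_fine)
  coarse <- gaussian_smooth(track, sigma_coarse)
  out <- fine
  out$value <- fine$value - coarse$value
  attr(out, "sigma") <- NULL
  out
}

#' Call peaks on a smoothing residual
#'
#' Candidate peaks are maximal runs of contiguous covered bins with positive
#' residual; each peak's area is the sum of the residual over the run and
#' its summit the center of the maximal bin. The top `top_fraction` of
#' candidates by area are kept.
#'
#' @param residual Track from [dual_smooth_residual()].
#' @param top_fraction Fraction of candidate peaks kept, by area (default
#'   0.10).
#' @return Sorted tibble `chrom`, `start`, `end`, `area`, `summit`; empty if
#'   the residual has no positive run.
#' @export
call_residual_peaks <- function(residual, top_fraction = 0.10) {
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must be in (0, 1]")
  }
  w <- bin_width(residual)
  parts <- lapply(split(as_tibble(residual), residual$chrom), function(sub) {
    pos <- sub$value > 0
    brk <- c(TRUE, sub$start[-1] != sub$end[-nrow(sub)])
    run <- cumsum(brk | c(FALSE, diff(pos) != 0))
    sub <- sub[pos, ]
    if (nrow(sub) == 0) return(NULL)
    sub$run <- run[pos]
    sub |>
      group_by(.data$chrom, .data$run) |>
      summarise(summit = (.data$start[which.max(.data$value)] +
                            .data$end[which.max(.data$value)]) / 2,
                area = sum(.data$value),
                start = min(.data$start), end = max(.data$end),
                .groups = "drop") |>
      select("chrom", "start", "end", "area", "summit")
  })
  peaks <- dplyr::bind_rows(parts)
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  area = numeric(), summit = numeric()))
  }
  n_keep <- ceiling(top_fraction * nrow(peaks))
  kept <- peaks |>
    arrange(dplyr::desc(.data$area), .data$chrom, .data$start) |>
    head(n_keep)
  sort_intervals(kept)
}

#' Partition a profile into S-phase fractions
#'
#' Orders covered bins by timing value (descending: earliest replicating
#' first) and splits them into `k` equal-count groups, S1 holding the
#' earliest-replicating 1/k of the covered genome. Ties are broken stably
#' by genomic position.
#'
#' @param profile A `timex_profile` (any [new_track()] works).
#' @param k Number of fractions (default 5).
#' @return Tibble of merged intervals with a `fraction` column (`"S1"` ...
#'   `"Sk"`); fractions are disjoint and cover exactly the covered bins.
#' @export
partition_s_fractions <- function(profile, k = 5) {
  if (k < 2) abort("`k` must be >= 2")
  tbl <- as_tibble(profile)
  ord <- order(-tbl$value, tbl$chrom, tbl$start)
  n <- nrow(tbl)
  grp <- ceiling(seq_len(n) * k / n)
  tbl$fraction <- NA_integer_
  tbl$fraction[ord] <- grp
  dplyr::bind_rows(lapply(seq_len(k), function(g) {
    merge_intervals(tbl[tbl$fraction == g, c("chrom", "start", "end")]) |>
      mutate(fraction = paste0("S", g))
  }))
}

#' Fraction of intervals overlapping a feature set
#'
#' Share of `a`-intervals with >= 1 bp overlap with any `b`-interval.
#'
#' @param a,b Interval tibbles.
#' @return Fraction in \[0, 1\].
#' @export
overlap_fraction <- function(a, b) {
  if (nrow(a) == 0) abort("`a` is empty")
  mean(overlaps_any(a, b))
}

#' Coverage-based expected overlap
#'
#' Closed-form chance expectation for the fraction of one peak set
#' overlapping another: `cov_a * partial_factor * cov_b`, where the
#' coverages are the fractions of the territory each set occupies and the
#' factor (default 3) accounts for partial overlaps.
#'
#' @param cov_a,cov_b Coverage fractions in \[0, 1\].
#' @param partial_factor Partial-overlap multiplier (default 3).
#' @return Expected overlap fraction.
#' @export
expected_overlap <- function(cov_a, cov_b, partial_factor = 3) {
  if (any(c(cov_a, cov_b) < 0) || any(c(cov_a, cov_b) > 1)) {
    abort("coverages must lie in [0, 1]")
  }
  cov_a * partial_factor * cov_b
}

#' Randomize interval locations within a territory
#'
#' Re-places each interval uniformly at random inside the territory,
#' preserving its width and never straddling a territory segment end.
#' Placements are independent (randomized intervals may overlap each
#' other).
#'
#' @param x Interval tibble to randomize.
#' @param territory Interval tibble defining where placements may fall
#'   (e.g. an S-phase fraction, or whole chromosomes).
#' @param seed Integer seed.
#' @return Interval tibble with the same width multiset, sorted.
#' @export
randomize_intervals <- function(x, territory, seed = NULL) {
  check_intervals(territory, "territory")
  force(x)
  if (!is.null(seed)) withr::local_seed(seed)
  terr <- merge_intervals(territory)
  widths <- x$end - x$start
  seg_len <- terr$end - terr$start
  seg_idx <- integer(length(widths))
  # segment choice is width-dependent (weights = available start positions)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    room <- seg_len - w
    if (all(room < 0)) abort("an interval is wider than every territory segment")
    probs <- pmax(room + 1, 0) * (room >= 0)
    seg_idx[sel] <- sample.int(nrow(terr), length(sel), replace = TRUE,
                               prob = probs)
  }
  starts <- floor(terr$start[seg_idx] +
                    runif(length(widths)) * (seg_len[seg_idx] - widths + 1))
  sort_intervals(tibble(chrom = terr$chrom[seg_idx], start = starts,
                        end = starts + widths))
}

#' Pearson correlation of two tracks at a common resolution
#'
#' Rebins both tracks to `bin` bp, optionally saturates each at its mean +
#' 3 SD, and correlates jointly covered bins.
#'
#' @param a,b Tracks on the same genome.
#' @param bin Common bin width in bp (default 3 kb).
#' @param saturate Saturate outliers before correlating (default `TRUE`).
#' @return Pearson r.
#' @export
track_correlation <- function(a, b, bin = 3000, saturate = TRUE) {
  ra <- rebin_track(a, bin)
  rb <- rebin_track(b, bin)
  if (saturate) {
    ra <- saturate_outliers(ra)
    rb <- saturate_outliers(rb)
  }
  joined <- dplyr::inner_join(as_tibble(ra),
                              as_tibble(rb)[, c("chrom", "start", "value")],
                              by = c("chrom", "start"), suffix = c("_a", "_b"))
  if (nrow(joined) < 3) abort("fewer than 3 jointly covered bins")
  cor(joined$value_a, joined$value_b)
}
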