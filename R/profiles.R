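# S/G1 timing profiles. The normalized, smoothed S-phase to G1-phase read
# depth ratio is a surrogate for replication timing: a locus replicating
# early is present in more copies in S-sorted cells, so its S/G1 ratio is
# high. A factor 1.4 maps observed ratios near the theoretical 1-2 range.

#' Scaled S/G1 ratio profile
#'
#' Divides a (normalized, smoothed) S track by the matching G1 track per bin
#' and multiplies by `scale_factor`. Bins covered in only one input are
#' uncovered in the output; covered G1 bins with value 0 are masked with a
#' warning rather than erroring, since SNP deserts make them routine.
#'
#' @param s,g1 Tracks from the same homolog, binned, normalized and smoothed
#'   with the same parameters.
#' @param scale_factor Unitless scaling (default 1.4, chosen so observed
#'   ratios fall near the theoretical 1-2 copy-number range).
#' @param homolog Label stored on the profile: `"maternal"`, `"paternal"` or
#'   `"combined"`.
#' @return A `timex_profile` track.
#' @export
timex_ratio <- function(s, g1, scale_factor = 1.4,
                        homolog = c("maternal", "paternal", "combined")) {
  homolog <- match.arg(homolog)
  if (!isTRUE(all.equal(bin_width(s), bin_width(g1)))) {
    abort("`s` and `g1` must share a bin width")
  }
  joined <- dplyr::inner_join(
    as_tibble(s), as_tibble(g1)[, c("chrom", "start", "value")],
    by = c("chrom", "start"), suffix = c("_s", "_g1"))
  zero <- joined$value_g1 == 0
  if (any(zero)) {
    warn(sprintf("%d covered bins with zero G1 signal masked", sum(zero)))
    joined <- joined[!zero, ]
  }
  out <- tibble(chrom = joined$chrom, start = joined$start, end = joined$end,
                value = scale_factor * (joined$value_s / joined$value_g1))
  new_track(out, bin_width(s), chrom_lengths(s),
            sigma = attr(s, "sigma"), scale_factor = scale_factor,
            homolog = homolog, class = "timex_profile")
}

#' Build an allele-specific timing profile from an allele-depth table
#'
#' The standard pipeline for one homolog: bin S and G1 depths into
#' `bin_width` windows, normalize each track to its total, Gaussian-smooth
#' both, then form the scaled S/G1 ratio.
#'
#' @param depths Allele-depth tibble.
#' @param homolog `"maternal"` or `"paternal"`.
#' @param bin_width Window width in bp (default 500).
#' @param sigma Gaussian smoothing sigma in bp (default 100 kb).
#' @param scale_factor S/G1 scaling (default 1.4).
#' @param chrom_lengths Optional chromosome lengths (else taken from the
#'   table).
#' @return A `timex_profile`.
#' @export
build_profile <- function(depths, homolog = c("maternal", "paternal"),
                          bin_width = 500, sigma = 1e5, scale_factor = 1.4,
                          chrom_lengths = NULL) {
  homolog <- match.arg(homolog)
  s <- bin_depths(depths, homolog, "s", bin_width, chrom_lengths) |>
    normalize_track() |> gaussian_smooth(sigma)
  g1 <- bin_depths(depths, homolog, "g1", bin_width, chrom_lengths) |>
    normalize_track() |> gaussian_smooth(sigma)
  timex_ratio(s, g1, scale_factor, homolog)
}

#' Mask of low SNP-density regions
#'
#' Flags fixed-width windows whose SNP count falls below `min_density` and
#' merges adjacent flagged windows, yielding intervals where timing values
#' are unreliable and should be excluded from downstream statistics (via
#' [apply_mask()]).
#'
#' @param positions SNP tibble (`chrom`, `pos`).
#' @param min_density Minimum SNPs per bp (e.g. `1/5000`).
#' @param window Window width in bp used to assess density.
#' @param chrom_lengths Chromosome lengths (else taken from `positions`).
#' @return Sorted, merged interval tibble.
#' @export
low_snp_mask <- function(positions, min_density = 1 / 5000, window = 1e5,
                         chrom_lengths = NULL) {
  cl <- as_chrom_lengths(chrom_lengths %||% attr(positions, "chrom_lengths") %||%
    vapply(split(positions$pos, positions$chrom), function(p) max(p) + 1, 0))
  counts <- positions |>
    mutate(bin = floor(.data$pos / window)) |>
    dplyr::count(.data$chrom, .data$bin)
  grid <- dplyr::bind_rows(imap(as.list(cl), function(len, ch) {
    tibble(chrom = ch, bin = seq_len(n_bins(len, window)) - 1)
  }))
  low <- grid |>
    dplyr::left_join(counts, by = c("chrom", "bin")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           start = .data$bin * window,
           end = pmin(.data$start + window, cl[.data$chrom])) |>
    dplyr::filter(.data$n / (.data$end - .data$start) < min_density)
  if (nrow(low) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  merge_intervals(low[, c("chrom", "start", "end")])
}

#' High-resolution (non-allele-specific) timing profile
#'
#' For deeply sequenced libraries where every read counts (not only
#' SNP-overlapping ones): S and G1 read counts in 1 kb bins are normalized
#' to their totals, the per-bin ratio is formed, outlier bins with raw ratio
#' above `outlier_cut` are removed, the ratio track is Gaussian-smoothed at
#' a light `sigma`, and finally the values are affinely indexed so the
#' covered minimum maps to 1 and the maximum to 2.
#'
#' @param s_reads,g1_reads Read-count tracks at matching (1 kb) bins.
#' @param outlier_cut Raw-ratio cutoff (default 2.4).
#' @param sigma Smoothing sigma in bp (default 20 kb).
#' @param robust If `TRUE`, index using the 0.1/99.9 covered percentiles
#'   (then clamp) instead of the strict min/max.
#' @return A `timex_profile` with values in \[1, 2\].
#' @export
hires_profile <- function(s_reads, g1_reads, outlier_cut = 2.4, sigma = 2e4,
                          robust = FALSE) {
  s <- normalize_track(s_reads)
  g1 <- normalize_track(g1_reads)
  raw_s <- as_tibble(s_reads)
  raw_g <- as_tibble(g1_reads)[, c("chrom", "start", "value")]
  raw <- dplyr::inner_join(raw_s, raw_g, by = c("chrom", "start"),
                           suffix = c("_s", "_g1"))
  ratio <- timex_ratio(s, g1, scale_factor = 1, homolog = "combined")
  raw_ratio <- ifelse(raw$value_g1 > 0, raw$value_s / raw$value_g1, Inf)
  bad <- raw[raw_ratio > outlier_cut, c("chrom", "start")]
  if (nrow(bad) > 0) {
    ratio <- rebuild_track(
      dplyr::anti_join(as_tibble(ratio), bad, by = c("chrom", "start")), ratio)
  }
  sm <- gaussian_smooth(ratio, sigma)
  if (robust) {
    rng <- quantile(sm$value, c(0.001, 0.999), names = FALSE)
  } else {
    rng <- range(sm$value)
  }
  if (diff(rng) == 0) abort("degenerate constant profile cannot be indexed")
  sm$value <- pmin(pmax(1 + (sm$value - rng[1]) / diff(rng), 1), 2)
  out <- new_track(sm, bin_width(s_reads), chrom_lengths(s_reads),
                   sigma = sigma, scale_factor = 1, homolog = "combined",
                   class = "timex_profile")
  out
}

#' Saturate track outliers at mean + 3 SD
#'
#' Values above the covered-bin mean plus three standard deviations are set
#' to exactly that cap; everything else is unchanged.
#'
#' @param track A [new_track()] with at least 2 covered bins.
#' @return The saturated track.
#' @export
saturate_outliers <- function(track) {
  if (nrow(track) < 2) abort("need at least 2 covered bins")
  cap <- mean(track$value) + 3 * sd(track$value)
  track$value <- pmin(track$value, cap)
  track
}

#' Combine allele-depth tables across individuals
#'
#' Sums per-SNP, per-homolog, per-fraction depths over several individuals
#' (union of SNP positions; absent SNPs count 0), producing the combined
#' table used to raise effective read depth.
#'
#' @param ... Allele-depth tibbles (or a single list of them).
#' @return Combined allele-depth tibble.
#' @export
combine_allele_depths <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) && !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) == 0) abort("no tables given")
  cl <- attr(tables[[1]], "chrom_lengths")
  out <- dplyr::bind_rows(tables) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(dplyr::across(c("mat_s", "pat_s", "mat_g1", "pat_g1"), sum),
              .groups = "drop") |>
    arrange(.data$chrom, .data$pos)
  attr(out, "chrom_lengths") <- cl
  out
}
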