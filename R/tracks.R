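# Binned genomic tracks. A track is a tibble with columns chrom, start, end,
# value holding *covered* bins only (a bin with no data is simply absent),
# plus attributes `bin_width` and `chrom_lengths`. Bins tile each chromosome
# from 0 in steps of `bin_width`; the last bin may be truncated.

#' Construct a binned track
#'
#' A `timex_track` is a tidy representation of a fixed-width binned genomic
#' signal: one row per *covered* bin (columns `chrom`, `start`, `end`,
#' `value`; 0-based half-open coordinates). Bins without data carry no row,
#' which is how coverage gaps -- routine in SNP-based tracks because of the
#' haplotype structure of the genome -- are represented.
#'
#' @param x Data frame with columns `chrom`, `start`, `end`, `value`.
#' @param bin_width Bin width in bp.
#' @param chrom_lengths Named numeric vector (or data frame with `chrom`,
#'   `length`) of chromosome lengths in bp.
#' @param ... Further attributes (e.g. `sigma`, `homolog`) stored on the
#'   object.
#' @param class Additional S3 classes to prepend.
#' @return A `timex_track` tibble sorted by position.
#' @export
new_track <- function(x, bin_width, chrom_lengths, ..., class = character()) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  out <- sort_intervals(as_tibble(x)[, c("chrom", "start", "end", "value")])
  attr(out, "bin_width") <- as.numeric(bin_width)
  attr(out, "chrom_lengths") <- as_chrom_lengths(chrom_lengths)
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c(class, "timex_track", class(tibble()))
  out
}

#' @rdname new_track
#' @export
bin_width <- function(x) attr(x, "bin_width")

#' @rdname new_track
#' @export
chrom_lengths <- function(x) attr(x, "chrom_lengths")

n_bins <- function(len, w) as.integer(ceiling(len / w))

# Rebuild a track after dplyr verbs stripped its attributes.
rebuild_track <- function(x, template, value = x$value) {
  new_track(x, bin_width(template), chrom_lengths(template),
            class = setdiff(class(template), c("timex_track", class(tibble()))))
}

#' Bin per-SNP allele depths into a fixed-width track
#'
#' Sums the read depth of one homolog and one cell-cycle fraction over
#' fixed-width genomic windows. A SNP at 0-based position `p` falls in bin
#' `floor(p / bin_width)` (half-open bins). Bins containing no SNP are left
#' uncovered.
#'
#' @param depths Allele-depth table: tibble with `chrom`, `pos` (0-based) and
#'   depth columns `mat_s`, `pat_s`, `mat_g1`, `pat_g1` (see
#'   [simulate_allele_depths()] / [read_allele_depths()]).
#' @param homolog `"maternal"` or `"paternal"`.
#' @param fraction `"s"` or `"g1"`.
#' @param bin_width Window width in bp (default 500).
#' @param chrom_lengths Chromosome lengths; taken from the table's
#'   `chrom_lengths` attribute when `NULL`, or inferred from the data.
#' @return A [new_track()] of summed depths.
#' @export
bin_depths <- function(depths, homolog = c("maternal", "paternal"),
                       fraction = c("s", "g1"), bin_width = 500,
                       chrom_lengths = NULL) {
  homolog <- match.arg(homolog)
  fraction <- match.arg(fraction)
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  col <- paste0(substr(homolog, 1, 3), "_", fraction)
  if (!col %in% names(depths)) abort(sprintf("column `%s` missing", col))
  cl <- chrom_lengths %||% attr(depths, "chrom_lengths") %||%
    vapply(split(depths$pos, depths$chrom), function(p) max(p) + 1, 0)
  cl <- as_chrom_lengths(cl)
  out <- depths |>
    mutate(bin = floor(.data$pos / bin_width)) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(value = sum(.data[[col]]), .groups = "drop") |>
    mutate(start = .data$bin * bin_width,
           end = pmin(.data$start + bin_width, cl[.data$chrom])) |>
    select("chrom", "start", "end", "value")
  new_track(out, bin_width, cl)
}

#' Normalize a track to its total
#'
#' Divides every covered value by the track-wide sum, so that tracks from
#' libraries of different depth become comparable (each track then sums to 1
#' over its covered bins).
#'
#' @param track A [new_track()].
#' @return The normalized track; coverage is unchanged.
#' @export
normalize_track <- function(track) {
  tot <- sum(track$value)
  if (!is.finite(tot) || tot <= 0) abort("track total must be > 0")
  track$value <- track$value / tot
  track
}

#' Gaussian-smooth a track across coverage gaps
#'
#' Replaces each covered bin by the weighted mean of covered bins, with
#' weights `exp(-d^2 / (2 sigma^2))` in genomic distance `d` between bin
#' centers, truncated at `4 sigma` and renormalized over covered bins only.
#' Uncovered bins stay uncovered. Computed by FFT convolution of the value
#' and coverage-indicator grids, which is exactly the covered-weight
#' renormalization.
#'
#' @param track A [new_track()].
#' @param sigma Kernel standard deviation in bp.
#' @return Smoothed track with identical coverage.
#' @export
gaussian_smooth <- function(track, sigma) {
  if (sigma <= 0) abort("`sigma` must be > 0")
  w <- bin_width(track)
  cl <- chrom_lengths(track)
  half <- as.integer(ceiling(4 * sigma / w))
  kern <- exp(-((-half:half) * w)^2 / (2 * sigma^2))
  parts <- lapply(split(track, track$chrom), function(sub) {
    ch <- sub$chrom[1]
    n <- n_bins(cl[[ch]], w)
    idx <- as.integer(sub$start / w) + 1L
    v <- numeric(n); v[idx] <- sub$value
    cvg <- numeric(n); cvg[idx] <- 1
    num <- conv_same(v, kern)
    den <- conv_same(cvg, kern)
    sub$value <- num[idx] / den[idx]
    sub
  })
  out <- rebuild_track(dplyr::bind_rows(parts), track)
  attr(out, "sigma") <- sigma
  out
}

# Same-size linear convolution with a symmetric odd-length kernel (FFT based).
conv_same <- function(x, k) {
  n <- length(x)
  half <- (length(k) - 1L) %/% 2L
  if (n == 0) return(x)
  full <- convolve(x, k, type = "open")
  full[(half + 1L):(half + n)]
}

#' Rebin a track to a coarser resolution
#'
#' Averages covered fine bins inside each coarse bin; coarse bins with no
#' covered fine bin are uncovered.
#'
#' @param track A [new_track()].
#' @param new_width New bin width in bp (need not be a multiple of the old).
#' @return A [new_track()] at `new_width`.
#' @export
rebin_track <- function(track, new_width) {
  if (new_width <= 0) abort("`new_width` must be > 0")
  cl <- chrom_lengths(track)
  mids <- (track$start + track$end) / 2
  out <- tibble(chrom = track$chrom, bin = floor(mids / new_width),
                value = track$value) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    mutate(start = .data$bin * new_width,
           end = pmin(.data$start + new_width, cl[.data$chrom])) |>
    select("chrom", "start", "end", "value")
  new_track(out, new_width, cl)
}

#' Remove masked regions from a track
#'
#' Marks bins overlapping the mask as uncovered (their rows are dropped);
#' no values are changed.
#'
#' @param track A [new_track()].
#' @param mask Interval tibble (`chrom`, `start`, `end`), e.g. from
#'   [low_snp_mask()].
#' @return The masked track.
#' @export
apply_mask <- function(track, mask) {
  check_intervals(mask, "mask")
  keep <- !overlaps_any(track, mask)
  rebuild_track(track[keep, ], track)
}
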