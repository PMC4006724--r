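# Synthetic phased allele-depth data with the statistical structure the
# S/G1 timing method assumes: heterogeneous SNP density, megabase-scale
# timing domains on the theoretical 1-2 scale, Poisson sequencing noise,
# and a binomial resampler with spike-in regions of configurable S-phase
# read excess.

#' Specify a synthetic genome
#'
#' Bundles the parameters of the synthetic-data generator. Defaults emulate
#' the study conditions of a family-phased human dataset: SNP spacing varying
#' between 1 SNP per 500 bp and 1 per 5 kb in haplotype-like blocks, ~25
#' reads per SNP per cell-cycle fraction per homolog, and megabase-scale
#' replication-timing domains.
#'
#' @param chrom_lengths Named numeric vector (or `chrom`/`length` data frame)
#'   of chromosome lengths in bp.
#' @param snp_spacing Length-2 numeric: minimum and maximum bp per SNP.
#' @param mean_depth Mean reads per SNP per fraction per homolog.
#' @param timing_domain_scale Characteristic width (bp) of timing domains.
#' @param seed Integer seed; all generators derive per-stage seeds from it.
#' @return A `synth_genome_spec` list.
#' @export
synth_genome_spec <- function(chrom_lengths, snp_spacing = c(500, 5000),
                              mean_depth = 25, timing_domain_scale = 1e6,
                              seed = 1L) {
  cl <- as_chrom_lengths(chrom_lengths)
  if (length(snp_spacing) != 2 || snp_spacing[1] < 1 ||
      snp_spacing[1] > snp_spacing[2]) {
    abort("`snp_spacing` must be (min_bp_per_snp, max_bp_per_snp) with 1 <= min <= max")
  }
  if (mean_depth <= 0) abort("`mean_depth` must be > 0")
  if (timing_domain_scale <= 0) abort("`timing_domain_scale` must be > 0")
  structure(list(chrom_lengths = cl, snp_spacing = as.numeric(snp_spacing),
                 mean_depth = mean_depth,
                 timing_domain_scale = timing_domain_scale,
                 seed = as.integer(seed)),
            class = "synth_genome_spec")
}

#' Generate heterozygous SNP positions with block-varying density
#'
#' Positions are laid out in piecewise-constant density blocks of 100 kb to
#' 1 Mb: each block draws one spacing uniformly between the configured
#' bounds and places SNPs at that spacing, so local density always stays
#' within the bounds while SNP-poor stretches (up to the maximum spacing)
#' exist, as in real haplotype structure.
#'
#' @param spec A [synth_genome_spec()].
#' @param seed Optional override of the spec's derived seed.
#' @return Tibble with `chrom`, `pos` (0-based), sorted and unique.
#' @export
gen_snp_positions <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  withr::local_seed(seed %||% derive_seed(spec$seed, "snp_positions"))
  sp <- spec$snp_spacing
  parts <- imap(as.list(spec$chrom_lengths), function(len, ch) {
    if (len <= 0) abort("zero-length chromosome")
    # density blocks
    n_blk <- max(1L, ceiling(len / 1e5))
    blk_len <- runif(n_blk, 1e5, 1e6)
    blk_end <- pmin(cumsum(blk_len), len)
    blk_start <- c(0, head(blk_end, -1))
    keep <- blk_start < len
    blk_start <- blk_start[keep]; blk_end <- blk_end[keep]
    spacing <- runif(length(blk_start), sp[1], sp[2])
    pos <- unlist(map(seq_along(blk_start), function(i) {
      first <- blk_start[i] + runif(1, 0, spacing[i])
      if (first >= blk_end[i]) return(numeric(0))
      seq(first, blk_end[i] - 1e-9, by = spacing[i])
    }))
    tibble(chrom = ch, pos = sort(unique(floor(pos))))
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "chrom_lengths") <- spec$chrom_lengths
  out
}

#' Generate a smooth replication-timing landscape
#'
#' Produces a "true" timing track with values in \[1, 2\] (1 = latest
#' replicating, 2 = earliest, matching the theoretical S/G1 copy-number
#' range) autocorrelated at the spec's domain scale: Gaussian-filtered white
#' noise, affinely mapped so the realized values span \[1, 2\]. Both
#' homologs are assumed to share this landscape unless regions are spiked.
#'
#' @param spec A [synth_genome_spec()].
#' @param constant If non-`NULL`, return a flat landscape at this value.
#' @param bin_width Resolution of the landscape track (bp).
#' @param seed Optional seed override.
#' @return A [new_track()] of true timing values.
#' @export
gen_timing_landscape <- function(spec, constant = NULL, bin_width = 1e4,
                                 seed = NULL) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  withr::local_seed(seed %||% derive_seed(spec$seed, "timing_landscape"))
  cl <- spec$chrom_lengths
  grid <- dplyr::bind_rows(imap(as.list(cl), function(len, ch) {
    n <- n_bins(len, bin_width)
    start <- (seq_len(n) - 1) * bin_width
    tibble(chrom = ch, start = start, end = pmin(start + bin_width, len),
           value = if (is.null(constant)) rnorm(n) else constant)
  }))
  track <- new_track(grid, bin_width, cl)
  if (!is.null(constant)) return(track)
  # Kernel sigma = scale / sqrt(2) so the field's autocorrelation falls to
  # exp(-1/2) at lag = timing_domain_scale.
  sm <- gaussian_smooth(track, spec$timing_domain_scale / sqrt(2))
  rng <- range(sm$value)
  if (diff(rng) == 0) {
    sm$value <- rep(1.5, nrow(sm))
  } else {
    sm$value <- 1 + (sm$value - rng[1]) / diff(rng)
  }
  attr(sm, "sigma") <- NULL
  sm
}

#' Draw per-SNP allele depths from a timing landscape
#'
#' For each SNP and each homolog independently, the G1 depth is
#' `Poisson(mean_depth)` and the S depth `Poisson(mean_depth * t / tbar)`,
#' where `t` is the local true timing value and `tbar` its mean across SNPs:
#' early regions (high `t`) are over-represented in S-phase DNA, so the
#' normalized S/G1 ratio recovers the landscape.
#'
#' @param positions SNP positions from [gen_snp_positions()].
#' @param timing Timing track from [gen_timing_landscape()].
#' @param spec A [synth_genome_spec()].
#' @param seed Optional seed override.
#' @return Allele-depth tibble: `chrom`, `pos`, `mat_s`, `pat_s`, `mat_g1`,
#'   `pat_g1`.
#' @export
gen_depths <- function(positions, timing, spec, seed = NULL) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  withr::local_seed(seed %||% derive_seed(spec$seed, "depths"))
  w <- bin_width(timing)
  key <- paste0(timing$chrom, ":", floor(timing$start / w))
  lut <- setNames(timing$value, key)
  t_snp <- unname(lut[paste0(positions$chrom, ":", floor(positions$pos / w))])
  if (anyNA(t_snp)) abort("timing track does not cover all SNP positions")
  lam_s <- spec$mean_depth * t_snp / mean(t_snp)
  n <- length(t_snp)
  out <- tibble(chrom = positions$chrom, pos = positions$pos,
                mat_s = rpois(n, lam_s), pat_s = rpois(n, lam_s),
                mat_g1 = rpois(n, spec$mean_depth),
                pat_g1 = rpois(n, spec$mean_depth))
  attr(out, "chrom_lengths") <- spec$chrom_lengths
  out
}

#' One-call synthetic allele-depth dataset
#'
#' Convenience wrapper chaining [gen_snp_positions()],
#' [gen_timing_landscape()] and [gen_depths()].
#'
#' @inheritParams gen_snp_positions
#' @param constant Optional flat timing value (see [gen_timing_landscape()]).
#' @return List with `positions`, `timing`, and `depths`.
#' @export
simulate_allele_depths <- function(spec, constant = NULL) {
  positions <- gen_snp_positions(spec)
  timing <- gen_timing_landscape(spec, constant = constant)
  list(positions = positions, timing = timing,
       depths = gen_depths(positions, timing, spec))
}

#' Binomial resampling of S-phase read counts
#'
#' Draws a resampled S count `~ Binomial(n = total, p = s / total)` per SNP;
#' the resampled G1 count is `total - draw`. Applied to both homologs of an
#' observed table this produces a null control pair whose homolog
#' differences are purely binomial.
#'
#' @param s_depth,total_depth Integer vectors, `0 <= s_depth <= total_depth`.
#' @param seed Optional integer seed.
#' @return Integer vector of resampled S counts.
#' @export
resample_binomial <- function(s_depth, total_depth, seed = NULL) {
  if (any(s_depth < 0) || any(total_depth < 0) || any(s_depth > total_depth)) {
    abort("need 0 <= s_depth <= total_depth")
  }
  force(s_depth); force(total_depth)
  if (!is.null(seed)) withr::local_seed(seed)
  p <- ifelse(total_depth > 0, s_depth / total_depth, 0)
  rbinom(length(s_depth), as.integer(round(total_depth)), p)
}

#' Resample a whole allele-depth table
#'
#' Applies [resample_binomial()] to each homolog independently, preserving
#' each SNP's total (S + G1) depth.
#'
#' @param depths Allele-depth tibble.
#' @param seed Integer seed.
#' @return Resampled allele-depth tibble.
#' @export
resample_depths <- function(depths, seed = NULL) {
  force(depths)
  if (!is.null(seed)) withr::local_seed(seed)
  mt <- depths$mat_s + depths$mat_g1
  pt <- depths$pat_s + depths$pat_g1
  ms <- resample_binomial(depths$mat_s, mt)
  ps <- resample_binomial(depths$pat_s, pt)
  out <- depths
  out$mat_s <- ms; out$mat_g1 <- mt - ms
  out$pat_s <- ps; out$pat_g1 <- pt - ps
  out
}

#' Build a matched homolog control pair from one source homolog
#'
#' Copies one homolog's observed S and G1 depths onto both homolog columns,
#' so that a subsequent resampling (e.g. [spike_regions()], which resamples
#' each homolog independently) yields a null control pair whose differences
#' are purely binomial -- the scheme spike-in simulations use: both
#' simulated homologs are imputed from the S and total read counts observed
#' for each SNP on a single source homolog.
#'
#' @param depths Allele-depth tibble.
#' @param source `"maternal"` or `"paternal"`: the homolog supplying the
#'   counts.
#' @return Allele-depth tibble with identical homolog columns.
#' @export
make_control_pair <- function(depths, source = c("maternal", "paternal")) {
  source <- match.arg(source)
  out <- depths
  if (source == "maternal") {
    out$pat_s <- out$mat_s; out$pat_g1 <- out$mat_g1
  } else {
    out$mat_s <- out$pat_s; out$mat_g1 <- out$pat_g1
  }
  out
}

#' Spike asynchronous regions into an allele-depth table
#'
#' Inside each spike interval, the target homolog's total (S + G1) read
#' count is inflated by `excess_fraction` -- `round(total * (1 + excess))`,
#' all extra reads assigned to S -- and the inflated (S, total) pair is then
#' passed through the binomial resampler; every other SNP/homolog pair is
#' resampled unchanged. This emulates one homolog replicating earlier over
#' the spiked region.
#'
#' @param depths Allele-depth tibble.
#' @param intervals Non-overlapping spike intervals (`chrom`, `start`, `end`).
#' @param excess_fraction Fractional total-read excess (e.g. 0.10 for 10%).
#' @param target `"maternal"` or `"paternal"`: the homolog made earlier.
#' @param seed Integer seed.
#' @return Resampled, spiked allele-depth tibble.
#' @export
spike_regions <- function(depths, intervals, excess_fraction,
                          target = c("maternal", "paternal"), seed = NULL) {
  target <- match.arg(target)
  check_intervals(intervals, "intervals")
  if (excess_fraction < 0) abort("`excess_fraction` must be >= 0")
  force(depths)
  if (!is.null(seed)) withr::local_seed(seed)
  snp_iv <- tibble(chrom = depths$chrom, start = depths$pos,
                   end = depths$pos + 1)
  inside <- overlaps_any(snp_iv, intervals)
  s_col <- if (target == "maternal") "mat_s" else "pat_s"
  g_col <- if (target == "maternal") "mat_g1" else "pat_g1"
  tot <- depths[[s_col]] + depths[[g_col]]
  new_tot <- as.integer(ifelse(inside, round(tot * (1 + excess_fraction)), tot))
  new_s <- depths[[s_col]] + (new_tot - tot)
  out <- depths
  draw <- resample_binomial(new_s, new_tot)
  out[[s_col]] <- draw
  out[[g_col]] <- new_tot - draw
  o_s <- if (target == "maternal") "pat_s" else "mat_s"
  o_g <- if (target == "maternal") "pat_g1" else "mat_g1"
  o_tot <- depths[[o_s]] + depths[[o_g]]
  o_draw <- resample_binomial(depths[[o_s]], o_tot)
  out[[o_s]] <- o_draw
  out[[o_g]] <- o_tot - o_draw
  out
}

#' Place random non-overlapping regions
#'
#' Draws `n` intervals with sizes sampled uniformly from `size_choices` and
#' uniform start positions (chromosomes weighted by length), rejecting
#' placements that overlap an already accepted interval.
#'
#' @param n Number of regions.
#' @param size_choices Numeric vector of candidate sizes (bp).
#' @param chrom_lengths Genome (named lengths or `chrom`/`length` frame).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget (default `200 * n`).
#' @return Sorted interval tibble `chrom`, `start`, `end`, `size`.
#' @export
place_random_regions <- function(n, size_choices, chrom_lengths, seed = NULL,
                                 max_tries = 200 * n) {
  cl <- as_chrom_lengths(chrom_lengths)
  force(size_choices)
  if (!is.null(seed)) withr::local_seed(seed)
  if (max(size_choices) > max(cl)) abort("region size exceeds every chromosome")
  placed <- vector("list", n)
  k <- 0L; tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > max_tries) abort("could not place non-overlapping regions")
    size <- if (length(size_choices) == 1) size_choices else sample(size_choices, 1)
    ok <- cl >= size
    ch <- sample(names(cl)[ok], 1, prob = cl[ok])
    start <- floor(runif(1, 0, cl[[ch]] - size + 1))
    cand <- tibble(chrom = ch, start = start, end = start + size, size = size)
    if (k > 0) {
      prev <- dplyr::bind_rows(placed[seq_len(k)])
      if (any(overlaps_any(cand, prev))) next
    }
    k <- k + 1L
    placed[[k]] <- cand
  }
  sort_intervals(dplyr::bind_rows(placed))
}
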