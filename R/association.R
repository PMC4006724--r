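# Replication-origin (nascent-strand) peak post-processing and
# feature-association statistics: width normalization, top-N selection,
# 1 bp-overlap association with feature windows, bootstrap enrichment,
# per-S-fraction origin statistics, GC/repeat content, and allele-specific
# nascent-strand ratios per asynchronous domain.

#' Fixed-width windows centered on genomic features
#'
#' Builds the windows the association statistics use: 1 kb windows centered
#' on transcription start sites and 400 bp windows centered on feature
#' midpoints (G-quadruplex motifs, DNase I hypersensitive sites). CpG
#' islands are used as given.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `strand` for
#'   TSS anchoring).
#' @param width Window width in bp.
#' @param anchor `"midpoint"` (default) or `"start_site"` (uses `start`, or
#'   `end` on minus-strand rows).
#' @param chrom_lengths Optional lengths used to clip windows to chromosome
#'   bounds.
#' @return Interval tibble of windows.
#' @export
feature_windows <- function(x, width = 400,
                            anchor = c("midpoint", "start_site"),
                            chrom_lengths = NULL) {
  anchor <- match.arg(anchor)
  check_intervals(x)
  center <- if (anchor == "midpoint") (x$start + x$end) / 2
  else if ("strand" %in% names(x)) ifelse(x$strand == "-", x$end, x$start)
  else x$start
  out <- tibble(chrom = x$chrom,
                start = pmax(0, floor(center - width / 2)),
                end = floor(center + width / 2))
  if (!is.null(chrom_lengths)) {
    cl <- as_chrom_lengths(chrom_lengths)
    out$end <- pmin(out$end, cl[out$chrom])
  }
  sort_intervals(out)
}

#' Normalize peak widths and merge
#'
#' Replaces each peak by a `width`-bp window centered on its midpoint, then
#' merges overlapping windows (merged windows count once -- with dense peak
#' sets this roughly halves the peak number).
#'
#' @param peaks Interval tibble.
#' @param width Target width in bp (default 400).
#' @return Merged interval tibble; isolated peaks have width exactly
#'   `width`.
#' @export
normalize_peak_widths <- function(peaks, width = 400) {
  if (width <= 0) abort("`width` must be > 0")
  merge_intervals(feature_windows(peaks, width, "midpoint"))
}

#' Keep the top-scoring peaks
#'
#' @param peaks Interval tibble with a `score` column.
#' @param n Number kept (default 100000); ties broken stably by genomic
#'   position.
#' @return Sorted interval tibble of at most `n` peaks.
#' @export
top_n_peaks <- function(peaks, n = 100000) {
  if (!"score" %in% names(peaks)) abort("`peaks` needs a `score` column")
  kept <- peaks |>
    arrange(dplyr::desc(.data$score), .data$chrom, .data$start) |>
    head(n)
  sort_intervals(kept)
}

#' Percent of peaks associated with a feature set
#'
#' A peak is associated when it overlaps any feature window by one base
#' pair or more.
#'
#' @param peaks Non-empty interval tibble.
#' @param features Interval tibble of feature windows.
#' @return Percent in \[0, 100\].
#' @export
percent_associated <- function(peaks, features) {
  if (nrow(peaks) == 0) abort("`peaks` is empty")
  100 * mean(overlaps_any(peaks, features))
}

#' Bootstrap enrichment of peak-feature association
#'
#' Compares the observed percent of peaks associated with a feature set to
#' the mean over `iters` randomizations in which the peaks are re-placed
#' uniformly within the territory ([randomize_intervals()]).
#'
#' @param peaks,features Interval tibbles.
#' @param territory Territory for random placement.
#' @param iters Randomization count (default 100).
#' @param seed Integer seed.
#' @return One-row tibble: `observed_pct`, `mean_random_pct`, `fold`
#'   (`NA` with a warning if the random mean is 0), `iters`.
#' @export
bootstrap_enrichment <- function(peaks, features, territory, iters = 100,
                                 seed = NULL) {
  if (iters < 1) abort("`iters` must be >= 1")
  force(peaks); force(features); force(territory)
  if (!is.null(seed)) withr::local_seed(seed)
  obs <- percent_associated(peaks, features)
  rand <- vapply(seq_len(iters), function(i) {
    percent_associated(randomize_intervals(peaks, territory), features)
  }, 0)
  mr <- mean(rand)
  if (mr == 0) warn("mean random association is 0: fold undefined")
  tibble(observed_pct = obs, mean_random_pct = mr,
         fold = if (mr > 0) obs / mr else NA_real_, iters = iters)
}

#' Origin statistics per S-phase fraction
#'
#' For each fraction of a genome partition: mean nascent-strand read signal
#' per 5 kb window, peak count and per-Mb rate, mean peak area, and the
#' median distance between consecutive peaks lying in the same fraction
#' segment.
#'
#' @param ns_reads Nascent-strand read track.
#' @param ns_peaks Peak tibble with an `area` column (e.g. from
#'   [call_residual_peaks()]).
#' @param fractions Partition tibble from [partition_s_fractions()]
#'   (`chrom`, `start`, `end`, `fraction`).
#' @param density_bin Window for the read-density statistic (default 5 kb).
#' @return Tibble, one row per fraction: `fraction`, `mean_reads_per_window`,
#'   `n_peaks`, `peaks_per_mb`, `mean_peak_area`, `median_interpeak_bp`
#'   (`NA` where a fraction holds < 2 peaks).
#' @export
fraction_origin_stats <- function(ns_reads, ns_peaks, fractions,
                                  density_bin = 5000) {
  reads5 <- rebin_track(ns_reads, density_bin)
  mids <- tibble(chrom = ns_peaks$chrom,
                 start = floor((ns_peaks$start + ns_peaks$end) / 2),
                 end = floor((ns_peaks$start + ns_peaks$end) / 2) + 1)
  rows <- lapply(split(fractions, fractions$fraction), function(fr) {
    seg_of_peak <- match_max_overlap(mids, fr)
    inside <- which(!is.na(seg_of_peak))
    pk <- ns_peaks[inside, ]
    seg <- seg_of_peak[inside]
    interpeak <- unlist(lapply(split(seq_len(nrow(pk)), seg), function(ix) {
      if (length(ix) < 2) return(numeric(0))
      p <- pk[ix, ][order(pk$start[ix]), ]
      p$start[-1] - p$end[-nrow(p)]
    }))
    win_in <- overlaps_any(reads5, fr)
    tibble(fraction = fr$fraction[1],
           mean_reads_per_window = mean(reads5$value[win_in]),
           n_peaks = nrow(pk),
           peaks_per_mb = nrow(pk) / (total_width(fr) / 1e6),
           mean_peak_area = if (nrow(pk) > 0) mean(pk$area) else NA_real_,
           median_interpeak_bp = if (length(interpeak) > 0)
             median(interpeak) else NA_real_)
  })
  dplyr::bind_rows(rows) |> arrange(.data$fraction)
}

#' Sliding-window GC content from sequence
#'
#' Percent G+C in `window`-bp windows evaluated every `step` bp.
#'
#' @param seq A named list (or character vector) of chromosome sequences
#'   (plain character strings, case-insensitive).
#' @param window Window width in bp (default 100 kb).
#' @param step Evaluation step in bp (default 10 kb).
#' @return A [new_track()] of percent GC (bins of width `step`; the value at
#'   a bin is the GC percent of the `window`-wide window centered on it,
#'   clipped at the chromosome ends).
#' @export
gc_content_windows <- function(seq, window = 1e5, step = 1e4) {
  seq <- as.list(seq)
  cl <- vapply(seq, nchar, 0)
  parts <- imap(seq, function(s, ch) {
    is_gc <- strsplit(toupper(s), "")[[1]] %in% c("G", "C")
    cs <- c(0, cumsum(is_gc))
    n <- nchar(s)
    starts <- seq(0, n - 1, by = step)
    lo <- pmax(0, starts + step / 2 - window / 2)
    hi <- pmin(n, starts + step / 2 + window / 2)
    tibble(chrom = ch, start = starts, end = pmin(starts + step, n),
           value = 100 * (cs[hi + 1] - cs[lo + 1]) / (hi - lo))
  })
  new_track(dplyr::bind_rows(parts), step, cl)
}

#' Sliding-window repeat content from a repeat annotation
#'
#' Percent of bases covered by repeat intervals (e.g. LINE/SINE/LTR classes)
#' in `window`-bp windows evaluated every `step` bp.
#'
#' @param repeats Interval tibble of repeat elements.
#' @param chrom_lengths Chromosome lengths.
#' @param window,step Window and step in bp (defaults 100 kb / 10 kb).
#' @return A [new_track()] of percent repeat bases.
#' @export
repeat_content_windows <- function(repeats, chrom_lengths, window = 1e5,
                                   step = 1e4) {
  cl <- as_chrom_lengths(chrom_lengths)
  merged <- merge_intervals(repeats)
  parts <- imap(as.list(cl), function(len, ch) {
    sub <- merged[merged$chrom == ch, ]
    starts <- seq(0, len - 1, by = step)
    lo <- pmax(0, starts + step / 2 - window / 2)
    hi <- pmin(len, starts + step / 2 + window / 2)
    # repeat bases in [0, x): width of intervals starting at or before x,
    # minus the part of the last such interval lying beyond x
    cum_cov <- function(x) {
      if (nrow(sub) == 0) return(numeric(length(x)))
      csum <- c(0, cumsum(sub$end - sub$start))
      i <- findInterval(x, sub$start)
      over <- ifelse(i > 0,
                     pmax(0, sub$end[pmax(i, 1)] - pmax(x, sub$start[pmax(i, 1)])),
                     0)
      csum[i + 1] - over
    }
    cov <- cum_cov(hi) - cum_cov(lo)
    tibble(chrom = ch, start = starts, end = pmin(starts + step, len),
           value = 100 * cov / (hi - lo))
  })
  new_track(dplyr::bind_rows(parts), step, cl)
}

#' Allele-specific nascent-strand ratio per asynchronous domain
#'
#' Pairs each domain's maternal/paternal nascent-strand read ratio with its
#' signed timing delay and reports their Pearson correlation; under
#' homolog-independent origin firing the correlation is near zero.
#'
#' @param ards A `timex_ards` tibble (needs `delay_minutes`).
#' @param mat_ns,pat_ns Per-domain nascent-strand read counts (vectors
#'   aligned with `ards` rows).
#' @return Tibble of per-domain `ns_ratio` and `delay_minutes` (domains with
#'   a zero denominator are skipped with a warning); attribute `pearson_r`
#'   holds the correlation.
#' @export
ard_allele_ns_ratio <- function(ards, mat_ns, pat_ns) {
  stopifnot(length(mat_ns) == nrow(ards), length(pat_ns) == nrow(ards))
  bad <- pat_ns == 0
  if (any(bad)) warn(sprintf("%d domains with zero paternal reads skipped", sum(bad)))
  out <- tibble(chrom = ards$chrom[!bad], start = ards$start[!bad],
                end = ards$end[!bad],
                ns_ratio = mat_ns[!bad] / pat_ns[!bad],
                delay_minutes = ards$delay_minutes[!bad])
  attr(out, "pearson_r") <- if (nrow(out) >= 3 && sd(out$ns_ratio) > 0 &&
                                 sd(out$delay_minutes) > 0)
    cor(out$ns_ratio, out$delay_minutes) else NA_real_
  out
}
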