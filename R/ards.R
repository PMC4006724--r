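# Detection of asynchronously replicated domains (ARDs): regions where the
# maternal and paternal homologs replicate at detectably different times.
# Two-step caller: (1) a SICER-style gap-tolerant island finder on the
# difference of the two homolog profiles; (2) a chi-square test on the raw
# read counts summed over each island, with Benjamini-Hochberg FDR control
# genome-wide across all candidate islands of both signs.

#' Island-finder parameters
#'
#' @param diff_threshold Minimum absolute profile difference (timing-ratio
#'   units) for a bin to seed an island. Default 0.02 for ARDs; cores use
#'   0.1.
#' @param max_gap Maximum gap (bp) of sub-threshold or uncovered bins merged
#'   into an island. Default 250 kb for ARDs; cores use 50 kb.
#' @param min_size Minimum island span (bp). Default 50 kb.
#' @return An `island_params` list.
#' @export
island_params <- function(diff_threshold = 0.02, max_gap = 250000,
                          min_size = 50000) {
  if (diff_threshold <= 0 || max_gap <= 0 || min_size <= 0) {
    abort("island parameters must all be > 0")
  }
  structure(list(diff_threshold = diff_threshold, max_gap = max_gap,
                 min_size = min_size), class = "island_params")
}

#' Difference of two homolog profiles
#'
#' Per-bin maternal minus paternal value where both are covered; uncovered
#' elsewhere. Positive values mean the maternal homolog replicates earlier
#' (higher S/G1).
#'
#' @param mat,pat `timex_profile` tracks with identical binning.
#' @return A [new_track()] of differences.
#' @export
difference_track <- function(mat, pat) {
  if (!isTRUE(all.equal(bin_width(mat), bin_width(pat)))) {
    abort("profiles have mismatched bin widths")
  }
  joined <- dplyr::inner_join(
    as_tibble(mat), as_tibble(pat)[, c("chrom", "start", "value")],
    by = c("chrom", "start"), suffix = c("_mat", "_pat"))
  out <- tibble(chrom = joined$chrom, start = joined$start, end = joined$end,
                value = joined$value_mat - joined$value_pat)
  new_track(out, bin_width(mat), chrom_lengths(mat))
}

#' Gap-tolerant signed island finder
#'
#' Finds maximal runs of bins at or above `+diff_threshold` (and separately
#' at or below `-diff_threshold`), merging runs separated by gaps -- of
#' sub-threshold, uncovered, or opposite-sign bins -- of at most `max_gap`
#' bp, and keeps islands spanning at least `min_size` bp. Islands of
#' opposite sign are never merged with each other.
#'
#' @param diff Difference track from [difference_track()].
#' @param params An [island_params()].
#' @return Sorted interval tibble with columns `chrom`, `start`, `end`,
#'   `sign` (+1: maternal earlier, -1: paternal earlier).
#' @export
find_islands <- function(diff, params = island_params()) {
  stopifnot(inherits(params, "island_params"))
  one_sign <- function(sub, sgn) {
    hit <- if (sgn > 0) sub$value >= params$diff_threshold
           else sub$value <= -params$diff_threshold
    sub <- sub[hit, ]
    if (nrow(sub) == 0) return(NULL)
    gap <- c(0, sub$start[-1] - sub$end[-nrow(sub)])
    grp <- cumsum(gap > params$max_gap)
    sub |>
      mutate(grp = grp) |>
      group_by(.data$chrom, .data$grp) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop") |>
      mutate(sign = sgn) |>
      select("chrom", "start", "end", "sign")
  }
  parts <- lapply(split(as_tibble(diff), diff$chrom), function(sub) {
    dplyr::bind_rows(one_sign(sub, 1L), one_sign(sub, -1L))
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  sign = integer()))
  }
  sort_intervals(out[out$end - out$start >= params$min_size, ])
}

#' Chi-square test of homolog-by-fraction read-count independence
#'
#' Pearson chi-square (1 df, no continuity correction; `stats::chisq.test`)
#' on the 2x2 table of summed S and G1 reads of the maternal and paternal
#' homologs. Vectorized over islands. Counts here are typically in the
#' 1e3-1e5 range where the continuity correction is negligible.
#'
#' @param mat_s,mat_g1,pat_s,pat_g1 Non-negative summed read counts
#'   (vectors).
#' @return P-values in \[0, 1\]; a zero row or column marginal yields p = 1
#'   with a warning.
#' @export
island_chisq <- function(mat_s, mat_g1, pat_s, pat_g1) {
  n <- length(mat_s)
  out <- numeric(n)
  bad <- (mat_s + mat_g1) == 0 | (pat_s + pat_g1) == 0 |
    (mat_s + pat_s) == 0 | (mat_g1 + pat_g1) == 0
  if (any(bad)) warn(sprintf("%d tables with a zero marginal: p set to 1", sum(bad)))
  for (i in seq_len(n)) {
    if (bad[i]) { out[i] <- 1; next }
    tab <- matrix(c(mat_s[i], mat_g1[i], pat_s[i], pat_g1[i]), nrow = 2,
                  byrow = TRUE)
    out[i] <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`), as used to
#' control the ARD false discovery rate at 5%.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, order-preserving, `q >= p`.
#' @export
bh_qvalues <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Convert a timing-ratio difference to minutes of replication delay
#'
#' `mean_diff * s_length_min / range_factor`: the S/G1 difference is scaled
#' by the S-phase length (480 min) and corrected by 1.2 because observed
#' profile values span about 0.9-2.1 rather than the theoretical 1-2 (the
#' observed scale is 1.2x wider, so raw differences overstate the S-phase
#' fraction). Signed: positive = maternal earlier.
#'
#' @param mean_diff Mean profile difference over a region.
#' @param s_length_min S-phase length in minutes (default 480).
#' @param range_factor Observed-to-theoretical range ratio (default 1.2).
#'   Set `range_action = "multiply"` to apply it as a multiplication
#'   instead.
#' @param range_action `"divide"` (default) or `"multiply"`.
#' @return Delay in minutes.
#' @export
delay_minutes <- function(mean_diff, s_length_min = 480, range_factor = 1.2,
                          range_action = c("divide", "multiply")) {
  range_action <- match.arg(range_action)
  if (range_action == "divide") mean_diff * s_length_min / range_factor
  else mean_diff * s_length_min * range_factor
}

#' Convert a spike-in read excess to nominal minutes of asynchrony
#'
#' `excess_fraction * s_length_min`: a 10% S-phase read excess corresponds
#' to a nominal 48-minute asynchrony under an 8-hour S phase.
#'
#' @param excess_fraction Fractional read excess (>= 0).
#' @param s_length_min S-phase length in minutes (default 480).
#' @return Minutes of asynchrony.
#' @export
excess_to_minutes <- function(excess_fraction, s_length_min = 480) {
  if (any(excess_fraction < 0)) abort("`excess_fraction` must be >= 0")
  excess_fraction * s_length_min
}

# Per-interval sums of sorted per-position columns via cumulative sums.
# depths must be sorted by chrom, pos. Returns a matrix, one row per
# interval, one column per requested depth column (plus n_snps, n_bins).
interval_depth_stats <- function(depths, intervals, bin_width = 500) {
  cols <- c("mat_s", "mat_g1", "pat_s", "pat_g1")
  out <- matrix(0, nrow = nrow(intervals), ncol = length(cols) + 2,
                dimnames = list(NULL, c(cols, "n_snps", "n_snp_bins")))
  for (ch in unique(intervals$chrom)) {
    rows <- which(intervals$chrom == ch)
    sub <- depths[depths$chrom == ch, ]
    pos <- sub$pos
    lo <- findInterval(intervals$start[rows] - 0.5, pos)
    hi <- findInterval(intervals$end[rows] - 0.5, pos)
    for (cc in cols) {
      cs <- c(0, cumsum(sub[[cc]]))
      out[rows, cc] <- cs[hi + 1] - cs[lo + 1]
    }
    out[rows, "n_snps"] <- hi - lo
    ub <- unique(floor(pos / bin_width) * bin_width)
    out[rows, "n_snp_bins"] <-
      findInterval(intervals$end[rows] - 0.5, ub) -
      findInterval(intervals$start[rows] - 0.5, ub)
  }
  out
}

# Mean difference-track value over each interval (covered bins only).
interval_mean_diff <- function(diff, intervals) {
  out <- rep(NA_real_, nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    rows <- which(intervals$chrom == ch)
    sub <- diff[diff$chrom == ch, ]
    cs <- c(0, cumsum(sub$value))
    lo <- findInterval(intervals$start[rows] - 0.5, sub$start)
    hi <- findInterval(intervals$end[rows] - 0.5, sub$start)
    n <- hi - lo
    out[rows] <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
  }
  out
}

#' Call asynchronously replicated domains
#'
#' Full two-step caller: candidate islands on the maternal-minus-paternal
#' difference track, chi-square on raw allele-depth counts summed per
#' island, BH adjustment genome-wide across all candidates of both signs,
#' and retention at `q < fdr`. Each retained ARD is annotated with its SNP
#' coverage, mean profile difference, delay in minutes, sign, and core
#' sub-intervals (stricter island parameters, same sign, within the ARD).
#'
#' @param mat,pat `timex_profile` tracks of the two homologs (same binning
#'   and smoothing).
#' @param depths The raw allele-depth table the profiles were built from
#'   (the contingency test requires unsmoothed counts).
#' @param params Island parameters for ARDs (default
#'   `island_params(0.02, 250000, 50000)`).
#' @param core_params Island parameters for cores (default
#'   `island_params(0.1, 50000, 50000)`).
#' @param fdr FDR level (default 0.05).
#' @param coverage_bin Window width (bp) for the SNP-coverage annotation
#'   (default 500).
#' @param s_length_min,range_factor Passed to [delay_minutes()].
#' @return A `timex_ards` tibble, one row per significant ARD: coordinates,
#'   `sign` (`"maternal-delayed"` / `"paternal-delayed"`), summed counts,
#'   `p_value`, `q_value`, `coverage`, `mean_diff`, `delay_minutes`, and a
#'   `cores` list-column of core sub-intervals with their own delays.
#'   Attributes record the candidate-island count and parameters.
#' @export
call_ards <- function(mat, pat, depths, params = island_params(),
                      core_params = island_params(0.1, 50000, 50000),
                      fdr = 0.05, coverage_bin = 500, s_length_min = 480,
                      range_factor = 1.2) {
  depths <- arrange(depths, .data$chrom, .data$pos)
  diff <- difference_track(mat, pat)
  isl <- find_islands(diff, params)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  length = numeric(), sign = character(), mat_s = numeric(),
                  mat_g1 = numeric(), pat_s = numeric(), pat_g1 = numeric(),
                  p_value = numeric(), q_value = numeric(),
                  coverage = numeric(), mean_diff = numeric(),
                  delay_minutes = numeric(), cores = list())
  if (nrow(isl) == 0) {
    return(structure(empty, class = c("timex_ards", class(tibble())),
                     n_candidates = 0L, fdr = fdr, params = params,
                     core_params = core_params))
  }
  stats_m <- interval_depth_stats(depths, isl, coverage_bin)
  p <- island_chisq(stats_m[, "mat_s"], stats_m[, "mat_g1"],
                    stats_m[, "pat_s"], stats_m[, "pat_g1"])
  q <- bh_qvalues(p)
  keep <- which(q < fdr)
  md <- interval_mean_diff(diff, isl)
  cores_all <- find_islands(diff, core_params)
  out <- tibble(
    chrom = isl$chrom[keep], start = isl$start[keep], end = isl$end[keep],
    length = isl$end[keep] - isl$start[keep],
    sign = ifelse(isl$sign[keep] > 0, "paternal-delayed", "maternal-delayed"),
    mat_s = stats_m[keep, "mat_s"], mat_g1 = stats_m[keep, "mat_g1"],
    pat_s = stats_m[keep, "pat_s"], pat_g1 = stats_m[keep, "pat_g1"],
    p_value = p[keep], q_value = q[keep],
    coverage = stats_m[keep, "n_snp_bins"] /
      pmax(1, floor((isl$end[keep] - isl$start[keep]) / coverage_bin)),
    mean_diff = md[keep],
    delay_minutes = delay_minutes(md[keep], s_length_min, range_factor))
  out$cores <- map(seq_len(nrow(out)), function(i) {
    cc <- cores_all[cores_all$chrom == out$chrom[i] &
                      cores_all$start < out$end[i] &
                      cores_all$end > out$start[i] &
                      cores_all$sign == isl$sign[keep][i], ]
    if (nrow(cc) == 0) {
      return(tibble(chrom = character(), start = numeric(), end = numeric(),
                    delay_minutes = numeric()))
    }
    cc$start <- pmax(cc$start, out$start[i])
    cc$end <- pmin(cc$end, out$end[i])
    cmd <- interval_mean_diff(diff, cc)
    tibble(chrom = cc$chrom, start = cc$start, end = cc$end,
           delay_minutes = delay_minutes(cmd, s_length_min, range_factor))
  })
  out <- sort_intervals(out)
  structure(out, class = c("timex_ards", class(tibble())),
            n_candidates = nrow(isl), fdr = fdr, params = params,
            core_params = core_params)
}

#' Overlapping ARD pairs between two call sets
#'
#' Pairs with at least 1 bp of overlap; each record appears at most once per
#' partner.
#'
#' @param a,b ARD tibbles (or any interval tibbles).
#' @return Tibble of overlapping pairs with indices `index_a`, `index_b` and
#'   both coordinate sets; `n_distinct(index_a)` counts `a`-records with a
#'   partner.
#' @export
ard_overlap <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(index_a = integer(), index_b = integer()))
  }
  parts <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    sa <- which(a$chrom == ch); sb <- which(b$chrom == ch)
    ir_a <- IRanges::IRanges(a$start[sa] + 1L, a$end[sa])
    ir_b <- IRanges::IRanges(b$start[sb] + 1L, b$end[sb])
    hits <- IRanges::findOverlaps(ir_a, ir_b)
    parts[[ch]] <- tibble(index_a = sa[S4Vectors::queryHits(hits)],
                          index_b = sb[S4Vectors::subjectHits(hits)])
  }
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) return(tibble(index_a = integer(), index_b = integer()))
  arrange(out, .data$index_a, .data$index_b)
}

#' Gene enrichment among the top-ranked ARDs
#'
#' Counts how many of the `top_n` most significant ARDs (smallest p-value)
#' contain -- or lie within `within` bp of -- a gene from `genes`, and
#' compares the count with a null built by repeatedly drawing `top_n` ARDs
#' at random from the full list. Used to test whether, e.g., imprinted genes
#' concentrate in the most asynchronous domains.
#'
#' @param ards A `timex_ards` tibble (needs `p_value`).
#' @param genes Interval tibble of gene bodies.
#' @param top_n Number of top ARDs (default 40).
#' @param within Proximity margin in bp (default 100 kb).
#' @param n_rand Number of randomizations (default 10000).
#' @param seed Integer seed.
#' @return One-row tibble: `observed`, `expected` (null mean), `p_value`
#'   (fraction of randomizations with count >= observed).
#' @export
gene_rank_enrichment <- function(ards, genes, top_n = 40, within = 1e5,
                                 n_rand = 10000, seed = NULL) {
  if (nrow(ards) < top_n) abort("fewer ARDs than `top_n`")
  force(genes)
  if (!is.null(seed)) withr::local_seed(seed)
  expanded <- tibble(chrom = ards$chrom,
                     start = pmax(0, ards$start - within),
                     end = ards$end + within)
  flag <- if (nrow(genes) == 0) rep(FALSE, nrow(ards)) else
    overlaps_any(expanded, genes)
  ord <- order(ards$p_value)
  observed <- sum(flag[ord[seq_len(top_n)]])
  null <- vapply(seq_len(n_rand),
                 function(i) sum(sample(flag, top_n)), 0)
  tibble(observed = observed, expected = mean(null),
         p_value = mean(null >= observed))
}
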