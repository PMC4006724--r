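# Fixture builders and independent oracles used across the suite.

# A track from a plain value vector: contiguous bins unless `keep` drops some.
toy_track <- function(values, bin_width = 500, chrom = "chrT",
                      keep = rep(TRUE, length(values))) {
  n <- length(values)
  start <- (seq_len(n) - 1) * bin_width
  new_track(tibble::tibble(chrom = chrom, start = start,
                           end = start + bin_width, value = values)[keep, ],
            bin_width, stats::setNames(n * bin_width, chrom))
}

# Independent O(n k) Gaussian smoothing oracle: direct weighted mean over
# covered bins with the same 4-sigma truncation as the implementation.
naive_gaussian_smooth <- function(track, sigma) {
  w <- timexr::bin_width(track)
  half <- as.integer(ceiling(4 * sigma / w))
  out <- track
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    idx <- as.integer(track$start[sel] / w)
    val <- track$value[sel]
    sm <- numeric(length(sel))
    for (i in seq_along(sel)) {
      d <- idx - idx[i]
      use <- abs(d) <= half
      wt <- exp(-(d[use] * w)^2 / (2 * sigma^2))
      sm[i] <- sum(wt * val[use]) / sum(wt)
    }
    out$value[sel] <- sm
  }
  out
}

# Brute-force all-pairs overlap flags (>= 1 bp) for interval tibbles.
brute_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, TRUE)
}

# Textbook Pearson chi-square on one 2x2 table of counts.
hand_chisq_p <- function(ms, mg, ps, pg) {
  o <- c(ms, mg, ps, pg)
  rows <- c(ms + mg, ps + pg)
  cols <- c(ms + ps, mg + pg)
  e <- c(rows[1] * cols[1], rows[1] * cols[2],
         rows[2] * cols[1], rows[2] * cols[2]) / sum(o)
  stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

# Hand-applied Benjamini-Hochberg: q_(k) = min over i >= k of m p_(i) / i.
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Small genome simulation shared by several tests.
small_sim <- function(seed = 42, len = 2e7, ...) {
  spec <- synth_genome_spec(c(chr1 = len), seed = seed, ...)
  simulate_allele_depths(spec)
}

# Shared-source resampled null pair (both homologs imputed from the
# maternal observed track).
null_pair <- function(depths, seed) {
  spike_regions(make_control_pair(depths, "maternal"),
                tibble::tibble(chrom = depths$chrom[1], start = 0, end = 1),
                0, seed = seed)
}
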