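test_that("feature windows center correctly and clip to bounds", {
  tss <- tibble::tibble(chrom = "c", start = c(1000, 5000), end = c(3000, 6000),
                        strand = c("+", "-"))
  w <- feature_windows(tss, 1000, "start_site")
  expect_equal(w$start, c(500, 5500))
  expect_equal(w$end, c(1500, 6500))
  g4 <- tibble::tibble(chrom = "c", start = 100, end = 300)
  expect_equal(feature_windows(g4, 400)$start, 0)
  expect_equal(feature_windows(g4, 400)$end, 400)
  clipped <- feature_windows(g4, 400, chrom_lengths = c(c = 350))
  expect_equal(clipped$end, 350)
})

test_that("peak width normalization centers, fixes width, and merges", {
  p <- tibble::tibble(chrom = "c", start = 1000, end = 1100)
  n <- normalize_peak_widths(p)
  expect_equal(n$start, 850)
  expect_equal(n$end, 1250)
  # two peaks 100 bp apart merge into one window
  pair <- tibble::tibble(chrom = "c", start = c(1000, 1200), end = c(1100, 1300))
  m <- normalize_peak_widths(pair)
  expect_equal(nrow(m), 1)
  # isolated peaks end up exactly 400 bp wide
  iso <- tibble::tibble(chrom = "c", start = c(1000, 9000), end = c(1100, 9100))
  expect_equal(normalize_peak_widths(iso)$end - normalize_peak_widths(iso)$start,
               c(400, 400))
})

test_that("top-N selection is score-ordered and tie-stable", {
  withr::with_seed(2, {
    pk <- tibble::tibble(chrom = "c", start = sample.int(1e6, 50))
    pk$end <- pk$start + 100
    pk$score <- c(rep(5, 10), stats::runif(40))
  })
  expect_equal(nrow(top_n_peaks(pk, 100)), 50)
  top <- top_n_peaks(pk, 10)
  expect_true(all(top$score == 5))
  expect_equal(top_n_peaks(pk, 7), top_n_peaks(pk, 7))
})

test_that("percent associated uses the 1 bp rule and matches brute force", {
  pk <- tibble::tibble(chrom = "c", start = c(0, 1000, 2000),
                       end = c(100, 1100, 2100))
  expect_equal(percent_associated(pk, pk), 100)
  far <- tibble::tibble(chrom = "c", start = 5000, end = 5100)
  expect_equal(percent_associated(pk, far), 0)
  withr::with_seed(14, {
    x <- tibble::tibble(chrom = "c", start = sample.int(1e5, 400))
    x$end <- x$start + sample.int(400, 400)
    y <- tibble::tibble(chrom = "c", start = sample.int(1e5, 400))
    y$end <- y$start + sample.int(400, 400)
  })
  expect_equal(percent_associated(x, y), 100 * mean(brute_overlaps_any(x, y)))
})

test_that("bootstrap enrichment calibrates to 1 under uniform placement", {
  terr <- tibble::tibble(chrom = "c", start = 0, end = 1e6)
  full <- tibble::tibble(chrom = "c", start = 0, end = 1e6)
  pk <- tibble::tibble(chrom = "c", start = seq(0, 99000, by = 1000),
                       end = seq(0, 99000, by = 1000) + 200)
  be <- bootstrap_enrichment(pk, full, terr, iters = 5, seed = 1)
  expect_equal(be$fold, 1)
  expect_equal(be$observed_pct, 100)

  feat <- tibble::tibble(chrom = "c", start = seq(0, 9e5, by = 1e5),
                         end = seq(0, 9e5, by = 1e5) + 3e4)
  big_pk <- tibble::tibble(chrom = "c", start = rep(0, 1000),
                           end = rep(200, 1000))
  unif <- randomize_intervals(big_pk, terr, seed = 4)
  be2 <- bootstrap_enrichment(unif, feat, terr, iters = 100, seed = 5)
  # observed hit rate ~30%; its sampling SE over 1000 peaks bounds the fold
  se_fold <- sqrt(0.3 * 0.7 / 1000) / 0.3
  expect_lt(abs(be2$fold - 1), 3 * se_fold)
  # fold invariant to peak input order
  be3 <- bootstrap_enrichment(unif[sample(nrow(unif)), ], feat, terr,
                              iters = 100, seed = 5)
  expect_equal(be3$fold, be2$fold)
})

test_that("per-fraction origin statistics reduce to global stats", {
  reads <- toy_track(rep(2, 200), bin_width = 1000)
  peaks <- tibble::tibble(chrom = "chrT", start = c(0, 500, 5000),
                          end = c(100, 600, 5100), area = c(1, 2, 3))
  whole <- tibble::tibble(chrom = "chrT", start = 0, end = 2e5,
                          fraction = "S1")
  st <- fraction_origin_stats(reads, peaks, whole)
  expect_equal(st$n_peaks, 3)
  expect_equal(st$mean_peak_area, 2)
  expect_equal(st$mean_reads_per_window, 2)
  # inter-peak distances: 400 and 4400 -> median 2400
  expect_equal(st$median_interpeak_bp, 2400)
  two_pk <- peaks[1:2, ]
  expect_equal(fraction_origin_stats(reads, two_pk, whole)$median_interpeak_bp,
               400)
  one_pk <- peaks[1, ]
  expect_true(is.na(fraction_origin_stats(reads, one_pk, whole)$median_interpeak_bp))
})

test_that("GC and repeat content windows are exact on constructed input", {
  expect_true(all(gc_content_windows(list(c = strrep("G", 5000)),
                                     window = 1000, step = 500)$value == 100))
  tiled <- gc_content_windows(list(c = strrep("ATGC", 2500)),
                              window = 1000, step = 500)
  # interior windows (not clipped at the chromosome ends) are exactly 50%
  interior <- tiled$start >= 250 & tiled$start <= 10000 - 750
  expect_true(all(abs(tiled$value[interior] - 50) < 1e-9))
  expect_true(all(abs(tiled$value - 50) < 0.2))

  reps <- tibble::tibble(chrom = "c", start = 0, end = 500)
  rc <- repeat_content_windows(reps, c(c = 10000), window = 1000, step = 1000)
  expect_equal(rc$value[1], 50)
  expect_equal(rc$value[3], 0)
})

test_that("allelic nascent-strand ratios pair with delays", {
  withr::with_seed(16, {
    ards <- tibble::tibble(chrom = "chr1", start = seq(0, 99) * 1e6,
                           end = seq(0, 99) * 1e6 + 5e5,
                           delay_minutes = stats::rnorm(100, sd = 30))
  })
  r_eq <- ard_allele_ns_ratio(ards, rep(100, 100), rep(100, 100))
  expect_true(all(r_eq$ns_ratio == 1))
  withr::with_seed(15, {
    mat <- rpois(100, 200); pat <- rpois(100, 200)
  })
  r1 <- ard_allele_ns_ratio(ards, mat, pat)
  r2 <- ard_allele_ns_ratio(ards, pat, mat)
  expect_equal(r1$ns_ratio, 1 / r2$ns_ratio)
  # homolog-independent nascent strands: no correlation with delay
  expect_lt(abs(attr(r1, "pearson_r")), 0.2)
  expect_warning(ard_allele_ns_ratio(ards, mat, c(0L, pat[-1])), "zero")
})
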