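test_that("the dual-smooth residual isolates fine structure", {
  w <- 1000
  expect_true(all(abs(dual_smooth_residual(
    toy_track(rep(2, 1000), bin_width = w))$value) < 1e-12))

  # slowly varying signal (wavelength 2 Mb >> coarse sigma) is cancelled
  x <- seq_len(2000)
  slow <- toy_track(sin(2 * pi * x * w / 2e6), bin_width = w)
  res_slow <- dual_smooth_residual(slow)
  # analytic attenuation: exp(-(2 pi sigma / lambda)^2 / 2) per smooth, so
  # the residual amplitude is about 0.048
  expect_lt(max(abs(res_slow$value[200:1800])), 0.06)

  # a 50 kb bump survives with positive peak area
  bump <- rep(0, 2000)
  bump[975:1025] <- sin(seq(0, pi, length.out = 51))
  res <- dual_smooth_residual(toy_track(bump, bin_width = w))
  peaks <- call_residual_peaks(res, top_fraction = 1)
  best <- peaks[which.max(peaks$area), ]
  expect_gt(best$area, 0)
  expect_true(best$start < 1025 * w && best$end > 975 * w)
  # residual matches the two convolution oracles' difference
  oracle <- naive_gaussian_smooth(toy_track(bump, bin_width = w), 2e4)$value -
    naive_gaussian_smooth(toy_track(bump, bin_width = w), 1e5)$value
  expect_equal(res$value, oracle, tolerance = 1e-9)
})

test_that("residual peaks are positive runs ranked by area", {
  # 10 bumps of strictly decreasing area separated by negative troughs
  vals <- unlist(lapply(10:1, function(h) c(rep(-1, 5), rep(h, h), rep(-1, 5))))
  tr <- toy_track(vals, bin_width = 100)
  all_peaks <- call_residual_peaks(tr, top_fraction = 1)
  expect_equal(nrow(all_peaks), 10)
  # areas equal the brute-force run sums (h bins of height h, width 100 bp)
  expect_equal(sort(all_peaks$area), sort((10:1)^2))
  top1 <- call_residual_peaks(tr, top_fraction = 0.10)
  expect_equal(nrow(top1), 1)
  expect_equal(top1$area, 100)
  # summit sits at the maximum bin
  single <- toy_track(c(-1, 1, 3, 2, -1), bin_width = 100)
  p <- call_residual_peaks(single, 1)
  expect_equal(p$summit, 250)
  expect_equal(nrow(call_residual_peaks(toy_track(rep(-1, 10)), 0.5)), 0)
})

test_that("S-phase fractions form an equal-count ordered partition", {
  withr::with_seed(8, tr <- toy_track(stats::runif(1003)))
  fr <- partition_s_fractions(new_track(tr, 500, c(chrT = 1003 * 500),
                                        class = "timex_profile"), k = 5)
  widths <- vapply(split(fr, fr$fraction), timexr:::total_width, 0)
  expect_true(all(abs(widths - 1003 * 500 / 5) <= 500))
  expect_equal(sum(widths), 1003 * 500)
  # value ordering: S1 holds the highest values
  val_of <- function(f) {
    tr$value[timexr:::overlaps_any(tr, fr[fr$fraction == f, ])]
  }
  expect_gte(min(val_of("S1")), max(val_of("S2")))
  expect_gte(min(val_of("S4")), max(val_of("S5")))
  # uniform-value profile: deterministic tie-break by position
  flat <- new_track(toy_track(rep(1, 100)), 500, c(chrT = 5e4),
                    class = "timex_profile")
  f1 <- partition_s_fractions(flat, 5)
  expect_equal(f1, partition_s_fractions(flat, 5))
  expect_equal(nrow(f1), 5)
})

test_that("overlap fraction matches brute force and the printed expectation", {
  a <- tibble::tibble(chrom = "c", start = c(0, 100, 200), end = c(50, 150, 250))
  expect_equal(overlap_fraction(a, a), 1)
  b <- tibble::tibble(chrom = "c", start = 300, end = 400)
  expect_equal(overlap_fraction(a, b), 0)
  withr::with_seed(13, {
    x <- tibble::tibble(chrom = "c", start = sample.int(1e5, 300))
    x$end <- x$start + sample.int(500, 300)
    y <- tibble::tibble(chrom = "c", start = sample.int(1e5, 300))
    y$end <- y$start + sample.int(500, 300)
  })
  expect_equal(overlap_fraction(x, y), mean(brute_overlaps_any(x, y)))
  expect_error(overlap_fraction(a[0, ], b), "empty")

  expect_equal(expected_overlap(0.219, 0.184), 0.219 * 3 * 0.184)
  expect_equal(expected_overlap(0, 0.5), 0)
  expect_equal(expected_overlap(0.3, 0.4, partial_factor = 1), 0.12)
})

test_that("interval randomization preserves widths and calibrates to coverage", {
  terr <- tibble::tibble(chrom = c("c1", "c2"), start = c(0, 0),
                         end = c(5e5, 3e5))
  x <- tibble::tibble(chrom = "c1", start = seq(0, 49000, by = 1000),
                      end = seq(0, 49000, by = 1000) + 500)
  r <- randomize_intervals(x, terr, seed = 3)
  expect_equal(sort(r$end - r$start), sort(x$end - x$start))
  expect_true(all(timexr:::overlaps_any(
    r, terr) & r$start >= 0 &
      r$end <= ifelse(r$chrom == "c1", 5e5, 3e5)))

  # width-1 probes against a 30% covered feature set: hit rate = coverage
  terr1 <- tibble::tibble(chrom = "c", start = 0, end = 1e6)
  feat <- tibble::tibble(chrom = "c", start = 0, end = 3e5)
  probes <- tibble::tibble(chrom = "c", start = 1:50, end = 2:51)
  withr::with_seed(9, {
    hits <- vapply(1:200, function(i) {
      overlap_fraction(randomize_intervals(probes, terr1), feat)
    }, 0)
  })
  p <- 0.3
  se <- sqrt(p * (1 - p) / (200 * 50))
  expect_lt(abs(mean(hits) - p), 3 * se * sqrt(50)) # probes within a draw correlate
})

test_that("track correlation follows the textbook formula", {
  a <- toy_track(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), bin_width = 3000)
  b <- toy_track(c(2, 1, 4, 3, 7, 5, 6, 10, 8, 9), bin_width = 3000)
  r <- track_correlation(a, b, bin = 3000, saturate = FALSE)
  # hand Pearson
  va <- a$value; vb <- b$value
  hand <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(r, hand)
  expect_equal(track_correlation(a, a, saturate = FALSE), 1)
  neg <- a; neg$value <- -neg$value
  expect_equal(track_correlation(a, neg, saturate = FALSE), -1)
  expect_error(track_correlation(toy_track(1:2, bin_width = 3000),
                                 toy_track(1:2, bin_width = 3000)),
               "fewer than 3")
})
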