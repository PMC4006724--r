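test_that("difference track is antisymmetric and gap-propagating", {
  s <- toy_track(c(0.2, 0.3, 0.5)); g <- toy_track(c(0.2, 0.3, 0.5))
  mat <- timex_ratio(s, g, homolog = "maternal")
  pat <- timex_ratio(toy_track(c(0.25, 0.3, 0.45)), g, homolog = "paternal")
  expect_true(all(difference_track(mat, mat)$value == 0))
  expect_equal(difference_track(mat, pat)$value,
               -difference_track(pat, mat)$value)
  pat_gap <- new_track(pat[-2, ], 500, c(chrT = 1500))
  expect_equal(nrow(difference_track(mat, pat_gap)), 2)
  wide <- timex_ratio(toy_track(1:3, bin_width = 1000),
                      toy_track(1:3, bin_width = 1000), homolog = "maternal")
  expect_error(difference_track(mat, wide), "bin width")
})

test_that("island finder merges gaps and respects sign and min size", {
  w <- 500
  # one 60 kb run of +0.05 (120 bins)
  vals <- c(rep(0, 20), rep(0.05, 120), rep(0, 20))
  isl <- find_islands(toy_track(vals), island_params(0.02, 250000, 50000))
  expect_equal(nrow(isl), 1)
  expect_equal(isl$end - isl$start, 60000)
  expect_equal(isl$sign, 1L)

  # two 60 kb runs separated by 300 kb of zeros with max_gap 250 kb
  vals2 <- c(rep(0.05, 120), rep(0, 600), rep(0.05, 120))
  isl2 <- find_islands(toy_track(vals2), island_params(0.02, 250000, 50000))
  expect_equal(nrow(isl2), 2)
  # ... but a 200 kb gap merges them
  vals3 <- c(rep(0.05, 120), rep(0, 400), rep(0.05, 120))
  expect_equal(nrow(find_islands(toy_track(vals3),
                                 island_params(0.02, 250000, 50000))), 1)

  # sub-threshold everywhere: no islands
  expect_equal(nrow(find_islands(toy_track(rep(0.01, 400)),
                                 island_params(0.02, 250000, 50000))), 0)

  # opposite signs never form one island; opposite-sign bins act as gap
  # content, so the two positive runs merge across the 60 kb negative run
  vals4 <- c(rep(0.05, 120), rep(-0.05, 120), rep(0.05, 120))
  isl4 <- find_islands(toy_track(vals4), island_params(0.02, 250000, 50000))
  expect_equal(sort(isl4$sign), c(-1L, 1L))
  expect_equal(isl4$end[isl4$sign == 1] - isl4$start[isl4$sign == 1], 180000)
  expect_equal(isl4$end[isl4$sign == -1] - isl4$start[isl4$sign == -1], 60000)
  # runs below min size are dropped (100 bins x 500 bp = exactly min size)
  expect_equal(nrow(find_islands(toy_track(c(rep(0.05, 100), rep(0, 10))),
                                 island_params(0.02, 250000, 50000))), 1)
  expect_equal(nrow(find_islands(toy_track(c(rep(0.05, 100), rep(0, 10))),
                                 island_params(0.02, 250000, 100000))), 0)
})

test_that("island chi-square matches the textbook statistic", {
  expect_equal(island_chisq(100, 100, 100, 100), 1)
  expect_equal(island_chisq(150, 100, 100, 100),
               hand_chisq_p(150, 100, 100, 100))
  # homolog-row swap leaves p unchanged
  expect_equal(island_chisq(150, 100, 100, 100),
               island_chisq(100, 100, 150, 100))
  withr::with_seed(4, {
    tabs <- matrix(rpois(40, 500), ncol = 4)
  })
  expect_equal(island_chisq(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4]),
               mapply(hand_chisq_p, tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4]))
  expect_warning(p0 <- island_chisq(0, 0, 10, 10), "zero marginal")
  expect_equal(p0, 1)
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(bh_qvalues(0.03), 0.03)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(5, p <- stats::runif(200)^2)
  q <- bh_qvalues(p)
  expect_equal(q, hand_bh(p))
  expect_true(all(q >= p))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("delay conversions follow the printed arithmetic", {
  expect_equal(delay_minutes(0), 0)
  expect_equal(delay_minutes(0.12), 48)
  expect_equal(delay_minutes(0.2), 2 * delay_minutes(0.1))
  expect_equal(delay_minutes(0.1, range_action = "multiply"), 0.1 * 480 * 1.2)
  expect_equal(excess_to_minutes(0.10), 48)
  expect_equal(excess_to_minutes(0.15), 72)
  expect_equal(excess_to_minutes(0.20), 96)
  expect_equal(excess_to_minutes(0), 0)
})

test_that("the ARD caller finds a strong spike and reports consistent records", {
  spec <- synth_genome_spec(c(chr1 = 3e7), seed = 31)
  sim <- simulate_allele_depths(spec)
  truth <- tibble::tibble(chrom = "chr1", start = 1e7, end = 1.2e7)
  spiked <- spike_regions(make_control_pair(sim$depths), truth, 0.50,
                          seed = 77)
  mat <- build_profile(spiked, "maternal")
  pat <- build_profile(spiked, "paternal")
  ards <- call_ards(mat, pat, spiked)
  expect_gt(nrow(ards), 0)
  hit <- ards[overlaps_any(ards, truth), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$sign, "paternal-delayed")
  expect_lt(hit$q_value, 0.05)
  expect_gt(hit$delay_minutes, 0)
  expect_true(all(ards$length >= 50000))
  expect_true(all(ards$q_value < 0.05))
  expect_true(all(ards$coverage >= 0 & ards$coverage <= 1))
  # detected ARDs sorted, non-overlapping within a sign
  for (sg in unique(ards$sign)) {
    sub <- ards[ards$sign == sg, ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
  # cores sit inside their ARD and carry larger delays than the whole domain
  expect_gt(nrow(hit$cores[[1]]), 0)
  core <- hit$cores[[1]]
  expect_true(all(core$start >= hit$start & core$end <= hit$end))
  expect_gte(max(abs(core$delay_minutes)), abs(hit$delay_minutes))
})

test_that("null resampled data yields no significant domains", {
  sig <- vapply(1:3, function(i) {
    sim <- small_sim(seed = 300 + i, len = 2e7)
    nd <- null_pair(sim$depths, seed = 400 + i)
    mat <- build_profile(nd, "maternal")
    pat <- build_profile(nd, "paternal")
    nrow(call_ards(mat, pat, nd))
  }, 0L)
  expect_equal(stats::median(sig), 0)
})

test_that("ARD overlap pairing is symmetric and 1 bp-strict", {
  a <- tibble::tibble(chrom = "chr1", start = c(0, 100, 300),
                      end = c(50, 200, 400))
  expect_equal(nrow(ard_overlap(a, a)), 3)
  b <- tibble::tibble(chrom = "chr1", start = c(50, 250), end = c(100, 300))
  expect_equal(nrow(ard_overlap(a, b)), 0)
  c2 <- tibble::tibble(chrom = "chr1", start = 199, end = 301)
  ov <- ard_overlap(a, c2)
  expect_equal(ov$index_a, c(2, 3))
})

test_that("top-rank gene enrichment matches the hypergeometric tail", {
  # 100 domains, the 10 smallest p-values all gene-associated
  ards <- tibble::tibble(chrom = "chr1",
                         start = seq(0, by = 2e6, length.out = 100),
                         end = seq(0, by = 2e6, length.out = 100) + 1e6,
                         p_value = seq(1e-10, 0.9, length.out = 100))
  # 30 gene-associated domains, 15 of them among the 40 smallest p-values
  assoc <- c(1:15, 61:75)
  genes <- tibble::tibble(chrom = "chr1", start = ards$start[assoc] + 1e5,
                          end = ards$start[assoc] + 2e5)
  res <- gene_rank_enrichment(ards, genes, top_n = 40, within = 0,
                              n_rand = 20000, seed = 6)
  expect_equal(res$observed, 15)
  p_hyper <- stats::phyper(14, 30, 70, 40, lower.tail = FALSE)
  expect_equal(res$p_value, p_hyper,
               tolerance = 3 * sqrt(p_hyper * (1 - p_hyper) / 20000) / p_hyper)
  # degenerate cases
  expect_equal(gene_rank_enrichment(ards, genes[0, ], top_n = 40,
                                    n_rand = 50, seed = 1)$p_value, 1)
  all_genes <- tibble::tibble(chrom = "chr1", start = ards$start,
                              end = ards$end)
  res_all <- gene_rank_enrichment(ards, all_genes, top_n = 40,
                                  n_rand = 50, seed = 1)
  expect_equal(res_all$observed, 40)
  expect_equal(res_all$p_value, 1)
})
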