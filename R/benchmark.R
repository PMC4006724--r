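# Spike-in simulation study: sensitivity, empirical FDR, and size/delay
# distortion of the ARD caller over a grid of spike sizes and S-phase read
# excess fractions.

#' Detection rate of simulated regions
#'
#' Fraction of truth intervals overlapped (>= 1 bp) by at least one detected
#' interval.
#'
#' @param detected,truth Interval tibbles.
#' @return Fraction in \[0, 1\].
#' @export
detection_rate <- function(detected, truth) {
  if (nrow(truth) == 0) abort("`truth` is empty")
  mean(overlaps_any(truth, detected))
}

#' Empirical false discovery rate of detected intervals
#'
#' Counts detected intervals that do and do not overlap any truth interval.
#' Two variants are reported: the conventional `fdr` = false / detected, and
#' `fdr_ratio` = false / true-overlapping (the ratio-style definition some
#' spike-in studies print); they agree when the false count is 0.
#'
#' @param detected,truth Interval tibbles.
#' @return One-row tibble: `n_detected`, `n_true`, `n_false`, `fdr`,
#'   `fdr_ratio` (both `NA` with a warning when their denominator is 0).
#' @export
empirical_fdr <- function(detected, truth) {
  hit <- overlaps_any(detected, truth)
  n_true <- sum(hit); n_false <- sum(!hit); n_det <- length(hit)
  if (n_det == 0 || n_true == 0) {
    warn("no detected (or no truth-overlapping) intervals: FDR undefined")
  }
  tibble(n_detected = n_det, n_true = n_true, n_false = n_false,
         fdr = if (n_det > 0) n_false / n_det else NA_real_,
         fdr_ratio = if (n_true > 0) n_false / n_true else NA_real_)
}

#' Size and delay distortion of detected vs simulated regions
#'
#' Matches each detected interval to the truth interval it overlaps most,
#' then forms per-pair ratios: detected span / truth span, and mean profile
#' difference over the detected span / mean over the truth span. Smoothing
#' widens detected domains and dilutes their mean differential, so size
#' ratios run above 1 and delay ratios below 1, most strongly for small
#' regions.
#'
#' @param detected Interval tibble (e.g. significant ARDs).
#' @param truth Simulated spike intervals.
#' @param diff Difference track the detection ran on.
#' @return Tibble of matched pairs with `size_ratio` and `delay_ratio`;
#'   attribute `summary` holds means and standard errors.
#' @export
distortion <- function(detected, truth, diff) {
  m <- match_max_overlap(detected, truth)
  keep <- which(!is.na(m))
  if (length(keep) == 0) abort("no detected interval matches a truth interval")
  det <- detected[keep, ]
  tru <- truth[m[keep], ]
  pairs <- tibble(
    chrom = det$chrom, start = det$start, end = det$end,
    truth_start = tru$start, truth_end = tru$end,
    size_ratio = (det$end - det$start) / (tru$end - tru$start),
    delay_ratio = interval_mean_diff(diff, det) / interval_mean_diff(diff, tru))
  sem <- function(x) sd(x) / sqrt(length(x))
  attr(pairs, "summary") <- tibble(
    metric = c("size_ratio", "delay_ratio"),
    mean = c(mean(pairs$size_ratio), mean(pairs$delay_ratio, na.rm = TRUE)),
    sem = c(sem(pairs$size_ratio), sem(pairs$delay_ratio[!is.na(pairs$delay_ratio)])))
  pairs
}

# One replicate genome of one grid cell: simulate, spike, profile, call.
simulate_spiked_cell <- function(size, excess, n_regions, genome_length,
                                 mean_depth, snp_spacing, seed, fdr = 0.05,
                                 bin_width = 500, sigma = 1e5,
                                 params = island_params(),
                                 core_params = island_params(0.1, 50000, 50000)) {
  cl <- c(chr1 = genome_length)
  spec <- synth_genome_spec(cl, snp_spacing, mean_depth, seed = seed)
  sim <- simulate_allele_depths(spec)
  truth <- place_random_regions(n_regions, size, cl,
                                seed = derive_seed(seed, "truth"))
  # both homolog controls derive from the maternal observed track, so homolog
  # differences are purely binomial resampling noise plus the spikes
  spiked <- spike_regions(make_control_pair(sim$depths, "maternal"), truth,
                          excess, target = "maternal",
                          seed = derive_seed(seed, "spike"))
  mat <- build_profile(spiked, "maternal", bin_width, sigma)
  pat <- build_profile(spiked, "paternal", bin_width, sigma)
  ards <- call_ards(mat, pat, spiked, params, core_params, fdr = fdr)
  list(truth = truth, ards = ards, diff = difference_track(mat, pat))
}

#' Spike-in power and FDR study over a size-by-excess grid
#'
#' For each (region size, excess fraction) cell: simulate replicate
#' synthetic genomes carrying randomly placed spiked regions on one homolog,
#' rebuild both homolog profiles, call ARDs at the given FDR, and score
#' detection rate, empirical FDR (both variants) and size/delay distortion
#' against the truth set. Regions are spread over enough replicate genomes
#' to keep spike occupancy below about a quarter of each genome.
#'
#' @param sizes Spike sizes in bp.
#' @param excesses Excess fractions (e.g. `c(0.05, 0.1, ...)`).
#' @param n_regions Total simulated regions per cell (default 150).
#' @param genome_length Replicate genome length in bp (default 200 Mb).
#' @param mean_depth Mean reads per SNP per fraction (default 25).
#' @param snp_spacing SNP spacing bounds in bp (default `c(500, 5000)`).
#' @param fdr FDR level for calling (default 0.05).
#' @param seed Integer seed.
#' @return A `timex_power_grid` tibble, one row per cell: `size`, `excess`,
#'   `n_simulated`, `n_detected_true`, `detection_rate`, island counts,
#'   `empirical_fdr`, `empirical_fdr_ratio`, `mean_size_ratio`,
#'   `mean_delay_ratio` (with `sem_` columns).
#' @export
run_power_study <- function(sizes, excesses, n_regions = 150,
                            genome_length = 2e8, mean_depth = 25,
                            snp_spacing = c(500, 5000), fdr = 0.05,
                            seed = 1L) {
  grid <- tidyr::expand_grid(size = sizes, excess = excesses)
  rows <- pmap(grid, function(size, excess) {
    n_per_rep <- max(1L, floor(0.25 * genome_length / size))
    n_reps <- ceiling(n_regions / n_per_rep)
    reps <- map(seq_len(n_reps), function(r) {
      simulate_spiked_cell(size, excess,
                           n_regions = min(n_per_rep, n_regions - (r - 1) * n_per_rep),
                           genome_length, mean_depth, snp_spacing,
                           seed = derive_seed(seed, paste(size, excess), r),
                           fdr = fdr)
    })
    n_sim <- sum(map_int(reps, ~ nrow(.x$truth)))
    n_hit <- sum(map_int(reps, ~ sum(overlaps_any(.x$truth, .x$ards))))
    det <- map(reps, ~ .x$ards)
    fdr_tab <- map2(det, reps, function(d, r) empirical_fdr(d, r$truth)) |>
      dplyr::bind_rows() |>
      summarise(n_detected = sum(.data$n_detected), n_true = sum(.data$n_true),
                n_false = sum(.data$n_false))
    dist <- map(reps, function(r) {
      if (nrow(r$ards) == 0 || !any(overlaps_any(r$ards, r$truth))) return(NULL)
      distortion(r$ards, r$truth, r$diff)
    }) |> dplyr::bind_rows()
    tibble(size = size, excess = excess, n_simulated = n_sim,
           n_detected_true = n_hit, detection_rate = n_hit / n_sim,
           n_islands = fdr_tab$n_detected, n_islands_true = fdr_tab$n_true,
           n_islands_false = fdr_tab$n_false,
           empirical_fdr = ifelse(fdr_tab$n_detected > 0,
                                  fdr_tab$n_false / fdr_tab$n_detected, NA_real_),
           empirical_fdr_ratio = ifelse(fdr_tab$n_true > 0,
                                        fdr_tab$n_false / fdr_tab$n_true, NA_real_),
           mean_size_ratio = mean(dist$size_ratio),
           sem_size_ratio = sd(dist$size_ratio) / sqrt(max(1, nrow(dist))),
           mean_delay_ratio = mean(dist$delay_ratio, na.rm = TRUE),
           sem_delay_ratio = sd(dist$delay_ratio, na.rm = TRUE) /
             sqrt(max(1, sum(!is.na(dist$delay_ratio)))))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("timex_power_grid", class(tibble())),
            seed = seed, fdr = fdr, n_regions = n_regions,
            genome_length = genome_length, mean_depth = mean_depth)
}

#' Ascending excess sweep for one spike size
#'
#' Runs [run_power_study()] cells for one region size over the excess grid
#' in ascending order, stopping after the first excess whose detection rate
#' reaches `target` (the remaining, easier cells are implied).
#'
#' @param size Spike size in bp.
#' @param excesses Excess grid, ascending (default the 5-50% study grid).
#' @param target Detection-rate target (default 0.9).
#' @param ... Passed to [run_power_study()] (`n_regions`, `genome_length`,
#'   ...).
#' @param seed Integer seed.
#' @return A `timex_power_grid` of the evaluated cells.
#' @export
excess_sweep <- function(size, excesses = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.50),
                         target = 0.9, ..., seed = 1L) {
  rows <- list()
  for (e in sort(excesses)) {
    g <- run_power_study(size, e, ..., seed = seed)
    rows[[length(rows) + 1]] <- as_tibble(g)
    if (g$detection_rate >= target) break
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("timex_power_grid", class(tibble())), seed = seed)
}

#' Smallest excess reaching a target detection rate
#'
#' Scans one size's detection rates over the excess grid (ascending) and
#' returns the smallest excess whose rate reaches `target`.
#'
#' @param grid A `timex_power_grid`.
#' @param size Region size to scan.
#' @param target Target detection rate (default 0.9).
#' @return The smallest excess fraction, or `NA` if none reaches the target.
#' @export
smallest_excess_detected <- function(grid, size, target = 0.9) {
  sub <- arrange(grid[grid$size == size, ], .data$excess)
  hit <- which(sub$detection_rate >= target)
  if (length(hit) == 0) return(NA_real_)
  sub$excess[hit[1]]
}
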