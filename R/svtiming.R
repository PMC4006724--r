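# Association between structural variants (SVs) and allelic timing
# asynchrony: windowed allelic timing ratios (inverted below 1 so the
# statistic captures absolute asynchrony), SV size-class means, and a
# location-randomization test.

#' Windowed allelic timing differential
#'
#' The maternal/paternal timing ratio is computed in `sub`-bp sub-windows
#' (mean profile value per homolog, jointly covered sub-windows only),
#' inverted where below 1 -- an SV may advance or delay either homolog --
#' and averaged over `window`-bp intervals overlapping every `step` bp.
#'
#' @param mat,pat Homolog `timex_profile` tracks with the same binning.
#' @param sub Sub-window width in bp (default 5 kb).
#' @param window Averaging interval in bp (default 500 kb).
#' @param step Interval step in bp (default 100 kb); must divide `window`.
#' @return Tibble `chrom`, `start`, `end`, `value` (>= 1); windows with no
#'   covered sub-window are omitted.
#' @export
allelic_ratio_windows <- function(mat, pat, sub = 5000, window = 5e5,
                                  step = 1e5) {
  if (window %% step != 0) abort("`step` must divide `window`")
  m5 <- rebin_track(mat, sub)
  p5 <- rebin_track(pat, sub)
  joined <- dplyr::inner_join(as_tibble(m5),
                              as_tibble(p5)[, c("chrom", "start", "value")],
                              by = c("chrom", "start"), suffix = c("_m", "_p"))
  ratio <- joined$value_m / joined$value_p
  joined$inv_ratio <- pmax(ratio, 1 / ratio)
  cl <- chrom_lengths(mat)
  parts <- imap(as.list(cl), function(len, ch) {
    sj <- joined[joined$chrom == ch, ]
    if (nrow(sj) == 0) return(NULL)
    starts <- seq(0, max(0, len - window), by = step)
    # sub-windows fully inside [ws, ws + window)
    lo <- findInterval(starts - 0.5, sj$start)
    hi <- findInterval(starts + window - sub, sj$start)
    cs <- c(0, cumsum(sj$inv_ratio))
    n <- hi - lo
    tibble(chrom = ch, start = starts, end = pmin(starts + window, len),
           value = ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)) |>
      dplyr::filter(!is.na(.data$value))
  })
  sort_intervals(dplyr::bind_rows(parts))
}

# Assign each window the largest size threshold met by any overlapping SV
# ("no_sv" when no overlapping SV reaches the smallest threshold).
sv_window_class <- function(windows, svs, classes) {
  classes <- sort(classes)
  sizes <- svs$end - svs$start
  lab <- function(x) paste0(">=", format(x, scientific = FALSE, trim = TRUE))
  cls <- rep("no_sv", nrow(windows))
  for (thr in classes) {
    big <- svs[sizes >= thr, ]
    hit <- overlaps_any(windows, big)
    cls[hit] <- lab(thr)
  }
  factor(cls, levels = c("no_sv", vapply(classes, lab, "")))
}

#' Allelic timing differential by SV size class
#'
#' Groups windowed differentials ([allelic_ratio_windows()]) by the largest
#' structural variant overlapping each window (thresholds in `classes`;
#' windows overlapping none are the `no_sv` baseline) and reports per-class
#' means with standard errors.
#'
#' @param windows Output of [allelic_ratio_windows()].
#' @param svs SV interval tibble.
#' @param classes SV size thresholds in bp (default 10/50/100 kb).
#' @return Tibble: `class`, `n`, `mean`, `sem`.
#' @export
sv_class_differential <- function(windows, svs,
                                  classes = c(1e4, 5e4, 1e5)) {
  cls <- sv_window_class(windows, svs, classes)
  tibble(class = cls, value = windows$value) |>
    group_by(.data$class, .drop = FALSE) |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sem = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
}

#' Randomization test for the SV-asynchrony association
#'
#' Re-places the SVs uniformly at random (widths preserved) across the
#' windows' territory `n_rand` times, recomputing the per-size-class mean
#' differential each time. For each class, p is the add-one-corrected
#' fraction of randomizations whose class mean is at least the observed
#' one.
#'
#' @param windows Output of [allelic_ratio_windows()].
#' @param svs SV interval tibble.
#' @param n_rand Number of randomizations (default 1000).
#' @param classes SV size thresholds in bp.
#' @param territory Optional placement territory (default: the span of the
#'   windows per chromosome).
#' @param seed Integer seed.
#' @return Tibble: `class`, `observed_mean`, `n_windows`, `p_value`,
#'   `n_rand`.
#' @export
sv_randomization_test <- function(windows, svs, n_rand = 1000,
                                  classes = c(1e4, 5e4, 1e5),
                                  territory = NULL, seed = NULL) {
  if (n_rand < 100) abort("`n_rand` must be >= 100")
  force(windows); force(svs)
  if (!is.null(seed)) withr::local_seed(seed)
  territory <- territory %||% (windows |>
    group_by(.data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop"))
  obs <- sv_class_differential(windows, svs, classes)
  obs <- obs[obs$class != "no_sv", ]
  hits <- matrix(0, nrow = n_rand, ncol = nrow(obs))
  for (r in seq_len(n_rand)) {
    rnd <- randomize_intervals(svs, territory)
    perm <- sv_class_differential(windows, rnd, classes)
    perm <- perm[match(obs$class, perm$class), ]
    hits[r, ] <- !is.na(perm$mean) & perm$mean >= obs$mean
  }
  tibble(class = obs$class, observed_mean = obs$mean, n_windows = obs$n,
         p_value = (colSums(hits) + 1) / (n_rand + 1), n_rand = n_rand)
}
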