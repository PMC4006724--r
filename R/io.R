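# Plain-text file interfaces. Coordinates are 0-based half-open internally;
# the allele-depth TSV stores 1-based positions (VCF convention), BED and
# bedGraph are 0-based half-open as usual.

DEPTH_COLS <- c("chrom", "pos", "mat_s", "pat_s", "mat_g1", "pat_g1")

#' Read a phased allele-depth table
#'
#' Tab-separated columns chrom, pos (1-based), mat_s, pat_s, mat_g1, pat_g1
#' with a `#`-prefixed header line. Positions are converted to 0-based;
#' unsorted input is sorted with a warning.
#'
#' @param path File path.
#' @return Allele-depth tibble.
#' @export
read_allele_depths <- function(path) {
  x <- readr::read_tsv(path, comment = "", col_names = DEPTH_COLS, skip = 1,
                       col_types = "ciiiii", progress = FALSE)
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) {
    abort("expected a '#'-prefixed header line")
  }
  n_file_cols <- length(strsplit(first, "\t")[[1]])
  if (n_file_cols < length(DEPTH_COLS)) {
    missing_cols <- DEPTH_COLS[(n_file_cols + 1):length(DEPTH_COLS)]
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (readr::problems(x) |> nrow() > 0) {
    pr <- readr::problems(x)
    abort(sprintf("malformed line %d in %s", pr$row[1] + 1, path))
  }
  if (anyNA(x)) {
    abort(sprintf("missing values (check columns %s)",
                  paste(DEPTH_COLS, collapse = ", ")))
  }
  x$pos <- x$pos - 1L
  resorted <- arrange(x, .data$chrom, .data$pos)
  if (!identical(resorted$pos, x$pos) || !identical(resorted$chrom, x$chrom)) {
    warn("input was not position-sorted; sorting")
    x <- resorted
  }
  x
}

#' Write a phased allele-depth table
#'
#' @param depths Allele-depth tibble (0-based positions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_depths <- function(depths, path) {
  stopifnot(all(DEPTH_COLS %in% names(depths)))
  out <- depths[, DEPTH_COLS]
  out$pos <- out$pos + 1L
  writeLines(paste0("#", paste(DEPTH_COLS, collapse = "\t")), path)
  readr::write_tsv(out, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

BED_COLS <- c("chrom", "start", "end", "name", "score", "strand",
              "thick_start", "thick_end", "item_rgb")

#' Read a BED file
#'
#' Accepts BED3 to BED9; `track`, `browser` and `#` lines are skipped.
#' Coordinates (0-based half-open) are preserved exactly.
#'
#' @param path File path.
#' @return Interval tibble with as many of `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, ... columns as the file has.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  x <- readr::read_tsv(I(lines[keep]), col_names = FALSE,
                       col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (ncol(x) < 3) abort("BED needs at least 3 columns")
  names(x) <- BED_COLS[seq_len(min(ncol(x), 9))]
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if ("score" %in% names(x)) x$score <- suppressWarnings(as.numeric(x$score))
  if (any(x$start < 0)) abort("negative coordinate in BED")
  if (any(x$start >= x$end)) abort("start >= end in BED")
  as_tibble(x)
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any of `name`, `score`, `strand`
#' present, in BED column order.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- intersect(BED_COLS, names(x))
  # BED columns are positional: stop at the first absent one
  cols <- cols[seq_len(match(FALSE, BED_COLS[seq_along(cols)] == cols,
                             nomatch = length(cols) + 1) - 1)]
  out <- x[, cols]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a track as bedGraph
#'
#' Uncovered bins are omitted; runs of adjacent bins with equal values are
#' merged into one record.
#'
#' @param track A [new_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  tbl <- as_tibble(track)
  if (nrow(tbl) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  brk <- c(TRUE, tbl$chrom[-1] != tbl$chrom[-nrow(tbl)] |
             tbl$start[-1] != tbl$end[-nrow(tbl)] |
             tbl$value[-1] != tbl$value[-nrow(tbl)])
  run <- cumsum(brk)
  out <- tbl |>
    mutate(run = run) |>
    group_by(.data$run) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), value = .data$value[1],
              .groups = "drop") |>
    select("chrom", "start", "end", "value")
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a track
#'
#' Expands run-length-merged records back into fixed-width bins.
#'
#' @param path File path.
#' @param bin_width Bin width of the original track.
#' @param chrom_lengths Chromosome lengths (default: inferred from data).
#' @return A [new_track()].
#' @export
read_bedgraph <- function(path, bin_width, chrom_lengths = NULL) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "cddd", progress = FALSE)
  cl <- chrom_lengths %||%
    vapply(split(x$end, x$chrom), max, 0)
  if (nrow(x) == 0) {
    return(new_track(tibble(chrom = character(), start = numeric(),
                            end = numeric(), value = numeric()),
                     bin_width, cl %||% c(chr1 = bin_width)))
  }
  expanded <- x |>
    mutate(bin0 = floor(.data$start / bin_width),
           bin1 = ceiling(.data$end / bin_width) - 1) |>
    rowwise() |>
    reframe(chrom = .data$chrom, bin = seq(.data$bin0, .data$bin1),
            value = .data$value) |>
    mutate(start = .data$bin * bin_width,
           end = pmin(.data$start + bin_width, as_chrom_lengths(cl)[.data$chrom]))
  new_track(expanded[, c("chrom", "start", "end", "value")], bin_width, cl)
}

#' Write called ARDs as BED9+
#'
#' Columns: chrom, start, end, name, score (`-10 log10 q`, capped at 1000),
#' strand (`+` = paternal-delayed), p, q, coverage, delay_minutes. Cores can
#' be written as a companion BED6.
#'
#' @param ards A `timex_ards` tibble.
#' @param path Output path.
#' @param cores_path Optional companion path for core sub-intervals.
#' @return `path`, invisibly.
#' @export
write_ards_bed <- function(ards, path, cores_path = NULL) {
  out <- tibble(chrom = ards$chrom,
                start = format(ards$start, scientific = FALSE, trim = TRUE),
                end = format(ards$end, scientific = FALSE, trim = TRUE),
                name = paste0("ard_", seq_len(nrow(ards))),
                score = round(pmin(1000, -10 * log10(pmax(ards$q_value, 1e-100)))),
                strand = ifelse(ards$sign == "paternal-delayed", "+", "-"),
                p = signif(ards$p_value, 4), q = signif(ards$q_value, 4),
                coverage = round(ards$coverage, 4),
                delay_minutes = round(ards$delay_minutes, 2))
  readr::write_tsv(out, path, col_names = FALSE)
  if (!is.null(cores_path)) {
    cores <- dplyr::bind_rows(ards$cores, .id = "ard")
    cc <- tibble(chrom = cores$chrom,
                 start = format(cores$start, scientific = FALSE, trim = TRUE),
                 end = format(cores$end, scientific = FALSE, trim = TRUE),
                 name = paste0("core_", cores$ard),
                 score = round(cores$delay_minutes, 2),
                 strand = ifelse(cores$delay_minutes >= 0, "+", "-"))
    readr::write_tsv(cc, cores_path, col_names = FALSE)
  }
  invisible(path)
}
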