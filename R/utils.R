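# Internal helpers shared across modules: chromosome bookkeeping, seed
# derivation, and tibble <-> IRanges bridging for interval arithmetic.
# All genomic coordinates are 0-based half-open internally; 1-based only at
# the TSV/VCF file boundary.

# Normalise chromosome lengths to a named numeric vector.
as_chrom_lengths <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "length") %in% names(x)))
    x <- setNames(as.numeric(x$length), as.character(x$chrom))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("chromosome lengths must be named")
  }
  if (any(x <= 0)) abort("chromosome lengths must be > 0")
  x
}

#' Derive a per-stage seed from a global seed
#'
#' Counter-based derivation: one global seed expands deterministically to
#' per-stage seeds so pipeline stages are individually reproducible. Results
#' stay below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label.
#' @param index Optional replicate counter.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  s <- (as.numeric(seed) %% m) * 48271 + h * 7919 + as.numeric(index) * 104729
  as.integer(s %% (m - 1)) + 1L
}

check_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns chrom, start, end", arg))
  }
  if (any(x$start < 0)) abort(sprintf("`%s` has negative coordinates", arg))
  if (any(x$start >= x$end)) abort(sprintf("`%s` has start >= end", arg))
  invisible(x)
}

sort_intervals <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

# IRanges views of a tidy interval tibble, one per chromosome.
# 0-based half-open [start, end) -> IRanges 1-based closed [start + 1, end].
.ir_by_chrom <- function(x) {
  split(IRanges::IRanges(start = x$start + 1L, end = x$end), x$chrom)
}

# Logical per row of `a`: does it overlap (>= 1 bp) any interval of `b`?
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  ir_b <- .ir_by_chrom(b)
  out <- rep(FALSE, nrow(a))
  for (ch in unique(a$chrom)) {
    sel <- which(a$chrom == ch)
    if (is.null(ir_b[[ch]])) next
    ir_a <- IRanges::IRanges(start = a$start[sel] + 1L, end = a$end[sel])
    out[sel] <- IRanges::overlapsAny(ir_a, ir_b[[ch]])
  }
  out
}

# Merge overlapping or bookended intervals (IRanges::reduce per chromosome).
merge_intervals <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) return(sort_intervals(x[, c("chrom", "start", "end")]))
  parts <- lapply(split(x, x$chrom), function(sub) {
    red <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1L, end = sub$end))
    tibble(chrom = sub$chrom[1],
           start = as.numeric(IRanges::start(red)) - 1,
           end = as.numeric(IRanges::end(red)))
  })
  sort_intervals(dplyr::bind_rows(parts))
}

# For each row of `a`, the row index in `b` with the largest overlap (NA if
# none). Used to match detected domains to simulated truth regions.
match_max_overlap <- function(a, b) {
  if (nrow(a) == 0) return(integer(0))
  out <- rep(NA_integer_, nrow(a))
  if (nrow(b) == 0) return(out)
  for (ch in unique(a$chrom)) {
    sa <- which(a$chrom == ch)
    sb <- which(b$chrom == ch)
    if (length(sb) == 0) next
    ir_a <- IRanges::IRanges(start = a$start[sa] + 1L, end = a$end[sa])
    ir_b <- IRanges::IRanges(start = b$start[sb] + 1L, end = b$end[sb])
    hits <- IRanges::findOverlaps(ir_a, ir_b)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(
      ir_a[S4Vectors::queryHits(hits)], ir_b[S4Vectors::subjectHits(hits)]))
    hl <- split(seq_along(ov), S4Vectors::queryHits(hits))
    for (q in names(hl)) {
      ids <- hl[[q]]
      best <- ids[which.max(ov[ids])]
      out[sa[as.integer(q)]] <- sb[S4Vectors::subjectHits(hits)[best]]
    }
  }
  out
}

# Sum of total interval widths.
total_width <- function(x) sum(x$end - x$start)
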