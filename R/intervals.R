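#' Genomic interval tibbles
#'
#' Intervals throughout tgscan are plain tibbles with columns `chrom`,
#' `start`, `end` (1-based, closed, `end >= start`) and optionally `strand`
#' (`"+"`, `"-"` or `"."`). `interval_tbl()` builds and validates one.
#'
#' @param chrom Character vector of reference names.
#' @param start,end Integer vectors, 1-based closed bounds, `end >= start`.
#' @param strand Optional strand vector, recycled.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' interval_tbl("chr1", c(1, 50), c(10, 99))
#' @export
interval_tbl <- function(chrom, start, end, strand = ".") {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$end < x$start)) {
    stop("interval end < start", call. = FALSE)
  }
  if (nrow(x) && any(x$start < 1L)) {
    stop("interval start < 1 (coordinates are 1-based)", call. = FALSE)
  }
  invisible(x)
}

iranges_by_chrom <- function(x) {
  split(IRanges::IRanges(start = x$start, end = x$end), x$chrom)
}

#' Merge intervals into a minimal disjoint cover
#'
#' Overlapping or bookended intervals on the same chromosome are unioned;
#' intervals on different chromosomes are never merged together.
#'
#' @param x An interval tibble (see [interval_tbl()]).
#' @return An interval tibble sorted by `(chrom, start)`, pairwise disjoint.
#' @examples
#' interval_merge(interval_tbl("s", c(1, 6), c(10, 15)))
#' @export
interval_merge <- function(x) {
  validate_intervals(x)
  if (!nrow(x)) {
    return(interval_tbl(character(), integer(), integer()))
  }
  merged <- lapply(iranges_by_chrom(x), IRanges::reduce)
  dplyr::bind_rows(lapply(names(merged), function(ch) {
    r <- merged[[ch]]
    tibble(chrom = ch, start = IRanges::start(r), end = IRanges::end(r),
           strand = ".")
  })) %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Total overlap of intervals against a track
#'
#' Counts, for each row of `x`, how many of its bases fall inside the merged
#' `track` (each base counted once even if the raw track covers it twice).
#'
#' @param x Interval tibble whose overlap is measured.
#' @param track Interval tibble acting as the reference track.
#' @return Integer vector, one total per row of `x`.
#' @examples
#' interval_overlap_length(interval_tbl("s", 1, 10), interval_tbl("s", 9, 20))
#' @export
interval_overlap_length <- function(x, track) {
  validate_intervals(x)
  merged <- interval_merge(track)
  out <- integer(nrow(x))
  if (!nrow(x) || !nrow(merged)) {
    return(out)
  }
  tr <- iranges_by_chrom(merged)
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    if (is.null(tr[[ch]])) next
    q <- IRanges::IRanges(start = x$start[idx], end = x$end[idx])
    hits <- IRanges::findOverlaps(q, tr[[ch]])
    if (length(hits)) {
      ov <- IRanges::pintersect(
        q[S4Vectors::queryHits(hits)],
        tr[[ch]][S4Vectors::subjectHits(hits)]
      )
      w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
      out[idx[as.integer(names(w))]] <- as.integer(w)
    }
  }
  out
}

#' Per-position depth of an interval set over one chromosome region
#'
#' @param x Interval tibble (e.g. aligned blocks).
#' @param chrom Chromosome to profile.
#' @param from,to 1-based closed bounds of the profiled window.
#' @return A tibble with columns `pos` and `depth` covering `from:to`.
#' @export
interval_depth <- function(x, chrom, from, to) {
  validate_intervals(x)
  stopifnot(to >= from, from >= 1)
  sel <- x[x$chrom == chrom & x$end >= from & x$start <= to, ]
  cov <- IRanges::coverage(
    IRanges::IRanges(start = pmax(sel$start, from), end = pmin(sel$end, to)),
    width = to
  )
  tibble(pos = seq.int(from, to),
         depth = as.integer(cov)[seq.int(from, to)])
}
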