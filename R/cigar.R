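#' CIGAR arithmetic
#'
#' Junction localization works directly on alignment CIGAR strings: the
#' reference span of an alignment is the summed length of its
#' reference-consuming operations (`M`, `D`, `N`, `=`, `X`), so the last
#' reference base touched by a record at `pos` is `pos + cigar_ref_span - 1`.
#'
#' @param cigar Character vector of CIGAR strings (e.g. `"50M75S"`); `"*"`
#'   yields span 0.
#' @return `cigar_ref_span()`/`cigar_query_span()`: integer vector.
#'   `cigar_ops()`: a list of tibbles with columns `op` and `len`.
#' @examples
#' cigar_ref_span("30M5I20M")   # 50: insertions consume the query only
#' cigar_ref_span("10M2D10M30S") # 22
#' @export
cigar_ref_span <- function(cigar) {
  cigar_op_sum(cigar, c("M", "D", "N", "=", "X"))
}

#' @rdname cigar_ref_span
#' @export
cigar_query_span <- function(cigar) {
  cigar_op_sum(cigar, c("M", "I", "S", "=", "X"))
}

#' @rdname cigar_ref_span
#' @export
cigar_ops <- function(cigar) {
  lens <- stringr::str_extract_all(cigar, "[0-9]+")
  ops <- stringr::str_extract_all(cigar, "[A-Za-z=]")
  purrr::map2(ops, lens, function(o, l) {
    bad <- setdiff(o, c("M", "I", "D", "N", "S", "H", "P", "=", "X"))
    if (length(bad)) {
      stop("unknown CIGAR operation: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    l <- as.integer(l)
    if (length(o) != length(l) || any(l <= 0)) {
      stop("malformed CIGAR string", call. = FALSE)
    }
    tibble(op = o, len = l)
  })
}

cigar_op_sum <- function(cigar, which_ops) {
  out <- integer(length(cigar))
  todo <- !is.na(cigar) & cigar != "*" & cigar != ""
  if (!any(todo)) return(out)
  # vectorized fast path: optional clip + single M + optional clip
  fp <- todo &
    grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", cigar)
  if (any(fp)) {
    m <- as.integer(stringr::str_match(cigar[fp], "([0-9]+)M")[, 2])
    cl <- cigar_clips(cigar[fp])
    out[fp] <- if ("M" %in% which_ops) m else 0L
    if ("S" %in% which_ops) out[fp] <- out[fp] + cl$left + cl$right
  }
  slow <- todo & !fp
  if (any(slow)) {
    out[slow] <- vapply(cigar_ops(cigar[slow]), function(tb) {
      sum(tb$len[tb$op %in% which_ops])
    }, integer(1))
  }
  out
}

#' Soft-clip lengths at either end of a CIGAR
#'
#' @param cigar Character vector of CIGAR strings.
#' @return A tibble with integer columns `left` and `right` (clip lengths,
#'   counting `S` and `H` operations at the respective end).
#' @export
cigar_clips <- function(cigar) {
  left <- as.integer(stringr::str_match(cigar, "^([0-9]+)[SH]")[, 2])
  right <- as.integer(stringr::str_match(cigar, "([0-9]+)[SH]$")[, 2])
  tibble(left = dplyr::coalesce(left, 0L), right = dplyr::coalesce(right, 0L))
}

#' Reference-aligned blocks of alignments
#'
#' Expands each record's CIGAR into the reference intervals its `M`/`=`/`X`/`D`
#' operations cover, splitting at `N` (skipped intron) operations. Used for
#' depth profiling and fragment counting.
#'
#' @param aln Alignment tibble (see [read_sam()]).
#' @param split_deletions If `TRUE`, `D` operations also split blocks (default
#'   `FALSE`: deleted reference bases count as covered, the convention of
#'   depth-from-alignment tools).
#' @return Interval tibble with an extra `row_id` column indexing `aln` rows.
#' @export
alignment_blocks <- function(aln, split_deletions = FALSE) {
  if (!nrow(aln)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), row_id = integer()))
  }
  consume <- c("M", "D", "N", "=", "X")
  breakers <- if (split_deletions) c("N", "D") else "N"
  # vectorized fast path: a single M run (clips allowed) is one block
  fp <- grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", aln$cigar)
  fast <- NULL
  if (any(fp)) {
    m <- as.integer(stringr::str_match(aln$cigar[fp], "([0-9]+)M")[, 2])
    fast <- tibble(start = aln$pos[fp], end = aln$pos[fp] + m - 1L,
                   row_id = which(fp))
  }
  if (all(fp)) {
    out <- fast
    return(tibble(chrom = aln$rname[out$row_id],
                  start = out$start, end = out$end,
                  strand = ifelse(aln$is_reverse[out$row_id], "-", "+"),
                  row_id = out$row_id))
  }
  slow_idx <- which(!fp)
  ops <- cigar_ops(aln$cigar[slow_idx])
  res <- purrr::imap(ops, function(tb, k) {
    i <- slow_idx[k]
    offs <- cumsum(c(0L, tb$len * (tb$op %in% consume)))
    keep <- which(tb$op %in% setdiff(consume, breakers))
    if (!length(keep)) return(NULL)
    st <- aln$pos[i] + offs[keep]
    en <- st + tb$len[keep] - 1L
    # fuse blocks adjacent on the reference (e.g. around a D op)
    grp <- cumsum(c(TRUE, st[-1] != en[-length(en)] + 1L))
    tibble(start = as.integer(tapply(st, grp, min)),
           end = as.integer(tapply(en, grp, max)),
           row_id = i)
  })
  out <- dplyr::bind_rows(c(list(fast), res))
  out <- out[order(out$row_id), ]
  tibble(chrom = aln$rname[out$row_id],
         start = out$start, end = out$end,
         strand = ifelse(aln$is_reverse[out$row_id], "-", "+"),
         row_id = out$row_id)
}
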