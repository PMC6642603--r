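#' Read and write SAM text
#'
#' The pipeline starts at alignments, consumed as SAM text (any aligner's
#' output). Records become a tibble with one row per alignment line:
#' `qname`, `flag`, `rname`, `pos` (1-based leftmost), `mapq`, `cigar`,
#' `rnext` (mate reference, `=` resolved), `pnext`, `tlen`, `seq`, `qual`,
#' decoded flag columns (`is_paired`, `is_proper`, `is_unmapped`,
#' `mate_unmapped`, `is_reverse`, `is_first`, `is_secondary`, `is_duplicate`,
#' `is_supplementary`), `nm` / `score` from the `NM:i` / `AS:i` tags, and the
#' raw `tags` string. The `@SQ` dictionary is kept in the `"sq"` attribute
#' (tibble `name`, `length`).
#'
#' @param path Path to a SAM file with an `@SQ` header covering every
#'   reference used by a mapped record.
#' @return A tibble of alignments (see Details).
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "@")]
  body <- ln[!startsWith(ln, "@") & nzchar(ln)]
  sq_ln <- hdr[startsWith(hdr, "@SQ")]
  sq <- tibble(
    name = stringr::str_match(sq_ln, "SN:([^\t]+)")[, 2],
    length = as.integer(stringr::str_match(sq_ln, "LN:([0-9]+)")[, 2])
  )
  if (!length(body)) {
    out <- empty_alignments()
    attr(out, "sq") <- sq
    return(out)
  }
  f <- stringr::str_split_fixed(body, "\t", 12)
  bad <- !grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", f[, 6])
  if (any(bad)) {
    stop("unknown or malformed CIGAR: ", f[which(bad)[1], 6], call. = FALSE)
  }
  rname <- f[, 3]
  known <- rname == "*" | rname %in% sq$name
  if (!all(known)) {
    stop("reference absent from @SQ header: ",
         paste(unique(rname[!known])[1:min(3, sum(!known))], collapse = ", "),
         call. = FALSE)
  }
  flag <- as.integer(f[, 2])
  tags <- f[, 12]
  aln <- tibble(
    qname = f[, 1], flag = flag, rname = rname,
    pos = as.integer(f[, 4]), mapq = as.integer(f[, 5]), cigar = f[, 6],
    rnext = ifelse(f[, 7] == "=", rname, f[, 7]),
    pnext = as.integer(f[, 8]), tlen = as.integer(f[, 9]),
    seq = f[, 10], qual = f[, 11],
    nm = as.integer(stringr::str_match(tags, "NM:i:(-?[0-9]+)")[, 2]),
    score = as.integer(stringr::str_match(tags, "AS:i:(-?[0-9]+)")[, 2]),
    tags = tags
  )
  aln <- decode_sam_flags(aln)
  qlen <- cigar_query_span(aln$cigar)
  with_seq <- aln$seq != "*" & aln$cigar != "*"
  if (any(with_seq & nchar(aln$seq) != qlen)) {
    stop("CIGAR query span disagrees with SEQ length", call. = FALSE)
  }
  attr(aln, "sq") <- sq
  aln
}

decode_sam_flags <- function(aln) {
  b <- function(bit) bitwAnd(aln$flag, bit) > 0L
  aln$is_paired <- b(1L); aln$is_proper <- b(2L)
  aln$is_unmapped <- b(4L); aln$mate_unmapped <- b(8L)
  aln$is_reverse <- b(16L); aln$is_first <- b(64L)
  aln$is_secondary <- b(256L); aln$is_duplicate <- b(1024L)
  aln$is_supplementary <- b(2048L)
  aln
}

empty_alignments <- function() {
  decode_sam_flags(tibble(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    rnext = character(), pnext = integer(), tlen = integer(),
    seq = character(), qual = character(), nm = integer(), score = integer(),
    tags = character()
  ))
}

#' @rdname read_sam
#' @param aln Alignment tibble.
#' @param sq `@SQ` dictionary tibble (`name`, `length`); defaults to the
#'   `"sq"` attribute of `aln`.
#' @export
write_sam <- function(aln, path, sq = attr(aln, "sq")) {
  stopifnot(!is.null(sq))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", sq$name, "\tLN:", sq$length))
  if (!nrow(aln)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  tags <- dplyr::coalesce(aln$tags, "")
  no_tag <- !nzchar(tags)
  rebuilt <- paste0(
    ifelse(is.na(aln$nm), "", paste0("NM:i:", aln$nm)),
    ifelse(is.na(aln$nm) | is.na(aln$score), "", "\t"),
    ifelse(is.na(aln$score), "", paste0("AS:i:", aln$score))
  )
  tags[no_tag] <- rebuilt[no_tag]
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                ifelse(aln$rnext == aln$rname & aln$rname != "*", "=",
                       aln$rnext),
                aln$pnext, aln$tlen, aln$seq, aln$qual, sep = "\t")
  body <- ifelse(nzchar(tags), paste(body, tags, sep = "\t"), body)
  writeLines(c(hdr, body), path)
  invisible(path)
}
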