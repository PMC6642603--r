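#' Classify the coding impact of variants
#'
#' A simplified codon-level consequence classifier. CDS SNVs are translated
#' with the standard genetic code after strand-aware codon extraction
#' (synonymous / missense / stop_gained / stop_lost / start_lost); CDS
#' indels are frameshift when the length difference is not a multiple of 3,
#' else inframe_indel; variants in the two intronic bases flanking an exon
#' are splice_site; everything else is non_coding. Impact levels:
#' frameshift, stop_gained, stop_lost, start_lost and splice_site are HIGH,
#' missense and inframe_indel MODERATE, synonymous LOW, non_coding MODIFIER.
#'
#' @param variants Variant tibble.
#' @param models Gene-model tibble.
#' @param genome FASTA tibble.
#' @return Tibble with one row per (variant, overlapping transcript):
#'   variant key columns plus `gene_id`, `transcript_id`, `consequence`,
#'   `impact`, `low_confidence` (set when the transcript's CDS length is
#'   not a multiple of 3).
#' @export
classify_impact <- function(variants, models, genome) {
  tx_ids <- unique(models$transcript_id)
  maps <- lapply(stats::setNames(tx_ids, tx_ids), function(tx) {
    cds <- models[models$transcript_id == tx & models$type == "cds", ]
    ex <- models[models$transcript_id == tx & models$type == "exon", ]
    if (!nrow(cds)) return(NULL)
    bm <- block_map_of(cds)
    list(bm = bm, exons = ex[order(ex$start), ],
         chrom = cds$chrom[1], strand = cds$strand[1],
         gene_id = cds$gene_id[1],
         cds_seq = spliced_seq(genome, bm),
         lo = min(cds$start), hi = max(cds$end))
  })
  maps <- maps[!vapply(maps, is.null, logical(1))]
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hits <- lapply(names(maps), function(tx) {
      classify_one(v, tx, maps[[tx]])
    })
    dplyr::bind_rows(hits)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene_id = character(),
                  transcript_id = character(), consequence = character(),
                  impact = character(), low_confidence = logical()))
  }
  out
}

block_map_of <- function(parts) {
  minus <- parts$strand[1] == "-"
  parts <- parts[order(parts$start), ]
  ord <- if (minus) rev(seq_len(nrow(parts))) else seq_len(nrow(parts))
  w <- parts$end[ord] - parts$start[ord] + 1L
  te <- cumsum(w)
  tibble(t_start = te - w + 1L, t_end = te, ref = parts$chrom[ord],
         ref_start = parts$start[ord], ref_end = parts$end[ord],
         strand = if (minus) "-" else "+")
}

spliced_seq <- function(genome, bm) {
  # bm rows are in transcript order; minus-strand blocks descend genomically
  s <- genome$seq[match(bm$ref[1], genome$id)]
  parts <- substring(s, bm$ref_start, bm$ref_end)
  if (bm$strand[1] == "-") {
    paste(unname(vapply(parts, revcomp, character(1))), collapse = "")
  } else {
    paste(parts, collapse = "")
  }
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

classify_one <- function(v, tx, mp) {
  if (v$chrom != mp$chrom) return(NULL)
  span_lo <- min(mp$exons$start); span_hi <- max(mp$exons$end)
  if (v$pos < span_lo - 2L || v$pos > span_hi + 2L) return(NULL)
  in_cds_block <- which(v$pos >= mp$bm$ref_start & v$pos <= mp$bm$ref_end)
  cons <- NULL
  low_conf <- nchar(mp$cds_seq) %% 3L != 0L
  if (v$vtype != "SNV") {
    # anchored-base convention: the event sits after `pos`
    ev_lo <- v$pos + 1L
    ev_hi <- v$pos + max(nchar(v$ref), 2L) - 1L
    touches_cds <- any(ev_lo <= mp$bm$ref_end & ev_hi >= mp$bm$ref_start)
    if (touches_cds) {
      shift <- abs(nchar(v$ref) - nchar(v$alt))
      cons <- if (shift %% 3L != 0L) "frameshift" else "inframe_indel"
    } else if (is_splice_site(v$pos, mp$exons) ||
                 is_splice_site(ev_hi, mp$exons)) {
      cons <- "splice_site"
    } else {
      cons <- "non_coding"
    }
  } else if (length(in_cds_block)) {
    b <- mp$bm[in_cds_block[1], ]
    cpos <- if (b$strand == "+") b$t_start + (v$pos - b$ref_start) else
      b$t_start + (b$ref_end - v$pos)
    alt_c <- if (b$strand == "+") v$alt else COMPLEMENT[[v$alt]]
    codon_i <- (cpos - 1L) %/% 3L + 1L
    c0 <- (codon_i - 1L) * 3L + 1L
    if (c0 + 2L > nchar(mp$cds_seq)) {
      cons <- "non_coding"  # trailing partial codon of a flagged CDS
    } else {
      ref_codon <- substr(mp$cds_seq, c0, c0 + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, cpos - c0 + 1L, cpos - c0 + 1L) <- alt_c
      aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
      aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
      cons <- if (codon_i == 1L && aa_alt != "M") {
        "start_lost"
      } else if (aa_ref != "*" && aa_alt == "*") {
        "stop_gained"
      } else if (aa_ref == "*" && aa_alt != "*") {
        "stop_lost"
      } else if (aa_ref == aa_alt) {
        "synonymous"
      } else {
        "missense"
      }
    }
  } else if (is_splice_site(v$pos, mp$exons)) {
    cons <- "splice_site"
  } else {
    cons <- "non_coding"
  }
  impact <- c(
    frameshift = "HIGH", stop_gained = "HIGH", stop_lost = "HIGH",
    start_lost = "HIGH", splice_site = "HIGH",
    missense = "MODERATE", inframe_indel = "MODERATE",
    synonymous = "LOW", non_coding = "MODIFIER"
  )[[cons]]
  tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
         gene_id = mp$gene_id, transcript_id = tx, consequence = cons,
         impact = impact, low_confidence = low_conf)
}

# within the 2 intronic bases flanking an internal exon boundary
is_splice_site <- function(pos, exons) {
  if (nrow(exons) < 2) return(FALSE)
  donors <- exons$end[-nrow(exons)]
  acceptors <- exons$start[-1]
  any(pos >= donors + 1L & pos <= donors + 2L) ||
    any(pos <= acceptors - 1L & pos >= acceptors - 2L)
}
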