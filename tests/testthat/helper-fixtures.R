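# shared builders and independent brute-force oracles

make_aln <- function(qname, flag, rname, pos, cigar,
                     seq = strrep("A", tgscan::cigar_query_span(cigar)),
                     mapq = 60L, rnext = rname, pnext = pos, tlen = 0L,
                     qual = strrep("I", nchar(seq)), nm = NA_integer_,
                     score = NA_integer_, tags = NA_character_,
                     sq = NULL) {
  n <- max(lengths(list(qname, flag, rname, pos, cigar)))
  aln <- tibble::tibble(
    qname = rep_len(qname, n), flag = as.integer(rep_len(flag, n)),
    rname = rep_len(rname, n), pos = as.integer(rep_len(pos, n)),
    mapq = as.integer(rep_len(mapq, n)), cigar = rep_len(cigar, n),
    rnext = rep_len(rnext, n), pnext = as.integer(rep_len(pnext, n)),
    tlen = as.integer(rep_len(tlen, n)), seq = rep_len(seq, n),
    qual = rep_len(qual, n), nm = rep_len(as.integer(nm), n),
    score = rep_len(as.integer(score), n), tags = rep_len(tags, n)
  )
  aln <- tgscan:::decode_sam_flags(aln)
  if (is.null(sq)) {
    refs <- unique(aln$rname[aln$rname != "*"])
    sq <- tibble::tibble(name = refs, length = 10000000L)
  }
  attr(aln, "sq") <- sq
  aln
}

# two-exon gene model on one scaffold, plus strand
toy_models <- function(chrom = "s1", starts = c(101L, 501L),
                       ends = c(300L, 700L), strand = "+",
                       gene_id = "gA", transcript_id = "gA.t1") {
  dplyr::bind_rows(
    tibble::tibble(chrom = chrom, type = "exon", start = starts,
                   end = ends, strand = strand, gene_id = gene_id,
                   transcript_id = transcript_id),
    tibble::tibble(chrom = chrom, type = "cds", start = starts,
                   end = ends, strand = strand, gene_id = gene_id,
                   transcript_id = transcript_id)
  )
}

toy_variant <- function(chrom = "c1", pos = 100L, ref = "A", alt = "G",
                        qual = 50, depth = 20L, ref_count = 0L,
                        alt_count = 20L, alt_fwd = 10L, alt_rev = 10L,
                        mq_mean = 60, mq0f = 0, vtype = "SNV") {
  n <- max(lengths(list(pos, ref, alt, depth)))
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n), depth = as.integer(rep_len(depth, n)),
    ref_count = as.integer(rep_len(ref_count, n)),
    alt_count = as.integer(rep_len(alt_count, n)),
    alt_fwd = as.integer(rep_len(alt_fwd, n)),
    alt_rev = as.integer(rep_len(alt_rev, n)),
    mq_mean = rep_len(mq_mean, n), mq0f = rep_len(mq0f, n),
    vtype = rep_len(vtype, n), info = "."
  )
}

# O(n^2) oracle for total overlap of each interval with a merged track
brute_overlap_length <- function(x, track) {
  vapply(seq_len(nrow(x)), function(i) {
    covered <- integer(0)
    tr <- track[track$chrom == x$chrom[i], ]
    for (j in seq_len(nrow(tr))) {
      lo <- max(x$start[i], tr$start[j]); hi <- min(x$end[i], tr$end[j])
      if (hi >= lo) covered <- union(covered, lo:hi)
    }
    length(covered)
  }, integer(1))
}

# exhaustive-subset oracle for the mutually-compatible-HSP fraction
brute_mchsp <- function(hsps, query_length) {
  n <- nrow(hsps)
  if (!n) return(0)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1) {
      s <- hsps$qstart[sel]; e <- hsps$qend[sel]
      o <- order(s)
      if (any(s[o][-1] <= e[o][-length(o)])) next
    }
    best <- max(best, sum(hsps$qend[sel] - hsps$qstart[sel] + 1))
  }
  best / query_length
}

# direct neighborhood-scan oracle for the transcriptomic positional rules
brute_positional_removed <- function(v, snv_indel = 10, indel_pair = 100,
                                     k = 3, span = 10) {
  removed <- rep(FALSE, nrow(v))
  for (i in seq_len(nrow(v))) {
    same <- which(v$chrom == v$chrom[i])
    others <- setdiff(same, i)
    if (v$vtype[i] == "SNV") {
      near_ind <- any(v$vtype[others] != "SNV" &
                        abs(v$pos[others] - v$pos[i]) <= snv_indel)
      snvs <- v$pos[same][v$vtype[same] == "SNV"]
      in_cluster <- FALSE
      if (length(snvs) >= k) {
        cmb <- utils::combn(snvs, k)
        hits <- cmb[, apply(cmb, 2, function(cc) {
          max(cc) - min(cc) <= span
        }), drop = FALSE]
        in_cluster <- v$pos[i] %in% as.vector(hits)
      }
      removed[i] <- near_ind || in_cluster
    } else {
      removed[i] <- any(v$vtype[others] != "SNV" &
                          abs(v$pos[others] - v$pos[i]) <= indel_pair)
    }
  }
  removed
}

random_hsps <- function(n, qlen) {
  s <- sample.int(qlen, n, replace = TRUE)
  w <- sample.int(max(2L, qlen %/% 3L), n, replace = TRUE)
  tibble::tibble(qstart = s, qend = pmin(qlen, s + w))
}

# truth bridging-pair set computed from fragment arithmetic, not CIGARs:
# each read's primary maps to the block holding the majority of its bases;
# a fragment bridges iff exactly one primary lies on the construct
truth_bridging <- function(fragments, haplotypes, read_length,
                           construct_name) {
  out <- character(0)
  for (i in seq_len(nrow(fragments))) {
    hp <- haplotypes[[fragments$hap[i]]]
    bl <- hp$blocks
    if (nrow(bl) == 1) next
    a1 <- fragments$start[i]; b1 <- a1 + read_length - 1L
    b2 <- fragments$start[i] + fragments$len[i] - 1L
    a2 <- b2 - read_length + 1L
    majority_block <- function(a, b) {
      ov <- pmax(0L, pmin(b, bl$hap_end) - pmax(a, bl$hap_start) + 1L)
      which.max(ov)
    }
    j1 <- majority_block(a1, b1); j2 <- majority_block(a2, b2)
    on_cons <- bl$ref[c(j1, j2)] == construct_name
    if (xor(on_cons[1], on_cons[2])) out <- c(out, fragments$qname[i])
  }
  out
}
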