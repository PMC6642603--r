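#' Mature transcript sequences and coordinate maps
#'
#' @param genome FASTA tibble.
#' @param models Gene-model tibble.
#' @param transcript_id Transcript to extract.
#' @return `transcript_seq()`: the spliced sequence (5'->3').
#'   `transcript_block_map()`: tibble mapping transcript coordinates to
#'   genome blocks (`t_start`, `t_end`, `ref`, `ref_start`, `ref_end`,
#'   `strand`), rows in transcript order.
#' @export
transcript_seq <- function(genome, models, transcript_id) {
  ex <- transcript_exons(models, transcript_id)
  s <- genome$seq[match(ex$chrom[1], genome$id)]
  parts <- substring(s, ex$start, ex$end)
  out <- paste(parts, collapse = "")
  if (ex$strand[1] == "-") revcomp(out) else out
}

transcript_exons <- function(models, transcript_id) {
  ex <- models[models$transcript_id == transcript_id &
                 models$type == "exon", ]
  if (!nrow(ex)) stop("transcript has no exons: ", transcript_id,
                      call. = FALSE)
  ex[order(ex$start), ]
}

#' @rdname transcript_seq
#' @export
transcript_block_map <- function(models, transcript_id) {
  ex <- transcript_exons(models, transcript_id)
  minus <- ex$strand[1] == "-"
  ord <- if (minus) rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  w <- ex$end[ord] - ex$start[ord] + 1L
  te <- cumsum(w)
  tibble(
    t_start = te - w + 1L, t_end = te,
    ref = ex$chrom[ord], ref_start = ex$start[ord], ref_end = ex$end[ord],
    strand = if (minus) "-" else "+"
  )
}

#' Simulate RNA-seq read pairs with truth alignments in two spaces
#'
#' Fragments are drawn from mature transcripts with expected pair count
#' `depth * abundance * length / (2 * read_length)` per transcript, so a
#' transcript at abundance 1 averages `depth` coverage. Truth alignments are
#' emitted both against the genome (spliced, `N` operations across introns)
#' and against the transcriptome plus cassette references (end-to-end). An
#' optional fusion transcript concatenates a construct's cassette to the
#' suffix of a host transcript starting at a given exon, preserving
#' downstream splicing; reads spanning the fusion point are soft-clipped on
#' their minor side.
#'
#' @param genome FASTA tibble.
#' @param models Gene-model tibble.
#' @param abundances Named numeric vector, `transcript_id -> relative
#'   abundance` (>= 0).
#' @param config A [read_sim_config()] (RNA defaults: shorter inserts are
#'   sensible, e.g. `insert_mean = 300, insert_sd = 30`).
#' @param fusion Optional list: `construct` (a [transgene_spec()]),
#'   `transcript_id`, `from_exon` (first retained exon, transcript
#'   orientation), `abundance`.
#' @return List with `tx_aln` (truth SAM vs transcriptome + cassette),
#'   `genome_aln` (truth spliced SAM vs genome + construct), `fragments`,
#'   and `transcripts` (id, length).
#' @export
simulate_rnaseq <- function(genome, models, abundances,
                            config = read_sim_config(insert_mean = 300,
                                                     insert_sd = 30),
                            fusion = NULL) {
  stopifnot(all(abundances >= 0))
  rl <- config$read_length
  tx_ids <- names(abundances)
  units <- lapply(tx_ids, function(tx) {
    gmap <- transcript_block_map(models, tx)
    seq <- transcript_seq(genome, models, tx)
    list(name = tx, seq = seq, abundance = unname(abundances[tx]),
         genome_blocks = add_hap_coords(gmap),
         tx_blocks = tibble(ref = tx, ref_start = 1L, ref_end = nchar(seq),
                            strand = "+", hap_start = 1L,
                            hap_end = nchar(seq)))
  })
  if (!is.null(fusion)) {
    units <- c(units, list(make_fusion_unit(genome, models, fusion)))
  }
  cassette_sq <- NULL
  if (!is.null(fusion)) {
    cs <- fusion$construct$segments
    clen <- cs$end[cs$segment == "C"] - cs$start[cs$segment == "C"] + 1L
    cassette_sq <- tibble(
      name = paste0(fusion$construct$name, "_cassette"), length = clen)
  }
  tx_sq <- dplyr::bind_rows(
    tibble(name = vapply(units, `[[`, character(1), "name"),
           length = vapply(units, function(u) nchar(u$seq), integer(1))),
    cassette_sq
  )
  tx_sq <- tx_sq[!duplicated(tx_sq$name), ]
  genome_sq <- reference_dict(genome,
                              if (is.null(fusion)) list() else
                                list(fusion$construct))
  withr::with_seed(config$seed, {
    frag_list <- list(); tx_rec <- list(); g_rec <- list()
    k <- 0L
    for (u in units) {
      len <- nchar(u$seq)
      if (len < rl) next
      lambda <- config$depth * u$abundance * len / (2 * rl)
      n <- stats::rpois(1, lambda)
      if (!n) next
      fl <- pmin(pmax(round(stats::rnorm(n, config$insert_mean,
                                         config$insert_sd)), rl), len)
      fs <- floor(stats::runif(n) * (len - fl + 1)) + 1L
      qn <- paste0(u$name, "_f", seq_len(n))
      sel <- tibble(qname = qn, start = as.integer(fs), len = as.integer(fl))
      sel$transcript <- u$name
      fe <- sel$start + sel$len - 1L
      hap_tx <- list(name = u$name, seq = u$seq, blocks = u$tx_blocks)
      hap_g <- list(name = u$name, seq = u$seq, blocks = u$genome_blocks)
      r1s <- sel$start; r1e <- sel$start + rl - 1L
      r2s <- fe - rl + 1L; r2e <- fe
      t1 <- extract_reads(hap_tx, r1s, r1e, FALSE, sel$qname,
                          config$error_rate)
      t2 <- extract_reads(hap_tx, r2s, r2e, TRUE, sel$qname,
                          config$error_rate)
      g1 <- extract_spliced_reads(hap_g, r1s, r1e, FALSE, sel$qname,
                                  config$error_rate)
      g2 <- extract_spliced_reads(hap_g, r2s, r2e, TRUE, sel$qname,
                                  config$error_rate)
      k <- k + 1L
      frag_list[[k]] <- sel
      tx_rec[[2 * k - 1]] <- pair_up(t1, t2, TRUE, sel)
      tx_rec[[2 * k]] <- pair_up(t2, t1, FALSE, sel)
      g_rec[[2 * k - 1]] <- pair_up(g1, g2, TRUE, sel)
      g_rec[[2 * k]] <- pair_up(g2, g1, FALSE, sel)
    }
    empty <- empty_alignments()
    tx_aln <- if (k) dplyr::bind_rows(tx_rec) else empty
    g_aln <- if (k) dplyr::bind_rows(g_rec) else empty
    list(
      tx_aln = finalize_alignments(tx_aln, tx_sq),
      genome_aln = finalize_alignments(g_aln, genome_sq),
      fragments = if (k) dplyr::bind_rows(frag_list) else NULL,
      transcripts = tx_sq
    )
  })
}

add_hap_coords <- function(gmap) {
  tibble(ref = gmap$ref, ref_start = gmap$ref_start, ref_end = gmap$ref_end,
         strand = gmap$strand, hap_start = gmap$t_start,
         hap_end = gmap$t_end)
}

make_fusion_unit <- function(genome, models, fusion) {
  cs <- fusion$construct$segments
  crow <- cs[cs$segment == "C", ]
  cass_seq <- substr(fusion$construct$seq, crow$start, crow$end)
  clen <- nchar(cass_seq)
  gmap <- transcript_block_map(models, fusion$transcript_id)
  if (fusion$from_exon < 1 || fusion$from_exon > nrow(gmap)) {
    stop("fusion references unknown exon index", call. = FALSE)
  }
  keep <- gmap[seq.int(fusion$from_exon, nrow(gmap)), ]
  t0 <- keep$t_start[1] - 1L
  host_seq <- substring(transcript_seq(genome, models, fusion$transcript_id),
                        keep$t_start[1])
  fseq <- paste0(cass_seq, host_seq)
  genome_blocks <- dplyr::bind_rows(
    tibble(ref = fusion$construct$name, ref_start = crow$start,
           ref_end = crow$end, strand = "+", hap_start = 1L, hap_end = clen),
    tibble(ref = keep$ref, ref_start = keep$ref_start,
           ref_end = keep$ref_end, strand = keep$strand,
           hap_start = keep$t_start - t0 + clen,
           hap_end = keep$t_end - t0 + clen)
  )
  tx_blocks <- dplyr::bind_rows(
    tibble(ref = paste0(fusion$construct$name, "_cassette"), ref_start = 1L,
           ref_end = clen, strand = "+", hap_start = 1L, hap_end = clen),
    tibble(ref = fusion$transcript_id, ref_start = keep$t_start[1],
           ref_end = keep$t_end[nrow(keep)], strand = "+",
           hap_start = clen + 1L,
           hap_end = clen + keep$t_end[nrow(keep)] - t0)
  )
  list(name = paste0(fusion$construct$name, "_fusion"), seq = fseq,
       abundance = fusion$abundance, genome_blocks = genome_blocks,
       tx_blocks = tx_blocks)
}

# spliced truth records: consecutive same-chromosome blocks join with N ops;
# segments on other references are soft-clipped away (minor side of a
# cassette-host junction read)
extract_spliced_reads <- function(hap, starts, ends, reverse, qname,
                                  error_rate) {
  seqs <- substring(hap$seq, starts, ends)
  rl <- ends - starts + 1L
  n_err <- integer(length(seqs))
  if (error_rate > 0) {
    n_err <- stats::rbinom(length(seqs), rl, error_rate)
    for (i in which(n_err > 0)) {
      at <- sample.int(rl[i], n_err[i])
      s <- strsplit(seqs[i], "")[[1]]
      s[at] <- vapply(s[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      seqs[i] <- paste(s, collapse = "")
    }
  }
  bl <- hap$blocks
  bi_s <- findInterval(starts, bl$hap_start)
  bi_e <- findInterval(ends, bl$hap_start)
  simple <- bi_s == bi_e
  parts <- vector("list", 2)
  if (any(simple)) {
    i <- which(simple)
    b <- bi_s[i]
    plus <- bl$strand[b] == "+"
    off_s <- starts[i] - bl$hap_start[b]
    off_e <- ends[i] - bl$hap_start[b]
    pos <- ifelse(plus, bl$ref_start[b] + off_s, bl$ref_end[b] - off_e)
    qn <- qname[i]
    parts[[1]] <- tibble(
      qname = qn, rname = bl$ref[b], pos = as.integer(pos),
      cigar = paste0(rl[i], "M"),
      seq = ifelse(plus, seqs[i], revcomp_chr(seqs[i])),
      reverse = xor(rep(reverse, length(i)), !plus),
      supplementary = FALSE, nm = n_err[i], primary_of = qn
    )
  }
  multi <- which(!simple)
  if (length(multi)) {
    rc_multi <- stats::setNames(revcomp_chr(seqs[multi]), multi)
    acc <- list()
    for (i in multi) {
      js <- bi_s[i]:bi_e[i]
      x <- pmax(starts[i], bl$hap_start[js])
      y <- pmin(ends[i], bl$hap_end[js])
      plus_b <- bl$strand[js] == "+"
      pos_b <- ifelse(plus_b,
                      bl$ref_start[js] + (x - bl$hap_start[js]),
                      bl$ref_end[js] - (y - bl$hap_start[js]))
      qs <- x - starts[i] + 1L
      qe <- y - starts[i] + 1L
      mlen <- y - x + 1L
      rn <- bl$ref[js]
      runs <- rle(rn)
      hi <- cumsum(runs$lengths)
      lo <- hi - runs$lengths + 1L
      n_rec <- length(runs$values)
      rec_pos <- integer(n_rec); rec_cigar <- character(n_rec)
      rec_mlen <- integer(n_rec); rec_plus <- logical(n_rec)
      for (g in seq_len(n_rec)) {
        j <- lo[g]:hi[g]
        plus <- plus_b[j[1]]
        p <- pos_b[j]; m <- mlen[j]
        o <- order(p); p <- p[o]; m <- m[o]
        gaps <- if (length(p) > 1) p[-1] - (p[-length(p)] + m[-length(m)]) else
          integer(0)
        pieces <- character(2L * length(p) - 1L)
        pieces[seq(1L, by = 2L, length.out = length(p))] <- paste0(m, "M")
        if (length(gaps)) {
          pieces[seq(2L, by = 2L, length.out = length(gaps))] <-
            paste0(gaps, "N")
        }
        lclip <- if (plus) qs[j[1]] - 1L else rl[i] - qe[j[length(j)]]
        rclip <- if (plus) rl[i] - qe[j[length(j)]] else qs[j[1]] - 1L
        rec_pos[g] <- p[1]
        rec_cigar[g] <- paste0(clip_str(lclip), paste(pieces, collapse = ""),
                               clip_str(rclip))
        rec_mlen[g] <- sum(m)
        rec_plus[g] <- plus
      }
      longest <- which.max(rec_mlen)
      acc[[length(acc) + 1]] <- list(
        qname = rep(qname[i], n_rec), rname = runs$values,
        pos = rec_pos, cigar = rec_cigar,
        seq = ifelse(rec_plus, seqs[i], rc_multi[[as.character(i)]]),
        reverse = xor(reverse, !rec_plus),
        supplementary = seq_len(n_rec) != longest,
        nm = rep(n_err[i], n_rec), primary_of = rep(qname[i], n_rec)
      )
    }
    parts[[2]] <- tibble(
      qname = unlist(lapply(acc, `[[`, "qname")),
      rname = unlist(lapply(acc, `[[`, "rname")),
      pos = as.integer(unlist(lapply(acc, `[[`, "pos"))),
      cigar = unlist(lapply(acc, `[[`, "cigar")),
      seq = unlist(lapply(acc, `[[`, "seq")),
      reverse = unlist(lapply(acc, `[[`, "reverse")),
      supplementary = unlist(lapply(acc, `[[`, "supplementary")),
      nm = as.integer(unlist(lapply(acc, `[[`, "nm"))),
      primary_of = unlist(lapply(acc, `[[`, "primary_of"))
    )
  }
  dplyr::bind_rows(parts)
}
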