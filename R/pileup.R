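#' Keep unique primary alignments and collapse PCR duplicates
#'
#' Keeps primary, non-supplementary mapped records; drops a read whose best
#' secondary alignment is within `min_score_gap` mismatches of its primary
#' (ambiguous placement); collapses PCR duplicates by the key
#' `(reference, 5'-clip-adjusted start, strand, mate reference, mate start)`,
#' keeping the record with the highest mean base quality.
#'
#' @param aln Alignment tibble; records with secondaries need `NM:i` (or
#'   `AS:i` as fallback) tags for the ambiguity test.
#' @param min_score_gap Required mismatch advantage of the primary over the
#'   best secondary alignment.
#' @return Filtered alignment tibble; counters (`n_ambiguous`,
#'   `n_duplicates`, `n_untestable`) in attribute `"dedup_counts"`.
#' @export
dedup_primary_unique <- function(aln, min_score_gap = 1L) {
  prim <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_unmapped, ]
  sec <- aln[aln$is_secondary & !aln$is_unmapped, ]
  n_ambig <- 0L; n_untest <- 0L
  if (nrow(sec)) {
    key <- paste(prim$qname, prim$is_first)
    skey <- paste(sec$qname, sec$is_first)
    best_nm <- tapply(sec$nm, skey, function(x) {
      if (all(is.na(x))) NA_integer_ else min(x, na.rm = TRUE)
    })
    best_as <- tapply(sec$score, skey, function(x) {
      if (all(is.na(x))) NA_integer_ else max(x, na.rm = TRUE)
    })
    has_sec <- key %in% names(best_nm)
    gap <- rep(NA_real_, nrow(prim))
    i <- which(has_sec)
    gap[i] <- as.numeric(best_nm[key[i]]) - as.numeric(prim$nm[i])
    as_gap <- as.numeric(prim$score[i]) - as.numeric(best_as[key[i]])
    gap[i] <- ifelse(is.na(gap[i]), as_gap, gap[i])
    untestable <- has_sec & is.na(gap)
    ambiguous <- has_sec & !is.na(gap) & gap < min_score_gap
    n_ambig <- sum(ambiguous)
    n_untest <- sum(untestable)
    if (n_untest) {
      warning(n_untest, " record(s) with secondaries lack NM and AS tags; ",
              "dropped", call. = FALSE)
    }
    prim <- prim[!ambiguous & !untestable, ]
  }
  clips <- cigar_clips(prim$cigar)
  adj_start <- ifelse(prim$is_reverse,
                      prim$pos + cigar_ref_span(prim$cigar) - 1L +
                        clips$right,
                      prim$pos - clips$left)
  dup_key <- paste(prim$rname, adj_start, prim$is_reverse, prim$is_first,
                   prim$rnext, prim$pnext)
  qmean <- mean_base_quality(prim$qual)
  ord <- order(dup_key, -qmean)
  dups <- duplicated(dup_key[ord])
  keep <- sort(ord[!dups])
  out <- prim[keep, ]
  attr(out, "dedup_counts") <- c(n_ambiguous = n_ambig,
                                 n_duplicates = nrow(prim) - length(keep),
                                 n_untestable = n_untest)
  attr(out, "sq") <- attr(aln, "sq")
  out
}

mean_base_quality <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || q == "*" || !nzchar(q)) return(0)
    mean(as.integer(charToRaw(q)) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Pileup genotyping of aligned reads
#'
#' Per reference position, counts bases (dropping those under `min_bq`),
#' splits alternative-allele counts by strand, and records mean mapping
#' quality and the MQ0 fraction. An SNV candidate is emitted where the
#' plurality non-reference base reaches `min_alt` reads; insertion and
#' deletion candidates come from `I`/`D` CIGAR operations, anchored at the
#' preceding reference base (left-aligned anchored-base convention). The
#' output is a raw (unfiltered) call set for [filter_callset()].
#'
#' This is a deliberate simplification of a likelihood-based caller: no
#' genotype likelihoods are computed and `qual` is left `NA`.
#'
#' @param aln Alignment tibble (run [dedup_primary_unique()] first).
#' @param genome FASTA tibble of the reference.
#' @param min_bq Minimum base quality for a base to count.
#' @param min_alt Minimum supporting reads to emit a candidate.
#' @return Variant tibble (see [read_vcf()] for columns).
#' @export
pileup_genotype <- function(aln, genome, min_bq = 20L, min_alt = 2L) {
  keep <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_duplicate &
                !aln$is_unmapped, ]
  bad_chrom <- setdiff(unique(keep$rname), genome$id)
  if (length(bad_chrom)) {
    stop("alignment reference(s) missing from genome: ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }
  out <- lapply(genome$id, function(ch) {
    sel <- keep[keep$rname == ch, ]
    if (!nrow(sel)) return(NULL)
    pileup_chrom(sel, genome$seq[match(ch, genome$id)], ch, min_bq, min_alt)
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(empty_variants())
  res %>% dplyr::arrange(.data$chrom, .data$pos)
}

pileup_chrom <- function(sel, refseq, ch, min_bq, min_alt) {
  simple <- grepl("^[0-9]+M$", sel$cigar)
  parts <- list()
  if (any(simple)) {
    s <- sel[simple, ]
    rl <- nchar(s$seq)
    parts[[1]] <- data.table::data.table(
      pos = rep(s$pos, rl) + sequence(rl) - 1L,
      base = unlist(strsplit(paste(s$seq, collapse = ""), "", fixed = TRUE)),
      bq = as.integer(charToRaw(paste(s$qual, collapse = ""))) - 33L,
      rev = rep(s$is_reverse, rl),
      mapq = rep(s$mapq, rl)
    )
  }
  indels <- list()
  if (any(!simple)) {
    s <- sel[!simple, ]
    ops <- cigar_ops(s$cigar)
    rows <- vector("list", nrow(s))
    irows <- vector("list", nrow(s))
    for (i in seq_len(nrow(s))) {
      tb <- ops[[i]]
      rpos <- s$pos[i]; qpos <- 1L
      m_ref <- integer(0); m_q <- integer(0)
      ind <- list()
      for (r in seq_len(nrow(tb))) {
        op <- tb$op[r]; w <- tb$len[r]
        if (op %in% c("M", "=", "X")) {
          m_ref <- c(m_ref, rpos:(rpos + w - 1L))
          m_q <- c(m_q, qpos:(qpos + w - 1L))
          rpos <- rpos + w; qpos <- qpos + w
        } else if (op %in% c("S", "H")) {
          if (op == "S") qpos <- qpos + w
        } else if (op == "I") {
          ind[[length(ind) + 1]] <- tibble(
            pos = rpos - 1L, vtype = "INS",
            alt_seq = substr(s$seq[i], qpos, qpos + w - 1L), del_len = 0L,
            rev = s$is_reverse[i])
          qpos <- qpos + w
        } else if (op %in% c("D", "N")) {
          if (op == "D") {
            ind[[length(ind) + 1]] <- tibble(
              pos = rpos - 1L, vtype = "DEL", alt_seq = "", del_len = w,
              rev = s$is_reverse[i])
          }
          rpos <- rpos + w
        }
      }
      rows[[i]] <- data.table::data.table(
        pos = m_ref,
        base = strsplit(s$seq[i], "", fixed = TRUE)[[1]][m_q],
        bq = (as.integer(charToRaw(s$qual[i])) - 33L)[m_q],
        rev = s$is_reverse[i], mapq = s$mapq[i]
      )
      if (length(ind)) irows[[i]] <- dplyr::bind_rows(ind)
    }
    parts[[2]] <- data.table::rbindlist(rows)
    indels <- irows
  }
  dt <- data.table::rbindlist(parts)
  if (!nrow(dt)) return(NULL)
  pos <- base <- bq <- mapq <- n <- nf <- NULL # data.table NSE
  mq <- dt[, list(mq_mean = mean(mapq), mq0f = mean(mapq == 0L)),
           by = pos]
  dt <- dt[bq >= min_bq & base %in% c("A", "C", "G", "T")]
  if (!nrow(dt)) return(NULL)
  tab <- dt[, list(n = .N, nf = sum(!rev)), by = list(pos, base)]
  depth <- tab[, list(depth = sum(n)), by = pos]
  refchar <- strsplit(refseq, "", fixed = TRUE)[[1]]
  tab[, "is_ref" := base == refchar[pos]]
  refc <- tab[tab$is_ref == TRUE, list(pos, ref_count = n)]
  alt <- tab[tab$is_ref == FALSE]
  if (nrow(alt)) {
    data.table::setorder(alt, pos, -n)
    alt <- alt[!duplicated(alt$pos)]
    alt <- alt[alt$n >= min_alt]
  }
  snv <- NULL
  if (nrow(alt)) {
    m <- merge(merge(alt, depth, by = "pos"), refc, by = "pos",
               all.x = TRUE)
    m <- merge(m, mq, by = "pos", all.x = TRUE)
    snv <- tibble(
      chrom = ch, pos = as.integer(m$pos), ref = refchar[m$pos],
      alt = m$base, qual = NA_real_, depth = as.integer(m$depth),
      ref_count = as.integer(dplyr::coalesce(m$ref_count, 0L)),
      alt_count = as.integer(m$n), alt_fwd = as.integer(m$nf),
      alt_rev = as.integer(m$n - m$nf), mq_mean = m$mq_mean,
      mq0f = m$mq0f, vtype = "SNV", info = "."
    )
  }
  ind_tb <- dplyr::bind_rows(indels)
  ind_out <- NULL
  if (!is.null(ind_tb) && nrow(ind_tb)) {
    grp <- ind_tb %>%
      dplyr::count(.data$pos, .data$vtype, .data$alt_seq, .data$del_len,
                   name = "n_sup") %>%
      dplyr::filter(.data$n_sup >= min_alt, .data$pos >= 1)
    if (nrow(grp)) {
      fwd <- ind_tb %>%
        dplyr::group_by(.data$pos, .data$vtype, .data$alt_seq,
                        .data$del_len) %>%
        dplyr::summarise(nf = sum(!.data$rev), .groups = "drop")
      grp <- dplyr::left_join(grp, fwd,
                              by = c("pos", "vtype", "alt_seq", "del_len"))
      dp <- depth$depth[match(grp$pos, depth$pos)]
      mqm <- mq$mq_mean[match(grp$pos, mq$pos)]
      mq0 <- mq$mq0f[match(grp$pos, mq$pos)]
      anchor <- refchar[grp$pos]
      ind_out <- tibble(
        chrom = ch, pos = as.integer(grp$pos), ref = ifelse(
          grp$vtype == "DEL",
          paste0(anchor, substring(refseq, grp$pos + 1L,
                                   grp$pos + grp$del_len)),
          anchor),
        alt = ifelse(grp$vtype == "DEL", anchor,
                     paste0(anchor, grp$alt_seq)),
        qual = NA_real_,
        depth = as.integer(dplyr::coalesce(dp, grp$n_sup)),
        ref_count = as.integer(pmax(dplyr::coalesce(dp, grp$n_sup) -
                                      grp$n_sup, 0L)),
        alt_count = as.integer(grp$n_sup), alt_fwd = as.integer(grp$nf),
        alt_rev = as.integer(grp$n_sup - grp$nf),
        mq_mean = dplyr::coalesce(mqm, NA_real_),
        mq0f = dplyr::coalesce(mq0, NA_real_), vtype = grp$vtype,
        info = "."
      )
    }
  }
  dplyr::bind_rows(snv, ind_out)
}
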