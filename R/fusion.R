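#' Detect transgene-host fusion transcript read pairs
#'
#' Scans alignments against a transcriptome-plus-cassettes reference for
#' read pairs with one mate on a transgene cassette ("insert mate") and the
#' other on a host transcript ("host mate"). Reads should be pre-cropped
#' (see [transform_reads()], `crop_to = 36`) when they come from a real
#' end-to-end mapping, so junction-spanning mates still align.
#'
#' @param aln Alignment tibble against transcript + cassette references.
#' @param models Gene-model tibble (for exon indexing of the host mate).
#' @param cassettes Character vector of cassette reference names; the
#'   construct label is the name with a trailing `"_cassette"` stripped.
#' @return Tibble of fusion evidence: one row per (gene, construct, exon)
#'   with `gene_id`, `transcript_id`, `construct`, `exon_index`, `pairs`.
#' @export
find_fusion_pairs <- function(aln, models, cassettes) {
  tx_ids <- unique(models$transcript_id)
  if (any(cassettes %in% tx_ids)) {
    stop("cassette reference names collide with transcript ids",
         call. = FALSE)
  }
  prim <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_unmapped &
                aln$is_paired, ]
  m1 <- prim[prim$is_first, ]
  m2 <- prim[!prim$is_first, ]
  j <- match(m1$qname, m2$qname)
  ok <- !is.na(j)
  m1 <- m1[ok, ]; m2 <- m2[j[ok], ]
  c1 <- m1$rname %in% cassettes; c2 <- m2$rname %in% cassettes
  t1 <- m1$rname %in% tx_ids; t2 <- m2$rname %in% tx_ids
  fus <- (c1 & t2) | (c2 & t1)
  if (!any(fus)) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  construct = character(), exon_index = integer(),
                  pairs = integer()))
  }
  ins <- dplyr::bind_rows(m1[fus & c1, ], m2[fus & c2, ])
  hst <- dplyr::bind_rows(m2[fus & c1, ], m1[fus & c2, ])
  exon_idx <- vapply(seq_len(nrow(hst)), function(i) {
    host_mate_exon(models, hst$rname[i], hst$pos[i],
                   hst$pos[i] + cigar_ref_span(hst$cigar[i]) - 1L)
  }, integer(1))
  tx2gene <- models %>%
    dplyr::distinct(.data$transcript_id, .data$gene_id)
  tibble(
    transcript_id = hst$rname,
    construct = sub("_cassette$", "", ins$rname),
    exon_index = exon_idx
  ) %>%
    dplyr::left_join(tx2gene, by = "transcript_id") %>%
    dplyr::count(.data$gene_id, .data$transcript_id, .data$construct,
                 .data$exon_index, name = "pairs") %>%
    dplyr::arrange(.data$gene_id, .data$construct, .data$exon_index)
}

# exon index (transcript orientation) maximally overlapped by a
# transcript-space interval
host_mate_exon <- function(models, transcript_id, t_start, t_end) {
  bm <- transcript_block_map(models, transcript_id)
  ov <- pmax(0L, pmin(t_end, bm$t_end) - pmax(t_start, bm$t_start) + 1L)
  if (all(ov == 0L)) NA_integer_ else which.max(ov)
}

#' Summarise fusion evidence per gene and construct
#'
#' @param fusion_pairs Output of [find_fusion_pairs()].
#' @return Tibble `gene_id`, `transcript_id`, `construct`,
#'   `supporting_pairs`, `min_exon` (most 5' exon hit).
#' @export
fusion_evidence <- function(fusion_pairs) {
  if (!nrow(fusion_pairs)) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  construct = character(), supporting_pairs = integer(),
                  min_exon = integer()))
  }
  fusion_pairs %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$construct) %>%
    dplyr::summarise(supporting_pairs = sum(.data$pairs),
                     min_exon = min(.data$exon_index, na.rm = TRUE),
                     .groups = "drop")
}

#' Mean per-exon depth of a transcript from spliced genome alignments
#'
#' @param aln Spliced alignment tibble against the genome.
#' @param models Gene-model tibble.
#' @param transcript_id Transcript to profile.
#' @param sample_label Optional label attached to the result.
#' @return Tibble `exon_index` (transcript orientation), `chrom`, `start`,
#'   `end`, `mean_depth`, `sample`.
#' @export
per_exon_coverage <- function(aln, models, transcript_id,
                              sample_label = NA_character_) {
  bm <- transcript_block_map(models, transcript_id)
  keep <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_duplicate &
                !aln$is_unmapped & aln$rname %in% bm$ref, ]
  blocks <- alignment_blocks(keep)
  depth_sum <- vapply(seq_len(nrow(bm)), function(i) {
    sel <- blocks[blocks$chrom == bm$ref[i], ]
    if (!nrow(sel)) return(0)
    sum(pmax(0L, pmin(sel$end, bm$ref_end[i]) -
               pmax(sel$start, bm$ref_start[i]) + 1L))
  }, numeric(1))
  w <- bm$ref_end - bm$ref_start + 1L
  tibble(exon_index = seq_len(nrow(bm)), chrom = bm$ref,
         start = bm$ref_start, end = bm$ref_end,
         mean_depth = depth_sum / w, sample = sample_label)
}

#' Call disruption zygosity of a gene from transcript evidence
#'
#' Wild-type support counts sequencing templates that connect the exons
#' flanking the insertion intron (exon `k` and exon `k + 1` in transcript
#' orientation): read pairs with one mate on each exon, plus (by default)
#' single reads splice-mapped across that intron. A gene is called
#' homozygously disrupted only when wild-type support is exactly zero,
#' fusion support reaches `min_fusion_support`, and both flanking exons have
#' at least `min_depth` mean coverage (guarding against calling homozygosity
#' from missing data).
#'
#' @param aln Spliced alignment tibble against the genome.
#' @param models Gene-model tibble.
#' @param transcript_id Transcript of the candidate disrupted gene.
#' @param intron_index Insertion intron `k` (between exon `k` and `k + 1`,
#'   transcript orientation).
#' @param fusion_pairs Number of fusion-supporting read pairs for this gene.
#' @param min_fusion_support Fusion pairs required to call disruption.
#' @param min_depth Minimum mean depth on both flanking exons for a hom call.
#' @param count_spliced_singles Also count single splice-mapped reads as
#'   wild-type evidence (strict pairs-only mode when `FALSE`).
#' @return One-row tibble: `gene_id`, `state` (`hom_disrupted`,
#'   `het_disrupted`, `intact`, `undetermined`), `wildtype_junction_pairs`,
#'   `fusion_pairs`.
#' @export
call_disruption_zygosity <- function(aln, models, transcript_id,
                                     intron_index, fusion_pairs,
                                     min_fusion_support = 3L,
                                     min_depth = 10L,
                                     count_spliced_singles = TRUE) {
  bm <- transcript_block_map(models, transcript_id)
  if (intron_index < 1 || intron_index >= nrow(bm)) {
    stop("intron index out of range for ", transcript_id, call. = FALSE)
  }
  ek <- bm[intron_index, ]; ek1 <- bm[intron_index + 1L, ]
  prim <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_unmapped, ]
  blocks <- alignment_blocks(prim)
  hits_exon <- function(exon) {
    sel <- blocks$chrom == exon$ref & blocks$start <= exon$ref_end &
      blocks$end >= exon$ref_start
    unique(blocks$row_id[sel])
  }
  in_k <- hits_exon(ek); in_k1 <- hits_exon(ek1)
  # spliced single reads touching both flanking exons
  spliced <- intersect(in_k, in_k1)
  spliced_templates <- unique(prim$qname[spliced])
  # mate pairs: one mate per exon
  key_k <- unique(prim$qname[in_k])
  key_k1 <- unique(prim$qname[in_k1])
  pair_templates <- setdiff(intersect(key_k, key_k1), spliced_templates)
  wt <- length(pair_templates) +
    if (count_spliced_singles) length(spliced_templates) else 0L
  cov <- per_exon_coverage(aln, models, transcript_id)
  depth_ok <- all(cov$mean_depth[c(intron_index, intron_index + 1L)] >=
                    min_depth)
  gene_id <- models$gene_id[match(transcript_id, models$transcript_id)]
  state <- if (fusion_pairs >= min_fusion_support && wt == 0L) {
    if (depth_ok) "hom_disrupted" else "undetermined"
  } else if (fusion_pairs >= min_fusion_support && wt > 0L) {
    "het_disrupted"
  } else if (wt > 0L) {
    "intact"
  } else {
    "undetermined"
  }
  tibble(gene_id = gene_id, state = state,
         wildtype_junction_pairs = as.integer(wt),
         fusion_pairs = as.integer(fusion_pairs))
}

#' Assign constructs to candidate insertion sites via fusion evidence
#'
#' A candidate whose scaffold carries a gene with fusion evidence for
#' construct X is assigned X directly; when exactly one candidate and one
#' construct remain, the leftover construct is assigned by elimination and
#' flagged. Contradictory evidence (two constructs fused to one gene)
#' leaves the candidate unassigned with a conflict flag.
#'
#' @param candidates Candidate tibble from [cluster_candidates()].
#' @param evidence Fusion evidence tibble from [fusion_evidence()].
#' @param models Gene-model tibble (locates each evidenced gene's scaffold).
#' @param constructs List of [transgene_spec()] objects (the full construct
#'   set).
#' @return `candidates` with `assigned_construct`, `assignment`
#'   (`direct` / `elimination` / `NA`) and `conflict` columns.
#' @export
assign_constructs <- function(candidates, evidence, models, constructs) {
  cn <- construct_names(constructs)
  out <- candidates
  out$assigned_construct <- NA_character_
  out$assignment <- NA_character_
  out$conflict <- FALSE
  if (nrow(evidence)) {
    gene_scaf <- models %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(chrom = .data$chrom[1], .groups = "drop")
    ev <- evidence %>% dplyr::left_join(gene_scaf, by = "gene_id")
    for (i in seq_len(nrow(out))) {
      hit <- ev[ev$chrom == out$scaffold[i], ]
      if (!nrow(hit)) next
      if (length(unique(hit$construct)) > 1) {
        out$conflict[i] <- TRUE
      } else {
        out$assigned_construct[i] <- hit$construct[1]
        out$assignment[i] <- "direct"
      }
    }
  }
  left_cand <- which(is.na(out$assigned_construct) & !out$conflict)
  left_cons <- setdiff(cn, out$assigned_construct)
  if (length(left_cand) == 1 && length(left_cons) == 1 &&
      any(!is.na(out$assigned_construct))) {
    out$assigned_construct[left_cand] <- left_cons
    out$assignment[left_cand] <- "elimination"
  }
  out
}
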