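#' Build expression hints from spliced alignments
#'
#' Exonpart hints are maximal runs of constant read coverage (from
#' reference-consuming blocks, introns excluded); intron hints are identical
#' `N`-operation spans with their support counts. Hint coverage is clamped
#' into `[clamp[1], clamp[2]]` (mode `"clip"`) or hints under the floor are
#' dropped entirely (mode `"drop"`). With several sources, per-position
#' exonpart coverage and duplicated intron spans are taken from the
#' highest-priority source.
#'
#' @param aln_sources A single alignment tibble, or a named list of them in
#'   priority order (first wins conflicts).
#' @param clamp `c(floor, ceiling)` for hint coverage.
#' @param floor_mode `"clip"` or `"drop"`.
#' @return Hint tibble: `kind` (`exonpart`/`intron`), `chrom`, `start`,
#'   `end`, `coverage`, `source`, `source_priority`.
#' @export
build_hints <- function(aln_sources, clamp = c(20L, 300L),
                        floor_mode = c("clip", "drop")) {
  floor_mode <- match.arg(floor_mode)
  if (is.data.frame(aln_sources)) {
    aln_sources <- list(main = aln_sources)
  }
  if (is.null(names(aln_sources))) {
    names(aln_sources) <- paste0("source", seq_along(aln_sources))
  }
  per_source <- purrr::imap(aln_sources, function(aln, src) {
    prim <- aln[!aln$is_secondary & !aln$is_supplementary &
                  !aln$is_unmapped, ]
    blocks <- alignment_blocks(prim)
    ex <- exonpart_segments(blocks)
    introns <- intron_spans(prim)
    ex$kind <- "exonpart"
    if (nrow(introns)) introns$kind <- "intron"
    out <- dplyr::bind_rows(ex, introns)
    out$source <- src
    out
  })
  for (i in seq_along(per_source)) {
    per_source[[i]]$source_priority <- i
  }
  hints <- dplyr::bind_rows(per_source)
  if (!nrow(hints)) return(hints)
  # conflict resolution: identical intron spans -> highest priority;
  # overlapping exonparts -> highest-priority source wins the overlap
  hints <- hints %>%
    dplyr::arrange(.data$source_priority) %>%
    dplyr::group_by(.data$kind, .data$chrom, .data$start, .data$end) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup()
  if (length(per_source) > 1) {
    ex <- hints[hints$kind == "exonpart", ]
    keep <- rep(TRUE, nrow(ex))
    for (i in seq_len(nrow(ex))) {
      higher <- ex[ex$source_priority < ex$source_priority[i] &
                     ex$chrom == ex$chrom[i], ]
      if (nrow(higher) &&
          interval_overlap_length(ex[i, ], higher) > 0) {
        keep[i] <- FALSE
      }
    }
    hints <- dplyr::bind_rows(ex[keep, ], hints[hints$kind == "intron", ])
  }
  if (floor_mode == "drop") {
    hints <- hints[hints$coverage >= clamp[1], ]
  }
  hints$coverage <- pmin(pmax(hints$coverage, clamp[1]), clamp[2])
  hints %>% dplyr::arrange(.data$kind, .data$chrom, .data$start)
}

exonpart_segments <- function(blocks) {
  res <- list()
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, ]
    cov <- IRanges::coverage(IRanges::IRanges(b$start, b$end))
    rl <- S4Vectors::runLength(cov)
    rv <- S4Vectors::runValue(cov)
    en <- cumsum(rl)
    st <- en - rl + 1L
    nz <- rv > 0
    res[[ch]] <- tibble(chrom = ch, start = st[nz], end = en[nz],
                        coverage = as.integer(rv[nz]))
  }
  dplyr::bind_rows(res)
}

intron_spans <- function(aln) {
  has_n <- grepl("N", aln$cigar, fixed = TRUE)
  if (!any(has_n)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  coverage = integer()))
  }
  sel <- aln[has_n, ]
  ops <- cigar_ops(sel$cigar)
  rows <- purrr::imap(ops, function(tb, i) {
    consume <- tb$op %in% c("M", "D", "N", "=", "X")
    offs <- cumsum(c(0L, tb$len * consume))
    ns <- which(tb$op == "N")
    tibble(chrom = sel$rname[i],
           start = sel$pos[i] + offs[ns],
           end = sel$pos[i] + offs[ns] + tb$len[ns] - 1L)
  })
  dplyr::bind_rows(rows) %>%
    dplyr::count(.data$chrom, .data$start, .data$end, name = "coverage")
}

#' Filter a predicted gene set
#'
#' A transcript is retained iff (1) at least `min_hint_support` of its
#' exonic length is covered by exonpart hints, (2) its CDS overlaps the
#' merged repeat track by at most `max_te_cds_overlap_nt` bases in total,
#' and (3) its peptide is at least `min_peptide_aa` amino acids. The
#' rejection ledger names every failed rule per dropped transcript.
#'
#' @param models Gene-model tibble.
#' @param hints Hint tibble from [build_hints()].
#' @param repeat_track Interval tibble of annotated repeats/TEs.
#' @param min_hint_support Minimum hint-covered exonic fraction.
#' @param max_te_cds_overlap_nt Maximum summed CDS-repeat overlap.
#' @param min_peptide_aa Minimum peptide length.
#' @param protein_lengths Optional tibble (`transcript_id`, `length_aa`);
#'   defaults to `floor(CDS length / 3) - 1`.
#' @return List: `retained` (model tibble), `ledger` (tibble
#'   `transcript_id`, `retained`, `hint_fraction`, `te_overlap_nt`,
#'   `peptide_aa`, `failed_rules`).
#' @export
filter_gene_set <- function(models, hints, repeat_track,
                            min_hint_support = 0.01,
                            max_te_cds_overlap_nt = 10L,
                            min_peptide_aa = 10L,
                            protein_lengths = NULL) {
  exhints <- hints[hints$kind == "exonpart", ]
  reps <- interval_merge(repeat_track)
  led <- models %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::group_map(function(tb, key) {
      ex <- tb[tb$type == "exon", ]
      cds <- tb[tb$type == "cds", ]
      exlen <- sum(ex$end - ex$start + 1L)
      hint_cov <- sum(interval_overlap_length(ex, exhints))
      te_ov <- sum(interval_overlap_length(cds, reps))
      pep <- if (!is.null(protein_lengths) &&
                   key$transcript_id %in% protein_lengths$transcript_id) {
        protein_lengths$length_aa[
          match(key$transcript_id, protein_lengths$transcript_id)]
      } else {
        max(0L, floor(sum(cds$end - cds$start + 1L) / 3) - 1L)
      }
      tibble(transcript_id = key$transcript_id,
             hint_fraction = hint_cov / exlen,
             te_overlap_nt = as.integer(te_ov),
             peptide_aa = as.integer(pep))
    }) %>%
    dplyr::bind_rows() %>%
    dplyr::mutate(
      fail_hint = .data$hint_fraction < min_hint_support,
      fail_te = .data$te_overlap_nt > max_te_cds_overlap_nt,
      fail_pep = .data$peptide_aa < min_peptide_aa,
      retained = !(.data$fail_hint | .data$fail_te | .data$fail_pep),
      failed_rules = purrr::pmap_chr(
        list(.data$fail_hint, .data$fail_te, .data$fail_pep),
        function(h, t, p) {
          paste(c(if (h) "hint_support", if (t) "te_overlap",
                  if (p) "short_peptide"), collapse = ",")
        })
    ) %>%
    dplyr::select("transcript_id", "retained", "hint_fraction",
                  "te_overlap_nt", "peptide_aa", "failed_rules")
  keep_tx <- led$transcript_id[led$retained]
  list(retained = models[models$transcript_id %in% keep_tx, ],
       ledger = led)
}

#' Gene-set summary metrics
#'
#' The twelve descriptive statistics of a gene set: gene and transcript
#' counts, multi-isoform genes, transcripts with both start and stop codon
#' (from `has_start`/`has_stop` columns when present), average gene length
#' (span including introns), average transcript length (summed exons),
#' average exons per transcript, single-exon transcripts, average exon, CDS
#' exon and intron lengths, and average protein length.
#'
#' @param models Gene-model tibble (optionally with `has_start`,
#'   `has_stop` logical columns on its rows).
#' @param protein_lengths Optional tibble (`transcript_id`, `length_aa`).
#' @return One-row tibble of the twelve metrics.
#' @export
geneset_metrics <- function(models, protein_lengths = NULL) {
  ex <- models[models$type == "exon", ]
  cds <- models[models$type == "cds", ]
  if (!nrow(ex)) stop("no exons in gene set", call. = FALSE)
  per_tx <- ex %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id) %>%
    dplyr::summarise(
      n_exons = dplyr::n(),
      tx_len = sum(.data$end - .data$start + 1L),
      span = max(.data$end) - min(.data$start) + 1L,
      .groups = "drop"
    )
  # introns as gaps between consecutive exons
  introns <- ex %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::summarise(gaps = list(.data$start[-1] -
                                   utils::head(.data$end, -1) - 1L)) %>%
    dplyr::pull(.data$gaps) %>%
    unlist()
  per_gene <- models %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(glen = max(.data$end) - min(.data$start) + 1L,
                     n_tx = dplyr::n_distinct(.data$transcript_id))
  pep <- if (!is.null(protein_lengths)) {
    protein_lengths$length_aa
  } else if (nrow(cds)) {
    cds %>%
      dplyr::group_by(.data$transcript_id) %>%
      dplyr::summarise(aa = floor(sum(.data$end - .data$start + 1L) / 3) -
                         1L) %>%
      dplyr::pull(.data$aa)
  } else {
    NA_integer_
  }
  has_flags <- all(c("has_start", "has_stop") %in% names(models))
  n_startstop <- if (has_flags) {
    models %>%
      dplyr::distinct(.data$transcript_id, .data$has_start,
                      .data$has_stop) %>%
      dplyr::summarise(n = sum(.data$has_start & .data$has_stop)) %>%
      dplyr::pull(.data$n)
  } else {
    NA_integer_
  }
  tibble(
    n_genes = nrow(per_gene),
    n_transcripts = nrow(per_tx),
    n_multi_isoform_genes = sum(per_gene$n_tx > 1),
    n_with_start_and_stop = n_startstop,
    avg_gene_length_nt = mean(per_gene$glen),
    avg_transcript_length_nt = mean(per_tx$tx_len),
    avg_exons_per_transcript = mean(per_tx$n_exons),
    n_single_exon_transcripts = sum(per_tx$n_exons == 1),
    avg_exon_length_nt = mean(ex$end - ex$start + 1L),
    avg_cds_exon_length_nt = if (nrow(cds)) {
      mean(cds$end - cds$start + 1L)
    } else NA_real_,
    avg_intron_length_nt = if (length(introns)) mean(introns) else NA_real_,
    avg_protein_length_aa = mean(pep)
  )
}

#' Query fraction covered by mutually compatible HSPs
#'
#' The aligned fraction of a homology hit is the largest share of the query
#' coverable by pairwise non-overlapping HSPs, found by weighted-interval
#' scheduling that maximizes covered length.
#'
#' @param hsps Tibble with 1-based closed query coordinates `qstart`,
#'   `qend`.
#' @param query_length Query length (same units as the coordinates).
#' @return Fraction in `[0, 1]`.
#' @examples
#' aligned_fraction_mchsp(tibble::tibble(qstart = 1, qend = 70), 100)  # 0.7
#' @export
aligned_fraction_mchsp <- function(hsps, query_length) {
  stopifnot(query_length >= 1)
  if (!nrow(hsps)) return(0)
  if (any(hsps$qstart < 1 | hsps$qend > query_length |
            hsps$qend < hsps$qstart)) {
    stop("HSP outside [1, query_length]", call. = FALSE)
  }
  o <- order(hsps$qend)
  s <- hsps$qstart[o]; e <- hsps$qend[o]
  w <- e - s + 1
  n <- length(s)
  p <- vapply(seq_len(n), function(i) {
    j <- which(e < s[i])
    if (length(j)) max(j) else 0L
  }, integer(1))
  f <- numeric(n + 1)
  for (i in seq_len(n)) {
    f[i + 1] <- max(f[i], w[i] + f[p[i] + 1])
  }
  f[n + 1] / query_length
}

#' Tiered homology-annotation cascade
#'
#' Queries are mapped against taxonomically ranked databases in order; each
#' query takes its best passing hit (lowest E-value, then highest bitscore)
#' from the earliest tier with one, and falls through otherwise. A hit
#' passes with E-value at most `max_evalue`, alignment length at least
#' `min_aln_aa`, identity at least `min_identity`, an aligned-fraction test
#' (see `af_comparator`), and a description not matching the descriptor
#' blacklist.
#'
#' The aligned-fraction criterion ships in two modes: the replication
#' default `"max"` keeps hits with fraction <= `af_cutoff` (0.90); mode
#' `"min"` keeps hits with fraction >= `af_cutoff` instead (a floor such as
#' 0.70 is the usual reading of a coverage filter). The mode used is
#' recorded in the output.
#'
#' @param tiers Named list of hit tables in tier order; columns `query_id`,
#'   `subject_id`, `evalue`, `identity_pct`, `aln_length_aa`, `bitscore`,
#'   `qstart`, `qend`, `description` (one row per HSP).
#' @param query_lengths Tibble `query_id`, `length_aa`.
#' @param max_evalue,min_aln_aa,min_identity Pass thresholds.
#' @param af_comparator `"max"` or `"min"`; `af_cutoff` its cutoff.
#' @param blacklist Descriptor regexes that disqualify a hit.
#' @return List: `annotations` (tibble `query_id`, `tier`, `subject_id`,
#'   `description`, `evalue`, `identity_pct`, `aligned_fraction`),
#'   `unannotated` (character), `params`.
#' @export
annotate_cascade <- function(tiers, query_lengths, max_evalue = 1e-10,
                             min_aln_aa = 70L, min_identity = 90,
                             af_comparator = c("max", "min"),
                             af_cutoff = 0.90,
                             blacklist = c("uncharacterized", "unknown",
                                           "hypothetical")) {
  af_comparator <- match.arg(af_comparator)
  if (!length(tiers)) stop("empty tier list", call. = FALSE)
  if (is.null(names(tiers))) names(tiers) <- paste0("tier", seq_along(tiers))
  pending <- query_lengths$query_id
  ann <- list()
  bl_re <- paste(blacklist, collapse = "|")
  for (tname in names(tiers)) {
    if (!length(pending)) break
    hits <- tiers[[tname]]
    hits <- hits[hits$query_id %in% pending, ]
    if (!nrow(hits)) next
    per_subject <- hits %>%
      dplyr::group_by(.data$query_id, .data$subject_id) %>%
      dplyr::group_modify(function(tb, key) {
        qlen <- query_lengths$length_aa[
          match(key$query_id, query_lengths$query_id)]
        tibble(
          evalue = min(tb$evalue),
          identity_pct = max(tb$identity_pct),
          aln_length_aa = max(tb$aln_length_aa),
          bitscore = max(tb$bitscore),
          description = tb$description[1],
          aligned_fraction = aligned_fraction_mchsp(
            tb[, c("qstart", "qend")], qlen)
        )
      }) %>%
      dplyr::ungroup()
    af_pass <- if (af_comparator == "max") {
      per_subject$aligned_fraction <= af_cutoff
    } else {
      per_subject$aligned_fraction >= af_cutoff
    }
    pass <- per_subject[per_subject$evalue <= max_evalue &
                          per_subject$aln_length_aa >= min_aln_aa &
                          per_subject$identity_pct >= min_identity &
                          af_pass &
                          !grepl(bl_re, per_subject$description,
                                 ignore.case = TRUE), ]
    if (!nrow(pass)) next
    best <- pass %>%
      dplyr::group_by(.data$query_id) %>%
      dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                     .by_group = TRUE) %>%
      dplyr::slice(1L) %>%
      dplyr::ungroup() %>%
      dplyr::mutate(tier = tname)
    ann[[tname]] <- best
    pending <- setdiff(pending, best$query_id)
  }
  annotations <- if (length(ann)) {
    dplyr::bind_rows(ann) %>%
      dplyr::select("query_id", "tier", "subject_id", "description",
                    "evalue", "identity_pct", "aligned_fraction")
  } else {
    tibble(query_id = character(), tier = character(),
           subject_id = character(), description = character(),
           evalue = numeric(), identity_pct = numeric(),
           aligned_fraction = numeric())
  }
  list(annotations = annotations, unannotated = pending,
       params = list(max_evalue = max_evalue, min_aln_aa = min_aln_aa,
                     min_identity = min_identity,
                     af_comparator = af_comparator, af_cutoff = af_cutoff))
}
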