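#' Estimate insert-size bounds from proper pairs
#'
#' Quantile bounds of observed template lengths, the desk equivalent of
#' estimating a mapper's `-I`/`-X` insert bounds from a read-pair subset.
#'
#' @param aln Alignment tibble.
#' @param lower_q,upper_q Quantiles defining the bounds.
#' @return Named numeric vector `c(min_insert, max_insert)`.
#' @export
estimate_insert_bounds <- function(aln, lower_q = 0.001, upper_q = 0.999) {
  tl <- aln$tlen[aln$is_proper & !aln$is_secondary & !aln$is_supplementary &
                   aln$tlen > 0]
  if (!length(tl)) stop("no proper pairs to estimate insert size from",
                        call. = FALSE)
  q <- stats::quantile(tl, c(lower_q, upper_q), names = FALSE)
  c(min_insert = q[1], max_insert = q[2])
}

construct_names <- function(constructs) {
  vapply(constructs, `[[`, character(1), "name")
}

# segment (P/C/T) with maximal overlap of [start,end] on the construct
construct_segment <- function(construct, start, end) {
  seg <- construct$segments
  seg <- seg[seg$segment %in% c("P", "C", "T"), ]
  ov <- pmax(0L, pmin(end, seg$end) - pmax(start, seg$start) + 1L)
  if (all(ov == 0L)) NA_character_ else seg$segment[which.max(ov)]
}

#' Classify transgene-bridging read pairs
#'
#' A bridging pair has one primary mate on a host scaffold and the other on
#' a construct; the construct-mapped mate is labeled by the construct
#' segment (P promoter / C cassette / T terminator) it maximally overlaps.
#'
#' @param aln Alignment tibble against the combined host + construct
#'   reference (primary records are used; secondary and supplementary
#'   records are ignored).
#' @param constructs List of [transgene_spec()] objects.
#' @return Tibble of bridging pairs: `qname`, `chrom`, `start`, `end`
#'   (host-mate anchor span), `construct`, `segment`.
#' @export
classify_bridging_pairs <- function(aln, constructs) {
  cn <- construct_names(constructs)
  sq <- attr(aln, "sq")
  if (!is.null(sq) && !any(cn %in% sq$name)) {
    stop("none of the construct names occur in the alignment reference ",
         "dictionary: ", paste(cn, collapse = ", "), call. = FALSE)
  }
  prim <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_unmapped &
                aln$is_paired, ]
  on_construct <- prim$rname %in% cn
  # join mates: first mate vs second mate of the same template
  m1 <- prim[prim$is_first, ]
  m2 <- prim[!prim$is_first, ]
  j <- match(m1$qname, m2$qname)
  ok <- !is.na(j)
  m1 <- m1[ok, ]; m2 <- m2[j[ok], ]
  host1 <- !(m1$rname %in% cn); host2 <- !(m2$rname %in% cn)
  bridge <- xor(host1, host2)
  if (!any(bridge)) {
    return(tibble(qname = character(), chrom = character(), start = integer(),
                  end = integer(), construct = character(),
                  segment = character()))
  }
  hm <- dplyr::bind_rows(m1[bridge & host1, ], m2[bridge & host2, ])
  cm <- dplyr::bind_rows(m2[bridge & host1, ], m1[bridge & host2, ])
  seg <- vapply(seq_len(nrow(cm)), function(i) {
    cs <- constructs[[match(cm$rname[i], cn)]]
    construct_segment(cs, cm$pos[i],
                      cm$pos[i] + cigar_ref_span(cm$cigar[i]) - 1L)
  }, character(1))
  out <- tibble(
    qname = hm$qname, chrom = hm$rname, start = hm$pos,
    end = hm$pos + cigar_ref_span(hm$cigar) - 1L,
    construct = cm$rname, segment = seg
  )
  out[!is.na(out$segment), ] %>% dplyr::arrange(.data$chrom, .data$start)
}

#' Cluster bridging pairs into candidate insertion sites
#'
#' Pairs are grouped per scaffold into clusters whose host anchors lie
#' within `window` of each other; clusters supported by fewer than
#' `min_support` promoter + terminator pairs are excluded.
#'
#' @param bridge_pairs Output of [classify_bridging_pairs()].
#' @param min_support Minimum P + T pair support (default 10, the published
#'   exclusion rule: connections with fewer than 10 bridging pairs are
#'   dropped).
#' @param window Maximum gap between consecutive anchors of one cluster; a
#'   sensible default is twice the upper insert bound.
#' @return Candidate tibble: `scaffold`, `anchor_start`, `anchor_end`,
#'   `p_pairs`, `t_pairs`, `c_pairs`, `support`, `construct` (modal
#'   construct among the cluster's pairs).
#' @export
cluster_candidates <- function(bridge_pairs, min_support = 10L,
                               window = 1550L) {
  if (!nrow(bridge_pairs)) {
    return(tibble(scaffold = character(), anchor_start = integer(),
                  anchor_end = integer(), p_pairs = integer(),
                  t_pairs = integer(), c_pairs = integer(),
                  support = integer(), construct = character()))
  }
  bridge_pairs %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(cluster = cumsum(
      c(TRUE, diff(.data$start) > window))) %>%
    dplyr::group_by(.data$chrom, .data$cluster) %>%
    dplyr::summarise(
      anchor_start = min(.data$start), anchor_end = max(.data$end),
      p_pairs = sum(.data$segment == "P"),
      t_pairs = sum(.data$segment == "T"),
      c_pairs = sum(.data$segment == "C"),
      construct = names(sort(table(.data$construct), decreasing = TRUE))[1],
      .groups = "drop"
    ) %>%
    dplyr::mutate(support = .data$p_pairs + .data$t_pairs) %>%
    dplyr::filter(.data$support >= min_support) %>%
    dplyr::rename(scaffold = "chrom") %>%
    dplyr::select(-"cluster") %>%
    dplyr::arrange(.data$scaffold, .data$anchor_start)
}

#' Call junction positions from chimeric reads
#'
#' Works on host-side records of split reads: the junction is computed from
#' the leftmost mapping position by performing the CIGAR operations. A
#' record clipped at its 3' end places the junction at
#' `pos + cigar_ref_span - 1` (last aligned host base); a record clipped at
#' its 5' end places it at `pos`. Sides are labeled P or T from the
#' construct segment the clipped portion maps to, and the modal position per
#' side is reported with its support (ties break to the smaller coordinate
#' and are flagged).
#'
#' @param aln Alignment tibble containing the split reads (primary records
#'   with their supplementary counterparts, as selected by keeping primary
#'   alignments that have supplementary alignments).
#' @param scaffold Host scaffold of the candidate.
#' @param constructs List of [transgene_spec()] objects.
#' @param region Optional `c(from, to)` restricting the host window.
#' @return Tibble with one row per detected side: `scaffold`, `side`,
#'   `position`, `support`, `construct`, `tie`.
#' @export
call_junctions <- function(aln, scaffold, constructs, region = NULL) {
  cn <- construct_names(constructs)
  mapped <- aln[!aln$is_secondary & !aln$is_unmapped, ]
  host <- mapped[mapped$rname == scaffold, ]
  if (!is.null(region)) {
    host <- host[host$pos <= region[2] &
                   host$pos + cigar_ref_span(host$cigar) - 1L >= region[1], ]
  }
  clips <- cigar_clips(host$cigar)
  host <- host[clips$left > 0 | clips$right > 0, ]
  if (!nrow(host)) return(empty_junctions())
  # counterpart construct record of the same read (same mate of same template)
  consl <- mapped[mapped$rname %in% cn, ]
  consl_key <- paste(consl$qname, consl$is_first)
  calls <- purrr::map_dfr(seq_len(nrow(host)), function(i) {
    cand <- consl[consl_key == paste(host$qname[i], host$is_first[i]), ]
    if (!nrow(cand)) return(NULL)
    cand <- cand[1, ]
    cl <- cigar_clips(host$cigar[i])
    three_prime <- cl$right >= cl$left
    pos <- if (three_prime) {
      host$pos[i] + cigar_ref_span(host$cigar[i]) - 1L
    } else {
      host$pos[i]
    }
    cs <- constructs[[match(cand$rname, cn)]]
    seg <- construct_segment(cs, cand$pos,
                             cand$pos + cigar_ref_span(cand$cigar) - 1L)
    if (is.na(seg) || seg == "C") return(NULL)
    tibble(side = seg, position = as.integer(pos), construct = cand$rname)
  })
  if (is.null(calls) || !nrow(calls)) return(empty_junctions())
  calls %>%
    dplyr::count(.data$side, .data$position, .data$construct) %>%
    dplyr::group_by(.data$side) %>%
    dplyr::summarise(
      position = .data$position[which.max(.data$n)],
      support = max(.data$n),
      construct = .data$construct[which.max(.data$n)],
      tie = sum(.data$n == max(.data$n)) > 1,
      .groups = "drop"
    ) %>%
    dplyr::mutate(scaffold = scaffold) %>%
    dplyr::select("scaffold", "side", "position", "support", "construct",
                  "tie")
}

empty_junctions <- function() {
  tibble(scaffold = character(), side = character(), position = integer(),
         support = integer(), construct = character(), tie = logical())
}

#' Infer the lesion between two junction positions
#'
#' With the junction convention "last retained host base adjacent to the
#' construct" on each side, the host bases lost at the integration site are
#' `|pos_T - pos_P| - 1`: adjacent junctions (difference 1) mean a clean
#' insertion with no deletion, a positive count is a flanking deletion, and
#' overlapping junctions are flagged complex for manual review.
#'
#' @param junction_p,junction_t 1-based junction positions of the promoter-
#'   and terminator-side junctions on one scaffold.
#' @return A one-row tibble: `lesion` (`"none"`, `"deletion"`, `"complex"`)
#'   and `deleted` (bases lost; `NA` for complex).
#' @examples
#' infer_lesion(27872, 27901)  # 28-base deletion
#' @export
infer_lesion <- function(junction_p, junction_t) {
  stopifnot(length(junction_p) == 1, length(junction_t) == 1)
  d <- abs(junction_t - junction_p) - 1L
  if (d < 0) {
    tibble(lesion = "complex", deleted = NA_integer_)
  } else if (d == 0) {
    tibble(lesion = "none", deleted = 0L)
  } else {
    tibble(lesion = "deletion", deleted = as.integer(d))
  }
}

#' Per-position read depth over a region
#'
#' Depth counts primary, non-duplicate, mapped records through their
#' reference-consuming CIGAR operations (deleted reference bases remain
#' covered; skipped `N` gaps do not).
#'
#' @param aln Alignment tibble.
#' @param chrom Reference name.
#' @param from,to 1-based closed window; defaults to the reference length
#'   from the `@SQ` dictionary.
#' @return Tibble `pos`, `depth`.
#' @export
profile_coverage <- function(aln, chrom, from = 1L, to = NULL) {
  sq <- attr(aln, "sq")
  if (is.null(to)) {
    if (is.null(sq) || !chrom %in% sq$name) {
      stop("no @SQ length for ", chrom, "; supply `to`", call. = FALSE)
    }
    to <- sq$length[match(chrom, sq$name)]
  }
  if (!is.null(sq) && chrom %in% sq$name &&
      to > sq$length[match(chrom, sq$name)]) {
    stop("region beyond reference end", call. = FALSE)
  }
  keep <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_duplicate &
                !aln$is_unmapped & aln$rname == chrom, ]
  blocks <- alignment_blocks(keep)
  interval_depth(blocks, chrom, from, to)
}

#' Zygosity of an insertion from wild-type junction-spanning reads
#'
#' Counts reads that align continuously (no clipping) across the 5'
#' junction boundary with at least `margin` bases on either side: such reads
#' can only come from an unmodified haplotype. No spanning reads with
#' adequate local depth calls the insertion homozygous; `min_wildtype` or
#' more call it heterozygous.
#'
#' @param aln Alignment tibble (host + construct reference).
#' @param scaffold,junction 1-based position of the last retained host base.
#' @param margin Minimum aligned bases required on each side.
#' @param min_wildtype Spanning reads required to call het.
#' @param min_depth Minimum local depth for a confident hom call.
#' @return One-row tibble: `zygosity` (`hom`/`het`/`undetermined`),
#'   `wildtype_spanning`, `local_depth`.
#' @export
call_insertion_zygosity <- function(aln, scaffold, junction, margin = 5L,
                                    min_wildtype = 3L, min_depth = 10L) {
  prim <- aln[!aln$is_secondary & !aln$is_supplementary & !aln$is_unmapped &
                aln$rname == scaffold, ]
  ends <- prim$pos + cigar_ref_span(prim$cigar) - 1L
  clips <- cigar_clips(prim$cigar)
  spanning <- sum(clips$left == 0 & clips$right == 0 &
                    prim$pos <= junction - margin + 1L &
                    ends >= junction + margin)
  # local depth counts every mapped segment touching the junction
  # (including supplementary split-read parts), so a hom call is only made
  # where data actually reach the junction
  mapped <- aln[!aln$is_secondary & !aln$is_unmapped &
                  aln$rname == scaffold, ]
  mends <- mapped$pos + cigar_ref_span(mapped$cigar) - 1L
  near <- sum(mapped$pos <= junction & mends >= junction)
  zyg <- if (spanning == 0 && near >= min_depth) {
    "hom"
  } else if (spanning >= min_wildtype) {
    "het"
  } else {
    "undetermined"
  }
  tibble(zygosity = zyg, wildtype_spanning = as.integer(spanning),
         local_depth = as.integer(near))
}
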